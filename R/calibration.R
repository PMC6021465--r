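#' Calibrate computed activity coefficients against measured solubility
#'
#' Fits the linear calibration that turns infinite-dilution activity
#' coefficients of the solute in candidate solvents into predicted
#' solubilities: ordinary least squares of experimental solubility
#' (mg/mL) on `ln gamma` (default), or of `ln` solubility on `ln gamma`
#' (`form = "log"`), since the underlying relation is only known to be
#' close to linear. The fitted object behaves like a standard R model:
#' `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
#' `confint` methods are provided.
#'
#' @param records data frame with columns `nades_id`, `s_exp` (mg/mL,
#'   > 0) and `ln_gamma`; at least 3 rows, `ln_gamma` not all equal.
#' @param form `"linear"` (solubility on ln gamma) or `"log"`
#'   (log-solubility on ln gamma).
#' @return An object of class `nades_calibration` wrapping the
#'   underlying [stats::lm()] fit, with elements `slope`, `intercept`,
#'   `r_squared`, `n`, `form`, `records`, `fit`.
#' @examples
#' recs <- data.frame(nades_id = paste0("n", 1:5),
#'                    ln_gamma = c(-2, -1, 0, 1, 2),
#'                    s_exp = 2 * c(-2, -1, 0, 1, 2) + 5)
#' cal <- fit_calibration(recs)
#' coef(cal)
#' predict(cal, ln_gamma = 0.5)
#' @export
fit_calibration <- function(records, form = c("linear", "log")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(records),
            all(c("nades_id", "s_exp", "ln_gamma") %in% names(records)))
  if (nrow(records) < 3L) stop("calibration needs at least 3 training records")
  if (any(!is.finite(records$s_exp)) || any(records$s_exp <= 0))
    stop("experimental solubilities must be finite and > 0")
  if (any(!is.finite(records$ln_gamma))) stop("ln_gamma must be finite")
  if (diff(range(records$ln_gamma)) == 0)
    stop("degenerate predictor: all ln_gamma values identical")
  y <- if (form == "log") log(records$s_exp) else records$s_exp
  dat <- data.frame(y = y, ln_gamma = records$ln_gamma)
  fit <- stats::lm(y ~ ln_gamma, data = dat)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = nrow(records), form = form,
                 records = records, fit = fit),
            class = "nades_calibration")
}

#' @export
print.nades_calibration <- function(x, ...) {
  lhs <- if (x$form == "log") "ln s" else "s [mg/mL]"
  cat(sprintf("Solubility calibration (%s): %s = %.4g * ln(gamma_inf) + %.4g\n",
              x$form, lhs, x$slope, x$intercept))
  cat(sprintf("  n = %d NADES, R^2 = %.3f\n", x$n, x$r_squared))
  invisible(x)
}

#' @export
summary.nades_calibration <- function(object, ...) {
  s <- summary(object$fit, ...)
  cat(sprintf("Calibration of solubility on ln(gamma_inf), %s form, n = %d\n\n",
              object$form, object$n))
  print(s$coefficients)
  cat(sprintf("\nR^2 = %.4f, residual sd = %.4g\n", s$r.squared, s$sigma))
  invisible(s)
}

#' @export
coef.nades_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.nades_calibration <- function(object, ...) {
  stats::residuals(object$fit)
}

#' @export
confint.nades_calibration <- function(object, parm, level = 0.95, ...) {
  ci <- stats::confint(object$fit, level = level, ...)
  rownames(ci) <- c("intercept", "slope")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict solubility from a fitted calibration
#'
#' @param object a [fit_calibration()] model.
#' @param ln_gamma numeric vector (optionally named by NADES id) of
#'   computed `ln gamma` values; defaults to the training predictors.
#' @param ... unused.
#' @return Predicted solubilities, mg/mL (back-transformed for the log
#'   form).
#' @export
predict.nades_calibration <- function(object, ln_gamma = NULL, ...) {
  if (is.null(ln_gamma)) ln_gamma <- object$records$ln_gamma
  stopifnot(is.numeric(ln_gamma))
  y <- object$intercept + object$slope * ln_gamma
  out <- if (object$form == "log") exp(y) else y
  names(out) <- names(ln_gamma)
  out
}

#' @export
plot.nades_calibration <- function(x, ...) {
  ylab <- if (x$form == "log") "ln solubility" else "solubility (mg/mL)"
  y <- if (x$form == "log") log(x$records$s_exp) else x$records$s_exp
  graphics::plot(x$records$ln_gamma, y,
                 xlab = expression(ln ~ gamma^infinity), ylab = ylab, ...)
  graphics::abline(x$intercept, x$slope)
  graphics::mtext(sprintf("R^2 = %.3f (n = %d)", x$r_squared, x$n),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(x)
}

#' Read a solubility training table from CSV
#'
#' Columns: `nades_id`, `s_exp_mg_per_ml`, `ln_gamma` (the latter may be
#' absent when the pipeline computes it).
#'
#' @param path CSV file path.
#' @return Data frame with columns `nades_id`, `s_exp` and, when
#'   present, `ln_gamma`.
#' @export
read_training_table <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("nades_id", "s_exp_mg_per_ml") %in% names(tab)))
    stop("training table must have columns nades_id, s_exp_mg_per_ml")
  out <- data.frame(nades_id = as.character(tab$nades_id),
                    s_exp = as.numeric(tab$s_exp_mg_per_ml),
                    stringsAsFactors = FALSE)
  if ("ln_gamma" %in% names(tab)) out$ln_gamma <- as.numeric(tab$ln_gamma)
  out
}
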