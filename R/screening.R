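#' Predict and rank candidate NADES
#'
#' Applies a fitted calibration to the computed `ln gamma` of each
#' candidate solvent pair and ranks by predicted solubility. Reported
#' percent increases over the reference solvent and fold-improvements
#' over water are rounded to the nearest integer (full precision is
#' retained in the `s_pred` column); predicted solubilities are reported
#' to 2 decimals.
#'
#' @param model a [fit_calibration()] object.
#' @param candidates named numeric vector of `ln gamma` per NADES id.
#' @param s_ref reference solubility, mg/mL (default 2.26, the best
#'   training solvent: glutamic acid-proline).
#' @param s_water solubility in water, mg/mL (default 0.120).
#' @param source optional character vector (`"experimental"` or
#'   `"estimated"`) per candidate; defaults to `"estimated"`.
#' @return A data frame of class `nades_screen`, sorted by `s_pred`
#'   descending, with columns `nades_id`, `ln_gamma`, `s_pred` (mg/mL,
#'   full precision), `s_pred_rounded`, `pct_increase_vs_ref` (integer
#'   %), `fold_vs_water` (integer), `source`.
#' @examples
#' recs <- data.frame(nades_id = paste0("n", 1:4),
#'                    ln_gamma = c(-3, -1, 1, 3),
#'                    s_exp = c(4.4, 3.0, 1.6, 0.4))
#' m <- fit_calibration(recs)
#' predict_and_rank(m, c(best = -4, mid = 0))
#' @export
predict_and_rank <- function(model, candidates, s_ref = 2.26,
                             s_water = 0.120, source = NULL) {
  stopifnot(inherits(model, "nades_calibration"),
            is.numeric(candidates), length(candidates) >= 1L,
            !is.null(names(candidates)),
            is.numeric(s_ref), s_ref > 0, is.numeric(s_water), s_water > 0)
  if (is.null(source)) source <- rep("estimated", length(candidates))
  stopifnot(length(source) == length(candidates),
            all(source %in% c("experimental", "estimated")))
  s_pred <- predict(model, candidates)
  out <- data.frame(nades_id = names(candidates),
                    ln_gamma = unname(candidates),
                    s_pred = unname(s_pred),
                    s_pred_rounded = round(unname(s_pred), 2),
                    pct_increase_vs_ref = as.integer(round(
                      100 * (unname(s_pred) - s_ref) / s_ref)),
                    fold_vs_water = as.integer(round(unname(s_pred) / s_water)),
                    source = source,
                    stringsAsFactors = FALSE)
  out <- out[order(out$s_pred, decreasing = TRUE), ]
  rownames(out) <- NULL
  attr(out, "s_ref") <- s_ref
  attr(out, "s_water") <- s_water
  class(out) <- c("nades_screen", "data.frame")
  out
}

#' @export
print.nades_screen <- function(x, ...) {
  cat(sprintf("NADES screen: %d candidates (reference %.2f mg/mL, water %.3f mg/mL)\n",
              nrow(x), attr(x, "s_ref"), attr(x, "s_water")))
  df <- as.data.frame(x)
  df$ln_gamma <- signif(df$ln_gamma, 4)
  df$s_pred <- NULL
  names(df)[names(df) == "s_pred_rounded"] <- "s_pred_mg_per_ml"
  print(df, row.names = FALSE)
  invisible(x)
}

#' Relative difference between experiment and prediction
#'
#' @param s_exp experimental solubility, mg/mL (> 0).
#' @param abs_diff absolute difference |experimental - computed|, mg/mL.
#' @return Percent relative difference, rounded to one decimal.
#' @examples
#' relative_difference(2.26, 0.0286)  # 1.3
#' @export
relative_difference <- function(s_exp, abs_diff) {
  stopifnot(is.numeric(s_exp), all(s_exp > 0), is.numeric(abs_diff),
            all(abs_diff >= 0))
  round(100 * abs_diff / s_exp, 1)
}

#' Substituent-acidity / solubility relationship
#'
#' Least-squares slope and Pearson correlation between the lowest
#' micro-pKa of the substituents on the carboxylic-acid chain and the
#' predicted solubility across a set of solvent pairs. A positive slope
#' supports the structure-performance reading that more basic (higher
#' pKa) chain substituents give better solubilization.
#'
#' @param pairs data frame (or 2-column matrix) with columns `pka`
#'   (lowest substituent micro-pKa) and `s_pred` (mg/mL); at least 3
#'   rows, pKa values not all equal.
#' @return List with `slope` (mg/mL per pKa unit), `pearson_r`,
#'   `p_value` and `n`.
#' @export
pka_solubility_correlation <- function(pairs) {
  pairs <- as.data.frame(pairs)
  if (!all(c("pka", "s_pred") %in% names(pairs)))
    names(pairs)[1:2] <- c("pka", "s_pred")
  stopifnot(nrow(pairs) >= 3L)
  if (diff(range(pairs$pka)) == 0) stop("pKa values must not all be equal")
  fit <- stats::lm(s_pred ~ pka, data = pairs)
  ct <- stats::cor.test(pairs$pka, pairs$s_pred, method = "pearson")
  list(slope = unname(stats::coef(fit)[2]),
       pearson_r = unname(ct$estimate),
       p_value = ct$p.value,
       n = nrow(pairs))
}

#' Write a screening table to CSV
#'
#' @param screen a [predict_and_rank()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_screening_csv <- function(screen, path) {
  stopifnot(inherits(screen, "nades_screen"))
  utils::write.csv(as.data.frame(screen), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
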