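#' Specify a binary (or larger) NADES mixture
#'
#' @param components named numeric vector of initial moles per compound
#'   code; the default unimolar 1:1 ratio mirrors how binary NADES are
#'   prepared experimentally.
#' @param forms `ionic_forms` table with every form of the listed
#'   components (and nothing else).
#' @param cond [thermo_conditions()].
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, forms, cond = thermo_conditions()) {
  stopifnot(is.numeric(components), !is.null(names(components)),
            inherits(forms, "data.frame"))
  if (any(components <= 0)) stop("all initial moles must be > 0")
  extra <- setdiff(forms$parent, names(components))
  if (length(extra))
    stop("forms table contains parents not in the mixture: ",
         paste(unique(extra), collapse = ", "))
  absent <- setdiff(names(components), forms$parent)
  if (length(absent))
    stop("no forms declared for component(s): ", paste(absent, collapse = ", "))
  for (p in names(components))
    if (sum(forms$parent == p & forms$charge == 0L) != 1L)
      stop("component ", p, " must have exactly one neutral form")
  structure(list(components = components, forms = forms, cond = cond),
            class = "mixture_spec")
}

# stoichiometry matrix (forms x reactions) from a reaction list
.stoich_matrix <- function(form_ids, reactions) {
  S <- matrix(0, nrow = length(form_ids), ncol = length(reactions),
              dimnames = list(form_ids,
                              vapply(reactions, `[[`, character(1), "reaction_id")))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    if (!all(names(st) %in% form_ids))
      stop("reaction ", reactions[[j]]$reaction_id,
           " references forms outside the mixture")
    S[names(st), j] <- st
  }
  S
}

# amounts at extent vector xi (no flooring)
.amounts <- function(n0, S, xi) n0 + drop(S %*% xi)

# log mass-action residual g_j = sum_i nu_ij ln x_i - ln K_j
.log_residual <- function(n, S, lnK, floor) {
  lnx <- log(pmax(n, floor) / sum(pmax(n, floor)))
  drop(crossprod(S, lnx)) - lnK
}

# one Gauss-Seidel sweep: solve each reaction's scalar mass-action by bisection
.gs_sweep <- function(n0, S, lnK, xi, floor, bis_iter = 100L) {
  for (j in seq_len(ncol(S))) {
    base <- .amounts(n0, S, replace(xi, j, 0))
    nu <- S[, j]
    act <- which(nu != 0)
    lo <- -Inf; hi <- Inf
    for (i in act) {
      if (nu[i] > 0) lo <- max(lo, -base[i] / nu[i])
      else hi <- min(hi, base[i] / (-nu[i]))
    }
    span <- hi - lo
    a <- lo + 1e-14 * span; b <- hi - 1e-14 * span
    gj <- function(t) {
      n <- base + nu * t
      lnx <- log(pmax(n, floor) / sum(pmax(n, floor)))
      sum(nu[act] * lnx[act]) - lnK[j]
    }
    if (gj(a) > 0) { xi[j] <- a; next }
    if (gj(b) < 0) { xi[j] <- b; next }
    for (it in seq_len(bis_iter)) {
      m <- 0.5 * (a + b)
      if (gj(m) < 0) a <- m else b <- m
    }
    xi[j] <- 0.5 * (a + b)
  }
  xi
}

#' Solve the coupled speciation equilibria of a NADES
#'
#' Finds the equilibrium amounts of every neutral and ionic form given
#' the proton-transfer reactions and their equilibrium constants. The
#' mass-action law is written on mole fractions (ideal mixing; see the
#' package vignette), taken over all forms of all components — the neat
#' binary liquid itself is the solvent. Mass balance is enforced by
#' construction through reaction extents; charge balance follows because
#' every reaction conserves charge and the initial state is neutral.
#'
#' The solver runs damped Newton iteration on the reaction extents
#' (Jacobian `S' diag(1/n) S`, step clamped to keep all amounts
#' positive), seeded by a few Gauss-Seidel sweeps in which each
#' reaction's scalar mass-action equation is solved by bisection while
#' the others are held fixed. If Newton stalls, the solver falls back to
#' bisection sweeps alone; non-convergence raises an error carrying the
#' final residuals.
#'
#' @param mix a [mixture_spec()].
#' @param reactions list of [reaction()] objects (all K finite and > 0;
#'   duplicated stoichiometries with conflicting K are rejected).
#' @param tol convergence tolerance on the worst relative mass-action
#'   residual |Q/K - 1|.
#' @param max_iter maximum Newton iterations.
#' @param floor numerical floor (mol) below which an amount is treated
#'   as vanishing when evaluating logarithms.
#' @return An object of class `speciation_result`: `x` (mole fractions
#'   over all forms), `extents` (mol per reaction), `residuals`
#'   (|Q/K - 1| per reaction), `iterations`, `converged`.
#' @examples
#' sys <- nades_example_reactions()
#' mix <- mixture_spec(c(`7` = 1, A = 1), sys$forms)
#' res <- solve_speciation(mix, sys$reactions)
#' dominant_forms(res, 0.01)
#' @export
solve_speciation <- function(mix, reactions, tol = 1e-10, max_iter = 200L,
                             floor = 1e-30) {
  stopifnot(inherits(mix, "mixture_spec"), is.list(reactions), length(reactions) > 0)
  K <- vapply(reactions, `[[`, numeric(1), "K")
  if (any(!is.finite(K)) || any(K <= 0)) stop("all K must be finite and > 0")
  keys <- vapply(reactions, function(r) {
    st <- r$stoich[order(names(r$stoich))]
    paste(names(st), st, collapse = " ")
  }, character(1))
  if (anyDuplicated(keys)) {
    dup <- split(K, keys)
    for (g in dup) if (length(g) > 1 && max(abs(g / g[1] - 1)) > 1e-12)
      stop("duplicated reaction stoichiometry with conflicting K")
  }

  forms <- mix$forms
  n0 <- stats::setNames(rep(0, nrow(forms)), forms$form_id)
  neutral <- forms$form_id[forms$charge == 0L]
  n0[neutral] <- mix$components[forms$parent[forms$charge == 0L]]
  S <- .stoich_matrix(forms$form_id, reactions)
  lnK <- log(K)
  N <- sum(n0)

  # interior start, then Gauss-Seidel sweeps to localize
  xi <- rep(0, ncol(S))
  for (s in seq_len(30L)) {
    xi <- .gs_sweep(n0, S, lnK, xi, floor)
    g <- .log_residual(.amounts(n0, S, xi), S, lnK, floor)
    if (max(abs(expm1(g))) < 1e-3) break
  }

  newton <- function(xi, iters) {
    for (it in seq_len(iters)) {
      n <- .amounts(n0, S, xi)
      g <- .log_residual(n, S, lnK, floor)
      res <- max(abs(expm1(g)))
      if (res < tol) return(list(xi = xi, iterations = it - 1L, converged = TRUE))
      w <- 1 / pmax(n, floor)
      J <- crossprod(S, S * w)
      # tiny Tikhonov ridge keeps the step defined when reactions are
      # stoichiometrically dependent (consistent K make g reachable anyway)
      delta <- tryCatch(solve(J, -g), error = function(e)
        tryCatch(solve(J + diag(1e-10 * max(diag(J)), nrow(J)), -g),
                 error = function(e2) NULL))
      if (is.null(delta) || any(!is.finite(delta))) return(list(xi = xi, iterations = it, converged = FALSE))
      dn <- drop(S %*% delta)
      t_max <- 1
      shrink <- dn < 0 & n > 0
      if (any(shrink)) t_max <- min(1, 0.9 * min(n[shrink] / (-dn[shrink])))
      xi <- xi + t_max * delta
    }
    list(xi = xi, iterations = iters, converged = FALSE)
  }

  out <- newton(xi, max_iter)
  if (!out$converged) {
    # fallback: pure bisection sweeps, then one more Newton polish
    xi <- out$xi
    for (s in seq_len(400L)) {
      xi <- .gs_sweep(n0, S, lnK, xi, floor)
      g <- .log_residual(.amounts(n0, S, xi), S, lnK, floor)
      if (max(abs(expm1(g))) < tol) break
    }
    out <- newton(xi, 50L)
    if (!out$converged) {
      g <- .log_residual(.amounts(n0, S, out$xi), S, lnK, floor)
      if (max(abs(expm1(g))) >= tol)
        stop(sprintf("speciation solver did not converge; worst |Q/K - 1| = %.3g",
                     max(abs(expm1(g)))))
      out$converged <- TRUE
    }
  }

  n <- pmax(.amounts(n0, S, out$xi), 0)
  x <- n / sum(n)
  g <- .log_residual(.amounts(n0, S, out$xi), S, lnK, floor)
  res <- structure(list(
    x = stats::setNames(x, forms$form_id),
    extents = stats::setNames(out$xi, colnames(S)),
    residuals = stats::setNames(abs(expm1(g)), colnames(S)),
    iterations = out$iterations,
    converged = out$converged,
    forms = forms,
    K = stats::setNames(K, colnames(S))),
    class = "speciation_result")

  stopifnot(abs(sum(res$x) - 1) < 1e-10,
            all(res$x >= 0),
            abs(sum(res$x * forms$charge)) < 1e-10)
  for (p in unique(forms$parent))
    stopifnot(abs(sum(res$x[forms$parent == p]) - mix$components[p] / N) < 1e-10)
  res
}

#' @export
print.speciation_result <- function(x, digits = 4, ...) {
  cat(sprintf("Speciation over %d forms, %d reaction(s); converged: %s (%d Newton iterations)\n",
              length(x$x), length(x$extents), x$converged, x$iterations))
  ord <- order(x$x, decreasing = TRUE)
  df <- data.frame(form = names(x$x)[ord],
                   parent = x$forms$parent[ord],
                   charge = x$forms$charge[ord],
                   mole_fraction = signif(unname(x$x[ord]), digits))
  print(df, row.names = FALSE)
  cat(sprintf("worst mass-action residual |Q/K - 1| = %.2e\n", max(x$residuals)))
  invisible(x)
}

#' Dominant forms of a speciation result
#'
#' @param result a [solve_speciation()] result.
#' @param threshold mole-fraction cutoff in `[0, 1)`; forms with
#'   `x >= threshold` are retained.
#' @return Named numeric vector of retained mole fractions, sorted
#'   descending, with attribute `discarded` holding the total mole
#'   fraction filtered out.
#' @export
dominant_forms <- function(result, threshold = 0.01) {
  stopifnot(inherits(result, "speciation_result"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold < 1)
  keep <- result$x[result$x >= threshold]
  keep <- keep[order(keep, decreasing = TRUE)]
  attr(keep, "discarded") <- sum(result$x) - sum(keep)
  keep
}

#' Write a speciation result to CSV
#'
#' One row per form: form id, parent, charge, mole fraction.
#'
#' @param result a [solve_speciation()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_speciation_csv <- function(result, path) {
  stopifnot(inherits(result, "speciation_result"))
  df <- data.frame(form_id = names(result$x),
                   parent = result$forms$parent,
                   charge = result$forms$charge,
                   mole_fraction = unname(result$x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
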