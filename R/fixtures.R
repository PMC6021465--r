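#' @title Seedable synthetic fixtures
#' @description Generators for self-consistent reaction networks with an
#'   attached independently computed equilibrium, plausible synthetic
#'   sigma profiles, and linear training sets with known ground truth.
#'   Every generator is a pure function of its parameters and seed; each
#'   draws from a named pseudo-random stream derived from the single
#'   master seed, so adding a generator never perturbs existing
#'   fixtures.
#' @name fixtures
NULL

# run expr under a reproducible stream-specific seed, restoring RNG state
.with_stream_seed <- function(seed, stream, expr) {
  codes <- utf8ToInt(stream)
  sub_seed <- (as.numeric(seed) * 7919 + sum(codes * seq_along(codes) * 131)) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(sub_seed))
  force(expr)
}

#' Brute-force speciation oracle
#'
#' Computes the equilibrium composition of a reaction network by direct
#' minimization of the ideal-mixing Gibbs energy
#' `G(n)/RT = sum_i n_i (ln x_i + mu0_i)` over the feasible box of
#' reaction extents, where the standard-state potentials `mu0` are
#' recovered from `ln K` by least squares on the stoichiometry matrix.
#' The minimizer is located by a coarse grid scan over feasible extents
#' followed by per-coordinate bisection refinement on the Gibbs
#' gradient. This is a deliberately independent route to the same
#' equilibrium as [solve_speciation()] (which solves the mass-action
#' equations by Newton iteration) and serves as its cross-check.
#'
#' @param mix a [mixture_spec()].
#' @param reactions list of [reaction()] objects with linearly
#'   independent stoichiometries.
#' @param grid_n grid points per extent dimension in the coarse scan.
#' @param tol convergence tolerance on the max Gibbs-gradient component.
#' @param max_sweeps refinement sweep cap.
#' @return Named mole-fraction vector over all forms.
#' @export
speciation_oracle <- function(mix, reactions, grid_n = 25L, tol = 1e-10,
                              max_sweeps = 5000L) {
  stopifnot(inherits(mix, "mixture_spec"))
  forms <- mix$forms
  n0 <- stats::setNames(rep(0, nrow(forms)), forms$form_id)
  n0[forms$form_id[forms$charge == 0L]] <-
    mix$components[forms$parent[forms$charge == 0L]]
  S <- .stoich_matrix(forms$form_id, reactions)
  lnK <- log(vapply(reactions, `[[`, numeric(1), "K"))
  d <- ncol(S)
  # minimal-norm standard-state potentials solving S' mu0 = -lnK (SVD
  # pseudo-inverse; handles stoichiometrically dependent reaction sets)
  sv <- svd(S)
  pos <- sv$d > 1e-10 * max(sv$d)
  mu0 <- drop(sv$u[, pos, drop = FALSE] %*%
                ((crossprod(sv$v[, pos, drop = FALSE], -lnK)) / sv$d[pos]))
  if (max(abs(drop(crossprod(S, mu0)) + lnK)) > 1e-8)
    stop("reaction network is thermodynamically inconsistent (cycle K mismatch)")

  gibbs <- function(xi) {
    n <- n0 + drop(S %*% xi)
    if (any(n < 0)) return(Inf)
    x <- n / sum(n)
    pos <- n > 0
    sum(n[pos] * (log(x[pos]) + mu0[pos]))
  }
  grad_j <- function(xi, j) {
    n <- pmax(n0 + drop(S %*% xi), 1e-300)
    x <- n / sum(n)
    sum(S[, j] * (log(x) + mu0))
  }

  # per-reaction extent caps from reactant availability (ignores coupling;
  # infeasible grid nodes are discarded by the Inf objective)
  cap <- vapply(seq_len(d), function(j) {
    r <- S[, j] < 0
    min(n0[r] / (-S[r, j]))
  }, numeric(1))
  pts <- lapply(seq_len(d), function(j) seq(0, cap[j], length.out = grid_n)[-grid_n])
  grid <- as.matrix(expand.grid(pts))
  vals <- apply(grid, 1, gibbs)
  xi <- grid[which.min(vals), ]

  # coordinate bisection on the Gibbs gradient (monotone in each extent)
  for (sweep in seq_len(max_sweeps)) {
    worst <- 0
    for (j in seq_len(d)) {
      base <- n0 + drop(S %*% replace(xi, j, 0))
      nu <- S[, j]
      lo <- -Inf; hi <- Inf
      for (i in which(nu != 0)) {
        if (nu[i] > 0) lo <- max(lo, -base[i] / nu[i])
        else hi <- min(hi, base[i] / (-nu[i]))
      }
      span <- hi - lo
      a <- lo + 1e-15 * span; b <- hi - 1e-15 * span
      ga <- grad_j(replace(xi, j, a), j)
      gb <- grad_j(replace(xi, j, b), j)
      if (ga >= 0) { xi[j] <- a; next }
      if (gb <= 0) { xi[j] <- b; next }
      for (it in seq_len(120L)) {
        m <- 0.5 * (a + b)
        if (grad_j(replace(xi, j, m), j) < 0) a <- m else b <- m
      }
      xi[j] <- 0.5 * (a + b)
      worst <- max(worst, abs(grad_j(xi, j)))
    }
    g_all <- vapply(seq_len(d), function(j) grad_j(xi, j), numeric(1))
    if (max(abs(g_all)) < tol) break
  }
  n <- pmax(n0 + drop(S %*% xi), 0)
  stats::setNames(n / sum(n), forms$form_id)
}

# bare form table for a synthetic parent: neutral + n_anion anions + n_cation cations
.synthetic_forms <- function(code, n_anion, n_cation) {
  ids <- code
  charges <- 0L
  if (n_anion > 0) {
    ids <- c(ids, if (n_anion > 1) paste0(code, seq_len(n_anion), "-") else paste0(code, "-"))
    charges <- c(charges, rep(-1L, n_anion))
  }
  if (n_cation > 0) {
    ids <- c(ids, if (n_cation > 1) paste0(code, seq_len(n_cation), "+") else paste0(code, "+"))
    charges <- c(charges, rep(1L, n_cation))
  }
  out <- data.frame(form_id = ids, parent = code, charge = charges,
                    site = NA_character_, profile_ref = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ionic_forms", "data.frame")
  out
}

#' Generate a random solvable reaction network with its oracle solution
#'
#' Builds a binary 1:1 mixture of two synthetic parents X and Y with
#' 1-3 proton-transfer reactions in the anion/cation pattern of the
#' reference glutamic acid-proline system (one, two, or three
#' independent anion-cation pairs), draws `log10 K` uniformly from
#' `log10K_range`, and attaches the composition computed by
#' [speciation_oracle()].
#'
#' @param n_reactions 1, 2 or 3.
#' @param log10K_range range for the uniform draw of log10 K.
#' @param seed integer master seed.
#' @return List with `mix` ([mixture_spec()]), `reactions`, and
#'   `oracle` (named mole fractions).
#' @export
make_equilibrium_fixture <- function(n_reactions = 2L, log10K_range = c(-6, 6),
                                     seed = 1L) {
  stopifnot(n_reactions %in% 1:3, length(log10K_range) == 2L,
            log10K_range[1] <= log10K_range[2])
  K <- .with_stream_seed(seed, paste0("equilibrium", n_reactions),
                         10^stats::runif(n_reactions, log10K_range[1], log10K_range[2]))
  # reaction templates: X1-+Y+, X2-+Y+, X++Y-
  xf <- .synthetic_forms("X", n_anion = min(n_reactions, 2L),
                         n_cation = if (n_reactions == 3L) 1L else 0L)
  yf <- .synthetic_forms("Y", n_anion = if (n_reactions == 3L) 1L else 0L,
                         n_cation = 1L)
  forms <- bind_forms(xf, yf)
  anx <- xf$form_id[xf$charge == -1L]
  stoichs <- lapply(anx, function(a)
    stats::setNames(c(-1L, -1L, 1L, 1L), c("X", "Y", a, "Y+")))
  if (n_reactions == 3L)
    stoichs[[3]] <- stats::setNames(c(-1L, -1L, 1L, 1L), c("X", "Y", "X+", "Y-"))
  reactions <- lapply(seq_len(n_reactions), function(j)
    reaction(paste0("K", j), stoichs[[j]], forms, K = K[j]))
  mix <- mixture_spec(c(X = 1, Y = 1), forms)
  list(mix = mix, reactions = reactions,
       oracle = speciation_oracle(mix, reactions))
}

#' Generate a set of plausible synthetic sigma profiles
#'
#' Each profile is a sum of 2-4 Gaussians with centres within
#' +/-0.015 e/A^2, widths 0.002-0.006 e/A^2, and total surface area
#' 150-400 A^2 — the scale of small-molecule screening surfaces.
#' Deterministic per (ids, seed).
#'
#' @param ids character vector of form ids (or an integer count, in
#'   which case ids `F1..Fn` are used).
#' @param seed integer master seed.
#' @return Named list of [sigma_profile()] objects.
#' @export
make_profile_set <- function(ids, seed = 1L) {
  if (is.numeric(ids) && length(ids) == 1L) ids <- paste0("F", seq_len(ids))
  stopifnot(is.character(ids), length(ids) >= 1L)
  out <- lapply(ids, function(id) {
    .with_stream_seed(seed, paste0("profile:", id), {
      k <- sample(2:4, 1)
      total <- stats::runif(1, 150, 400)
      w <- stats::runif(k); w <- w / sum(w)
      spec <- lapply(seq_len(k), function(g)
        c(center = stats::runif(1, -0.015, 0.015),
          width = stats::runif(1, 0.002, 0.006),
          area = total * w[g]))
      synthesize_profile(spec, label = id)
    })
  })
  stats::setNames(out, ids)
}

#' Generate a synthetic solubility training set with known truth
#'
#' Draws `ln gamma` values uniformly on `[-2.5, 1]` (the scale on which
#' the best training solvents sit near 2.26 mg/mL and the worst near
#' water-like solubility) and sets
#' `s_exp = slope * ln_gamma + intercept + N(0, noise_sd)`, redrawing
#' any non-positive solubility. The generating truth is attached for
#' recovery tests. The default noise level puts the refit R^2 near
#' 0.97, the regime of a well-calibrated screen.
#'
#' @param n number of training NADES (default 15).
#' @param slope,intercept generating line (mg/mL per ln-gamma unit;
#'   mg/mL).
#' @param noise_sd Gaussian noise standard deviation, mg/mL.
#' @param seed integer master seed.
#' @return Data frame with columns `nades_id`, `ln_gamma`, `s_exp` and
#'   attribute `truth` (list: slope, intercept, noise_sd).
#' @export
make_training_set <- function(n = 15L, slope = -0.5, intercept = 1.0,
                              noise_sd = 0.09, seed = 1L) {
  stopifnot(n >= 3L, noise_sd >= 0)
  out <- .with_stream_seed(seed, "training", {
    lg <- stats::runif(n, -2.5, 1)
    s <- slope * lg + intercept + stats::rnorm(n, 0, noise_sd)
    for (tries in seq_len(100L)) {
      bad <- s <= 0
      if (!any(bad)) break
      s[bad] <- slope * lg[bad] + intercept + stats::rnorm(sum(bad), 0, noise_sd)
    }
    if (any(s <= 0)) s[s <= 0] <- 1e-3
    data.frame(nades_id = sprintf("syn-%02d", seq_len(n)),
               ln_gamma = lg, s_exp = s, stringsAsFactors = FALSE)
  })
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd)
  out
}

#' Lowest substituent micro-pKa of a compound
#'
#' The smallest declared micro-pKa among the compound's basic
#' (chain-substituent) sites; `NA` when the compound has none.
#' Used for the substituent-acidity / solubility analysis.
#'
#' @param comp a [compound()].
#' @return Numeric scalar or `NA`.
#' @export
lowest_substituent_pka <- function(comp) {
  stopifnot(inherits(comp, "nades_compound"))
  kinds <- vapply(comp$sites, `[[`, character(1), "kind")
  pka <- vapply(comp$sites, `[[`, numeric(1), "micro_pKa")
  pka <- pka[kinds == "basic" & !is.na(pka)]
  if (length(pka) == 0L) NA_real_ else min(pka)
}
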