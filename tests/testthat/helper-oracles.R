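# Independent oracles used across the suite. These deliberately avoid the
# package's solution paths: closed forms, direct summation, and a plain
# undamped-free fixed-point iteration written from the defining equations.

# closed-form equilibrium of A + B = C + D from 1:1 neutrals (extent root
# of the quadratic mass-action condition on mole fractions, N constant)
quadratic_equilibrium <- function(K) {
  sK <- sqrt(K)
  xi <- sK / (1 + sK)
  c(A = (1 - xi) / 2, B = (1 - xi) / 2, C = xi / 2, D = xi / 2)
}

# direct evaluation of the segment equations by plain damped substitution
# with naive exponentials (no log-sum-exp, no acceleration); independent
# of solve_segment_potentials
substitution_segment_mu <- function(p_S, sigma_grid, params, tol = 1e-12,
                                    max_iter = 2e5, damping = 0.5) {
  beta <- params$a_eff / params$cond$RT
  E <- outer(sigma_grid, sigma_grid,
             function(s, sp) {
               don <- pmin(s, sp); acc <- pmax(s, sp)
               (params$alpha_misfit / 2) * (s + sp)^2 +
                 params$c_hb * pmax(0, acc - params$sigma_hb) *
                   pmax(0, -don - params$sigma_hb) + params$c_vdw
             })
  mu <- numeric(length(p_S))
  for (it in seq_len(max_iter)) {
    integ <- as.vector(exp(beta * outer(rep(1, length(mu)), mu) - beta * E) %*% p_S)
    mu_new <- -(1 / beta) * log(integ)
    if (max(abs(mu_new - mu)) < tol) return(mu_new)
    mu <- (1 - damping) * mu + damping * mu_new
  }
  stop("oracle substitution did not converge")
}

# ln gamma by the independent substitution path on the same grid
oracle_ln_gamma <- function(solute, solvent_mix, params) {
  mu_solv <- substitution_segment_mu(solvent_mix$p_S, solvent_mix$sigma_grid,
                                     params)
  mu_pure <- substitution_segment_mu(solute$p / solute$total_area,
                                     solute$sigma_grid, params)
  mu_S <- sum(solute$p * mu_solv) / params$a_eff
  mu_P <- sum(solute$p * mu_pure) / params$a_eff
  (mu_S - mu_P) / params$cond$RT
}

# fabricate a speciation_result for operations that only filter/report
fake_speciation_result <- function(x) {
  structure(list(x = x,
                 extents = numeric(0), residuals = numeric(0),
                 iterations = 0L, converged = TRUE,
                 forms = data.frame(form_id = names(x),
                                    parent = rep("Z", length(x)),
                                    charge = 0L)),
            class = "speciation_result")
}

# a tiny two-parent system usable without compound() role constraints
minimal_forms <- function() {
  out <- data.frame(form_id = c("A", "A-", "B", "B+"),
                    parent = c("A", "A", "B", "B"),
                    charge = c(0L, -1L, 0L, 1L),
                    site = NA_character_, profile_ref = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("ionic_forms", "data.frame")
  out
}

std_params <- function(...) interaction_params(...)

zero_params <- function(T = 298.15)
  interaction_params(alpha_misfit = 0, c_hb = 0, c_vdw = 0,
                     cond = thermo_conditions(T = T))
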