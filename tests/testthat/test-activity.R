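test_that("segment interaction energy follows the misfit + hydrogen-bond decomposition", {
  prm <- std_params()
  # neutral contact, no vdW: zero energy
  expect_equal(interaction_energy(0, 0, zero_params()), 0)
  # perfectly screening pair: misfit vanishes
  prm_nohb <- interaction_params(c_hb = 0)
  expect_equal(interaction_energy(0.013, -0.013, prm_nohb), 0)
  # hand-evaluated hydrogen-bond term at the threshold convention
  e <- interaction_energy(0.02, -0.02, prm)
  expect_equal(e, prm$c_hb * (0.02 - prm$sigma_hb) * (0.02 - prm$sigma_hb),
               tolerance = 1e-12)
  expect_lt(e, 0)  # attractive
  # symmetry over many random pairs
  set.seed(31)
  s1 <- runif(1e4, -0.025, 0.025); s2 <- runif(1e4, -0.025, 0.025)
  expect_equal(interaction_energy(s1, s2, prm), interaction_energy(s2, s1, prm),
               tolerance = 1e-15)
})

test_that("the conductor-limit fixed point mu = 0 holds when interactions vanish", {
  pr <- synthesize_profile(list(c(0.004, 0.005, 280)), "x")
  mx <- mixture_profile(list(pr), 1)
  sp <- solve_segment_potentials(mx, zero_params())
  expect_equal(max(abs(sp$mu)), 0)
  # invariant under temperature change
  sp2 <- solve_segment_potentials(mx, zero_params(T = 596.3))
  expect_equal(max(abs(sp2$mu)), 0)
})

test_that("a single occupied bin reproduces the closed-form segment potential", {
  g <- sigma_grid_default()
  i0 <- 33L
  p <- numeric(length(g)); p[i0] <- 250
  pr <- sigma_profile(g, p, "onebin")
  mx <- mixture_profile(list(pr), 1)
  prm <- std_params()
  sp <- solve_segment_potentials(mx, prm, tol = 1e-12)
  # with all solvent area at sigma0: mu(sigma) = e(sigma, sigma0) - e(sigma0, sigma0)/2
  closed <- interaction_energy(g, g[i0], prm) -
    interaction_energy(g[i0], g[i0], prm) / 2
  expect_equal(sp$mu, closed, tolerance = 1e-10)
})

test_that("compound chemical potential is the linear quadrature of segment potentials", {
  a <- synthesize_profile(list(c(-0.006, 0.004, 220)), "a")
  b <- synthesize_profile(list(c(0.007, 0.004, 300)), "b")
  mx <- mixture_profile(list(a, b), c(0.4, 0.6))
  prm <- std_params()
  sp <- solve_segment_potentials(mx, prm)
  mu_a <- chemical_potential(a, sp, prm)
  # independent summation
  expect_equal(mu_a, sum(a$p * sp$mu) / prm$a_eff, tolerance = 1e-14)
  # mu_S = 0 everywhere gives zero for any profile
  sp0 <- solve_segment_potentials(mx, zero_params())
  expect_equal(chemical_potential(a, sp0, zero_params()), 0)
  # homogeneity: doubled surface doubles the potential
  a2 <- sigma_profile(a$sigma_grid, 2 * a$p, "a2")
  expect_equal(chemical_potential(a2, sp, prm), 2 * mu_a, tolerance = 1e-12)
  wrong <- sigma_profile(sigma_grid_default(-0.026, 0.026, 53), rep(1, 53), "w")
  expect_error(chemical_potential(wrong, sp, prm), "grids")
})

test_that("segment potentials are invariant to padding the grid with empty bins", {
  spec <- list(c(-0.005, 0.003, 180), c(0.008, 0.003, 120))
  prm <- std_params()
  g51 <- sigma_grid_default()
  pr51 <- synthesize_profile(spec, "p", g51)
  mu51 <- solve_segment_potentials(mixture_profile(list(pr51), 1), prm,
                                   tol = 1e-12)$mu
  # embed the same bin masses into a wider grid, padded with exact zeros
  g61 <- sigma_grid_default(-0.030, 0.030, 61L)
  shared <- match(round(g51, 6), round(g61, 6))
  p61 <- numeric(61L); p61[shared] <- pr51$p
  mu61 <- solve_segment_potentials(
    mixture_profile(list(sigma_profile(g61, p61, "p")), 1), prm,
    tol = 1e-12)$mu
  expect_equal(mu61[shared], mu51, tolerance = 1e-10)
})

test_that("infinite-dilution activity coefficients match the independent substitution oracle", {
  prm <- std_params()
  solute <- synthesize_profile(list(c(-0.006, 0.004, 220), c(0.009, 0.003, 90)),
                               "solute")
  solv <- mixture_profile(list(synthesize_profile(list(c(0.004, 0.005, 310)),
                                                  "solv")), 1)
  lg <- ln_gamma_infinite_dilution(solute, solv, prm)
  expect_true(is.finite(lg))
  expect_equal(as.numeric(lg), oracle_ln_gamma(solute, solv, prm),
               tolerance = 1e-6)
  # gamma = 1 when the solvent is the solute's own medium
  self <- mixture_profile(list(solute), 1)
  expect_equal(as.numeric(ln_gamma_infinite_dilution(solute, self, prm)), 0)
  # residual-only model with all prefactors zero: gamma = 1 for any pair
  expect_equal(as.numeric(ln_gamma_infinite_dilution(solute, solv, zero_params())), 0)
  # ionic solutes force the infinite-dilution reference
  expect_error(ln_gamma_infinite_dilution(solute, solv, prm, charge = -1L),
               "infinite-dilution reference")
  expect_equal(as.numeric(ln_gamma_infinite_dilution(solute, solv, prm,
                                                     reference = "infinite_dilution",
                                                     charge = -1L)), 0)
})

test_that("gamma approaches 1 continuously as the solvent morphs into the solute", {
  prm <- std_params()
  solute <- synthesize_profile(list(c(-0.004, 0.004, 250)), "s")
  other <- synthesize_profile(list(c(0.010, 0.003, 180)), "o")
  lg_at <- function(t) {
    blend <- sigma_profile(solute$sigma_grid,
                           (1 - t) * other$p + t * solute$p, "blend")
    as.numeric(ln_gamma_infinite_dilution(solute, mixture_profile(list(blend), 1),
                                          prm))
  }
  path <- vapply(c(0, 0.5, 0.9, 1), lg_at, numeric(1))
  expect_equal(path[4], 0)
  expect_true(all(diff(abs(path)) < 0))
})

test_that("finite-composition activity coefficients satisfy the Gibbs-Duhem relation", {
  prm <- std_params()
  p1 <- synthesize_profile(list(c(-0.006, 0.004, 220), c(0.009, 0.003, 90)), "c1")
  p2 <- synthesize_profile(list(c(0.004, 0.005, 310)), "c2")
  mu_pure <- function(pr)
    chemical_potential(pr, solve_segment_potentials(mixture_profile(list(pr), 1),
                                                    prm, tol = 1e-12), prm)
  mp1 <- mu_pure(p1); mp2 <- mu_pure(p2)
  ln_g <- function(x1, pr, mp) {
    mx <- mixture_profile(list(p1, p2), c(x1, 1 - x1))
    (chemical_potential(pr, solve_segment_potentials(mx, prm, tol = 1e-12), prm) -
       mp) / prm$cond$RT
  }
  for (x1 in c(0.25, 0.375, 0.5, 0.625, 0.75)) {
    gd <- function(h) {
      d1 <- (ln_g(x1 + h, p1, mp1) - ln_g(x1 - h, p1, mp1)) / (2 * h)
      d2 <- (ln_g(x1 + h, p2, mp2) - ln_g(x1 - h, p2, mp2)) / (2 * h)
      x1 * d1 + (1 - x1) * d2
    }
    r_h <- gd(1e-3); r_h2 <- gd(5e-4)
    expect_lt(abs(r_h), 1e-3)
    # the residual is pure central-difference error: it shrinks ~4x with h/2
    if (abs(r_h) > 1e-8) expect_lt(abs(r_h2), 0.5 * abs(r_h))
  }
})
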