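test_that("single symmetric proton transfer recovers the analytic quadratic root", {
  fx <- make_equilibrium_fixture(1, c(0, 0), seed = 7)   # K = 1
  res <- solve_speciation(fx$mix, fx$reactions)
  expect_equal(unname(res$x), rep(0.25, 4), tolerance = 1e-10)
  expect_equal(unname(res$extents), 0.5, tolerance = 1e-10)

  # strongly product-favoured: exact closed form, residual neutrals ~ sqrt(1/K)/2
  forms <- minimal_forms()
  K <- 1e9
  rx <- list(reaction("r", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms, K = K))
  mix <- mixture_spec(c(A = 1, B = 1), forms)
  res9 <- solve_speciation(mix, rx)
  oracle <- quadratic_equilibrium(K)
  expect_equal(res9$x[["A"]], oracle[["A"]], tolerance = 1e-8)
  expect_equal(res9$x[["A-"]], oracle[["C"]], tolerance = 1e-10)
  expect_equal(res9$x[["A"]], 1 / (2 * (1 + sqrt(K))), tolerance = 1e-8)
})

test_that("the reference three-reaction glutamic acid-proline system solves to the oracle", {
  sys <- nades_example_reactions()
  mix <- mixture_spec(c(`7` = 1, A = 1), sys$forms)
  res <- solve_speciation(mix, sys$reactions)
  expect_true(res$converged)
  expect_true(all(res$residuals < 1e-6))
  orc <- speciation_oracle(mix, sys$reactions)
  expect_lt(max(abs(res$x - orc[names(res$x)])), 1e-6)
  # ion pairing dominates: the most acidic carboxylate and the protonated amine
  dom <- dominant_forms(res, 0.01)
  expect_identical(names(dom)[1:2], c("P+", "G1-"))
})

test_that("solver composition matches the Gibbs-minimization oracle across random networks", {
  for (seed in 1:12) {
    n_rxn <- 1L + (seed %% 3L)
    fx <- make_equilibrium_fixture(n_rxn, c(-6, 6), seed = seed)
    res <- solve_speciation(fx$mix, fx$reactions)
    expect_lt(max(abs(res$x - fx$oracle[names(res$x)])), 1e-6)
    # conservation invariants
    expect_equal(sum(res$x), 1, tolerance = 1e-10)
    expect_true(all(res$x >= 0))
    expect_lt(abs(sum(res$x * fx$mix$forms$charge)), 1e-10)
    for (p in unique(fx$mix$forms$parent))
      expect_equal(sum(res$x[fx$mix$forms$parent == p]), 0.5,
                   tolerance = 1e-10)
    floorv <- 1e-25
    active <- vapply(fx$reactions, function(r)
      all(res$x[names(r$stoich)] > floorv), logical(1))
    expect_true(all(res$residuals[active] < 1e-6))
  }
})

test_that("composition is invariant to reaction order and monotone in K", {
  fx <- make_equilibrium_fixture(3, c(-3, 3), seed = 42)
  res_fwd <- solve_speciation(fx$mix, fx$reactions)
  res_rev <- solve_speciation(fx$mix, rev(fx$reactions))
  expect_lt(max(abs(res_fwd$x - res_rev$x[names(res_fwd$x)])), 1e-12)

  forms <- minimal_forms()
  mix <- mixture_spec(c(A = 1, B = 1), forms)
  xc <- vapply(10^seq(-6, 6, by = 1), function(K) {
    rx <- list(reaction("r", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms, K = K))
    solve_speciation(mix, rx)$x[["A-"]]
  }, numeric(1))
  expect_true(all(diff(xc) > 0))
})

test_that("vanishing K recovers the naive undissociated composition", {
  sys <- nades_example_reactions()
  tiny <- lapply(sys$reactions, function(r)
    reaction(r$reaction_id, r$stoich, sys$forms, K = 1e-14))
  mix <- mixture_spec(c(`7` = 1, A = 1), sys$forms)
  res <- solve_speciation(mix, tiny)
  expect_equal(res$x[["G"]], 0.5, tolerance = 1e-6)
  expect_equal(res$x[["P"]], 0.5, tolerance = 1e-6)
  expect_lt(sum(res$x[!names(res$x) %in% c("G", "P")]), 1e-6)
})

test_that("dominant-form filtering reports retained forms and discarded mass", {
  res <- fake_speciation_result(c(a = 0.5, b = 0.3, c = 0.15, d = 0.04, e = 0.01))
  all_forms <- dominant_forms(res, 0)
  expect_length(all_forms, 5L)
  expect_equal(attr(all_forms, "discarded"), 0)
  kept <- dominant_forms(res, 0.05)
  expect_identical(names(kept), c("a", "b", "c"))
  expect_equal(attr(kept, "discarded"), 0.05)
  one <- dominant_forms(fake_speciation_result(c(z = 1)), 1 - 1e-9)
  expect_identical(names(one), "z")
  expect_error(dominant_forms(res, 1), "threshold")
})

test_that("ill-posed speciation inputs are rejected", {
  forms <- minimal_forms()
  mix <- mixture_spec(c(A = 1, B = 1), forms)
  r1 <- reaction("r1", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms, K = 10)
  r2 <- reaction("r2", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms, K = 20)
  expect_error(solve_speciation(mix, list(r1, r2)), "conflicting K")
  bad <- r1; bad$K <- -1
  expect_error(solve_speciation(mix, list(bad)), "finite and > 0")
  expect_error(mixture_spec(c(A = 0, B = 1), forms), "> 0")
})
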