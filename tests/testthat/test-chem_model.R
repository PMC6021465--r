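test_that("equilibrium constant and reaction free energy are exact inverses", {
  cond <- thermo_conditions()
  expect_equal(equilibrium_constant(0, cond), 1)
  set.seed(11)
  dG <- runif(50, -15, 15)
  expect_equal(gibbs_from_K(equilibrium_constant(dG, cond), cond), dG,
               tolerance = 1e-12)
  K <- 10^runif(50, -8, 8)
  expect_true(all(abs(equilibrium_constant(gibbs_from_K(K, cond), cond) / K - 1)
                  < 1e-12))
  # strictly decreasing in dG at fixed T
  dG_sorted <- sort(dG)
  expect_true(all(diff(equilibrium_constant(dG_sorted, cond)) < 0))
  expect_error(equilibrium_constant(NaN), "finite")
  expect_error(gibbs_from_K(-1), "> 0")
})

test_that("reference proton-transfer constants reproduce the printed free energies", {
  cond <- thermo_conditions()
  expect_identical(round(gibbs_from_K(1.62e5, cond), 2), -7.11)
  expect_identical(round(gibbs_from_K(6.17e2, cond), 2), -3.81)
  expect_lt(abs(gibbs_from_K(1.02e4, cond) - (-5.48)), 0.015)
})

test_that("compound construction enforces identity and site invariants", {
  s_ac <- function(l, p = NA) ionizable_site(l, "acidic", p)
  s_ba <- function(l, p = NA) ionizable_site(l, "basic", p)
  expect_error(compound("z", "x", "NOT-AN-INCHIKEY", "amino_acid",
                        list(s_ac("c1"), s_ba("n1"))), "InChIKey")
  expect_error(compound("z", "x", "ONIBWKKTOPOVIA-BYPYZUCNSA-N",
                        "carboxylic_acid", list(s_ac("c1"))),
               "two acidic")
  expect_error(compound("z", "x", "ONIBWKKTOPOVIA-BYPYZUCNSA-N",
                        "amino_acid", list(s_ac("c1"))),
               "one acidic and one basic")
  expect_error(ionizable_site("c1", "acidic", 25), "range")
  cp <- compound("z", "x", "ONIBWKKTOPOVIA-BYPYZUCNSA-N", "amino_acid",
                 list(s_ac("c1", 2.0), s_ba("n1", 10.1)))
  expect_s3_class(cp, "nades_compound")
})

test_that("ionic-form enumeration yields the neutral plus one singly charged form per site", {
  lib <- nades_compound_library()
  glu <- enumerate_ionic_forms(lib[["7"]], prefix = "G")
  expect_setequal(glu$form_id, c("G", "G1-", "G2-", "G+"))
  expect_identical(sum(glu$charge == 0L), 1L)
  pro <- enumerate_ionic_forms(lib[["A"]], prefix = "P")
  expect_setequal(pro$form_id, c("P", "P-", "P+"))
  # site-driven: a single acidic site gives exactly neutral + anion
  one_acid <- structure(list(code = "Z", name = "z", inchikey = NA,
                             role = "carboxylic_acid",
                             sites = list(ionizable_site("c1", "acidic"))),
                        class = "nades_compound")
  expect_setequal(enumerate_ionic_forms(one_acid)$form_id, c("Z", "Z-"))
  no_sites <- structure(list(code = "Z", name = "z", sites = list()),
                        class = "nades_compound")
  expect_error(enumerate_ionic_forms(no_sites), "no ionizable sites")
  # never multiply charged
  orn <- enumerate_ionic_forms(lib[["D"]])
  expect_true(all(abs(orn$charge) <= 1L))
})

test_that("reaction enumeration pairs every anion with every counter-cation", {
  lib <- nades_compound_library()
  glu <- enumerate_ionic_forms(lib[["7"]], prefix = "G")
  pro <- enumerate_ionic_forms(lib[["A"]], prefix = "P")
  rx <- enumerate_reactions(glu, pro)
  expect_length(rx, 3L)
  sig <- vapply(rx, function(r)
    paste(sort(names(r$stoich)[r$stoich > 0]), collapse = "+"), character(1))
  expect_setequal(sig, c("G1-+P+", "G2-+P+", "G++P-"))
  # exhaustive pair-count oracle: nA_acid*nC_amino + nA_amino*nC_acid
  count_oracle <- function(af, mf) {
    sum(af$charge == -1L) * sum(mf$charge == 1L) +
      sum(mf$charge == -1L) * sum(af$charge == 1L)
  }
  orn <- enumerate_ionic_forms(lib[["D"]])
  expect_length(enumerate_reactions(glu, orn), count_oracle(glu, orn))
  mal <- enumerate_ionic_forms(lib[["16"]])  # two anions, no cation
  expect_length(enumerate_reactions(mal, pro), count_oracle(mal, pro))
  expect_error(enumerate_reactions(glu[glu$charge != 0L, ], pro),
               "neutral")
})

test_that("reaction constructor enforces conservation laws and the dG/K link", {
  forms <- minimal_forms()
  ok <- reaction("r1", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms, K = 10)
  expect_equal(ok$dG, gibbs_from_K(10))
  # charge conservation violation: anion produced without the cation
  expect_error(reaction("r2", c(A = -1, `A-` = 1), forms, K = 1), "charge")
  # parent mass violation (charge balanced, A not conserved)
  expect_error(reaction("r3", c(A = -2, B = -1, `A-` = 1, `B+` = 1), forms,
                        K = 1), "mass")
  # declared in the reversed direction: inverted on ingestion
  rev <- reaction("r4", c(`A-` = -1, `B+` = -1, A = 1, B = 1), forms, K = 0.1)
  expect_equal(rev$K, 10)
  expect_true(all(rev$stoich[c("A", "B")] == -1L))
  # inconsistent dG/K pair
  expect_error(reaction("r5", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms,
                        dG = -5, K = 10), "disagree")
  # consistent pair accepted
  ok2 <- reaction("r6", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms,
                  dG = gibbs_from_K(250), K = 250)
  expect_equal(ok2$K, 250)
  expect_error(reaction("r7", c(A = -1, B = -1, `A-` = 1, `B+` = 1), forms),
               "at least one")
})

test_that("packaged component library matches the study roster", {
  lib <- nades_compound_library()
  expect_length(lib, 27L)
  roles <- vapply(lib, `[[`, character(1), "role")
  expect_identical(sum(roles == "carboxylic_acid"), 21L)
  expect_identical(sum(roles == "amino_acid"), 6L)
  expect_identical(lib[["7"]]$name, "Glutamic acid")
  expect_identical(lib[["A"]]$inchikey, "ONIBWKKTOPOVIA-BYPYZUCNSA-N")
  ik <- vapply(lib, `[[`, character(1), "inchikey")
  expect_true(all(grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", ik)))
})
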