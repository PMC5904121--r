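test_that("hand-solvable toy LPs give the known optima", {
  expect_equal(fba(toy_chain_model(5))$growth_rate, 5, tolerance = 1e-9)
  expect_equal(fba(toy_chain_model(0))$growth_rate, 0, tolerance = 1e-9)
  # all exchanges closed to uptake: nothing to consume
  m <- set_medium(the_core(), character())
  expect_equal(fba(m)$growth_rate, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy mass balance and bounds", {
  m <- set_medium(the_augmented(), c("EX_glcn", "EX_meoh"))
  sol <- fba(m)
  expect_identical(sol$status, "optimal")
  S <- stoich_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  b <- flux_bounds(m)
  expect_true(all(sol$fluxes >= b$lower - 1e-6))
  expect_true(all(sol$fluxes <= b$upper + 1e-6))
  expect_equal(sol$fluxes[["BIOMASS"]], sol$growth_rate, tolerance = 1e-8)
})

test_that("simplex optimum equals exhaustive vertex enumeration on toys", {
  set.seed(17)
  for (rep in 1:30) {
    # random 2-metabolite, 5-reaction networks with random signed
    # stoichiometry and bounds; skip unbounded-looking cases by bounding all
    n <- 5
    S <- matrix(sample(c(-2, -1, 0, 1, 2), 2 * n, replace = TRUE), 2, n)
    if (qr(S)$rank < 2) next
    lb <- round(runif(n, -6, 0), 2)
    ub <- lb + round(runif(n, 0, 8), 2)
    cc <- round(rnorm(n), 2)
    res <- rumpdesign:::.simplex_lp(cc, S, c(0, 0), lb, ub, TRUE)
    oracle <- vertex_enum_max(S, lb, ub, cc)
    if (is.finite(oracle)) {
      expect_identical(res$status, "optimal")
      expect_equal(res$objective, oracle, tolerance = 1e-7)
    } else {
      expect_identical(res$status, "infeasible")
    }
  }
})

test_that("the two independent LP assemblies agree on the core model", {
  cfgs <- list(list(src = "EX_glcn", ko = character()),
               list(src = c("EX_glcn", "EX_meoh"), ko = c("EDD", "RPI")),
               list(src = "EX_meoh", ko = "MALDH"),
               list(src = "EX_ac", ko = "GND"))
  for (cs in cfgs) {
    m <- knockout(set_medium(the_augmented(), cs$src), reactions = cs$ko)
    direct <- fba(m)$growth_rate
    split <- rumpdesign:::.fba_split_formulation(m)$growth_rate
    expect_equal(direct, split, tolerance = 1e-6)
  }
})

test_that("growth_on composes medium, knockout and FBA", {
  a <- the_augmented()
  expect_gt(growth_on(a, "EX_glcn"), 0.01)      # wild type grows
  expect_gt(growth_on(a, "EX_meoh"), 0.01)      # methylotrophic potential
  expect_equal(growth_on(a, character()), 0)
  mu1 <- growth_on(a, "EX_glcn", reactions = c("EDD", "RPI"))
  mu2 <- growth_on(a, "EX_glcn", genes = c("edd", "rpiA", "rpiB"))
  expect_equal(mu1, mu2, tolerance = 1e-9)
})

test_that("knockout monotonicity: more deletions never increase growth", {
  a <- the_augmented()
  cand <- rumpdesign:::.ko_candidates(a)
  set.seed(23)
  for (i in 1:100) {
    A <- sample(cand, 2)
    B <- sample(cand, 2)
    # infeasible-to-zero mapping may warn; irrelevant to monotonicity
    mu_A <- suppressWarnings(growth_on(a, "EX_glcn", reactions = A))
    mu_AB <- suppressWarnings(growth_on(a, "EX_glcn",
                                        reactions = union(A, B)))
    expect_lte(mu_AB, mu_A + 1e-6)
  }
})

test_that("LP homogeneity: doubling the uptake doubles the optimum", {
  a <- the_augmented()
  for (src in list("EX_glcn", "EX_meoh", c("EX_glcn", "EX_meoh"))) {
    mu1 <- growth_on(a, src, uptake_rate = 7)
    mu2 <- growth_on(a, src, uptake_rate = 14)
    expect_equal(mu2, 2 * mu1, tolerance = 1e-6)
  }
})

test_that("solver status is explicit, never a silent zero", {
  # infeasible: force flux through a reaction with no open exchange
  m <- set_medium(the_core(), character())
  m$reactions$GLCNt$lower_bound <- 1  # demand uptake of an absent substrate
  sol <- fba(m)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$growth_rate))
  expect_warning(mu <- growth_on(the_core(), character()) , NA)
})
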