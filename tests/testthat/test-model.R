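test_that("the packaged core model is well formed", {
  m <- the_core()
  expect_s3_class(m, "metabolic_model")
  expect_gte(length(m$reactions), 60)
  expect_identical(m$objective, "BIOMASS")
  expect_equal(sum(names(m$reactions) == "BIOMASS"), 1L)
  expect_silent(validate_model(m))
})

test_that("model validation errors name the offending field", {
  mets <- data.frame(id = "A", name = "A", compartment = "c", n_carbon = 1L)
  rx_ok <- list(id = "R1", stoich = c(A = -1), is_exchange = TRUE)
  expect_error(
    metabolic_model(mets, list(list(id = "R1", stoich = c(B = -1))),
                    objective = "R1"),
    "unknown metabolite.*B")
  expect_error(metabolic_model(mets, list(), objective = "R1"),
               "empty reaction list")
  expect_error(metabolic_model(mets, list(rx_ok), objective = "NOPE"),
               "objective")
  bad_bounds <- list(id = "R1", stoich = c(A = -1), lower_bound = 2,
                     upper_bound = 1)
  expect_error(metabolic_model(mets, list(bad_bounds), objective = "R1"),
               "lower_bound > upper_bound")
  two_mets <- rbind(mets, data.frame(id = "B", name = "B",
                                     compartment = "c", n_carbon = 1L))
  bad_ex <- list(id = "EX", stoich = c(A = -1, B = 1), is_exchange = TRUE)
  expect_error(metabolic_model(two_mets, list(bad_ex), objective = "EX"),
               "exactly one metabolite")
})

test_that("every internal reaction of the core model is carbon balanced", {
  m <- the_core()
  bal <- carbon_balance(m)
  is_ex <- vapply(m$reactions, `[[`, logical(1), "is_exchange")
  internal <- setdiff(names(m$reactions)[!is_ex], "BIOMASS")
  expect_true(all(abs(bal[internal]) < 1e-9))
  # exchanges of carbon metabolites are deliberately unbalanced
  expect_true(abs(bal[["EX_glcn"]]) > 0)
})

test_that("stoichiometric matrix matches reaction definitions", {
  m <- toy_chain_model()
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(3L, 4L))
  expect_equal(unname(S[, "CONV"]), c(0, -1, 1))
  expect_equal(unname(S[, "EX_A"]), c(-1, 0, 0))
  Sc <- stoich_matrix(the_core())
  expect_equal(ncol(Sc), length(the_core()$reactions))
  expect_equal(rownames(Sc), the_core()$metabolites$id)
})

test_that("knockout zeroes bounds of targeted reactions only", {
  m <- the_core()
  ko <- knockout(m, genes = "edd")
  expect_equal(ko$reactions$EDD$upper_bound, 0)
  expect_equal(ko$reactions$EDD$lower_bound, 0)
  untouched <- setdiff(names(m$reactions), "EDD")
  for (rid in untouched) {
    expect_identical(ko$reactions[[rid]]$lower_bound,
                     m$reactions[[rid]]$lower_bound)
    expect_identical(ko$reactions[[rid]]$upper_bound,
                     m$reactions[[rid]]$upper_bound)
  }
  # isozyme OR semantics: one rpi gene leaves RPI active
  ko_rpiA <- knockout(m, genes = "rpiA")
  expect_gt(ko_rpiA$reactions$RPI$upper_bound, 0)
  ko_both <- knockout(m, genes = c("rpiA", "rpiB"))
  expect_equal(ko_both$reactions$RPI$upper_bound, 0)
  expect_error(knockout(m, genes = "nogene"), "unknown gene")
  expect_error(knockout(m, reactions = "NOPE"), "unknown reaction")
})

test_that("knockout is idempotent and monotone in deactivated reactions", {
  m <- the_core()
  set.seed(5)
  genes <- m$genes
  for (i in 1:10) {
    gs <- sample(genes, 4)
    once <- knockout(m, genes = gs)
    twice <- knockout(once, genes = gs)
    expect_identical(flux_bounds(once), flux_bounds(twice))
    sub <- reactions_disabled_by(m, gs[1:2])
    sup <- reactions_disabled_by(m, gs)
    expect_true(all(sub %in% sup))
  }
})

test_that("set_medium opens listed sources and closes other carbon uptake", {
  m <- set_medium(the_core(), c("EX_glcn", "EX_meoh"), 7)
  expect_equal(m$reactions$EX_glcn$lower_bound, -7)
  expect_equal(m$reactions$EX_meoh$lower_bound, -7)
  expect_equal(m$reactions$EX_glc$lower_bound, 0)   # carbon: closed
  expect_equal(m$reactions$EX_co2$lower_bound, 0)   # carbon: closed
  expect_equal(m$reactions$EX_o2$lower_bound, -1000)  # inorganic: open
  expect_equal(m$reactions$EX_nh4$lower_bound, -1000)
  # secretion stays possible for every exchange
  ubs <- vapply(exchange_ids(m), function(r) m$reactions[[r]]$upper_bound,
                numeric(1))
  expect_true(all(ubs > 0))
  expect_error(set_medium(the_core(), "GNTK"), "not an exchange")
  # rate 0 equals an empty source set, flux-wise
  expect_identical(flux_bounds(set_medium(the_core(), "EX_glc", 0)),
                   flux_bounds(set_medium(the_core(), character())))
})

test_that("RuMP augmentation adds three carbon-balanced reactions once", {
  m <- the_core()
  a <- add_rump_pathway(m)
  expect_setequal(setdiff(names(a$reactions), names(m$reactions)),
                  c("MDH", "HPS", "PHI"))
  bal <- carbon_balance(a)[c("MDH", "HPS", "PHI")]
  expect_true(all(abs(bal) < 1e-9))
  expect_true("h6p_c" %in% a$metabolites$id)
  # the base model is untouched
  expect_false("MDH" %in% names(m$reactions))
  expect_error(add_rump_pathway(a), "already present")
  m2 <- m
  m2$metabolites <- m2$metabolites[m2$metabolites$id != "fald_c", ]
  m2$reactions <- m2$reactions[!vapply(m2$reactions, function(r)
    "fald_c" %in% names(r$stoich), logical(1))]
  expect_error(add_rump_pathway(m2), "fald_c")
})

test_that("JSON round trip preserves the flux-relevant model exactly", {
  m <- the_core()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- read_model_json(path)
  expect_equal(stoich_matrix(m2), stoich_matrix(m))
  expect_equal(flux_bounds(m2), flux_bounds(m))
  expect_identical(m2$objective, m$objective)
  expect_identical(m2$genes, m$genes)
  expect_equal(fba(set_medium(m2, "EX_glc"))$growth_rate,
               fba(set_medium(m, "EX_glc"))$growth_rate, tolerance = 1e-9)
})

test_that("the shipped core-model JSON matches the generator", {
  path <- system.file("extdata", "ecoli_core_rump.json",
                      package = "rumpdesign")
  expect_true(nzchar(path))
  shipped <- load_model(path)
  expect_gte(length(shipped$reactions), 60)
  expect_equal(stoich_matrix(shipped), stoich_matrix(the_core()))
  expect_equal(flux_bounds(shipped), flux_bounds(the_core()))
})

test_that("SBML Level 3 FBC import reads species, GPRs, bounds, objective", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_toy_sbml(path)
  m <- load_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_identical(m$objective, "GROW")
  expect_equal(nrow(m$metabolites), 3L)
  expect_equal(m$metabolites$n_carbon[m$metabolites$id == "A_c"], 2L)
  expect_equal(m$reactions$EX_A$lower_bound, -4)
  expect_identical(m$reactions$T_A$gene_rule, "tA")
  expect_match(m$reactions$CONV$gene_rule, "cv1 or cv2")
  expect_equal(unname(m$reactions$CONV$stoich[c("A_c", "B_c")]), c(-1, 2))
  # A (2 carbons) -> 2 B; uptake 4 -> growth 8
  expect_equal(fba(m)$growth_rate, 8, tolerance = 1e-8)
})
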