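cfg <- search_config()

test_that("classification separates essential, non-rescuable and neutral", {
  a <- the_augmented()
  g <- classify_knockout(a, reactions = c("EDD", "RPI"),
                         co_substrate = "EX_glcn", config = cfg)
  expect_identical(g$classification, "methanol_essential")
  expect_lte(g$mu_co, cfg$growth_threshold)
  expect_gt(g$mu_co_meoh, cfg$growth_threshold)
  expect_gt(g$mu_meoh, cfg$growth_threshold)
  expect_equal(g$differential_score, g$mu_co_meoh - g$mu_co)

  # co-substrate transporter knockout: methanol cannot rescue gluconate use
  gt <- classify_knockout(a, reactions = "GLCNt",
                          co_substrate = "EX_glcn", config = cfg)
  expect_identical(gt$classification, "non_rescuable")
  # kinase knockout likewise
  gk <- classify_knockout(a, reactions = "GNTK",
                          co_substrate = "EX_glcn", config = cfg)
  expect_identical(gk$classification, "non_rescuable")

  g0 <- classify_knockout(a, co_substrate = "EX_glcn", config = cfg)
  expect_identical(g0$classification, "neutral")
  expect_gt(g0$mu_co, cfg$growth_threshold)
})

test_that("gene knockouts route through GPR rules in classification", {
  a <- the_augmented()
  g <- classify_knockout(a, genes = c("edd", "rpiA", "rpiB"),
                         co_substrate = "EX_glcn", config = cfg)
  expect_setequal(g$deleted_reactions, c("EDD", "RPI"))
  expect_identical(g$classification, "methanol_essential")
})

test_that("single-knockout screen is exhaustive, ordered and deterministic", {
  a <- the_augmented()
  screened <- screen_knockouts(a, character(), "EX_glcn", cfg)
  cand <- rumpdesign:::.ko_candidates(a)
  expect_length(screened, length(cand))
  ids <- vapply(screened, function(g) g$deleted_reactions, character(1))
  expect_identical(ids, cand)  # lexicographic candidate order
  # no single knockout couples methanol on gluconate
  cls <- vapply(screened, `[[`, character(1), "classification")
  expect_false(any(cls == "methanol_essential"))
  # deleting EDD on a fixed EDD background changes nothing: candidates only
  on_edd <- screen_knockouts(a, "EDD", "EX_glcn", cfg)
  expect_length(on_edd, length(cand) - 1L)
  ess <- vapply(on_edd, `[[`, character(1), "classification") ==
    "methanol_essential"
  expect_true(any(vapply(on_edd[ess], function(g)
    setequal(g$deleted_reactions, c("EDD", "RPI")), logical(1))))
})

test_that("differential ranking orders by score with lexicographic ties", {
  mk <- function(rxn, score, cls = "neutral") {
    structure(list(deleted_reactions = rxn, deleted_genes = character(),
                   co_substrate = "EX_glcn", mu_co = 0.5,
                   mu_co_meoh = 0.5 + score, mu_meoh = 0.1,
                   classification = cls, differential_score = score),
              class = "knockout_genotype")
  }
  ranked <- rank_differential_fitness(list(
    mk("B", 0.1), mk("A", 0.3), mk("D", 0.1), mk("C", 0.1),
    mk("X", 0.9, cls = "non_rescuable")))
  ids <- vapply(ranked, function(g) g$deleted_reactions, character(1))
  expect_identical(ids, c("A", "B", "C", "D"))
  expect_identical(rank_differential_fitness(list(mk("X", 1, "non_rescuable"))),
                   list())
})

test_that("beam search recovers the gluconate design and is deterministic", {
  a <- the_augmented()
  rep1 <- methanol_essential_search(a, "EX_glcn",
                                    search_config(max_depth = 3))
  keys <- vapply(rep1$genotypes, function(g)
    paste(g$deleted_reactions, collapse = "+"), character(1))
  expect_true("EDD+RPI" %in% keys)
  edd_rpi <- rep1$genotypes[[which(keys == "EDD+RPI")]]
  expect_setequal(edd_rpi$deleted_genes, c("edd", "rpiA", "rpiB"))
  # byte-identical serialisation on re-run
  rep2 <- methanol_essential_search(a, "EX_glcn",
                                    search_config(max_depth = 3))
  expect_identical(jsonlite::toJSON(rep1$trace, digits = NA),
                   jsonlite::toJSON(rep2$trace, digits = NA))
  expect_identical(keys, vapply(rep2$genotypes, function(g)
    paste(g$deleted_reactions, collapse = "+"), character(1)))
})

test_that("every reported genotype satisfies the soundness inequalities", {
  a <- the_augmented()
  rep <- methanol_essential_search(a, "EX_glcn", cfg)
  expect_gt(length(rep$genotypes), 0)
  eps <- cfg$growth_threshold
  for (g in rep$genotypes) {
    chk <- classify_knockout(a, reactions = g$deleted_reactions,
                             co_substrate = "EX_glcn", config = cfg)
    expect_lte(chk$mu_co, eps)
    expect_gt(chk$mu_co_meoh, eps)
    expect_gt(chk$mu_meoh, eps)
    expect_lte(chk$mu_co, chk$mu_co_meoh + 1e-9)  # substrate monotonicity
  }
})

test_that("hexose-family substrates need multiple knockouts; gluconeogenic
           substrates can be coupled by a single cut", {
  a <- the_augmented()
  # no single knockout couples methanol on gluconate or glucose
  for (src in c("EX_glcn", "EX_glc")) {
    rep <- methanol_essential_search(a, src, search_config(max_depth = 1))
    expect_length(rep$genotypes, 0)
  }
  # on acetate, cutting the glyoxylate shunt leaves acetate as an energy
  # source only, so biomass carbon must come from methanol: a single-KO
  # coupling
  rep_ac <- methanol_essential_search(a, "EX_ac",
                                      search_config(max_depth = 1))
  keys <- vapply(rep_ac$genotypes, function(g)
    paste(g$deleted_reactions, collapse = "+"), character(1))
  expect_true(all(c("ICL", "MALS") %in% keys))
})

test_that("maldh and the oxidative TCA cycle are dispensable with methanol", {
  a <- the_augmented()
  res <- reaction_dispensability(a, c("MALDH", "EDD", "RPI"),
                                 c("EX_glcn", "EX_meoh"), cfg)
  expect_true(res$dispensable)
  expect_gt(res$growth_rate, cfg$growth_threshold)
  # the sole producer of a biomass precursor is not dispensable: citrate
  # synthase is the only route to 2-oxoglutarate
  res2 <- reaction_dispensability(a, "CS", c("EX_glcn", "EX_meoh"), cfg)
  expect_false(res2$dispensable)
  # empty set is dispensable whenever the base model grows
  res3 <- reaction_dispensability(a, character(), "EX_glcn", cfg)
  expect_true(res3$dispensable)
})

test_that("gene mapping yields all minimal realising gene sets", {
  m <- the_core()
  sets <- genes_for_reactions(m, c("EDD", "RPI"))
  expect_length(sets, 1L)
  expect_setequal(sets[[1]], c("edd", "rpiA", "rpiB"))
  # PFK has isozymes: both genes needed, and nothing else is hit
  sets2 <- genes_for_reactions(m, "PFK")
  expect_length(sets2, 1L)
  expect_setequal(sets2[[1]], c("pfkA", "pfkB"))
  # a spontaneous reaction cannot be realised by gene deletion
  expect_length(genes_for_reactions(m, "MEOHt"), 0L)
  # deleting tkt genes would hit TKT1 and TKT2 together: no exact single map
  expect_length(genes_for_reactions(m, "TKT1"), 0L)
})
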