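#' Configuration of the methanol-essentiality screen
#'
#' @param growth_threshold essentiality threshold epsilon in h^-1; predicted
#'   growth at or below it counts as "no growth" (default 0.01).
#' @param uptake_rate uptake bound per carbon source, mmol gCDW^-1 h^-1
#'   (default 7).
#' @param co_substrates exchange ids of the multi-carbon sources screened as
#'   methanol co-substrates (default: the eight-substrate panel of acetate,
#'   gluconate, glucose, glycerol, pyruvate, ribose, xylose, succinate).
#' @param max_depth maximum number of stacked knockouts explored (default 4).
#' @param beam_width number of best knockout backgrounds carried to the next
#'   depth (default 5).
#' @param require_methylotrophy if `TRUE` (default) a genotype only counts as
#'   methanol essential when it also retains growth on methanol as the sole
#'   carbon source.
#' @param stop_at_first_depth if `TRUE` (default) the iterative search stops
#'   at the shallowest depth at which a methanol-essential genotype is found;
#'   set `FALSE` to keep extending to `max_depth` (e.g. to compare against
#'   exhaustive enumeration).
#' @param methanol_exchange exchange id of methanol.
#' @return An object of class `search_config`.
#' @export
search_config <- function(growth_threshold = 0.01, uptake_rate = 7,
                          co_substrates = c("EX_ac", "EX_glcn", "EX_glc",
                                            "EX_glyc", "EX_pyr", "EX_rib",
                                            "EX_xyl", "EX_succ"),
                          max_depth = 4L, beam_width = 5L,
                          require_methylotrophy = TRUE,
                          stop_at_first_depth = TRUE,
                          methanol_exchange = "EX_meoh") {
  stopifnot(growth_threshold > 0, max_depth >= 1L, beam_width >= 1L,
            uptake_rate >= 0)
  structure(list(growth_threshold = growth_threshold,
                 uptake_rate = uptake_rate, co_substrates = co_substrates,
                 max_depth = as.integer(max_depth),
                 beam_width = as.integer(beam_width),
                 require_methylotrophy = isTRUE(require_methylotrophy),
                 stop_at_first_depth = isTRUE(stop_at_first_depth),
                 methanol_exchange = methanol_exchange),
            class = "search_config")
}

# Pre-assembled diagnostic media problems for one (model, co-substrate)
# combination; knockouts are applied by zeroing bound entries, which avoids
# rebuilding the stoichiometric matrix in the screening loops.
.screen_context <- function(model, co_substrate, config,
                            fba_cfg = fba_config()) {
  mk <- function(sources) {
    .fba_problem(set_medium(model, sources, config$uptake_rate))
  }
  list(model = model,
       co = mk(co_substrate),
       co_meoh = mk(c(co_substrate, config$methanol_exchange)),
       meoh = mk(config$methanol_exchange),
       co_substrate = co_substrate,
       config = config, fba_cfg = fba_cfg)
}

.ctx_growth <- function(ctx, medium, ko_idx) {
  prob <- ctx[[medium]]
  lower <- prob$lower; upper <- prob$upper
  lower[ko_idx] <- 0; upper[ko_idx] <- 0
  res <- .fba_solve_raw(prob, ctx$fba_cfg, lower, upper)
  if (res$status == "infeasible") return(list(mu = 0, flux = NULL))
  if (res$status != "optimal")
    stop("FBA failed (", res$status, ") during screening", call. = FALSE)
  list(mu = res$objective, flux = as.numeric(res$x))
}

.classify_rates <- function(mu_co, mu_co_meoh, mu_meoh, config) {
  eps <- config$growth_threshold
  rescued <- mu_co_meoh > eps &&
    (mu_co_meoh - mu_meoh) > eps  # methanol must rescue co-substrate growth,
                                  # not merely replace it (transporter KOs
                                  # grow on methanol alone but are unrescued)
  if (mu_co <= eps && rescued &&
      (!config$require_methylotrophy || mu_meoh > eps)) {
    "methanol_essential"
  } else if (mu_co <= eps) {
    "non_rescuable"
  } else {
    "neutral"
  }
}

.make_genotype <- function(ctx, ko_ids, mu_co, mu_co_meoh, mu_meoh) {
  structure(list(
    deleted_reactions = sort(ko_ids),
    deleted_genes = .primary_gene_set(ctx$model, sort(ko_ids)),
    co_substrate = ctx$co_substrate,
    mu_co = mu_co, mu_co_meoh = mu_co_meoh, mu_meoh = mu_meoh,
    classification = .classify_rates(mu_co, mu_co_meoh, mu_meoh,
                                     ctx$config),
    differential_score = mu_co_meoh - mu_co),
    class = "knockout_genotype")
}

#' @export
print.knockout_genotype <- function(x, ...) {
  cat("<knockout_genotype> {", paste(x$deleted_reactions, collapse = ", "),
      "} on ", x$co_substrate, "\n",
      "  genes: ", paste(x$deleted_genes, collapse = ", "), "\n",
      sprintf("  mu(co) = %.4g, mu(co+MeOH) = %.4g, mu(MeOH) = %.4g\n",
              x$mu_co, x$mu_co_meoh, x$mu_meoh),
      "  classification: ", x$classification, "\n", sep = "")
  invisible(x)
}

#' Classify a knockout set on a co-substrate
#'
#' Computes predicted growth under the three diagnostic media (co-substrate
#' alone, co-substrate plus methanol, methanol alone) and classifies the
#' genotype. A genotype is `methanol_essential` when growth on the
#' co-substrate alone is at or below the threshold, adding methanol restores
#' growth above both the threshold and the methanol-only rate (i.e. the
#' co-substrate is actually co-consumed), and -- when methylotrophy retention
#' is required -- methanol alone still supports growth. Knockouts that
#' methanol cannot rescue (e.g. co-substrate transporters) are
#' `non_rescuable`; genotypes still growing on the co-substrate are
#' `neutral`, with the differential fitness score
#' mu(co+MeOH) - mu(co) recorded.
#'
#' @param model a `metabolic_model` augmented with the RuMP entry reactions.
#' @param reactions reaction ids to delete.
#' @param genes gene ids to delete (translated through GPR rules).
#' @param co_substrate exchange id of the co-substrate.
#' @param config a [search_config()].
#' @return An object of class `knockout_genotype`.
#' @examples
#' m <- add_rump_pathway(core_model())
#' classify_knockout(m, reactions = c("EDD", "RPI"), co_substrate = "EX_glcn")
#' @export
classify_knockout <- function(model, reactions = character(),
                              genes = character(),
                              co_substrate, config = search_config()) {
  if (length(genes))
    reactions <- union(reactions, reactions_disabled_by(model, genes))
  unknown <- setdiff(reactions, names(model$reactions))
  if (length(unknown))
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ctx <- .screen_context(model, co_substrate, config)
  idx <- match(reactions, ctx$co$reaction_ids)
  mu_co <- .ctx_growth(ctx, "co", idx)$mu
  mu_co_meoh <- .ctx_growth(ctx, "co_meoh", idx)$mu
  mu_meoh <- .ctx_growth(ctx, "meoh", idx)$mu
  .make_genotype(ctx, reactions, mu_co, mu_co_meoh, mu_meoh)
}

# Reactions eligible for knockout: internal, non-objective and
# gene-associated (spontaneous diffusion and maintenance pseudo-reactions
# cannot be removed by a gene deletion).
.ko_candidates <- function(model) {
  ids <- names(model$reactions)
  keep <- !vapply(model$reactions, `[[`, logical(1), "is_exchange") &
    ids != model$objective &
    nzchar(vapply(model$reactions, `[[`, character(1), "gene_rule"))
  sort(ids[keep])
}

#' Screen all single-reaction knockouts on a background
#'
#' Classifies every candidate single internal-reaction deletion stacked on a
#' fixed knockout background, in deterministic (lexicographic) order.
#'
#' @param model augmented `metabolic_model`.
#' @param fixed_reactions knockout background applied to every candidate.
#' @param co_substrate exchange id of the co-substrate.
#' @param config a [search_config()].
#' @return List of `knockout_genotype`, one per candidate reaction.
#' @export
screen_knockouts <- function(model, fixed_reactions = character(),
                             co_substrate, config = search_config()) {
  ctx <- .screen_context(model, co_substrate, config)
  candidates <- setdiff(.ko_candidates(model), fixed_reactions)
  fixed_idx <- match(fixed_reactions, ctx$co$reaction_ids)
  # optimal flux vectors of the background: a candidate reaction carrying no
  # flux in a medium's optimum cannot change that optimum when deleted
  # (the solution stays feasible and the knockout only restricts), so the
  # background growth rate is reused exactly
  media <- c("co", "co_meoh", "meoh")
  parent <- lapply(media, function(md) .ctx_growth(ctx, md, fixed_idx))
  names(parent) <- media
  zero_tol <- ctx$fba_cfg$zero_tol
  lapply(candidates, function(r) {
    ko <- sort(c(fixed_reactions, r))
    ri <- match(r, ctx$co$reaction_ids)
    idx <- c(fixed_idx, ri)
    mu <- vapply(media, function(md) {
      p <- parent[[md]]
      if (!is.null(p$flux) && abs(p$flux[ri]) <= zero_tol) p$mu
      else .ctx_growth(ctx, md, idx)$mu
    }, numeric(1))
    .make_genotype(ctx, ko, mu[["co"]], mu[["co_meoh"]], mu[["meoh"]])
  })
}

#' Rank neutral knockout candidates by differential fitness
#'
#' Orders neutral candidates by descending differential fitness score
#' mu(co+MeOH) - mu(co); ties are broken lexicographically by the deleted
#' reaction ids. Non-rescuable and methanol-essential candidates are
#' excluded from the ranking.
#'
#' @param genotypes list of `knockout_genotype` from [screen_knockouts()].
#' @return Ordered list of the neutral `knockout_genotype`s.
#' @export
rank_differential_fitness <- function(genotypes) {
  neutral <- Filter(function(g) g$classification == "neutral", genotypes)
  if (length(neutral) == 0L) return(list())
  score <- vapply(neutral, `[[`, numeric(1), "differential_score")
  key <- vapply(neutral, function(g)
    paste(g$deleted_reactions, collapse = "+"), character(1))
  neutral[order(-score, key)]
}

.genotype_key <- function(g) paste(g$deleted_reactions, collapse = "+")

#' Iterative beam search for methanol-essential genotypes
#'
#' Reproduces the iterative knockout workflow: at each depth the
#' `beam_width` best knockout backgrounds (by differential fitness ranking)
#' are each extended by one further reaction deletion; every
#' methanol-essential genotype encountered is collected and re-verified by
#' direct [classify_knockout()] calls. By default the search stops at the
#' shallowest depth at which a solution exists. The report is deterministic
#' for a fixed model and configuration.
#'
#' @param model augmented `metabolic_model`.
#' @param co_substrate exchange id of the co-substrate.
#' @param config a [search_config()].
#' @return An object of class `search_report`: the co-substrate, the list of
#'   methanol-essential `genotypes` found (deduplicated, lexicographic
#'   order), and a `trace` data.frame recording every screened candidate
#'   (depth, background, candidate, growth rates, classification).
#' @examples
#' m <- add_rump_pathway(core_model())
#' rep <- methanol_essential_search(m, "EX_glcn",
#'                                  search_config(max_depth = 2))
#' sapply(rep$genotypes, function(g) paste(g$deleted_reactions, collapse = "+"))
#' @export
methanol_essential_search <- function(model, co_substrate,
                                      config = search_config()) {
  frontier <- list(character())
  found <- list()
  trace <- list()
  for (depth in seq_len(config$max_depth)) {
    level <- list()
    for (fixed in frontier) {
      screened <- screen_knockouts(model, fixed, co_substrate, config)
      for (g in screened) {
        trace[[length(trace) + 1L]] <- data.frame(
          depth = depth,
          background = paste(fixed, collapse = "+"),
          candidate = setdiff(g$deleted_reactions, fixed)[1],
          mu_co = g$mu_co, mu_co_meoh = g$mu_co_meoh, mu_meoh = g$mu_meoh,
          differential = g$differential_score,
          classification = g$classification,
          stringsAsFactors = FALSE)
      }
      level <- c(level, screened)
    }
    keys <- vapply(level, .genotype_key, character(1))
    level <- level[!duplicated(keys)]

    ess <- Filter(function(g) g$classification == "methanol_essential",
                  level)
    if (length(ess)) {
      # re-verification through the public, independent entry point
      ess <- Filter(function(g) {
        chk <- classify_knockout(model, reactions = g$deleted_reactions,
                                 co_substrate = co_substrate,
                                 config = config)
        chk$classification == "methanol_essential"
      }, ess)
      found <- c(found, ess)
    }
    if (length(found) && config$stop_at_first_depth) break
    if (depth == config$max_depth) break
    ranked <- rank_differential_fitness(level)
    frontier <- lapply(head(ranked, config$beam_width),
                       `[[`, "deleted_reactions")
    if (length(frontier) == 0L) break
  }
  found <- found[!duplicated(vapply(found, .genotype_key, character(1)))]
  found <- found[order(vapply(found, .genotype_key, character(1)))]
  structure(list(co_substrate = co_substrate,
                 genotypes = found,
                 trace = do.call(rbind, trace),
                 config = config),
            class = "search_report")
}

#' @export
print.search_report <- function(x, ...) {
  cat("<search_report> co-substrate:", x$co_substrate, "\n")
  if (length(x$genotypes) == 0L) {
    cat("  no methanol-essential genotype found\n")
  } else {
    for (g in x$genotypes)
      cat("  {", paste(g$deleted_reactions, collapse = ", "),
          "} -> genes {", paste(g$deleted_genes, collapse = ", "), "}\n")
  }
  cat("  candidates screened:", nrow(x$trace), "\n")
  invisible(x)
}

#' Exhaustively enumerate minimal methanol-essential knockout sets
#'
#' Brute-force enumeration of all internal-reaction subsets up to
#' `max_size`, classifying each and returning the minimal
#' methanol-essential sets (no essential proper subset). Feasible flux
#' vectors from previous solves are reused as certificates: a cached
#' co-substrate flux distribution with growth above threshold that carries
#' no flux through a candidate set proves the set cannot be
#' methanol-essential without another LP solve.
#'
#' @param model augmented `metabolic_model`.
#' @param co_substrate exchange id of the co-substrate.
#' @param config a [search_config()].
#' @param max_size largest knockout set size enumerated (default 3).
#' @return List of `knockout_genotype`, minimal sets only, in lexicographic
#'   order.
#' @export
enumerate_methanol_essential <- function(model, co_substrate,
                                         config = search_config(),
                                         max_size = 3L) {
  ctx <- .screen_context(model, co_substrate, config)
  candidates <- .ko_candidates(model)
  ncand <- length(candidates)
  cand_idx <- match(candidates, ctx$co$reaction_ids)
  eps <- config$growth_threshold
  zero_tol <- ctx$fba_cfg$zero_tol

  # certificate pool for the co-substrate medium: row = cached feasible
  # solution with growth above threshold, col = candidate; TRUE when the
  # cached flux avoids that reaction. A row avoiding a whole knockout set
  # proves the set still grows on the co-substrate alone.
  pool <- matrix(logical(0), nrow = 0, ncol = ncand)
  pool_max <- 256L
  add_cert <- function(flux) {
    if (is.null(flux) || nrow(pool) >= pool_max) return()
    pool <<- rbind(pool, abs(flux[cand_idx]) <= zero_tol)
  }

  base <- .ctx_growth(ctx, "co", integer())
  if (base$mu > eps) add_cert(base$flux)

  essential <- list()
  ess_sets <- list()      # index sets of found essential knockouts
  dead_sets <- list()     # index sets dead even with methanol (or without
                          # methylotrophic potential): supersets can never
                          # be methanol essential, by knockout monotonicity
  dead_single <- rep(FALSE, ncand)

  classify_subset <- function(cb) {
    idx <- cand_idx[cb]
    co <- .ctx_growth(ctx, "co", idx)
    if (co$mu > eps) {
      add_cert(co$flux)
      return(NULL)
    }
    mu_co_meoh <- .ctx_growth(ctx, "co_meoh", idx)$mu
    if (mu_co_meoh <= eps) {
      dead_sets[[length(dead_sets) + 1L]] <<- cb
      if (length(cb) == 1L) dead_single[cb] <<- TRUE
      return(NULL)
    }
    mu_meoh <- .ctx_growth(ctx, "meoh", idx)$mu
    if (config$require_methylotrophy && mu_meoh <= eps) {
      dead_sets[[length(dead_sets) + 1L]] <<- cb
      if (length(cb) == 1L) dead_single[cb] <<- TRUE
      return(NULL)
    }
    g <- .make_genotype(ctx, candidates[cb], co$mu, mu_co_meoh, mu_meoh)
    if (g$classification == "methanol_essential") {
      essential[[length(essential) + 1L]] <<- g
      ess_sets[[length(ess_sets) + 1L]] <<- cb
    }
    NULL
  }

  for (size in seq_len(max_size)) {
    combos <- combn(ncand, size)
    for (k in seq_len(ncol(combos))) {
      cb <- combos[, k]
      if (any(dead_single[cb])) next
      # supersets of a known essential set are never minimal; supersets of a
      # methanol-dead set are never essential
      if (length(ess_sets) &&
          any(vapply(ess_sets, function(s) all(s %in% cb), logical(1))))
        next
      if (length(dead_sets) &&
          any(vapply(dead_sets, function(s) all(s %in% cb), logical(1))))
        next
      if (nrow(pool) &&
          any(rowSums(pool[, cb, drop = FALSE]) == length(cb)))
        next  # certified: still grows on the co-substrate alone
      classify_subset(cb)
    }
  }
  essential[order(vapply(essential, .genotype_key, character(1)))]
}

#' Check whether a reaction set is dispensable on a medium
#'
#' Used for design checks such as confirming that the NAD-dependent malate
#' dehydrogenase (and with it a closed oxidative TCA cycle) is not required
#' for growth on gluconate plus methanol.
#'
#' @param model augmented `metabolic_model`.
#' @param reactions reaction ids to delete.
#' @param carbon_sources exchange ids of the medium.
#' @param config a [search_config()].
#' @return list with `dispensable` (logical: growth above threshold with the
#'   deletions applied) and `growth_rate`.
#' @examples
#' m <- add_rump_pathway(core_model())
#' reaction_dispensability(m, c("MALDH", "EDD", "RPI"),
#'                         c("EX_glcn", "EX_meoh"))
#' @export
reaction_dispensability <- function(model, reactions, carbon_sources,
                                    config = search_config()) {
  mu <- growth_on(model, carbon_sources, config$uptake_rate,
                  reactions = reactions)
  list(dispensable = mu > config$growth_threshold, growth_rate = mu)
}

# All minimal gene deletion sets that deactivate exactly the given reactions
# (deactivating no other reaction of the model).
.gene_sets_for_reactions <- function(model, reactions) {
  if (length(reactions) == 0L) return(list(character()))
  cuts <- lapply(reactions, function(rid) {
    tree <- parse_gene_rule(model$reactions[[rid]]$gene_rule)
    .gpr_cut_sets(tree)
  })
  if (any(vapply(cuts, length, integer(1)) == 0L))
    return(list())  # some reaction has no gene association: gene KO impossible
  acc <- list(character())
  for (cs in cuts) {
    acc <- unlist(lapply(acc, function(a)
      lapply(cs, function(b) sort(unique(c(a, b))))), recursive = FALSE)
  }
  acc <- .minimal_sets(acc)
  exact <- Filter(function(gs) {
    setequal(reactions_disabled_by(model, gs), reactions)
  }, acc)
  exact[order(vapply(exact, paste, character(1), collapse = "+"))]
}

.primary_gene_set <- function(model, reactions) {
  sets <- .gene_sets_for_reactions(model, reactions)
  if (length(sets) == 0L) character() else sets[[1]]
}

#' Minimal gene deletion sets realising a reaction knockout
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to deactivate.
#' @return List of minimal gene sets whose deletion deactivates exactly the
#'   given reactions (empty if some reaction has no gene association or any
#'   realising deletion would hit further reactions).
#' @examples
#' genes_for_reactions(core_model(), c("EDD", "RPI"))
#' @export
genes_for_reactions <- function(model, reactions) {
  .gene_sets_for_reactions(model, reactions)
}
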