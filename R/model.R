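#' Construct a stoichiometric metabolic model
#'
#' A `metabolic_model` holds metabolites (with carbon counts), reactions
#' (stoichiometry, flux bounds in mmol gCDW^-1 h^-1, GPR rule, exchange flag),
#' the gene inventory, and the id of the biomass objective reaction. Exchange
#' reactions are boundary pseudo-reactions touching exactly one metabolite;
#' by convention negative exchange flux is uptake.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `n_carbon` (non-negative integer carbon atoms; cofactor carrier moieties
#'   such as CoA or the adenine of NAD are not counted, so that `n_carbon`
#'   tracks transferable backbone carbon).
#' @param reactions list of reactions; each a list with `id`, `name`,
#'   `stoich` (named numeric, names are metabolite ids, negative =
#'   consumed), `lower_bound`, `upper_bound`, `gene_rule` (character GPR),
#'   `is_exchange` (logical).
#' @param genes character vector of gene ids (defaults to the union of all
#'   rule genes).
#' @param objective id of the biomass reaction to maximise.
#' @param id model identifier.
#' @return A validated object of class `metabolic_model`.
#' @seealso [load_model()], [core_model()], [fba()]
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective, id = "model") {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- lapply(reactions, .canonical_reaction)
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions, function(r)
      gene_rule_genes(parse_gene_rule(r$gene_rule))))))
  }
  model <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = as.character(genes), objective = objective),
    class = "metabolic_model")
  validate_model(model)
  model
}

.canonical_reaction <- function(r) {
  stopifnot(!is.null(r$id), !is.null(r$stoich))
  list(id = as.character(r$id),
       name = if (is.null(r$name)) as.character(r$id) else as.character(r$name),
       stoich = unlist(r$stoich),
       lower_bound = if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound),
       upper_bound = if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound),
       gene_rule = if (is.null(r$gene_rule)) "" else as.character(r$gene_rule),
       is_exchange = isTRUE(r$is_exchange))
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids, non-negative carbon counts,
#' non-empty stoichiometries whose metabolites all exist, ordered bounds,
#' exchange reactions touching exactly one metabolite, a resolvable objective
#' reaction, and gene rules restricted to the gene inventory.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly; errors name the offending field.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  need <- c("id", "name", "compartment", "n_carbon")
  missing_cols <- setdiff(need, names(met))
  if (length(missing_cols))
    stop("metabolites: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(met$id))
    stop("metabolites: duplicated id(s) ",
         paste(unique(met$id[duplicated(met$id)]), collapse = ", "),
         call. = FALSE)
  if (any(met$n_carbon < 0) || any(met$n_carbon != round(met$n_carbon)))
    stop("metabolites: n_carbon must be a non-negative integer", call. = FALSE)

  if (length(model$reactions) == 0L)
    stop("reactions: empty reaction list (no objective resolvable)",
         call. = FALSE)
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids))
    stop("reactions: duplicated id(s) ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "), call. = FALSE)
  for (r in model$reactions) {
    if (length(r$stoich) == 0L)
      stop("reaction ", r$id, ": empty stoichiometry", call. = FALSE)
    dangling <- setdiff(names(r$stoich), met$id)
    if (length(dangling))
      stop("reaction ", r$id, ": unknown metabolite id(s) ",
           paste(dangling, collapse = ", "), call. = FALSE)
    if (r$lower_bound > r$upper_bound)
      stop("reaction ", r$id, ": lower_bound > upper_bound", call. = FALSE)
    if (r$is_exchange && length(r$stoich) != 1L)
      stop("exchange reaction ", r$id, ": must touch exactly one metabolite",
           call. = FALSE)
    rule_genes <- gene_rule_genes(parse_gene_rule(r$gene_rule))
    unknown <- setdiff(rule_genes, model$genes)
    if (length(unknown))
      stop("reaction ", r$id, ": gene(s) not in model ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!model$objective %in% rids)
    stop("objective: reaction '", model$objective, "' not in model",
         call. = FALSE)
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_ex <- sum(vapply(x$reactions, `[[`, logical(1), "is_exchange"))
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites), "\n",
      "  reactions:   ", length(x$reactions),
      " (", n_ex, " exchanges)\n",
      "  genes:       ", length(x$genes), "\n",
      "  objective:   ", x$objective, "\n", sep = "")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return Dense numeric matrix, metabolites (rows) by reactions (columns);
#'   entry (i, j) is the signed coefficient of metabolite i in reaction j.
#' @export
stoich_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- names(model$reactions)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoich
    S[names(st), j] <- st
  }
  S
}

#' Flux bounds of a model
#' @param model a `metabolic_model`.
#' @return list with numeric vectors `lower` and `upper`, named by reaction.
#' @export
flux_bounds <- function(model) {
  list(lower = vapply(model$reactions, `[[`, numeric(1), "lower_bound"),
       upper = vapply(model$reactions, `[[`, numeric(1), "upper_bound"))
}

#' Carbon balance of each reaction
#'
#' Sums carbon-weighted stoichiometric coefficients per reaction. Internal
#' (non-exchange, non-biomass) reactions of a well-formed model balance to
#' zero; exchanges and the lumped biomass reaction do not.
#'
#' @param model a `metabolic_model`.
#' @return named numeric vector of net carbon per unit flux.
#' @export
carbon_balance <- function(model) {
  nc <- setNames(model$metabolites$n_carbon, model$metabolites$id)
  vapply(model$reactions, function(r) sum(r$stoich * nc[names(r$stoich)]),
         numeric(1))
}

#' Apply gene and reaction knockouts
#'
#' Reactions listed directly, plus reactions whose GPR rule evaluates false
#' once the given genes are deleted, get both flux bounds set to zero; all
#' other bounds are untouched. Knockouts are monotone and idempotent.
#'
#' @param model a `metabolic_model`.
#' @param genes character vector of gene ids to delete.
#' @param reactions character vector of reaction ids to disable.
#' @return A new `metabolic_model`; the input is unmodified.
#' @examples
#' m <- core_model()
#' ko <- knockout(m, genes = "edd")
#' @export
knockout <- function(model, genes = character(), reactions = character()) {
  genes <- as.character(genes); reactions <- as.character(reactions)
  unknown_g <- setdiff(genes, model$genes)
  if (length(unknown_g))
    stop("unknown gene id(s): ", paste(unknown_g, collapse = ", "),
         call. = FALSE)
  unknown_r <- setdiff(reactions, names(model$reactions))
  if (length(unknown_r))
    stop("unknown reaction id(s): ", paste(unknown_r, collapse = ", "),
         call. = FALSE)
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    dead <- rid %in% reactions ||
      (length(genes) > 0L &&
         !eval_gene_rule(parse_gene_rule(r$gene_rule), deleted = genes))
    if (dead) {
      model$reactions[[rid]]$lower_bound <- 0
      model$reactions[[rid]]$upper_bound <- 0
    }
  }
  model
}

#' Reactions disabled by a gene deletion set
#' @param model a `metabolic_model`.
#' @param genes character vector of deleted gene ids.
#' @return character vector of reaction ids whose GPR evaluates false.
#' @export
reactions_disabled_by <- function(model, genes) {
  rids <- names(model$reactions)
  rids[!vapply(model$reactions, function(r)
    eval_gene_rule(parse_gene_rule(r$gene_rule), deleted = genes),
    logical(1))]
}

#' Set the growth medium
#'
#' Opens uptake (lower bound `-uptake_rate`) for the listed carbon-source
#' exchanges and closes uptake for every other carbon exchange. Exchanges of
#' carbon-free nutrients (O2, NH4+, Pi, H2O, H+, ...) are untouched, and
#' secretion stays allowed for all exchanges.
#'
#' @param model a `metabolic_model`.
#' @param carbon_sources character vector of exchange reaction ids.
#' @param uptake_rate non-negative uptake bound, mmol gCDW^-1 h^-1
#'   (default 7, the conventional shake-flask glucose uptake approximation).
#' @return A new `metabolic_model` with medium bounds applied.
#' @export
set_medium <- function(model, carbon_sources = character(), uptake_rate = 7) {
  stopifnot(uptake_rate >= 0)
  carbon_sources <- as.character(carbon_sources)
  nc <- setNames(model$metabolites$n_carbon, model$metabolites$id)
  for (src in carbon_sources) {
    r <- model$reactions[[src]]
    if (is.null(r) || !r$is_exchange)
      stop("'", src, "' is not an exchange reaction of the model",
           call. = FALSE)
  }
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (!r$is_exchange) next
    if (nc[names(r$stoich)] <= 0) next  # carbon-free nutrient: leave open
    model$reactions[[rid]]$lower_bound <-
      if (rid %in% carbon_sources) -uptake_rate else 0
  }
  model
}

#' Exchange reactions of a model
#' @param model a `metabolic_model`.
#' @param carbon_only if `TRUE`, only exchanges of carbon-bearing metabolites.
#' @return character vector of exchange reaction ids.
#' @export
exchange_ids <- function(model, carbon_only = FALSE) {
  nc <- setNames(model$metabolites$n_carbon, model$metabolites$id)
  ids <- character()
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    if (!r$is_exchange) next
    if (carbon_only && nc[names(r$stoich)] <= 0) next
    ids <- c(ids, rid)
  }
  ids
}

#' Add the heterologous RuMP-cycle entry reactions
#'
#' Adds NAD-dependent methanol dehydrogenase (Mdh: methanol + NAD+ ->
#' formaldehyde + NADH + H+), 3-hexulose-6-phosphate synthase (Hps:
#' formaldehyde + ribulose 5-phosphate -> hexulose 6-phosphate) and
#' 6-phospho-3-hexuloisomerase (Phi: hexulose 6-phosphate -> fructose
#' 6-phosphate). The hexulose 6-phosphate intermediate is created if absent.
#' Each added reaction is carbon balanced.
#'
#' @param model a `metabolic_model` containing the required species.
#' @param species named list mapping the roles `methanol`, `formaldehyde`,
#'   `nad`, `nadh`, `h`, `ru5p`, `f6p` (and optionally `h6p`) to metabolite
#'   ids in the model.
#' @param ids reaction ids for the three additions.
#' @param genes gene ids associated with the three reactions.
#' @return A new, augmented `metabolic_model`; the input is unmodified.
#' @examples
#' m <- add_rump_pathway(core_model())
#' @export
add_rump_pathway <- function(model,
                             species = list(methanol = "meoh_c",
                                            formaldehyde = "fald_c",
                                            nad = "nad_c", nadh = "nadh_c",
                                            h = "h_c", ru5p = "ru5p_c",
                                            f6p = "f6p_c", h6p = "h6p_c"),
                             ids = c(mdh = "MDH", hps = "HPS", phi = "PHI"),
                             genes = c(mdh = "mdh", hps = "hps", phi = "phi")) {
  required <- c("methanol", "formaldehyde", "nad", "nadh", "h", "ru5p", "f6p")
  missing_species <- setdiff(unlist(species[required]), model$metabolites$id)
  if (length(missing_species))
    stop("model lacks required species: ",
         paste(missing_species, collapse = ", "), call. = FALSE)
  clash <- intersect(ids, names(model$reactions))
  if (length(clash))
    stop("reaction id(s) already present: ", paste(clash, collapse = ", "),
         call. = FALSE)
  h6p <- if (is.null(species$h6p)) "h6p_c" else species$h6p
  if (!h6p %in% model$metabolites$id) {
    model$metabolites <- rbind(
      model$metabolites,
      data.frame(id = h6p, name = "D-arabino-3-hexulose 6-phosphate",
                 compartment = "c", n_carbon = 6L,
                 stringsAsFactors = FALSE))
  }
  rx <- function(id, name, stoich, rule, lb = 0, ub = 1000) {
    .canonical_reaction(list(id = id, name = name, stoich = stoich,
                             lower_bound = lb, upper_bound = ub,
                             gene_rule = rule, is_exchange = FALSE))
  }
  add <- list(
    rx(ids[["mdh"]], "methanol dehydrogenase (NAD-dependent)",
       setNames(c(-1, -1, 1, 1, 1),
                c(species$methanol, species$nad, species$formaldehyde,
                  species$nadh, species$h)),
       genes[["mdh"]]),
    rx(ids[["hps"]], "3-hexulose-6-phosphate synthase",
       setNames(c(-1, -1, 1), c(species$formaldehyde, species$ru5p, h6p)),
       genes[["hps"]]),
    rx(ids[["phi"]], "6-phospho-3-hexuloisomerase",
       setNames(c(-1, 1), c(h6p, species$f6p)), genes[["phi"]]))
  names(add) <- vapply(add, `[[`, character(1), "id")
  model$reactions <- c(model$reactions, add)
  model$genes <- sort(unique(c(model$genes, unname(genes))))
  validate_model(model)
  bal <- carbon_balance(model)[unname(ids)]
  if (any(abs(bal) > 1e-9))
    stop("heterologous reaction(s) not carbon balanced: ",
         paste(names(bal)[abs(bal) > 1e-9], collapse = ", "), call. = FALSE)
  model
}
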