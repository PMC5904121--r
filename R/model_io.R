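#' Load a metabolic model from JSON or SBML
#'
#' The JSON dialect is the package's primary, round-trippable format (see
#' `system.file("extdata", "model-schema.md", package = "rumpdesign")`).
#' SBML import (Level 3 with the FBC package) is read-only and covers the
#' subset needed for flux balance models: species, reactions with
#' stoichiometries, flux-bound parameters, gene-product associations and the
#' active objective. Carbon counts are taken from FBC chemical formulas.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension by
#'   default.
#' @return A validated `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' @rdname load_model
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("metabolites", "reactions", "objective"))
    if (is.null(doc[[field]]))
      stop("model JSON: missing required field '", field, "'", call. = FALSE)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    for (field in c("id", "n_carbon"))
      if (is.null(m[[field]]))
        stop("model JSON: metabolite missing field '", field, "'",
             call. = FALSE)
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               n_carbon = as.integer(m$n_carbon),
               stringsAsFactors = FALSE)
  }))
  rxns <- lapply(doc$reactions, function(r) {
    for (field in c("id", "stoichiometry"))
      if (is.null(r[[field]]))
        stop("model JSON: reaction missing field '", field, "'",
             call. = FALSE)
    list(id = r$id, name = r$name,
         stoich = unlist(r$stoichiometry),
         lower_bound = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
         upper_bound = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
         gene_rule = if (is.null(r$gene_rule)) "" else r$gene_rule,
         is_exchange = isTRUE(r$is_exchange))
  })
  metabolic_model(mets, rxns,
                  genes = if (is.null(doc$genes)) NULL else unlist(doc$genes),
                  objective = doc$objective,
                  id = if (is.null(doc$id)) "model" else doc$id)
}

#' Write a metabolic model to the JSON dialect
#'
#' `read_model_json(write_model_json(m, path))` round-trips to a
#' flux-equivalent model (identical stoichiometric matrix and bounds).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  doc <- list(
    schema_version = "1.0",
    id = model$id,
    objective = model$objective,
    genes = as.list(model$genes),
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      m <- model$metabolites[i, ]
      list(id = m$id, name = m$name, compartment = m$compartment,
           n_carbon = m$n_carbon)
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, name = r$name,
           stoichiometry = as.list(r$stoich),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           gene_rule = r$gene_rule, is_exchange = r$is_exchange)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname load_model
#' @export
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  attr1 <- function(node, names) {
    for (nm in names) {
      v <- xml2::xml_attr(node, nm)
      if (!is.na(v)) return(v)
    }
    NA_character_
  }
  params <- new.env(parent = emptyenv())
  for (p in xml2::xml_find_all(doc, ".//listOfParameters/parameter")) {
    assign(xml2::xml_attr(p, "id"), as.numeric(xml2::xml_attr(p, "value")),
           envir = params)
  }
  bound_value <- function(id, default) {
    if (is.na(id) || !exists(id, envir = params)) default
    else get(id, envir = params)
  }
  gene_label <- new.env(parent = emptyenv())
  for (gp in xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")) {
    gid <- attr1(gp, c("id", "fbc:id"))
    lab <- attr1(gp, c("label", "fbc:label"))
    assign(gid, if (is.na(lab)) gid else lab, envir = gene_label)
  }
  carbon_from_formula <- function(f) {
    if (is.na(f)) return(0L)
    m <- regmatches(f, regexec("C([0-9]*)([A-Z]|$)", f))[[1]]
    if (length(m) == 0L) return(0L)
    if (m[2] == "") 1L else as.integer(m[2])
  }
  mets <- do.call(rbind, lapply(
    xml2::xml_find_all(doc, ".//listOfSpecies/species"), function(s) {
      data.frame(
        id = xml2::xml_attr(s, "id"),
        name = {
          nm <- xml2::xml_attr(s, "name")
          if (is.na(nm)) xml2::xml_attr(s, "id") else nm
        },
        compartment = xml2::xml_attr(s, "compartment"),
        n_carbon = carbon_from_formula(
          attr1(s, c("chemicalFormula", "fbc:chemicalFormula"))),
        stringsAsFactors = FALSE)
    }))
  gpr_string <- function(node) {
    nm <- sub("^.*:", "", xml2::xml_name(node))
    if (nm == "geneProductRef") {
      gid <- attr1(node, c("geneProduct", "fbc:geneProduct"))
      lab <- if (exists(gid, envir = gene_label)) get(gid, envir = gene_label)
             else gid
      return(lab)
    }
    parts <- vapply(xml2::xml_children(node), gpr_string, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }
  rxns <- lapply(xml2::xml_find_all(doc, ".//listOfReactions/reaction"),
                 function(rn) {
    st <- numeric()
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      k <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[sp] <- (if (is.na(k)) -1 else -k) + if (sp %in% names(st)) st[sp] else 0
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      sp <- xml2::xml_attr(sr, "species")
      k <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      st[sp] <- (if (is.na(k)) 1 else k) + if (sp %in% names(st)) st[sp] else 0
    }
    gpa <- xml2::xml_find_first(rn,
      "./*[local-name()='geneProductAssociation']")
    rule <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0L) "" else gpr_string(kids[[1]])
    }
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    list(id = xml2::xml_attr(rn, "id"),
         name = xml2::xml_attr(rn, "name"),
         stoich = st,
         lower_bound = bound_value(
           attr1(rn, c("lowerFluxBound", "fbc:lowerFluxBound")),
           if (rev) -1000 else 0),
         upper_bound = bound_value(
           attr1(rn, c("upperFluxBound", "fbc:upperFluxBound")), 1000),
         gene_rule = rule,
         is_exchange = length(st) == 1L)
  })
  obj_node <- xml2::xml_find_first(doc,
    ".//*[local-name()='fluxObjective']")
  if (inherits(obj_node, "xml_missing"))
    stop("SBML: no flux objective found", call. = FALSE)
  objective <- attr1(obj_node, c("reaction", "fbc:reaction"))
  model_node <- xml2::xml_find_first(doc, ".//model")
  id <- xml2::xml_attr(model_node, "id")
  metabolic_model(mets, rxns, objective = objective,
                  id = if (is.na(id)) "sbml_model" else id)
}
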