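#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with `and`
#' (enzyme complex: all subunits required) and `or` (isozymes: any suffices),
#' e.g. `"rpiA or rpiB"` or `"(sucA and sucB) or lpd"`. An empty rule means
#' the reaction is spontaneous or its enzyme is not gene-associated, so it
#' can never be removed by a gene deletion.
#'
#' @param rule character scalar; `""` or `NA` denote the empty rule.
#' @return A parse tree: `NULL` (empty rule), a character gene id (leaf), or
#'   a list with elements `op` (`"and"`/`"or"`) and `args` (list of subtrees).
#' @examples
#' parse_gene_rule("rpiA or rpiB")
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)

  tokens <- .gpr_tokenize(rule)
  parsed <- .gpr_parse_or(tokens, 1L)
  if (parsed$pos != length(tokens) + 1L)
    stop("malformed gene rule: ", rule, call. = FALSE)
  parsed$node
}

.gpr_tokenize <- function(rule) {
  spaced <- gsub("\\(", " ( ", gsub("\\)", " ) ", rule))
  tokens <- strsplit(trimws(spaced), "\\s+")[[1]]
  if (any(!nzchar(tokens))) tokens <- tokens[nzchar(tokens)]
  tokens
}

# grammar: or := and ("or" and)* ; and := atom ("and" atom)* ;
# atom := gene | "(" or ")"
.gpr_parse_or <- function(tokens, pos) {
  lhs <- .gpr_parse_and(tokens, pos)
  args <- list(lhs$node); pos <- lhs$pos
  while (pos <= length(tokens) && tolower(tokens[pos]) == "or") {
    nxt <- .gpr_parse_and(tokens, pos + 1L)
    args <- c(args, list(nxt$node)); pos <- nxt$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  list(node = node, pos = pos)
}

.gpr_parse_and <- function(tokens, pos) {
  lhs <- .gpr_parse_atom(tokens, pos)
  args <- list(lhs$node); pos <- lhs$pos
  while (pos <= length(tokens) && tolower(tokens[pos]) == "and") {
    nxt <- .gpr_parse_atom(tokens, pos + 1L)
    args <- c(args, list(nxt$node)); pos <- nxt$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  list(node = node, pos = pos)
}

.gpr_parse_atom <- function(tokens, pos) {
  if (pos > length(tokens)) stop("malformed gene rule", call. = FALSE)
  tok <- tokens[pos]
  if (tok == "(") {
    inner <- .gpr_parse_or(tokens, pos + 1L)
    if (inner$pos > length(tokens) || tokens[inner$pos] != ")")
      stop("unbalanced parentheses in gene rule", call. = FALSE)
    return(list(node = inner$node, pos = inner$pos + 1L))
  }
  if (tok %in% c(")", "and", "or"))
    stop("malformed gene rule near '", tok, "'", call. = FALSE)
  list(node = tok, pos = pos + 1L)
}

#' Evaluate a gene rule under a set of deleted genes
#'
#' @param tree parse tree from [parse_gene_rule()].
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains catalysed, `FALSE` if the deletion
#'   set removes it. The empty rule always evaluates `TRUE`.
#' @export
eval_gene_rule <- function(tree, deleted = character()) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) return(!(tree %in% deleted))
  vals <- vapply(tree$args, eval_gene_rule, logical(1), deleted = deleted)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a gene rule
#' @param tree parse tree from [parse_gene_rule()].
#' @return character vector of gene ids (possibly empty).
#' @export
gene_rule_genes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  sort(unique(unlist(lapply(tree$args, gene_rule_genes))))
}

# minimal gene sets whose deletion makes the rule evaluate FALSE
# (minimal cut sets of the boolean tree); empty rule has none
.gpr_cut_sets <- function(tree) {
  if (is.null(tree)) return(list())
  if (is.character(tree)) return(list(tree))
  child <- lapply(tree$args, .gpr_cut_sets)
  if (any(vapply(child, length, integer(1)) == 0L) && tree$op == "or")
    return(list())  # an un-cuttable branch keeps an OR alive forever
  sets <- if (tree$op == "and") {
    unlist(child, recursive = FALSE)  # cutting any factor suffices
  } else {
    # OR: must cut every branch; take unions across the cartesian product
    acc <- list(character())
    for (cs in child) {
      acc <- unlist(lapply(acc, function(a)
        lapply(cs, function(b) sort(unique(c(a, b))))), recursive = FALSE)
    }
    acc
  }
  .minimal_sets(sets)
}

.minimal_sets <- function(sets) {
  sets <- unique(lapply(sets, function(s) sort(unique(s))))
  if (length(sets) <= 1L) return(sets)
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && all(sets[[j]] %in% sets[[i]]) &&
          length(sets[[j]]) < length(sets[[i]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  sets[keep]
}
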