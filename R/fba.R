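#' FBA solver configuration
#'
#' @param feasibility_tol tolerance used by the simplex solver when testing
#'   reduced costs and ratios (dimensionless, default 1e-9).
#' @param zero_tol flux magnitude treated as zero when reporting fluxes or
#'   checking solution certificates (default 1e-6). Growth comparisons
#'   against the essentiality threshold always use the raw objective value,
#'   never `zero_tol`.
#' @return An object of class `fba_config`.
#' @export
fba_config <- function(feasibility_tol = 1e-9, zero_tol = 1e-6) {
  stopifnot(feasibility_tol > 0, zero_tol > 0)
  structure(list(feasibility_tol = feasibility_tol, zero_tol = zero_tol),
            class = "fba_config")
}

# Assemble the LP data (S, bounds, objective index) once; reused heavily by
# the screening loops, where bounds are patched per knockout instead of
# rebuilding the model.
.fba_problem <- function(model) {
  S <- stoich_matrix(model)
  bounds <- flux_bounds(model)
  list(S = S, lower = bounds$lower, upper = bounds$upper,
       obj = match(model$objective, colnames(S)),
       reaction_ids = colnames(S))
}

.fba_solve_raw <- function(prob, config = fba_config(), lower = NULL,
                           upper = NULL) {
  if (is.null(lower)) lower <- prob$lower
  if (is.null(upper)) upper <- prob$upper
  cvec <- numeric(ncol(prob$S))
  cvec[prob$obj] <- 1
  .simplex_lp(cvec, prob$S, numeric(nrow(prob$S)), lower, upper,
              TRUE, config$feasibility_tol)
}

#' Maximise the biomass objective by flux balance analysis
#'
#' Solves the linear program max c'v subject to S v = 0 and the model's flux
#' bounds, with c selecting the biomass objective reaction. Only the
#' objective value is deterministic; the flux vector may be any optimum.
#'
#' @param model a `metabolic_model`.
#' @param config an [fba_config()].
#' @return An object of class `flux_solution`: `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `growth_rate` (objective value, h^-1;
#'   `NA` unless optimal) and `fluxes` (named vector, mmol gCDW^-1 h^-1).
#' @examples
#' sol <- fba(set_medium(core_model(), "EX_glc"))
#' sol$growth_rate
#' @export
fba <- function(model, config = fba_config()) {
  prob <- .fba_problem(model)
  res <- .fba_solve_raw(prob, config)
  if (res$status == "iteration_limit")
    stop("FBA solver failed to converge (iteration limit); model: ",
         model$id, call. = FALSE)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, growth_rate = NA_real_,
                          fluxes = NULL), class = "flux_solution"))
  }
  v <- setNames(as.numeric(res$x), prob$reaction_ids)
  resid <- max(abs(prob$S %*% v))
  if (resid > 1e-6)
    stop("FBA solution violates mass balance (|S v| = ",
         format(resid), ")", call. = FALSE)
  if (any(v < prob$lower - 1e-6) || any(v > prob$upper + 1e-6))
    stop("FBA solution violates flux bounds", call. = FALSE)
  v[abs(v) < config$zero_tol] <- 0
  structure(list(status = "optimal",
                 growth_rate = as.numeric(res$objective),
                 fluxes = v),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status)
  if (x$status == "optimal")
    cat(", growth rate:", format(x$growth_rate, digits = 6), "h^-1")
  cat("\n")
  invisible(x)
}

#' Growth rate under a medium and knockout set
#'
#' Convenience composition of [set_medium()], [knockout()] and [fba()]. An
#' infeasible program is reported as zero growth with a warning so that
#' screening loops stay total.
#'
#' @param model a `metabolic_model`.
#' @param carbon_sources exchange ids opened for uptake.
#' @param uptake_rate uptake bound per source, mmol gCDW^-1 h^-1.
#' @param genes,reactions knockouts applied before solving.
#' @param config an [fba_config()].
#' @return Growth rate in h^-1 (0 for infeasible models).
#' @export
growth_on <- function(model, carbon_sources = character(), uptake_rate = 7,
                      genes = character(), reactions = character(),
                      config = fba_config()) {
  m <- set_medium(model, carbon_sources, uptake_rate)
  m <- knockout(m, genes = genes, reactions = reactions)
  sol <- fba(m, config)
  if (sol$status == "infeasible") {
    warning("infeasible FBA problem mapped to zero growth", call. = FALSE)
    return(0)
  }
  if (sol$status != "optimal")
    stop("FBA failed with status ", sol$status, call. = FALSE)
  sol$growth_rate
}

# Independent second LP assembly used as a cross-check: substitute
# v = v_plus - v_minus with non-negative split variables, so the equality
# system, bounds handling and objective wiring are all constructed
# differently from the direct path.
.fba_split_formulation <- function(model, config = fba_config()) {
  S <- stoich_matrix(model)
  b <- flux_bounds(model)
  n <- ncol(S)
  S2 <- cbind(S, -S)
  lb2 <- c(pmax(b$lower, 0), pmax(-b$upper, 0))
  ub2 <- c(pmax(b$upper, 0), pmax(-b$lower, 0))
  cvec <- numeric(2 * n)
  i <- match(model$objective, colnames(S))
  cvec[i] <- 1
  cvec[n + i] <- -1
  res <- .simplex_lp(cvec, S2, numeric(nrow(S2)), lb2, ub2, TRUE,
                     config$feasibility_tol)
  list(status = res$status,
       growth_rate = if (res$status == "optimal") res$objective else NA_real_)
}
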