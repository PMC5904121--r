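# Shared fixtures: models are built once per test run.

the_core <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- core_model()
    cache
  }
})

the_augmented <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- add_rump_pathway(core_model())
    cache
  }
})

# Small hand-built model: uptake of A (bound 5), conversion A -> B,
# biomass consuming B. Optimal growth = 5.
toy_chain_model <- function(uptake = 5) {
  mets <- data.frame(id = c("A_e", "A", "B"), name = c("A ext", "A", "B"),
                     compartment = c("e", "c", "c"), n_carbon = c(1L, 1L, 1L))
  rxns <- list(
    list(id = "EX_A", stoich = c(A_e = -1), lower_bound = -uptake,
         upper_bound = 1000, is_exchange = TRUE),
    list(id = "T_A", stoich = c(A_e = -1, A = 1), lower_bound = 0,
         upper_bound = 1000),
    list(id = "CONV", stoich = c(A = -1, B = 1), lower_bound = 0,
         upper_bound = 1000),
    list(id = "GROW", stoich = c(B = -1), lower_bound = 0,
         upper_bound = 1000))
  metabolic_model(mets, rxns, objective = "GROW", id = "toy_chain")
}

# Brute-force LP oracle: enumerate candidate vertices of
# {S v = 0, lb <= v <= ub} by fixing (n - rank(S)) variables at bounds and
# solving for the rest; returns the maximal objective value over feasible
# vertices. Requires S to have full row rank (true for the toys used).
vertex_enum_max <- function(S, lb, ub, cvec, tol = 1e-8) {
  n <- ncol(S)
  m <- nrow(S)
  stopifnot(qr(S)$rank == m)
  nfree <- n - m
  best <- -Inf
  fix_sets <- if (nfree == 0) list(integer()) else
    combn(n, nfree, simplify = FALSE)
  for (fixed in fix_sets) {
    rest <- setdiff(seq_len(n), fixed)
    Srest <- S[, rest, drop = FALSE]
    if (abs(det(Srest)) < 1e-12) next
    patterns <- if (length(fixed) == 0) list(numeric()) else
      do.call(expand.grid, rep(list(c(FALSE, TRUE)), length(fixed)))
    if (is.data.frame(patterns)) patterns <- split(as.matrix(patterns),
                                                   seq_len(nrow(patterns)))
    for (pat in patterns) {
      vfix <- ifelse(as.logical(pat), ub[fixed], lb[fixed])
      rhs <- if (length(fixed)) -S[, fixed, drop = FALSE] %*% vfix else
        matrix(0, m, 1)
      vrest <- solve(Srest, rhs)
      v <- numeric(n)
      v[fixed] <- vfix
      v[rest] <- vrest
      if (all(v >= lb - tol) && all(v <= ub + tol))
        best <- max(best, sum(cvec * v))
    }
  }
  best
}

avg_time_series <- function(series_list) {
  time_series(series_list[[1]]$times,
              rowMeans(sapply(series_list, `[[`, "values")),
              series_list[[1]]$kind)
}

# minimal SBML Level 3 + FBC document exercising the import subset
write_toy_sbml <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy_sbml" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_e" name="A external" compartment="e" fbc:chemicalFormula="C2H4O2"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="A_c" name="A" compartment="c" fbc:chemicalFormula="C2H4O2"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="B_c" name="B" compartment="c" fbc:chemicalFormula="CH2O"
               hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_uptake" value="-4" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="g_tA" fbc:label="tA"/>
      <fbc:geneProduct fbc:id="g_cv1" fbc:label="cv1"/>
      <fbc:geneProduct fbc:id="g_cv2" fbc:label="cv2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="EX_A" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_uptake" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="T_A" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="g_tA"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="CONV" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="2" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="g_cv1"/>
            <fbc:geneProductRef fbc:geneProduct="g_cv2"/>
          </fbc:or>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="GROW" reversible="false" fast="false"
                fbc:lowerFluxBound="lb_zero" fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="GROW" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>', path)
  path
}
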