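#' Isotopologue distribution of a metabolite
#'
#' @param abundances numeric vector of M+0 .. M+n intensities (arbitrary
#'   units, non-negative, at least one positive) for an n-carbon metabolite.
#' @param metabolite_id optional metabolite label.
#' @return An object of class `isotopologue_distribution` with fields
#'   `metabolite_id`, `n` (carbon count) and `abundances`.
#' @export
isotopologue_distribution <- function(abundances, metabolite_id = "") {
  abundances <- as.numeric(abundances)
  n <- length(abundances) - 1L
  if (n < 1L) stop("need at least M+0 and M+1 entries", call. = FALSE)
  if (any(abundances < 0)) stop("negative abundances", call. = FALSE)
  if (sum(abundances) <= 0) stop("all-zero abundances", call. = FALSE)
  structure(list(metabolite_id = metabolite_id, n = n,
                 abundances = abundances),
            class = "isotopologue_distribution")
}

.as_abund <- function(dist) {
  if (inherits(dist, "isotopologue_distribution")) dist$abundances
  else isotopologue_distribution(dist)$abundances
}

#' Average labeled-carbon fraction of an isotopologue distribution
#'
#' The mean fraction of labeled carbon atoms in the metabolite pool:
#' sum(A_i * i) / (n * sum(A_i)), where A_i is the abundance of the M+i
#' isotopologue and n the carbon count. Invariant under rescaling of the
#' abundances.
#'
#' @param dist an [isotopologue_distribution()] or a numeric vector of
#'   M+0..M+n intensities.
#' @return Labeled fraction in \[0, 1\].
#' @examples
#' labeled_fraction(c(0.25, 0.25, 0.25, 0.25))  # 0.5 for a 3-carbon pool
#' @export
labeled_fraction <- function(dist) {
  a <- .as_abund(dist)
  n <- length(a) - 1L
  sum(a * seq(0L, n)) / (n * sum(a))
}

# lower-triangular convolution matrix: entry [j+1, i+1] is the probability
# that a species with i labeled carbons is observed as M+j, when each of its
# n - i unlabeled carbons is naturally labeled with probability a
.natural_abundance_matrix <- function(n, a) {
  M <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) {
    for (j in i:n) {
      M[j + 1L, i + 1L] <- choose(n - i, j - i) * a^(j - i) * (1 - a)^(n - j)
    }
  }
  M
}

#' Forward-convolve a distribution with natural isotope abundance
#'
#' Applies the binomial natural-labeling model: each carbon not already
#' labeled carries a heavy isotope with probability `a`. This is the forward
#' model inverted by [natural_abundance_correction()].
#'
#' @param dist an [isotopologue_distribution()] or numeric abundance vector.
#' @param a natural heavy-isotope abundance per carbon (default 0.0107 for
#'   13C).
#' @return An `isotopologue_distribution` with the same total intensity.
#' @export
convolve_natural_abundance <- function(dist, a = 0.0107) {
  stopifnot(a >= 0, a < 1)
  x <- .as_abund(dist)
  out <- as.numeric(.natural_abundance_matrix(length(x) - 1L, a) %*% x)
  isotopologue_distribution(out,
    if (inherits(dist, "isotopologue_distribution")) dist$metabolite_id
    else "")
}

#' Correct an observed distribution for natural isotope abundance
#'
#' Solves the lower-triangular system observed = M * true, where M is the
#' binomial natural-labeling matrix (diagonal (1-a)^n > 0, hence never
#' singular). Small negative corrected abundances arising from measurement
#' noise are clipped to zero with a warning, and the output is renormalised
#' to the input total intensity.
#'
#' @inheritParams convolve_natural_abundance
#' @return An `isotopologue_distribution` of corrected abundances.
#' @examples
#' obs <- convolve_natural_abundance(c(1, 0, 0), a = 0.5)
#' natural_abundance_correction(obs, a = 0.5)$abundances  # (1, 0, 0)
#' @export
natural_abundance_correction <- function(dist, a = 0.0107) {
  stopifnot(a >= 0, a < 1)
  x <- .as_abund(dist)
  n <- length(x) - 1L
  M <- .natural_abundance_matrix(n, a)
  corrected <- as.numeric(forwardsolve(M, x))
  if (any(corrected < -sqrt(.Machine$double.eps) * sum(x)))
    warning("negative corrected abundances clipped to zero ",
            "(noise artifact)", call. = FALSE)
  corrected[corrected < 0] <- 0
  if (sum(corrected) > 0)
    corrected <- corrected * sum(x) / sum(corrected)
  isotopologue_distribution(corrected,
    if (inherits(dist, "isotopologue_distribution")) dist$metabolite_id
    else "")
}

#' Expected labeled fraction under equimolar co-assimilation
#'
#' Stoichiometric expectation for a metabolite of `n_total` carbons of which
#' `n_from_methanol` derive from the labeled one-carbon substrate: e.g. one
#' methanol-derived carbon per hexose 6-phosphate under equimolar
#' gluconate/methanol consumption gives 1/6, i.e. 17% at nearest-percent
#' rounding.
#'
#' @param n_from_methanol labeled carbons per molecule.
#' @param n_total carbon count of the metabolite.
#' @return Expected labeled fraction in \[0, 1\].
#' @export
expected_fraction_equimolar <- function(n_from_methanol, n_total) {
  stopifnot(n_total >= 1, n_from_methanol >= 0,
            n_from_methanol <= n_total)
  n_from_methanol / n_total
}

#' Stoichiometric biomass gain from equimolar methanol co-assimilation
#'
#' Assuming no carbon loss, co-consuming one molecule of methanol
#' (`n_carbon_methanol` carbons) per molecule of an `n_carbon_cosubstrate`
#' co-substrate increases assimilable carbon, and hence maximal biomass, by
#' the carbon ratio: 1/6, i.e. 17%, for a C6 substrate such as gluconate.
#'
#' @param n_carbon_cosubstrate carbons of the multi-carbon substrate
#'   (default 6).
#' @param n_carbon_methanol carbons of the one-carbon substrate (default 1).
#' @return Fractional biomass increase.
#' @export
equimolar_yield_gain <- function(n_carbon_cosubstrate = 6,
                                 n_carbon_methanol = 1) {
  stopifnot(n_carbon_cosubstrate >= 1, n_carbon_methanol >= 0)
  n_carbon_methanol / n_carbon_cosubstrate
}

#' Round a fraction to the nearest integer percent
#'
#' Half-up rounding, as used when comparing labeled fractions to
#' percent-level stoichiometric expectations.
#'
#' @param fraction numeric fraction(s) in \[0, 1\].
#' @return Integer percent value(s).
#' @export
percent_round <- function(fraction) {
  floor(fraction * 100 + 0.5)
}

#' Read an isotopologue table
#'
#' Tab-separated input with columns `metabolite`, `n_carbon` and intensity
#' columns `M0`, `M1`, ... `M<n>`; rows may leave trailing columns beyond
#' their carbon count as NA or absent.
#'
#' @param path TSV file path.
#' @return List of `isotopologue_distribution` objects.
#' @export
read_isotopologue_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("metabolite", "n_carbon")
  if (!all(need %in% names(df)))
    stop("isotopologue table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    n <- df$n_carbon[i]
    cols <- paste0("M", 0:n)
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols))
      stop("row ", i, ": missing intensity column(s) ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    isotopologue_distribution(as.numeric(df[i, cols]),
                              metabolite_id = df$metabolite[i])
  })
}

#' Labeled-fraction analysis of an isotopologue table
#'
#' Applies natural-abundance correction followed by the labeled-fraction
#' computation to each row.
#'
#' @param dists list of `isotopologue_distribution` (e.g. from
#'   [read_isotopologue_table()]).
#' @param a natural 13C abundance (default 0.0107).
#' @return data.frame with columns `metabolite`, `n_carbon`,
#'   `labeled_fraction`, `labeled_percent`.
#' @export
labeling_analysis <- function(dists, a = 0.0107) {
  rows <- lapply(dists, function(d) {
    corrected <- natural_abundance_correction(d, a)
    lf <- labeled_fraction(corrected)
    data.frame(metabolite = d$metabolite_id, n_carbon = d$n,
               labeled_fraction = lf, labeled_percent = percent_round(lf),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
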