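#' Specification of a synthetic cultivation experiment
#'
#' Parameter defaults emulate the evolved methanol-essential strain growing
#' on 5 mM gluconate / 500 mM methanol batch cultures: specific growth rate
#' 0.081 h^-1, specific methanol uptake 13 mmol gCDW^-1 h^-1, inoculum OD600
#' 0.05 (X0 = 0.0165 gCDW L^-1), 500 mM initial methanol, a linear abiotic
#' methanol loss of 1 mM h^-1 (evaporation, measured on a non-consuming
#' control culture), 1% multiplicative measurement noise and 8 sampling
#' points over 40 h (about 4.7 doublings, final OD ~1.3).
#'
#' @param seed integer seed; every generator is a pure function of the spec.
#' @param mu specific growth rate, h^-1.
#' @param X0 initial biomass, gCDW L^-1.
#' @param q_true specific substrate uptake rate, mmol gCDW^-1 h^-1.
#' @param S0 initial substrate concentration, mM.
#' @param evap_rate linear abiotic substrate loss, mM h^-1.
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise on OD and concentration readings.
#' @param n_points number of sampling times (uniform over \[0, t_end\]).
#' @param t_end culture duration, h.
#' @param cdw_factor OD600-to-CDW factor, gCDW L^-1.
#' @param true_labeled_fraction labeled-carbon fraction generating
#'   isotopologue data (default 1/6, the equimolar expectation).
#' @param natural_abundance natural 13C abundance per carbon.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, mu = 0.081, X0 = 0.0165,
                            q_true = 13, S0 = 500, evap_rate = 1,
                            noise_cv = 0.01, n_points = 8L, t_end = 40,
                            cdw_factor = 0.33,
                            true_labeled_fraction = 1 / 6,
                            natural_abundance = 0.0107) {
  stopifnot(noise_cv >= 0, n_points >= 2L, t_end > 0, X0 > 0, mu >= 0,
            true_labeled_fraction >= 0, true_labeled_fraction <= 1,
            natural_abundance >= 0, natural_abundance < 1)
  structure(list(seed = as.integer(seed), mu = mu, X0 = X0, q_true = q_true,
                 S0 = S0, evap_rate = evap_rate, noise_cv = noise_cv,
                 n_points = as.integer(n_points), t_end = t_end,
                 cdw_factor = cdw_factor,
                 true_labeled_fraction = true_labeled_fraction,
                 natural_abundance = natural_abundance),
            class = "simulation_spec")
}

# run fn() under the spec's seed without disturbing the caller's RNG stream
.with_spec_seed <- function(spec, offset, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(spec$seed + offset)
  fn()
}

#' Simulate a batch culture with evaporation control
#'
#' Generates an OD600 series OD(t) = (X0/cdw_factor) e^(mu t) (1 + eps), a
#' culture substrate series S(t) = S0 - evap t - q X0/mu (e^(mu t) - 1)
#' plus noise, and a matching non-consuming evaporation-control series
#' S0 - evap t plus noise. Noise is i.i.d. multiplicative Gaussian with the
#' spec's coefficient of variation. Substrate values driven negative are
#' truncated at zero with a warning. Identical specs give identical output.
#'
#' @param spec a [simulation_spec()].
#' @return list of `time_series`: `od`, `substrate`, `evap_control`.
#' @examples
#' sim <- simulate_culture(simulation_spec(seed = 7))
#' fit_exponential_growth(sim$od)
#' @export
simulate_culture <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  t <- seq(0, spec$t_end, length.out = spec$n_points)
  .with_spec_seed(spec, 0L, function() {
    noise <- function() 1 + spec$noise_cv * rnorm(spec$n_points)
    od_true <- spec$X0 / spec$cdw_factor * exp(spec$mu * t)
    consumed <- if (spec$mu > 0) {
      spec$q_true * spec$X0 / spec$mu * (exp(spec$mu * t) - 1)
    } else {
      spec$q_true * spec$X0 * t
    }
    s_true <- spec$S0 - spec$evap_rate * t - consumed
    e_true <- spec$S0 - spec$evap_rate * t
    od <- od_true * noise()
    s <- s_true * noise()
    e <- e_true * noise()
    if (any(s_true < 0) || any(s < 0) || any(e < 0)) {
      warning("substrate driven negative; truncated at 0", call. = FALSE)
      s[s < 0] <- 0; e[e < 0] <- 0
    }
    list(od = time_series(t, od, "od"),
         substrate = time_series(t, s, "substrate"),
         evap_control = time_series(t, e, "substrate"))
  })
}

#' Simulate an isotopologue distribution
#'
#' Position-level generative model: `n_labeled_positions` of the
#' `n_carbon` atoms are tracer-labeled independently with probability
#' true_labeled_fraction * n_carbon / n_labeled_positions (so the expected
#' average labeled fraction equals the spec value), and every carbon not
#' tracer-labeled carries a natural heavy isotope with probability
#' `natural_abundance`. The exact distribution (binomial tracer convolution
#' then natural-abundance convolution) receives i.i.d. multiplicative noise
#' per isotopologue.
#'
#' @param spec a [simulation_spec()].
#' @param n_carbon carbon count of the metabolite.
#' @param n_labeled_positions number of tracer-accessible positions.
#' @param metabolite_id label for the output.
#' @return An [isotopologue_distribution()].
#' @examples
#' simulate_isotopologues(simulation_spec(), 6, 1)  # hexose 6-phosphate
#' @export
simulate_isotopologues <- function(spec, n_carbon, n_labeled_positions,
                                   metabolite_id = "") {
  stopifnot(inherits(spec, "simulation_spec"), n_carbon >= 1,
            n_labeled_positions >= 0, n_labeled_positions <= n_carbon)
  k <- n_labeled_positions
  p1 <- if (k > 0) spec$true_labeled_fraction * n_carbon / k else 0
  if (p1 > 1 + 1e-12)
    stop("position labeling probability ", signif(p1, 4),
         " exceeds 1; fewer labeled positions than the target fraction ",
         "requires", call. = FALSE)
  p1 <- min(p1, 1)
  tracer <- c(dbinom(0:k, k, p1), rep(0, n_carbon - k))
  obs <- .natural_abundance_matrix(n_carbon, spec$natural_abundance) %*%
    tracer
  .with_spec_seed(spec, 1L, function() {
    noisy <- as.numeric(obs) *
      (1 + spec$noise_cv * rnorm(n_carbon + 1L))
    noisy[noisy < 0] <- 0
    isotopologue_distribution(noisy, metabolite_id)
  })
}

#' Write simulated culture data as TSV files
#'
#' Emits `od.tsv`, `substrate.tsv` and `evap_control.tsv` (columns `time`,
#' `value`) into a directory, the input format of the physiology module.
#'
#' @param sim result of [simulate_culture()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_culture_tsv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(sim)) {
    write.table(data.frame(time = sim[[nm]]$times, value = sim[[nm]]$values),
                file.path(dir, paste0(nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a (time, value) TSV as a time series
#'
#' @param path TSV with columns `time` and `value`.
#' @param kind `"substrate"` or `"od"`.
#' @return A [time_series()].
#' @export
read_timeseries <- function(path, kind = c("substrate", "od")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("time", "value") %in% names(df)))
    stop("expected columns 'time' and 'value'", call. = FALSE)
  time_series(df$time, df$value, match.arg(kind))
}
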