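# Stem-cell models of the testis.
#
# Growth phase: from the founding cell, growth_generations symmetric doublings
# build the pool of 2^G self-renewing spermatogonia present at puberty.  Every
# daughter cell mutates with probability mu per division; because divisions
# are symmetric, a mutation at generation g founds a clone of 2^(G-g-1) cells
# at puberty.  Adult phase: every cycle_days days each stem cell either
# divides symmetrically (two stem daughters) or differentiates towards sperm;
# wild-type cells do either with probability 1/2 (keeping the pool constant),
# mutant cells divide symmetrically with probability sym_bias (1/2 in the
# hot-spot model, > 1/2 in the selection model).  Clones occupy contiguous
# arcs of the unit circle (descendants stay in close proximity); the circle is
# cut into n_pieces equal arcs to emulate the dissection.

#' Configuration for the stem-cell simulator
#'
#' @param model `"hotspot"` (mutants behave like wild type; free parameter is
#'   the mutation rate per cell division) or `"selection"` (mutants divide
#'   symmetrically with probability `sym_bias` > 1/2; free parameter is the
#'   bias, with the mutation rate fixed by `genome_site_rate`).
#' @param donor_age_years age of the testis donor; with `puberty_age_years`
#'   and `cycle_days` it sets the number of adult cycles
#'   `floor((age - puberty) * 365.25 / cycle_days)`.
#' @param growth_generations pre-pubertal doubling generations (default 30,
#'   implying a pool of 2^30 stem cells).
#' @param cycle_days adult division interval in days (default 16).
#' @param puberty_age_years age at sexual maturity (default 13).
#' @param n_pieces number of equal arcs the simulated testis is cut into
#'   (48 for pool-level comparisons, 192 for piece-level; toy values allowed).
#' @param mutation_rate probability of mutating a given site per daughter cell
#'   per division.  For the selection model the default calibrates it so the
#'   expected mutant fraction accumulated over the growth phase equals the
#'   genome-average per-site de novo rate: `genome_site_rate /
#'   growth_generations`.  For the hot-spot model it is the free parameter and
#'   must be supplied (or fitted).
#' @param sym_bias probability that a mutant stem cell divides symmetrically
#'   (0.5 for the hot-spot model; in `[0.5, 1)` for the selection model).
#' @param genome_site_rate genome-average mutation rate per site per
#'   generation used to calibrate the selection model (default 1.1e-8).
#' @param ploidy_factor conversion from mutant-cell fraction to measured
#'   allele fraction (default 0.5: diploid cells, heterozygous mutation).
#' @param match_tolerance relative window within which a simulated average
#'   testis frequency counts as matching the observed one (default 0.05).
#' @param n_matched_target matched simulations required for a Monte-Carlo
#'   p-value (default 10000).
#' @param rng_seed optional integer seed applied by the simulation wrappers.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(model = c("hotspot", "selection"),
                       donor_age_years,
                       growth_generations = 30L,
                       cycle_days = 16,
                       puberty_age_years = 13,
                       n_pieces = 48L,
                       mutation_rate = NULL,
                       sym_bias = NULL,
                       genome_site_rate = 1.1e-8,
                       ploidy_factor = 0.5,
                       match_tolerance = 0.05,
                       n_matched_target = 10000L,
                       rng_seed = NULL) {
  model <- match.arg(model)
  stopifnot(growth_generations >= 1, cycle_days > 0,
            donor_age_years > puberty_age_years,
            n_pieces >= 1, ploidy_factor > 0, ploidy_factor <= 1,
            match_tolerance > 0)
  if (is.null(sym_bias)) sym_bias <- 0.5
  if (model == "hotspot" && sym_bias != 0.5)
    stop("hot-spot model requires sym_bias = 0.5")
  if (sym_bias < 0.5 || sym_bias >= 1)
    stop("sym_bias must lie in [0.5, 1)")
  if (model == "selection" && is.null(mutation_rate))
    mutation_rate <- genome_site_rate / growth_generations
  if (!is.null(mutation_rate)) {
    stopifnot(mutation_rate >= 0, mutation_rate < 1)
    if (mutation_rate * growth_generations >= 1)
      stop("parameter regime: expected mutant fraction mu * G >= 1")
  }
  structure(list(model = model,
                 donor_age_years = donor_age_years,
                 growth_generations = as.integer(growth_generations),
                 cycle_days = cycle_days,
                 puberty_age_years = puberty_age_years,
                 n_pieces = as.integer(n_pieces),
                 mutation_rate = mutation_rate,
                 sym_bias = sym_bias,
                 genome_site_rate = genome_site_rate,
                 ploidy_factor = ploidy_factor,
                 match_tolerance = match_tolerance,
                 n_matched_target = as.integer(n_matched_target),
                 rng_seed = rng_seed),
            class = "sim_config")
}

#' Number of adult-phase division cycles for a config
#'
#' @param config a [sim_config()].
#' @return integer cycle count `floor((age - puberty) * 365.25 / cycle_days)`.
#' @export
n_adult_cycles <- function(config) {
  floor((config$donor_age_years - config$puberty_age_years) * 365.25 /
          config$cycle_days)
}

#' Expected average testis frequency under a model configuration
#'
#' Closed-form expectation of the simulated average frequency.  Growth-phase
#' layers contribute `mu` each in expectation; a clone alive at puberty is
#' multiplied by `(2 p)^T` in expectation over T adult cycles (martingale at
#' p = 1/2), and adult-phase arrivals contribute
#' `mu * ((2p)^T - 1) / (2p - 1)` (= `mu * T` at p = 1/2).  Scaled by the
#' ploidy factor.
#'
#' @param config a [sim_config()]; `mutation_rate` must be set.
#' @param mutation_rate,sym_bias optional overrides.
#' @return expected average frequency on the VAF scale.
#' @export
expected_avg_freq <- function(config, mutation_rate = config$mutation_rate,
                              sym_bias = config$sym_bias) {
  stopifnot(!is.null(mutation_rate))
  G <- config$growth_generations
  T_cycles <- n_adult_cycles(config)
  d2 <- 2 * sym_bias - 1   # offspring mean is 1 + d2
  A <- (1 + d2)^T_cycles
  adult <- if (abs(d2) < 1e-12) T_cycles else (A - 1) / d2
  config$ploidy_factor * mutation_rate * (G * A + adult)
}

#' Simulate the pre-pubertal growth phase (mutant lineages only)
#'
#' @param config a [sim_config()] with `mutation_rate` set.
#' @return data frame of clones: `origin` (growth-generation index, 0-based),
#'   `size` (mutant stem cells at puberty), `position` (uniform on the unit
#'   circle; the clone occupies the contiguous arc of width `size / 2^G`).
#' @export
simulate_growth_phase <- function(config) {
  mu <- config$mutation_rate
  stopifnot(!is.null(mu))
  G <- config$growth_generations
  if (mu * G >= 1)
    stop("parameter regime: expected mutant count exceeds the population")
  out <- lapply(seq_len(G) - 1L, function(g) {
    m <- rpois(1, 2^(g + 1) * mu)
    if (m == 0) return(NULL)
    data.frame(origin = g, size = 2^(G - g - 1), position = runif(m))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(origin = integer(), size = numeric(), position = numeric())
  res
}

#' Advance mutant clones through adult-phase cycles
#'
#' Per cycle each clone of size n is replaced by `2 * Binomial(n, sym_bias)`
#' (each mutant cell divides symmetrically with probability `sym_bias`, else
#' differentiates out of the pool); extinct clones are dropped; new mutant
#' lineages arrive as `Poisson(2^G * mutation_rate)` clones of size 1 at
#' uniform positions, appended after the update.
#'
#' @param clones data frame as from [simulate_growth_phase()].
#' @param config a [sim_config()].
#' @param cycles number of cycles (default [n_adult_cycles()]).
#' @return updated clone data frame (adult arrivals get `origin = G + cycle`).
#' @export
simulate_adult_phase <- function(clones, config, cycles = n_adult_cycles(config)) {
  G <- config$growth_generations
  pool <- 2^G
  p <- config$sym_bias
  mu <- config$mutation_rate
  lam <- pool * mu
  for (t in seq_len(cycles)) {
    if (nrow(clones)) {
      clones$size <- 2 * rbinom(nrow(clones), clones$size, p)
      clones <- clones[clones$size > 0, , drop = FALSE]
      if (sum(clones$size) > pool)
        stop("parameter regime: mutant clones exceed the stem-cell pool")
    }
    m <- if (lam > 0) rpois(1, lam) else 0L
    if (m > 0) {
      clones <- rbind(clones,
                      data.frame(origin = G + t, size = rep(1, m),
                                 position = runif(m)))
    }
  }
  clones
}

#' Render a clone set into piece frequencies
#'
#' The unit circle is split into `n_pieces` equal arcs; each clone occupies
#' the contiguous arc `[position, position + size/2^G)` and contributes its
#' overlap with each piece.  Piece frequency is the ploidy-scaled fraction of
#' the piece's cells that are mutant; the average frequency is the
#' ploidy-scaled mutant fraction of the whole pool.
#'
#' @param clones clone data frame.
#' @param config a [sim_config()].
#' @return list of class `"sim_result"`: `avg_freq`, `piece_freqs` (length
#'   `n_pieces`), `max_piece_freq`, `n_clones`.
#' @export
render_testis <- function(clones, config) {
  G <- config$growth_generations
  P <- config$n_pieces
  pool <- 2^G
  piece <- numeric(P)
  if (nrow(clones)) {
    for (i in seq_len(nrow(clones))) {
      x <- clones$position[i] * P
      p0 <- min(floor(x), P - 1)
      remain <- clones$size[i] / pool * P
      first <- min(remain, p0 + 1 - x)
      piece[p0 + 1] <- piece[p0 + 1] + first
      remain <- remain - first
      pi <- (p0 + 1) %% P
      while (remain > 0) {
        add <- min(remain, 1)
        piece[pi + 1] <- piece[pi + 1] + add
        remain <- remain - add
        pi <- (pi + 1) %% P
      }
    }
  }
  pf <- config$ploidy_factor * piece
  structure(list(avg_freq = config$ploidy_factor * sum(clones$size) / pool,
                 piece_freqs = pf,
                 max_piece_freq = if (P > 0) max(pf) else 0,
                 n_clones = nrow(clones)),
            class = "sim_result")
}

#' Simulate one testis (growth + adult phase + rendering)
#'
#' Readable single-replicate path through [simulate_growth_phase()],
#' [simulate_adult_phase()] and [render_testis()]; for large replicate counts
#' use [simulate_testis_reps()].
#'
#' @param config a [sim_config()] with `mutation_rate` set.
#' @param seed optional seed (defaults to `config$rng_seed` if set).
#' @return a `"sim_result"` list.
#' @export
simulate_testis <- function(config, seed = config$rng_seed) {
  if (!is.null(seed)) set.seed(seed)
  clones <- simulate_growth_phase(config)
  clones <- simulate_adult_phase(clones, config)
  render_testis(clones, config)
}

#' Batched testis simulations (C++ engine)
#'
#' Runs `n_reps` independent replicates of the configured model and returns
#' the simulated average and maximum piece frequencies.  Simulations whose
#' mutant lineages exceed the stem-cell pool (unphysical parameter regimes)
#' are capped and flagged `saturated`, with `avg_freq = ploidy_factor`.
#'
#' @param config a [sim_config()] with `mutation_rate` set.
#' @param n_reps number of replicates.
#' @param seed optional seed (defaults to `config$rng_seed`).
#' @param return_pieces also return the `n_reps x n_pieces` matrix of piece
#'   frequencies (memory-heavy; default `FALSE`).
#' @return data frame with columns `avg_freq`, `max_piece_freq`, `saturated`
#'   (plus a `piece_freqs` matrix attribute when requested).
#' @export
simulate_testis_reps <- function(config, n_reps, seed = config$rng_seed,
                                 return_pieces = FALSE) {
  stopifnot(!is.null(config$mutation_rate), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_sim_reps(as.integer(n_reps), config$growth_generations,
                      as.double(n_adult_cycles(config)),
                      config$mutation_rate, config$sym_bias,
                      config$n_pieces, config$ploidy_factor,
                      isTRUE(return_pieces))
  out <- data.frame(avg_freq = res$avg_freq,
                    max_piece_freq = res$max_piece_freq,
                    saturated = res$saturated)
  if (isTRUE(return_pieces)) attr(out, "piece_freqs") <- res$piece_freqs
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %s model, donor age %s y, G = %d, %d adult cycles (%g-d), %d pieces\n",
              x$model, format(x$donor_age_years), x$growth_generations,
              n_adult_cycles(x), x$cycle_days, x$n_pieces))
  cat(sprintf("  mutation_rate = %s, sym_bias = %g, ploidy = %g\n",
              if (is.null(x$mutation_rate)) "<free>" else format(x$mutation_rate, digits = 4),
              x$sym_bias, x$ploidy_factor))
  invisible(x)
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: avg = %.4g, max piece = %.4g (%d pieces, %d clones)\n",
              x$avg_freq, x$max_piece_freq, length(x$piece_freqs), x$n_clones))
  invisible(x)
}
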