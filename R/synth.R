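# Synthetic-data generators emulating the sampling designs: sperm-donor
# cohorts screened by digital PCR, the 6-slice x 32-piece dissected testis,
# and spike-in dilution series.  Every generator returns its ground truth
# alongside the observations so recovery tests compare against truth.

#' Specification of a synthetic sperm-donor cohort
#'
#' Donor VAFs follow a zero-inflated lognormal background: with probability
#' `zero_inflation` a donor is mutation-free; otherwise the true VAF is
#' lognormal with median `baseline_vaf * (1 + age_slope)^(age - 40)` (age 40
#' is near the cohort midpoint) and a log-scale spread set from `vaf_iqr`
#' (the IQR a null cohort of median `baseline_vaf` would show).  The
#' lognormal reproduces the heavy right tail of published cohorts (Max/IQR
#' ratios of 5-66).  Observed counts are molecule-level: each sample's
#' molecules are split over `n_reactions` reactions and mutant molecules are
#' binomial draws at `truth + false_positive_rate`.
#'
#' @param n_donors number of donors (default 90).
#' @param age_range inclusive integer age range, sampled uniformly
#'   (default 23-59).
#' @param baseline_vaf median true VAF of mutation-positive donors at age 40
#'   (default 1.5e-5).
#' @param vaf_iqr interquartile range parameterising the lognormal spread
#'   (default 2e-5).
#' @param age_slope per-year multiplicative VAF trend (0 = null cohort).
#' @param zero_inflation probability a donor carries no mutation
#'   (default 0.15).
#' @param molecules_range molecules screened per sample, sampled uniformly
#'   (default 270,000-300,000).
#' @param n_reactions reactions per sample (default 4).
#' @param false_positive_rate per-molecule artifact probability
#'   (default 1e-6).
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_donors = 90, age_range = c(23, 59),
                        baseline_vaf = 1.5e-5, vaf_iqr = 2e-5,
                        age_slope = 0, zero_inflation = 0.15,
                        molecules_range = c(270000, 300000),
                        n_reactions = 4, false_positive_rate = 1e-6) {
  stopifnot(n_donors >= 1, age_range[1] < age_range[2],
            baseline_vaf >= 0, vaf_iqr >= 0,
            zero_inflation >= 0, zero_inflation <= 1,
            molecules_range[1] > 0, n_reactions >= 1,
            false_positive_rate >= 0, false_positive_rate <= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

# log-scale sd such that a lognormal with median m has the requested IQR:
# quartiles m * exp(+-0.6745 s) => IQR = 2 m sinh(0.6745 s)
.lognormal_sdlog <- function(median_vaf, iqr) {
  if (median_vaf <= 0 || iqr <= 0) return(1)
  asinh(iqr / (2 * median_vaf)) / qnorm(0.75)
}

#' Generate a synthetic donor cohort with per-reaction dPCR counts
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @param variant_id label attached to all rows (default `"synthetic"`).
#' @return list with `truth` (donor_id, age, true_vaf), `reactions`
#'   (per-reaction count table in the [read_dpcr_reactions()] dialect) and
#'   `donors` (per-donor table with the observed Poisson-corrected `vaf`, in
#'   the [read_donor_table()] dialect).
#' @export
gen_cohort <- function(spec, seed, variant_id = "synthetic") {
  set.seed(seed)
  n <- spec$n_donors
  age <- sample(seq(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  sdlog <- .lognormal_sdlog(spec$baseline_vaf, spec$vaf_iqr)
  med <- spec$baseline_vaf * (1 + spec$age_slope)^(age - 40)
  truth <- ifelse(runif(n) < spec$zero_inflation | spec$baseline_vaf == 0,
                  0, rlnorm(n, meanlog = log(pmax(med, 1e-300)), sdlog = sdlog))
  truth <- pmin(truth, 0.5)
  donor_id <- sprintf("D%03d", seq_len(n))

  mols <- round(runif(n, spec$molecules_range[1], spec$molecules_range[2]))
  per <- floor(mols / spec$n_reactions)
  rows <- lapply(seq_len(n), function(i) {
    m_r <- rep(per[i], spec$n_reactions)
    m_r[1] <- m_r[1] + mols[i] - sum(m_r)
    p <- min(truth[i] + spec$false_positive_rate, 1)
    mut <- rbinom(spec$n_reactions, m_r, p)
    data.frame(sample_id = donor_id[i], variant_id = variant_id,
               reaction_index = seq_len(spec$n_reactions),
               mutant_positive = mut, wildtype_positive = m_r - mut,
               stringsAsFactors = FALSE)
  })
  reactions <- do.call(rbind, rows)
  samples <- summarize_dpcr_samples(reactions)
  donors <- data.frame(donor_id = donor_id, age = age,
                       variant_id = variant_id,
                       vaf = samples$vaf[match(donor_id, samples$sample_id)],
                       stringsAsFactors = FALSE)
  list(truth = data.frame(donor_id = donor_id, age = age, true_vaf = truth,
                          stringsAsFactors = FALSE),
       reactions = reactions,
       donors = donors)
}

#' Specification of a synthetic dissected testis
#'
#' @param background_vaf uniform background allele fraction of every piece
#'   (default 3e-6).
#' @param planted_clones data frame of planted subclones with columns
#'   `slice, strip, row, cell_fraction` (one row per affected piece;
#'   contiguous coordinates emulate a spatially coherent clone).
#' @param molecules_per_piece screening depth per piece (default 30,000).
#' @param ploidy_factor cell-fraction to allele-fraction conversion
#'   (default 0.5).
#' @return list of class `"testis_spec"`.
#' @export
testis_spec <- function(background_vaf = 3e-6,
                        planted_clones = NULL,
                        molecules_per_piece = 30000,
                        ploidy_factor = 0.5) {
  if (is.null(planted_clones))
    planted_clones <- data.frame(slice = integer(), strip = integer(),
                                 row = integer(), cell_fraction = numeric())
  stopifnot(background_vaf >= 0, molecules_per_piece > 0,
            all(planted_clones$cell_fraction >= 0),
            all(planted_clones$cell_fraction <= 1))
  if (nrow(planted_clones) &&
      (any(planted_clones$slice < 1) || any(planted_clones$slice > 6) ||
       any(planted_clones$strip < 1) || any(planted_clones$strip > 4) ||
       any(planted_clones$row < 1) || any(planted_clones$row > 8)))
    stop("planted clone coordinates outside the 6 x 4 x 8 grid")
  structure(list(background_vaf = background_vaf,
                 planted_clones = planted_clones,
                 molecules_per_piece = molecules_per_piece,
                 ploidy_factor = ploidy_factor),
            class = "testis_spec")
}

#' Generate a synthetic testis map with molecule counts
#'
#' Piece-level true allele fraction is `background_vaf` plus the
#' ploidy-scaled planted cell fraction; overlapping planted entries in one
#' piece are summed and capped at 1 with a warning.  Observed mutant counts
#' are binomial at the per-piece screening depth.
#'
#' @param spec a [testis_spec()].
#' @param seed integer seed.
#' @return list with `truth` (per-piece true VAF and the planted pool ids)
#'   and `map` (a [testis_map()] with counts).
#' @export
gen_testis <- function(spec, seed) {
  set.seed(seed)
  pooling <- default_pooling()
  pieces <- pooling[, c("slice", "strip", "row")]
  truth <- rep(spec$background_vaf, nrow(pieces))
  pc <- spec$planted_clones
  if (nrow(pc)) {
    key <- paste(pieces$slice, pieces$strip, pieces$row)
    add <- tapply(pc$cell_fraction, paste(pc$slice, pc$strip, pc$row), sum)
    idx <- match(names(add), key)
    if (anyNA(idx)) stop("planted clone coordinates outside the grid")
    frac <- as.numeric(add)
    if (any(frac > 1)) {
      warning("overlapping planted clones exceed cell fraction 1; capped")
      frac <- pmin(frac, 1)
    }
    truth[idx] <- truth[idx] + spec$ploidy_factor * frac
  }
  truth <- pmin(truth, 1)
  mut <- rbinom(length(truth), spec$molecules_per_piece, truth)
  pieces$mutant_positive <- mut
  pieces$wildtype_positive <- spec$molecules_per_piece - mut
  map <- testis_map(pieces, pooling)
  planted_pools <- unique(map$pieces$pool_id[truth > spec$background_vaf])
  list(truth = cbind(pieces[, c("slice", "strip", "row")],
                     true_vaf = truth, pool_id = map$pieces$pool_id),
       planted_pools = sort(planted_pools),
       map = map)
}

#' Generate a spike-in serial dilution series
#'
#' Mutant:wild-type mixing ratios are observed through binomial molecule
#' sampling at the stated depth; steps where no mutant molecule is sampled
#' get observed ratio 0 (excluded from [calibration_fit()] and flagged).
#'
#' @param ratios expected mutant:wild-type ratios
#'   (default `10^-(1:4)`, i.e. 1:10 ... 1:10,000 in 10-fold steps).
#' @param molecules genomes screened per step; recycled
#'   (default 20,000, as for single-reaction dilution steps).
#' @param seed integer seed.
#' @return a [calibration_series()] with an attached `truth` attribute.
#' @export
gen_dilution_series <- function(ratios = 10^-(1:4), molecules = 20000, seed) {
  stopifnot(all(ratios > 0))
  set.seed(seed)
  molecules <- rep_len(molecules, length(ratios))
  frac <- ratios / (1 + ratios)
  mut <- rbinom(length(ratios), molecules, frac)
  obs <- ifelse(mut < molecules, mut / (molecules - mut), Inf)
  out <- calibration_series(ratios, obs)
  attr(out, "truth") <- data.frame(expected_ratio = ratios,
                                   molecules = molecules, mutant = mut)
  out
}
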