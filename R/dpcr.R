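#' Poisson-corrected variant allele frequency from compartment counts
#'
#' Digital PCR partitions a sample into compartments (droplets or beads) so
#' that single molecules amplify in isolation.  Because a compartment can hold
#' more than one template, the raw fraction of mutant-positive compartments
#' underestimates the mutant concentration; the Poisson occupancy correction
#' recovers the mean number of mutant templates per informative compartment as
#' \deqn{\lambda = -\ln(1 - \mathrm{mut}/(\mathrm{mut}+\mathrm{wt})).}
#' At the rare frequencies relevant for germline mosaicism (\eqn{\le 10^{-4}})
#' the correction is tiny, but it is exact at any occupancy below saturation.
#'
#' @param mutant_positive number of mutant-positive compartments (>= 0).
#' @param wildtype_positive number of wild-type-positive compartments (>= 0).
#' @return the corrected allele fraction \eqn{\lambda} (unitless, >= 0).
#' @examples
#' poisson_vaf(3, 299997)     # ~1.000005e-05
#' poisson_vaf(0, 300000)     # exactly 0
#' @export
poisson_vaf <- function(mutant_positive, wildtype_positive) {
  stopifnot(length(mutant_positive) == length(wildtype_positive))
  if (any(mutant_positive < 0) || any(wildtype_positive < 0))
    stop("compartment counts must be non-negative")
  total <- mutant_positive + wildtype_positive
  if (any(total == 0))
    stop("invalid input: mutant_positive + wildtype_positive must be > 0")
  frac <- mutant_positive / total
  if (any(frac >= 1))
    stop("saturation: every compartment mutant-positive, lambda undefined")
  -log1p(-frac)
}

#' Construct a single digital-PCR reaction record
#'
#' @param mutant_positive,wildtype_positive compartment counts.
#' @param total_compartments optional total number of compartments read
#'   (for occupancy diagnostics); must be >= mutant + wild type when given.
#' @param genomes_loaded optional expected input genome count.
#' @return an object of class `"dpcr_reaction"`.
#' @export
dpcr_reaction <- function(mutant_positive, wildtype_positive,
                          total_compartments = NA_real_,
                          genomes_loaded = NA_real_) {
  stopifnot(mutant_positive >= 0, wildtype_positive >= 0)
  if (!is.na(total_compartments) &&
      mutant_positive + wildtype_positive > total_compartments)
    stop("positive compartments exceed total_compartments")
  structure(list(mutant_positive = mutant_positive,
                 wildtype_positive = wildtype_positive,
                 total_compartments = total_compartments,
                 genomes_loaded = genomes_loaded),
            class = "dpcr_reaction")
}

#' Merge replicate reactions into one sample-level measurement
#'
#' A sample is typically split over 4 reactions (~300,000 genomes in total).
#' Counts are summed across reactions before the Poisson correction is applied
#' once; this is equivalent to averaging per-reaction corrections at rare
#' frequencies and, unlike averaging, is well defined when individual
#' reactions have zero mutant counts.
#'
#' @param reactions a list of [dpcr_reaction()] objects, or a data frame with
#'   columns `mutant_positive` and `wildtype_positive` (one row per reaction).
#' @return an object of class `"sample_measurement"`: a list with elements
#'   `vaf` (Poisson-corrected allele fraction), `molecules_screened` (summed
#'   informative molecules), `is_negative` (no mutant-positive compartment in
#'   any reaction), `n_reactions`, and the summed counts.
#' @export
merge_sample <- function(reactions) {
  if (is.data.frame(reactions)) {
    if (nrow(reactions) == 0) stop("invalid input: no reactions supplied")
    mut <- reactions$mutant_positive
    wt <- reactions$wildtype_positive
  } else {
    if (length(reactions) == 0) stop("invalid input: no reactions supplied")
    if (inherits(reactions, "dpcr_reaction")) reactions <- list(reactions)
    mut <- vapply(reactions, function(r) r$mutant_positive, numeric(1))
    wt <- vapply(reactions, function(r) r$wildtype_positive, numeric(1))
  }
  if (any(mut < 0) || any(wt < 0)) stop("compartment counts must be non-negative")
  m <- sum(mut); w <- sum(wt)
  structure(list(mutant_positive = m,
                 wildtype_positive = w,
                 vaf = poisson_vaf(m, w),
                 molecules_screened = m + w,
                 is_negative = m == 0,
                 n_reactions = length(mut)),
            class = "sample_measurement")
}

#' @export
print.sample_measurement <- function(x, ...) {
  cat(sprintf("dPCR sample: %d reactions, %s molecules screened\n",
              x$n_reactions, format(x$molecules_screened, big.mark = ",")))
  cat(sprintf("  VAF = %.4g%s\n", x$vaf,
              if (x$is_negative) " (negative sample)" else ""))
  invisible(x)
}

#' Spike-in dilution series
#'
#' @param expected_ratio expected mutant:wild-type mixing ratios (> 0), one
#'   per dilution step (e.g. `10^-(1:4)` for 1:10 ... 1:10,000).
#' @param observed_ratio measured ratios, same length; steps with observed 0
#'   are retained in the object but excluded from the correlation.
#' @return an object of class `"calibration_series"`.
#' @export
calibration_series <- function(expected_ratio, observed_ratio) {
  stopifnot(length(expected_ratio) == length(observed_ratio))
  if (any(expected_ratio <= 0)) stop("expected ratios must be positive")
  structure(list(expected_ratio = expected_ratio,
                 observed_ratio = observed_ratio),
            class = "calibration_series")
}

#' Pearson correlation of a log-scaled dilution series
#'
#' Serial spike-in dilutions span several orders of magnitude, so accuracy is
#' assessed as the Pearson correlation of log10(expected) against
#' log10(observed) mixing ratios.  Steps with an observed ratio of zero (no
#' mutant molecule sampled) carry no log-scale information and are excluded
#' from the correlation but reported.
#'
#' @param series a [calibration_series()] (or a list with `expected_ratio`,
#'   `observed_ratio`).
#' @return a list with `pearson_r`, `n_used`, and `dropped_zero` (indices of
#'   zero-observed steps).
#' @export
calibration_fit <- function(series) {
  ex <- series$expected_ratio
  ob <- series$observed_ratio
  if (any(ex <= 0)) stop("expected ratios must be positive")
  usable <- is.finite(ob) & ob > 0
  if (sum(usable) < 3)
    stop("insufficient data: need >= 3 dilution steps with non-zero observed ratios")
  r <- cor(log10(ex[usable]), log10(ob[usable]), method = "pearson")
  list(pearson_r = r, n_used = sum(usable), dropped_zero = which(!usable))
}

#' Two-sided Fisher's exact test between two count-based VAF measurements
#'
#' Compares mutant incidence between two platforms (e.g. digital PCR and
#' duplex sequencing) as a 2x2 table of mutant vs non-mutant molecules.
#'
#' @param mut_a,total_a mutant and total molecule counts on platform A.
#' @param mut_b,total_b mutant and total molecule counts on platform B.
#' @return two-sided p-value of Fisher's exact test.
#' @export
fisher_compare <- function(mut_a, total_a, mut_b, total_b) {
  stopifnot(mut_a >= 0, mut_b >= 0)
  if (total_a == 0 || total_b == 0) stop("invalid input: zero total molecules")
  if (mut_a > total_a || mut_b > total_b)
    stop("mutant count exceeds total")
  tab <- matrix(c(mut_a, total_a - mut_a, mut_b, total_b - mut_b), nrow = 2)
  fisher.test(tab)$p.value
}

#' Probability of detecting a variant at a given screening depth
#'
#' With `molecules` informative molecules screened and a true allele fraction
#' `true_vaf`, the number of mutant molecules sampled is approximately
#' Poisson with mean `true_vaf * molecules`; the probability that at least one
#' is observed is `1 - exp(-true_vaf * molecules)`.
#'
#' @param true_vaf true allele fraction, in `[0, 1)`.
#' @param molecules number of molecules screened (> 0).
#' @return probability of observing >= 1 mutant molecule.
#' @examples
#' detection_probability(1e-5, 300000)  # 1 - exp(-3) ~ 0.95
#' @export
detection_probability <- function(true_vaf, molecules) {
  stopifnot(all(true_vaf >= 0), all(true_vaf < 1), all(molecules > 0))
  -expm1(-true_vaf * molecules)
}

# ---- per-reaction CSV interface --------------------------------------------

#' Read a per-reaction digital-PCR count table
#'
#' Expected columns: `sample_id, variant_id, reaction_index, mutant_positive,
#' wildtype_positive` and optionally `total_compartments`.
#'
#' @param path CSV file path.
#' @return a validated data frame of reactions.
#' @export
read_dpcr_reactions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "variant_id", "reaction_index",
           "mutant_positive", "wildtype_positive")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$mutant_positive < 0) || any(df$wildtype_positive < 0))
    stop("compartment counts must be non-negative")
  if ("total_compartments" %in% names(df)) {
    bad <- !is.na(df$total_compartments) &
      df$mutant_positive + df$wildtype_positive > df$total_compartments
    if (any(bad)) stop("positive compartments exceed total_compartments")
  }
  df
}

#' Collapse a per-reaction table to per-sample Poisson-corrected VAFs
#'
#' @param reactions data frame as returned by [read_dpcr_reactions()].
#' @return data frame with one row per (`sample_id`, `variant_id`):
#'   summed counts, `vaf`, `molecules_screened`, `is_negative`, `n_reactions`.
#' @export
summarize_dpcr_samples <- function(reactions) {
  key <- interaction(reactions$sample_id, reactions$variant_id, drop = TRUE)
  out <- lapply(split(reactions, key), function(d) {
    m <- merge_sample(d)
    data.frame(sample_id = d$sample_id[1], variant_id = d$variant_id[1],
               n_reactions = m$n_reactions,
               mutant_positive = m$mutant_positive,
               wildtype_positive = m$wildtype_positive,
               vaf = m$vaf, molecules_screened = m$molecules_screened,
               is_negative = m$is_negative,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the per-sample VAF table
#'
#' @param samples data frame from [summarize_dpcr_samples()].
#' @param path output CSV path.
#' @export
write_dpcr_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
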