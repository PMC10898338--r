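# Digital-PCR quantification: Poisson occupancy correction, reaction
# merging, calibration, platform comparison, detection limits.

test_that("poisson correction matches its closed form and series oracle", {
  expect_identical(poisson_vaf(0, 300000), 0)
  # occupancy at the Poisson zero class: fraction 1 - e^-1 gives lambda = 1
  frac <- 1 - exp(-1)
  expect_equal(poisson_vaf(frac * 1e6, (1 - frac) * 1e6), 1, tolerance = 1e-12)
  # rare-variant regime against a high-precision series expansion
  expect_equal(poisson_vaf(3, 299997), series_neg_log1m(3 / 300000),
               tolerance = 1e-14)
  expect_equal(poisson_vaf(17, 54321 - 17), series_neg_log1m(17 / 54321),
               tolerance = 1e-14)
})

test_that("poisson correction is monotone, dominates the raw fraction, and converges to it", {
  set.seed(42)
  for (i in 1:20) {
    total <- sample(1e4:1e6, 1)
    m <- sort(sample(0:(total %/% 2), 2))
    expect_lt(poisson_vaf(m[1], total - m[1]), poisson_vaf(m[2], total - m[2]) + 1e-18)
    frac <- m[2] / total
    lam <- poisson_vaf(m[2], total - m[2])
    expect_gte(lam, frac)
    if (frac > 0 && frac < 1e-4)
      expect_lt((lam - frac) / frac, 1e-4)
  }
})

test_that("poisson correction rejects empty and saturated input", {
  expect_error(poisson_vaf(0, 0), "invalid input")
  expect_error(poisson_vaf(100, 0), "saturation")
  expect_error(poisson_vaf(-1, 10), "non-negative")
})

test_that("reaction merging sums counts before correcting, once", {
  rx <- function(m, w) dpcr_reaction(m, w)
  neg <- merge_sample(list(rx(0, 75000), rx(0, 75000), rx(0, 75000), rx(0, 75000)))
  expect_identical(neg$vaf, 0)
  expect_true(neg$is_negative)
  expect_identical(neg$molecules_screened, 300000)

  four <- merge_sample(list(rx(1, 74999), rx(1, 74999), rx(1, 74999), rx(1, 74999)))
  one <- merge_sample(list(rx(4, 299996)))
  expect_identical(four$vaf, one$vaf)

  mixed <- merge_sample(list(rx(2, 74998), rx(0, 75000), rx(1, 74999), rx(0, 75000)))
  expect_identical(mixed$vaf, poisson_vaf(3, 299997))
  expect_false(mixed$is_negative)

  # order invariance
  set.seed(1)
  rxs <- lapply(1:6, function(i) rx(rpois(1, 2), 50000))
  expect_identical(merge_sample(rxs)$vaf, merge_sample(rev(rxs))$vaf)

  expect_error(merge_sample(list()), "no reactions")
})

test_that("calibration correlation is computed on log scale with zero steps excluded", {
  ex <- 10^-(1:4)
  expect_equal(calibration_fit(calibration_series(ex, ex))$pearson_r, 1)
  expect_equal(calibration_fit(calibration_series(ex, rev(ex)))$pearson_r, -1)

  set.seed(7)
  obs <- ex * exp(rnorm(4, 0, 0.2))
  r <- calibration_fit(calibration_series(ex, obs))$pearson_r
  # direct covariance oracle on the log pairs
  lx <- log10(ex); ly <- log10(obs)
  r_direct <- mean((lx - mean(lx)) * (ly - mean(ly))) / (sd(lx) * sd(ly)) *
    length(lx) / (length(lx) - 1)
  expect_equal(r, r_direct, tolerance = 1e-12)

  fit <- calibration_fit(calibration_series(ex, c(obs[1:3], 0)))
  expect_identical(fit$dropped_zero, 4L)
  expect_identical(fit$n_used, 3L)
  expect_error(calibration_fit(calibration_series(ex, c(obs[1:2], 0, 0))),
               "insufficient data")
})

test_that("platform comparison agrees with exhaustive hypergeometric enumeration", {
  expect_equal(fisher_compare(5, 100, 5, 100), 1)
  expect_equal(fisher_compare(3, 50, 3, 50), 1)
  expect_equal(fisher_compare(0, 10, 10, 10), enum_fisher(0, 10, 10, 10),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:25) {
    ta <- sample(5:50, 1); tb <- sample(5:50, 1)
    ma <- sample(0:ta, 1); mb <- sample(0:tb, 1)
    expect_equal(fisher_compare(ma, ta, mb, tb), enum_fisher(ma, ta, mb, tb),
                 tolerance = 1e-9)
  }
  expect_error(fisher_compare(0, 0, 1, 10), "invalid input")
})

test_that("detection probability follows the Poisson zero class", {
  expect_identical(detection_probability(0, 1e6), 0)
  expect_equal(detection_probability(1e-5, 300000), 1 - exp(-3), tolerance = 1e-12)
  expect_equal(detection_probability(log(2) / 1e5, 1e5), 0.5, tolerance = 1e-12)
})

test_that("per-reaction tables round-trip through the CSV interface", {
  df <- data.frame(sample_id = rep(c("s1", "s2"), each = 4),
                   variant_id = "c.1620C>A",
                   reaction_index = rep(1:4, 2),
                   mutant_positive = c(1, 0, 2, 0, 0, 0, 0, 0),
                   wildtype_positive = rep(74000, 8))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  rd <- read_dpcr_reactions(path)
  smp <- summarize_dpcr_samples(rd)
  expect_identical(nrow(smp), 2L)
  s1 <- smp[smp$sample_id == "s1", ]
  expect_equal(s1$vaf, poisson_vaf(3, 4 * 74000))
  expect_true(smp$is_negative[smp$sample_id == "s2"])
  out <- tempfile(fileext = ".csv")
  write_dpcr_samples(smp, out)
  expect_equal(read.csv(out)$vaf, smp$vaf)
  unlink(c(path, out))

  bad <- df; bad$mutant_positive[1] <- -1
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_dpcr_reactions(path), "non-negative")
  unlink(path)
})
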