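# Dissected-testis workflow: pooling layout, pooled VAFs, drill-down,
# clustering summaries.

make_count_map <- function(mut, depth = 75000) {
  pooling <- default_pooling()
  pieces <- pooling[, c("slice", "strip", "row")]
  pieces$mutant_positive <- mut
  pieces$wildtype_positive <- depth - mut
  testis_map(pieces, pooling)
}

test_that("the default pooling tiles each slice with contiguous 2x2 blocks", {
  p <- default_pooling()
  expect_identical(nrow(p), 192L)
  expect_identical(length(unique(p$pool_id)), 48L)
  sizes <- table(p$pool_id)
  expect_true(all(sizes == 4))
  for (d in split(p, p$pool_id)) {
    expect_identical(length(unique(d$slice)), 1L)   # pools never span slices
    expect_identical(sort(unique(d$strip)) [2] - sort(unique(d$strip))[1], 1L)
    expect_identical(sort(unique(d$row))[2] - sort(unique(d$row))[1], 1L)
    expect_identical(nrow(unique(d[, c("strip", "row")])), 4L)
  }
})

test_that("count-mode pooling conserves molecules and matches the summing oracle", {
  set.seed(13)
  mut <- rpois(192, 0.5)
  map <- make_count_map(mut)
  pools <- pool_pieces(map, mode = "counts")
  expect_identical(nrow(pools), 48L)
  expect_identical(sum(pools$mutant_positive), sum(mut))
  expect_identical(sum(pools$wildtype_positive), sum(75000 - mut))
  for (i in sample(48, 6)) {
    members <- map$pieces[map$pieces$pool_id == pools$pool_id[i], ]
    expect_equal(pools$vaf[i],
                 poisson_vaf(sum(members$mutant_positive),
                             sum(members$wildtype_positive)))
  }
  # single positive molecule among 4 members of ~300,000 molecules
  mut1 <- integer(192); mut1[1] <- 1L
  p1 <- pool_pieces(make_count_map(mut1), mode = "counts")
  pid <- make_count_map(mut1)$pieces$pool_id[1]
  expect_equal(p1$vaf[p1$pool_id == pid], poisson_vaf(1, 4 * 75000 - 1))
})

test_that("mean-mode pooling averages member VAFs", {
  pooling <- default_pooling()
  pieces <- pooling[, c("slice", "strip", "row")]
  pieces$vaf <- 0
  pieces$vaf[pieces$slice == 1 & pieces$strip == 1 & pieces$row == 1] <- 1e-3
  map <- testis_map(pieces, pooling)
  pools <- pool_pieces(map, mode = "mean")
  pid <- map$pieces$pool_id[map$pieces$slice == 1 & map$pieces$strip == 1 &
                              map$pieces$row == 1]
  expect_equal(pools$vaf[pools$pool_id == pid], 2.5e-4)
  expect_true(all(pools$vaf[pools$pool_id != pid] == 0))
  # uniform members pool to the same value
  pieces$vaf <- 7e-6
  expect_true(all(pool_pieces(testis_map(pieces, pooling), "mean")$vaf == 7e-6))
})

test_that("hot pools are flagged at the drill-down threshold", {
  pooling <- default_pooling()
  pieces <- pooling[, c("slice", "strip", "row")]
  pieces$vaf <- 1e-6
  map <- testis_map(pieces, pooling)
  expect_identical(nrow(hot_pool_drilldown(map)$flagged), 0L)
  pieces$vaf[pieces$slice == 3 & pieces$strip == 2 & pieces$row == 5] <- 4 * 1e-4
  map <- testis_map(pieces, pooling)
  drill <- hot_pool_drilldown(map)
  expect_identical(nrow(drill$flagged), 1L)
  expect_identical(nrow(drill$members), 4L)
})

test_that("coarse pool measurements are checked against their fine members", {
  members <- c(1, 2, 3, 4) * 1e-5
  r <- coarse_fine_consistency(mean(members), members)
  expect_true(r$pass)
  expect_equal(r$deviation, 0)
  r2 <- coarse_fine_consistency(1e-4, members)
  expect_false(r2$pass)   # mean 2.5e-5, sd ~1.29e-5: deviation is outside
  r3 <- coarse_fine_consistency(5e-6, c(5e-6, NA, NA, NA))
  expect_true(is.na(r3$pass))
})

test_that("cluster summaries are permutation invariant with the IQR sentinel", {
  set.seed(3)
  v <- rlnorm(48, log(1e-5), 1)
  a <- cluster_summary(v)
  b <- cluster_summary(sample(v))
  expect_equal(a, b)
  expect_equal(a$max_over_iqr, max(v) / a$iqr)
  cc <- cluster_summary(rep(2e-5, 10))
  expect_identical(cc$iqr, 0)
  expect_identical(cc$sd, 0)
  expect_true(is.na(cc$max_over_iqr))
})

test_that("a growing planted clone inflates Max/IQR but not the median", {
  ratios <- numeric(0)
  for (f in c(0.02, 0.05, 0.1, 0.2, 0.4)) {
    spec <- testis_spec(background_vaf = 2e-5,
                        planted_clones = data.frame(slice = 2, strip = 2,
                                                    row = 3, cell_fraction = f),
                        molecules_per_piece = 50000)
    gt <- gen_testis(spec, seed = 77)
    cs <- cluster_summary(gt$map$pieces$vaf)
    ratios <- c(ratios, cs$max_over_iqr)
    expect_lt(cs$median_vaf, 1e-4)   # median stays at background
  }
  expect_true(all(diff(ratios) > 0))
})

test_that("testis summaries use pools for spread and the finest unit for the maximum", {
  set.seed(21)
  mut <- rpois(192, 0.3)
  mut[100] <- 40   # one hot piece (~5.3e-4) drives its pool above threshold
  map <- make_count_map(mut)
  ts <- testis_summary(map)
  pools <- pool_pieces(map)
  expect_identical(ts$n_units, 48L)
  expect_equal(ts$median_vaf, median(pools$vaf))
  piece_max <- max(map$pieces$vaf)
  expect_gt(piece_max, max(pools$vaf))
  expect_equal(ts$max_vaf, piece_max)
})

test_that("testis maps render as a bubble grid", {
  set.seed(2)
  map <- make_count_map(rpois(192, 1))
  pdf(NULL)
  on.exit(dev.off())
  out <- plot(map)
  expect_identical(nrow(out), 192L)
  out2 <- plot(map, level = "pool")
  expect_identical(nrow(out2), 48L)
})
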