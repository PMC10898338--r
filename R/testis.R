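# Dissected-testis workflow: the 6-slice x 32-piece map, pooling of adjacent
# pieces, hot-pool drill-down and clustering summary statistics.

#' Default pooling layout: 2 x 2 blocks within each slice
#'
#' Each of the 6 slices is a 4-strip x 8-row grid of 32 pieces.  Pools merge
#' 4 spatially adjacent pieces; the default layout tiles every slice with
#' 2-strip x 2-row blocks in row-major order, giving 8 pools per slice and 48
#' pools per testis.
#'
#' @param n_slices,n_strips,n_rows grid dimensions (defaults 6, 4, 8).
#' @return data frame with columns `pool_id, slice, strip, row` (one row per
#'   piece, 4 rows per pool).
#' @export
default_pooling <- function(n_slices = 6, n_strips = 4, n_rows = 8) {
  if (n_strips %% 2 != 0 || n_rows %% 2 != 0)
    stop("strips and rows must be even for 2x2 pooling")
  grid <- expand.grid(row = seq_len(n_rows), strip = seq_len(n_strips),
                      slice = seq_len(n_slices))
  block_strip <- (grid$strip - 1) %/% 2
  block_row <- (grid$row - 1) %/% 2
  pools_per_slice <- (n_strips %/% 2) * (n_rows %/% 2)
  grid$pool_id <- (grid$slice - 1) * pools_per_slice +
    block_row * (n_strips %/% 2) + block_strip + 1
  grid[, c("pool_id", "slice", "strip", "row")]
}

#' Build a testis map from per-piece measurements
#'
#' @param pieces data frame with columns `slice` (1-6), `strip` (1-4), `row`
#'   (1-8) and either molecule counts (`mutant_positive`, `wildtype_positive`)
#'   or a `vaf` column (or both).  Missing pieces are allowed (absent rows or
#'   `NA` values).
#' @param pooling pooling table as from [default_pooling()]; every piece must
#'   belong to exactly one pool of 4 members.
#' @return object of class `"testis_map"`: list with `pieces` (with `pool_id`
#'   attached), `pooling`, and the grid dimensions.
#' @export
testis_map <- function(pieces, pooling = default_pooling()) {
  req <- c("slice", "strip", "row")
  miss <- setdiff(req, names(pieces))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  has_counts <- all(c("mutant_positive", "wildtype_positive") %in% names(pieces))
  if (!has_counts && !"vaf" %in% names(pieces))
    stop("pieces need either count columns or a vaf column")
  key_p <- paste(pieces$slice, pieces$strip, pieces$row)
  if (anyDuplicated(key_p)) stop("duplicate piece coordinates")
  key_pool <- paste(pooling$slice, pooling$strip, pooling$row)
  idx <- match(key_p, key_pool)
  if (anyNA(idx)) stop("piece coordinates outside the pooling grid")
  pieces$pool_id <- pooling$pool_id[idx]
  if (has_counts && !"vaf" %in% names(pieces)) {
    tot <- pieces$mutant_positive + pieces$wildtype_positive
    pieces$vaf <- ifelse(!is.na(tot) & tot > 0,
                         -log1p(-pieces$mutant_positive / tot), NA_real_)
  }
  sizes <- table(pooling$pool_id)
  if (any(sizes != 4)) stop("every pool must have exactly 4 member pieces")
  structure(list(pieces = pieces, pooling = pooling,
                 n_slices = max(pooling$slice),
                 n_pools = length(sizes),
                 has_counts = has_counts),
            class = "testis_map")
}

#' @export
print.testis_map <- function(x, ...) {
  cat(sprintf("testis map: %d pieces measured (grid %d slices x 32), %d pools\n",
              sum(!is.na(x$pieces$vaf)), x$n_slices, x$n_pools))
  invisible(x)
}

#' Pool piece-level measurements into 4-piece pool VAFs
#'
#' When molecule counts are available the pool VAF is computed from the summed
#' mutant and total molecule counts of the members (count mode, conserving
#' molecules exactly); otherwise it is the mean of the member VAFs (mean
#' mode).  Pools whose members are all missing get `NA`.
#'
#' @param map a [testis_map()].
#' @param mode `"counts"` (default when counts exist) or `"mean"`.
#' @return data frame with one row per pool: `pool_id`, `slice`, `vaf`,
#'   `n_members`, and summed counts in count mode.
#' @export
pool_pieces <- function(map, mode = if (map$has_counts) "counts" else "mean") {
  mode <- match.arg(mode, c("counts", "mean"))
  if (mode == "counts" && !map$has_counts)
    stop("count mode requires mutant/wildtype counts")
  pc <- map$pieces
  rows <- lapply(split(pc, pc$pool_id), function(d) {
    if (mode == "counts") {
      ok <- !is.na(d$mutant_positive) & !is.na(d$wildtype_positive)
      m <- sum(d$mutant_positive[ok]); w <- sum(d$wildtype_positive[ok])
      vaf <- if (sum(ok) == 0 || m + w == 0) NA_real_ else -log1p(-m / (m + w))
      data.frame(pool_id = d$pool_id[1], slice = d$slice[1], vaf = vaf,
                 n_members = sum(ok), mutant_positive = m, wildtype_positive = w)
    } else {
      ok <- !is.na(d$vaf)
      data.frame(pool_id = d$pool_id[1], slice = d$slice[1],
                 vaf = if (any(ok)) mean(d$vaf[ok]) else NA_real_,
                 n_members = sum(ok))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pool_id), ]
}

#' Flag hot pools for fine-scale (per-piece) analysis
#'
#' Pools whose VAF exceeds the drill-down threshold (default 5e-5) are flagged
#' for measurement of their 4 individual member pieces; where piece data
#' already exist they are attached.
#'
#' @param map a [testis_map()].
#' @param threshold pool VAF above which a pool is drilled into (default 5e-5).
#' @param pools optional precomputed [pool_pieces()] output.
#' @return list with `flagged` (pool-level rows above threshold) and `members`
#'   (piece rows of the flagged pools, where measured).
#' @export
hot_pool_drilldown <- function(map, threshold = 5e-5, pools = NULL) {
  if (is.null(pools)) pools <- pool_pieces(map)
  hot <- pools[!is.na(pools$vaf) & pools$vaf > threshold, , drop = FALSE]
  members <- map$pieces[map$pieces$pool_id %in% hot$pool_id, , drop = FALSE]
  list(flagged = hot, members = members, threshold = threshold)
}

#' Consistency of a coarse pool measurement with its fine-scale members
#'
#' The coarse (pooled) VAF is consistent with the fine analysis when it falls
#' within one standard deviation of the member mean.
#'
#' @param pool_vaf the pooled measurement.
#' @param member_vafs VAFs of exactly the pool's member pieces.
#' @return list with `pass` (`NA` when fewer than 2 members have values, so
#'   the SD is undefined), `deviation` (pool - member mean), `member_mean`,
#'   `member_sd`.
#' @export
coarse_fine_consistency <- function(pool_vaf, member_vafs) {
  v <- member_vafs[!is.na(member_vafs)]
  if (length(v) < 2) {
    return(list(pass = NA, deviation = NA_real_,
                member_mean = if (length(v)) mean(v) else NA_real_,
                member_sd = NA_real_))
  }
  m <- mean(v); s <- sd(v)
  dev <- pool_vaf - m
  list(pass = abs(dev) <= s, deviation = dev, member_mean = m, member_sd = s)
}

#' Clustering summary statistics for a set of testis units
#'
#' Median, IQR (type-7 quartiles, linearly interpolated order statistics),
#' mean, sample SD, maximum, and the Max/IQR clustering statistic: the ratio
#' of the maximum unit frequency to the interquartile range.  Under spatial
#' uniformity Max/IQR is near 1; subclonal expansions inflate the maximum
#' while leaving the IQR at background, producing large ratios.
#'
#' @param vafs vector of unit VAFs (pieces or pools); `NA`s are excluded with
#'   `n_units` reporting the effective count.
#' @return one-row data frame of class `"cluster_summary"`; `max_over_iqr` is
#'   `NA` (not defined) when the IQR is 0.
#' @export
cluster_summary <- function(vafs) {
  v <- vafs[!is.na(vafs)]
  if (length(v) < 2) stop("need >= 2 units with values")
  if (any(v < 0)) stop("frequencies must be >= 0")
  iqr <- unname(diff(quantile(v, c(0.25, 0.75), type = 7)))
  mx <- max(v)
  out <- data.frame(n_units = length(v),
                    median_vaf = median(v), iqr = iqr,
                    mean_vaf = mean(v), sd = sd(v),
                    max_vaf = mx,
                    max_over_iqr = if (iqr > 0) mx / iqr else NA_real_,
                    ratio_defined = iqr > 0)
  class(out) <- c("cluster_summary", class(out))
  out
}

#' Table-style summary of one testis
#'
#' Median/IQR/mean/SD are computed over the 48 pools (the uniformly measured
#' unit); the maximum is taken over the finest available unit — measured
#' individual pieces from drilled-down hot pools where they exist, else pools
#' — mirroring the mixed "Max piece" reporting of dissection studies.
#'
#' @param map a [testis_map()].
#' @param threshold drill-down threshold passed to [hot_pool_drilldown()].
#' @return one-row data frame: the pool-level [cluster_summary()] columns with
#'   `max_vaf`/`max_over_iqr` replaced by the finest-unit maximum.
#' @export
testis_summary <- function(map, threshold = 5e-5) {
  pools <- pool_pieces(map)
  cs <- cluster_summary(pools$vaf)
  drill <- hot_pool_drilldown(map, threshold, pools = pools)
  fine <- drill$members$vaf[!is.na(drill$members$vaf)]
  mx <- max(c(cs$max_vaf, fine))
  cs$max_vaf <- mx
  cs$max_over_iqr <- if (cs$iqr > 0) mx / cs$iqr else NA_real_
  cs
}

#' Read a per-unit testis measurement table
#'
#' Expected columns: `testis_id, slice, strip, row, unit_type` (piece|pool),
#' `mutant_positive, wildtype_positive` and/or `vaf`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_testis_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("testis_id", "slice", "strip", "row", "unit_type")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!any(c("vaf", "mutant_positive") %in% names(df)))
    stop("need vaf or molecule count columns")
  df
}

#' Bubble-grid plot of a testis map
#'
#' Renders the 6 slices side by side as 4 x 8 grids with circle area
#' proportional to the piece (or pool) VAF; empty cells are unmeasured or
#' mutation-free units.
#'
#' @param x a [testis_map()].
#' @param level `"piece"` or `"pool"`.
#' @param main plot title.
#' @param ... ignored.
#' @return invisibly, the plotted data frame.
#' @export
plot.testis_map <- function(x, level = c("piece", "pool"), main = "testis map", ...) {
  level <- match.arg(level)
  if (level == "piece") {
    d <- x$pieces
    xc <- (d$slice - 1) * 5 + d$strip
    yc <- d$row
    v <- d$vaf
  } else {
    pools <- pool_pieces(x)
    memb <- x$pooling[match(pools$pool_id, x$pooling$pool_id), ]
    xc <- (memb$slice - 1) * 5 + memb$strip + 0.5
    yc <- memb$row + 0.5
    v <- pools$vaf
  }
  plot(NA, xlim = c(0, max(xc) + 1), ylim = c(0, 9), axes = FALSE,
       xlab = "slice / strip", ylab = "row", main = main, asp = 1)
  ns <- x$n_slices
  for (s in seq_len(ns))
    rect((s - 1) * 5 + 0.5, 0.5, (s - 1) * 5 + 4.5, 8.5, border = "grey70")
  ok <- !is.na(v) & v > 0
  if (any(ok)) {
    r <- 0.45 * sqrt(v[ok] / max(v[ok]))
    symbols(xc[ok], yc[ok], circles = r, inches = FALSE, add = TRUE,
            bg = adjustcolor("firebrick", 0.6), fg = "firebrick")
  }
  text((seq_len(ns) - 1) * 5 + 2.5, rep(8.9, ns), paste("slice", seq_len(ns)),
       cex = 0.7)
  invisible(data.frame(x = xc, y = yc, vaf = v))
}
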