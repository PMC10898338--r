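# Independent oracles used to freeze expected values.  These deliberately
# take different computational routes from the package code.

# -ln(1 - x) by direct series expansion sum x^k / k (x in [0, 1))
series_neg_log1m <- function(x, tol = 1e-18) {
  total <- 0
  term <- x
  k <- 1
  while (abs(term / k) > tol * max(total, .Machine$double.xmin)) {
    total <- total + term / k
    k <- k + 1
    term <- term * x
    if (k > 10000) break
  }
  total
}

# two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities <= that of the
# observed table (with the same relative tolerance fisher.test uses)
enum_fisher <- function(mut_a, total_a, mut_b, total_b) {
  m <- mut_a + mut_b
  lo <- max(0, m - total_b)
  hi <- min(m, total_a)
  probs <- vapply(lo:hi, function(k) {
    exp(lchoose(total_a, k) + lchoose(total_b, m - k) -
          lchoose(total_a + total_b, m))
  }, numeric(1))
  p_obs <- probs[mut_a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact permutation null of the Spearman rank correlation (no ties, small n):
# rho via the sum of squared rank differences, p as the share of permutations
# at least as extreme in |rho|
perm_spearman <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_from_s <- function(s) 1 - 6 * s / (n * (n^2 - 1))
  rho_obs <- rho_from_s(sum((rx - ry)^2))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  rhos <- vapply(perms(seq_len(n)),
                 function(ix) rho_from_s(sum((rx - ry[ix])^2)), numeric(1))
  list(rho = rho_obs, p = mean(abs(rhos) >= abs(rho_obs) - 1e-12))
}

# textbook BH step-up: adjusted p = cummin over decreasing p of p * n / rank
bh_manual <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * n / seq(n, 1)))
  adj[order(o)]
}

# cell-by-cell forward simulation of one testis: every mutant stem cell is an
# explicit entry updated with its own Bernoulli draw; new mutations are
# per-daughter Bernoulli (Binomial over the pool's daughters); clones occupy
# contiguous arcs at uniform positions, overlap computed by interval
# intersection.  Returns c(avg, max) or NULL when the mutant lineages exceed
# the pool (saturated regime, excluded from comparisons).
cellwise_sim <- function(G, T_cycles, mu, p_sym, n_pieces, ploidy) {
  pool <- 2^G
  clone_pos <- numeric(0)
  cells <- integer(0)            # clone id per mutant cell
  next_id <- 0L
  layer_cells <- 1L              # wild-type ancestors, doubling per layer
  for (g in seq_len(G)) {
    cells <- rep(cells, each = 2L)
    n_daughters <- 2L * layer_cells
    m <- rbinom(1, n_daughters, mu)
    if (m > 0) {
      ids <- next_id + seq_len(m)
      clone_pos[ids] <- runif(m)
      cells <- c(cells, ids)     # new single mutant daughters
      next_id <- next_id + m
    }
    layer_cells <- n_daughters
  }
  for (t in seq_len(T_cycles)) {
    if (length(cells)) {
      keep <- runif(length(cells)) < p_sym
      cells <- rep(cells[keep], each = 2L)
      if (length(cells) > pool) return(NULL)
    }
    m <- rbinom(1, pool, mu)
    if (m > 0) {
      ids <- next_id + seq_len(m)
      clone_pos[ids] <- runif(m)
      cells <- c(cells, ids)
      next_id <- next_id + m
    }
  }
  piece <- numeric(n_pieces)
  if (length(cells)) {
    tab <- table(cells)
    bounds <- seq(0, 1, length.out = n_pieces + 1)
    for (k in seq_along(tab)) {
      id <- as.integer(names(tab)[k])
      len <- as.integer(tab[[k]]) / pool
      a <- clone_pos[id]
      segs <- if (a + len <= 1) list(c(a, a + len))
              else list(c(a, 1), c(0, a + len - 1))
      for (s in segs) {
        ov <- pmax(0, pmin(s[2], bounds[-1]) - pmax(s[1], bounds[-(n_pieces + 1)]))
        piece <- piece + ov
      }
    }
  }
  c(avg = ploidy * length(cells) / pool,
    max = ploidy * max(piece) * n_pieces)
}
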