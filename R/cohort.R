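# Cohort analysis of per-donor sperm VAFs: age association, multiplicity
# adjustment, age-group contrasts and summary-table statistics.

#' Spearman correlation between donor age and VAF
#'
#' Rank correlation with mid-rank tie handling.  Donors with VAF 0 are
#' included as true zeros (negative samples are informative).  For small
#' cohorts (n <= 7) without ties the two-sided p-value is computed from the
#' exact permutation null of the rank correlation; otherwise [stats::cor.test()]
#' is used (exact where it can be, asymptotic with ties).
#'
#' @param records data frame with columns `age` and `vaf` (one row per donor).
#' @return list with `rho`, `p_value`, `n`, `method`, and `degenerate`
#'   (`TRUE` when either axis is constant, in which case `rho` and `p_value`
#'   are `NA` rather than an error).
#' @export
spearman_age <- function(records) {
  age <- records$age
  vaf <- records$vaf
  n <- length(age)
  if (n < 3) stop("need at least 3 donors")
  if (length(unique(age)) < 2 || length(unique(vaf)) < 2) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "degenerate", degenerate = TRUE))
  }
  ties <- anyDuplicated(age) > 0 || anyDuplicated(vaf) > 0
  if (n <= 7 && !ties) {
    rho_obs <- cor(rank(age), rank(vaf), method = "pearson")
    perms <- .permutations(n)
    ra <- rank(age)
    rv <- rank(vaf)
    rhos <- apply(perms, 1, function(ix) cor(ra, rv[ix], method = "pearson"))
    p <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
    return(list(rho = rho_obs, p_value = p, n = n,
                method = "exact permutation", degenerate = FALSE))
  }
  ct <- suppressWarnings(cor.test(age, vaf, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       method = if (ties) "asymptotic (ties)" else "cor.test",
       degenerate = FALSE)
}

# all permutations of 1:n as a matrix (n! rows); n is small (<= 7)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment across the family of variants analysed in one
#' run; thin wrapper over [stats::p.adjust()] with input validation so the
#' family is always explicit.
#'
#' @param p_values vector of unadjusted p-values in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Assign donors to the age groups used for categorical contrasts
#'
#' Younger (<= 30), middle (31-44) and older (>= 45) years.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `younger`, `middle`, `older`.
#' @export
age_group <- function(age) {
  cut(age, breaks = c(-Inf, 30, 44, Inf),
      labels = c("younger", "middle", "older"))
}

#' Omnibus and pairwise comparison of VAFs across donor age groups
#'
#' An initial Kruskal-Wallis test across the non-empty age groups; pairwise
#' two-sided Mann-Whitney U tests are run only when the omnibus p-value falls
#' below `threshold`.  Pairwise contrasts involving a group with fewer than 2
#' members are skipped with a warning.
#'
#' @param records data frame with columns `age` and `vaf`.
#' @param threshold omnibus significance threshold gating the pairwise tests
#'   (default 0.05).
#' @return list with `omnibus` (statistic, df, p_value), `pairwise` (data
#'   frame of contrasts, or `NULL` when not run), and `group_sizes`.
#' @export
age_group_compare <- function(records, threshold = 0.05) {
  grp <- droplevels(age_group(records$age))
  sizes <- table(grp)
  if (length(sizes) < 2) stop("need >= 2 non-empty age groups")
  kw <- kruskal.test(records$vaf, grp)
  out <- list(omnibus = list(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p_value = kw$p.value),
              pairwise = NULL,
              group_sizes = sizes)
  if (is.finite(kw$p.value) && kw$p.value < threshold) {
    combs <- utils::combn(names(sizes), 2)
    rows <- lapply(seq_len(ncol(combs)), function(i) {
      g1 <- combs[1, i]; g2 <- combs[2, i]
      if (sizes[[g1]] < 2 || sizes[[g2]] < 2) {
        warning(sprintf("skipping contrast %s vs %s: group with < 2 members",
                        g1, g2))
        return(NULL)
      }
      wt <- suppressWarnings(
        wilcox.test(records$vaf[grp == g1], records$vaf[grp == g2]))
      data.frame(group1 = g1, group2 = g2,
                 U = unname(wt$statistic), p_value = wt$p.value,
                 stringsAsFactors = FALSE)
    })
    out$pairwise <- do.call(rbind, rows)
  }
  out
}

#' Summary-table statistics for one variant's donor cohort
#'
#' Mean, median, interquartile range (type-7 quartiles), maximum, the
#' Max VAF/IQR clustering ratio, and the share of donors with a positive VAF.
#' The ratio is reported raw (`max_over_iqr`) and rounded for display to two
#' significant digits (`max_over_iqr_display`), matching the mixed precision
#' of published summary tables.  When the IQR is 0 and the maximum positive,
#' the ratio is not defined and reported as `NA` with `ratio_defined = FALSE`.
#'
#' @param records data frame with columns `vaf` and optionally `variant_id`.
#' @return one-row data frame of class `"variant_summary"`.
#' @export
summarize_variant <- function(records) {
  v <- records$vaf
  if (length(v) < 1) stop("need >= 1 donor")
  if (any(v < 0)) stop("vaf must be >= 0")
  iqr <- unname(diff(quantile(v, c(0.25, 0.75), type = 7)))
  mx <- max(v)
  ratio <- if (iqr > 0) mx / iqr else NA_real_
  out <- data.frame(
    variant_id = if (!is.null(records$variant_id)) as.character(records$variant_id[1]) else NA_character_,
    n_donors = length(v),
    mean_vaf = mean(v),
    median_vaf = median(v),
    iqr = iqr,
    max_vaf = mx,
    max_over_iqr = ratio,
    max_over_iqr_display = if (is.na(ratio)) NA_real_ else signif(ratio, 2),
    ratio_defined = !is.na(ratio),
    fraction_positive = mean(v > 0),
    stringsAsFactors = FALSE)
  class(out) <- c("variant_summary", class(out))
  out
}

#' Age association for every variant in a cohort table, with BH adjustment
#'
#' Runs [spearman_age()] per variant and adjusts the p-values across the
#' variant set (the FDR family is exactly the set of variants in `records`).
#'
#' @param records data frame with columns `variant_id`, `age`, `vaf`.
#' @return data frame with one row per variant: `variant_id`, `n`, `rho`,
#'   `p_value`, `fdr`.
#' @export
age_associations <- function(records) {
  parts <- split(records, records$variant_id)
  rows <- lapply(parts, function(d) {
    s <- spearman_age(d)
    data.frame(variant_id = as.character(d$variant_id[1]), n = s$n,
               rho = s$rho, p_value = s$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Read a per-donor cohort table
#'
#' Expected columns: `donor_id, age, variant_id, vaf`.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_donor_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("donor_id", "age", "variant_id", "vaf")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(df$age <= 0)) stop("age must be positive")
  if (any(df$vaf < 0)) stop("vaf must be >= 0")
  df
}
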