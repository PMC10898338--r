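# Matched-simulation parameter fitting and the Monte-Carlo maximum test.
#
# The free parameter (mutation rate in the hot-spot model, symmetric-division
# bias in the selection model) is estimated as the value that maximises the
# fraction of simulated average testis frequencies falling within
# match_tolerance (default 5%) of the observed average.  The p-value against
# clustering is then the fraction of matched simulations whose maximum piece
# frequency strictly exceeds the observed maximum.

# objective for one parameter value: common-random-numbers matched fraction
.matched_fraction <- function(config, theta, observed_avg, n_reps, eval_seed) {
  cfg <- config
  if (config$model == "hotspot") cfg$mutation_rate <- theta
  else cfg$sym_bias <- 0.5 + theta
  sims <- simulate_testis_reps(cfg, n_reps, seed = eval_seed)
  tol <- config$match_tolerance * observed_avg
  mean(!sims$saturated & abs(sims$avg_freq - observed_avg) <= tol)
}

#' Fit the free model parameter to an observed average testis frequency
#'
#' One-dimensional search over the free parameter: a 13-point log grid
#' spanning `grid_decades` decades either side of a moment-matching initial
#' guess (the parameter whose expected average frequency equals the observed
#' one, see [expected_avg_freq()]), followed by golden-section refinement
#' between the bracketing grid neighbours of the maximiser.  Every evaluation
#' reuses the same derived seed (common random numbers), making the matched
#' fraction a deterministic function of the parameter so the refinement is
#' well posed.  Grid points whose expected average frequency exceeds the
#' observed one by a large factor (3x hot-spot, 50x selection) are recorded as
#' pruned with matched fraction 0: at such parameters the simulated average is
#' a concentrated sum far above the window, so simulating them would waste the
#' budget without affecting the maximiser.
#'
#' @param config a [sim_config()].
#' @param observed_avg observed average testis frequency (VAF scale, > 0).
#' @param n_reps simulations per evaluated parameter value (default 2000).
#' @param grid_points,grid_decades coarse-grid size and half-width in decades
#'   (defaults 13 and 3).
#' @param refine_tol stop refinement when the log10 bracket is narrower than
#'   this (default 0.05).
#' @param seed master seed for the common-random-numbers evaluations
#'   (defaults to `config$rng_seed`).
#' @return list of class `"germ_fit_profile"`: `parameter` (fitted mutation
#'   rate or `sym_bias`), `matched_fraction` at the fit, `profile` (data frame
#'   of evaluated values), `n_sims`, `model`, `observed_avg`.
#' @export
fit_parameter <- function(config, observed_avg, n_reps = 2000,
                          grid_points = 13, grid_decades = 3,
                          refine_tol = 0.05, seed = config$rng_seed) {
  stopifnot(observed_avg > 0)
  if (is.null(seed)) seed <- 1L
  eval_seed <- as.integer(seed %% .Machine$integer.max)
  model <- config$model
  G <- config$growth_generations
  T_cycles <- n_adult_cycles(config)

  if (model == "hotspot") {
    theta0 <- (observed_avg / config$ploidy_factor) / (G + T_cycles)
    exp_avg <- function(th) expected_avg_freq(config, mutation_rate = th)
    prune_factor <- 3
    theta_max <- 1 / (2 * G)  # keep mu * G < 1
  } else {
    exp_avg <- function(th) expected_avg_freq(config, sym_bias = 0.5 + th)
    prune_factor <- 50
    theta_max <- 0.49
    # moment-matching guess: delta with expected average = observed
    f <- function(ld) exp_avg(10^ld) - observed_avg
    lo <- -8; hi <- log10(theta_max)
    theta0 <- if (f(lo) >= 0) 10^lo
      else if (f(hi) <= 0) 10^hi
      else 10^uniroot(f, c(lo, hi), tol = 1e-10)$root
  }

  lg0 <- log10(theta0)
  grid <- 10^seq(lg0 - grid_decades, lg0 + grid_decades, length.out = grid_points)
  grid <- pmin(grid, theta_max)
  grid <- sort(unique(grid))

  n_sims <- 0L
  evaluate <- function(theta) {
    if (exp_avg(theta) > prune_factor * observed_avg)
      return(c(matched = 0, pruned = 1))
    n_sims <<- n_sims + as.integer(n_reps)
    c(matched = .matched_fraction(config, theta, observed_avg, n_reps, eval_seed),
      pruned = 0)
  }

  ev <- t(vapply(grid, evaluate, c(matched = 0, pruned = 0)))
  profile <- data.frame(theta = grid, matched_fraction = ev[, "matched"],
                        pruned = ev[, "pruned"] > 0, stage = "grid",
                        stringsAsFactors = FALSE)

  if (all(profile$matched_fraction == 0)) {
    cond <- structure(class = c("spermosaic_fit_failure", "error", "condition"),
                      list(message = "fit failure: no parameter in the searched range matched the observed average",
                           call = sys.call(-1), profile = profile))
    stop(cond)
  }

  best_i <- which.max(profile$matched_fraction)
  lo <- log10(grid[max(1, best_i - 1)])
  hi <- log10(grid[min(length(grid), best_i + 1)])

  # golden-section refinement on the CRN (deterministic) objective
  gr <- (sqrt(5) - 1) / 2
  cache <- new.env(parent = emptyenv())
  f_log <- function(lg) {
    key <- sprintf("%.12f", lg)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- evaluate(10^lg)
    profile <<- rbind(profile,
                      data.frame(theta = 10^lg, matched_fraction = val["matched"],
                                 pruned = val["pruned"] > 0, stage = "refine",
                                 stringsAsFactors = FALSE))
    cache[[key]] <- unname(val["matched"])
    cache[[key]]
  }
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f_log(x1); f2 <- f_log(x2)
  iter <- 0
  while (b - a > refine_tol && iter < 40) {
    if (f1 >= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- f_log(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- f_log(x2) }
    iter <- iter + 1
  }
  rownames(profile) <- NULL
  best <- profile[which.max(profile$matched_fraction), ]
  theta_hat <- best$theta

  structure(list(model = model,
                 parameter = if (model == "hotspot")
                   c(mutation_rate = theta_hat) else c(sym_bias = 0.5 + theta_hat),
                 theta = theta_hat,
                 matched_fraction = best$matched_fraction,
                 profile = profile,
                 n_sims = n_sims,
                 n_reps = n_reps,
                 observed_avg = observed_avg,
                 seed = eval_seed),
            class = "germ_fit_profile")
}

#' Monte-Carlo maximum-statistic test at a fitted parameter
#'
#' Simulates the configured model at the fitted parameter until `n_matched`
#' simulations have an average frequency within the match tolerance of the
#' observed average, then reports the fraction of those whose maximum piece
#' frequency strictly exceeds the observed maximum (ties are not exceedances).
#' When no matched simulation exceeds the observed maximum the p-value is
#' reported as 0 with an add-one upper bound `1 / (n_matched + 1)`.
#'
#' @param config a [sim_config()].
#' @param parameter fitted free parameter (mutation rate or `sym_bias`).
#' @param observed_avg,observed_max observed average and maximum piece
#'   frequency (VAF scale).
#' @param n_matched matched simulations required (default
#'   `config$n_matched_target`).
#' @param batch_reps simulations per batch (default 5000).
#' @param max_sims simulation budget; exceeding it raises a budget error of
#'   class `"spermosaic_budget_error"` carrying the partial result (default
#'   `40 * n_matched`).
#' @param seed master seed (defaults to `config$rng_seed`); batch `i` uses
#'   `seed + i`.
#' @return list of class `"germ_mc_test"`: `p_value`, `p_upper` (add-one
#'   bound), `n_matched`, `n_exceed`, `matched_fraction`, `n_sims`,
#'   `matched_max` (maxima of the matched simulations).
#' @export
mc_test <- function(config, parameter, observed_avg, observed_max,
                    n_matched = config$n_matched_target, batch_reps = 5000,
                    max_sims = 40 * n_matched, seed = config$rng_seed) {
  stopifnot(observed_avg > 0, observed_max >= 0)
  if (is.null(seed)) seed <- 1L
  cfg <- config
  if (config$model == "hotspot") cfg$mutation_rate <- unname(parameter)
  else cfg$sym_bias <- unname(parameter)
  tol <- config$match_tolerance * observed_avg
  matched_max <- numeric(0)
  total <- 0L
  batch_i <- 0L
  while (length(matched_max) < n_matched) {
    if (total >= max_sims) {
      partial <- list(p_value = mean(matched_max > observed_max),
                      n_matched = length(matched_max), n_sims = total)
      cond <- structure(class = c("spermosaic_budget_error", "error", "condition"),
                        list(message = sprintf(
                          "simulation budget exceeded: %d matched of %d required after %d simulations",
                          length(matched_max), n_matched, total),
                          call = sys.call(-1), partial = partial))
      stop(cond)
    }
    batch_i <- batch_i + 1L
    bseed <- as.integer((seed + batch_i) %% .Machine$integer.max)
    sims <- simulate_testis_reps(cfg, batch_reps, seed = bseed)
    ok <- !sims$saturated & abs(sims$avg_freq - observed_avg) <= tol
    matched_max <- c(matched_max, sims$max_piece_freq[ok])
    total <- total + as.integer(batch_reps)
  }
  matched_max <- matched_max[seq_len(n_matched)]
  n_exceed <- sum(matched_max > observed_max)
  structure(list(p_value = n_exceed / n_matched,
                 p_upper = (n_exceed + 1) / (n_matched + 1),
                 n_matched = n_matched,
                 n_exceed = n_exceed,
                 matched_fraction = n_matched / total,
                 n_sims = total,
                 matched_max = matched_max,
                 observed_max = observed_max),
            class = "germ_mc_test")
}

#' Fit a spermatogonial clone model to observed testis frequencies
#'
#' The central fitting interface: estimates the free parameter of the chosen
#' stem-cell model from the observed average testis mutation frequency
#' ([fit_parameter()]) and, when an observed maximum piece frequency is
#' supplied, runs the Monte-Carlo maximum-statistic test ([mc_test()]) for
#' subclonal clustering beyond what the model explains.
#'
#' @param observed_avg observed average testis frequency (VAF scale).
#' @param observed_max observed maximum piece/pool frequency; `NULL` skips the
#'   Monte-Carlo test.
#' @param donor_age donor age in years.
#' @param model `"hotspot"` or `"selection"`.
#' @param n_pieces simulated partition size (default 48).
#' @param config optional [sim_config()] overriding the defaults.
#' @param fit_reps simulations per parameter evaluation during fitting.
#' @param n_matched matched simulations for the Monte-Carlo test.
#' @param seed master seed.
#' @param ... further arguments to [sim_config()].
#' @return object of class `"germ_fit"` with `print`, `summary`, `coef`,
#'   `simulate` and `plot` methods.
#' @examples
#' \donttest{
#' fit <- germ_fit(3.5e-5, observed_max = 4.1e-4, donor_age = 68,
#'                 model = "selection", fit_reps = 200, n_matched = 200,
#'                 seed = 1)
#' coef(fit)
#' }
#' @export
germ_fit <- function(observed_avg, observed_max = NULL, donor_age,
                     model = c("hotspot", "selection"), n_pieces = 48,
                     config = NULL, fit_reps = 2000,
                     n_matched = 10000, seed = NULL, ...) {
  model <- match.arg(model)
  if (is.null(config))
    config <- sim_config(model = model, donor_age_years = donor_age,
                         n_pieces = n_pieces, rng_seed = seed, ...)
  if (!is.null(seed)) config$rng_seed <- seed
  fit <- fit_parameter(config, observed_avg, n_reps = fit_reps)
  mc <- NULL
  if (!is.null(observed_max)) {
    par_val <- if (model == "hotspot") fit$parameter[["mutation_rate"]]
      else fit$parameter[["sym_bias"]]
    mc <- mc_test(config, par_val, observed_avg, observed_max,
                  n_matched = n_matched)
  }
  structure(list(model = model,
                 coefficients = fit$parameter,
                 fit = fit,
                 mc = mc,
                 observed = list(avg = observed_avg, max = observed_max),
                 config = config,
                 n_sims = fit$n_sims + if (is.null(mc)) 0L else mc$n_sims),
            class = "germ_fit")
}

#' @export
coef.germ_fit <- function(object, ...) object$coefficients

#' @export
print.germ_fit <- function(x, ...) {
  cat(sprintf("Spermatogonial %s model fit\n", x$model))
  cat(sprintf("  observed average testis frequency: %.3g\n", x$observed$avg))
  cat(sprintf("  fitted %s = %.6g (matched fraction %.3f)\n",
              names(x$coefficients), x$coefficients,
              x$fit$matched_fraction))
  if (!is.null(x$mc)) {
    p <- x$mc$p_value
    cat(sprintf("  observed maximum piece frequency: %.3g\n", x$observed$max))
    if (x$mc$n_exceed == 0)
      cat(sprintf("  Monte-Carlo p-value < %.2g (0 of %d matched simulations exceed)\n",
                  1 / x$mc$n_matched, x$mc$n_matched))
    else
      cat(sprintf("  Monte-Carlo p-value = %.3g (%d of %d matched simulations exceed)\n",
                  p, x$mc$n_exceed, x$mc$n_matched))
  }
  invisible(x)
}

#' @export
summary.germ_fit <- function(object, ...) {
  out <- list(model = object$model,
              coefficients = object$coefficients,
              matched_fraction = object$fit$matched_fraction,
              profile = object$fit$profile,
              observed = object$observed,
              p_value = if (!is.null(object$mc)) object$mc$p_value else NA_real_,
              p_upper = if (!is.null(object$mc)) object$mc$p_upper else NA_real_,
              n_matched = if (!is.null(object$mc)) object$mc$n_matched else 0L,
              n_sims = object$n_sims,
              adult_cycles = n_adult_cycles(object$config))
  class(out) <- "summary.germ_fit"
  out
}

#' @export
print.summary.germ_fit <- function(x, ...) {
  cat(sprintf("Spermatogonial %s model (%d adult cycles)\n", x$model, x$adult_cycles))
  cat(sprintf("  fitted %s = %.6g\n", names(x$coefficients), x$coefficients))
  cat(sprintf("  matched fraction at fit: %.3f; total simulations: %d\n",
              x$matched_fraction, x$n_sims))
  if (x$n_matched > 0)
    cat(sprintf("  Monte-Carlo p-value: %.3g (upper bound %.3g, %d matched sims)\n",
                x$p_value, x$p_upper, x$n_matched))
  invisible(x)
}

#' Simulate from a fitted clone model
#'
#' @param object a [germ_fit()] object.
#' @param nsim number of replicates.
#' @param seed optional seed.
#' @param ... ignored.
#' @return data frame of simulated `avg_freq` / `max_piece_freq`.
#' @export
simulate.germ_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- object$config
  if (object$model == "hotspot")
    cfg$mutation_rate <- object$coefficients[["mutation_rate"]]
  else cfg$sym_bias <- object$coefficients[["sym_bias"]]
  simulate_testis_reps(cfg, nsim, seed = seed)
}

#' Plot a fitted clone model
#'
#' Left: matched-fraction profile over the searched parameter range (log
#' axis).  Right (when the Monte-Carlo test was run): histogram of the
#' maximum piece frequencies of the matched simulations with the observed
#' maximum marked.
#'
#' @param x a [germ_fit()] object.
#' @param ... ignored.
#' @export
plot.germ_fit <- function(x, ...) {
  prof <- x$fit$profile[!x$fit$profile$pruned, ]
  two <- !is.null(x$mc)
  if (two) { op <- par(mfrow = c(1, 2)); on.exit(par(op)) }
  plot(prof$theta, prof$matched_fraction, log = "x",
       xlab = if (x$model == "hotspot") "mutation rate per division"
              else "selection bias (sym_bias - 1/2)",
       ylab = "matched fraction", main = "parameter profile",
       pch = ifelse(prof$stage == "grid", 1, 19))
  abline(v = x$fit$theta, lty = 2)
  if (two) {
    hist(x$mc$matched_max, breaks = 40, main = "matched simulations",
         xlab = "simulated maximum piece frequency")
    abline(v = x$mc$observed_max, col = "firebrick", lwd = 2)
  }
  invisible(x)
}
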