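# Stem-cell simulator: growth phase, adult branching dynamics, rendering,
# and the batched engine.

toy_cfg <- function(model = "hotspot", G = 8L, cycles = 10, mu = 1e-3,
                    sym_bias = if (model == "hotspot") 0.5 else 0.52,
                    n_pieces = 4L) {
  sim_config(model, donor_age_years = 13 + cycles * 16 / 365.25 + 1e-3,
             growth_generations = G, n_pieces = n_pieces,
             mutation_rate = mu, sym_bias = sym_bias)
}

test_that("configurations are validated", {
  expect_error(sim_config("hotspot", donor_age_years = 40, sym_bias = 0.51),
               "hot-spot")
  expect_error(sim_config("selection", donor_age_years = 10), "puberty")
  expect_error(sim_config("selection", donor_age_years = 40, sym_bias = 0.4),
               "sym_bias")
  expect_error(sim_config("hotspot", donor_age_years = 40,
                          mutation_rate = 0.1), "parameter regime")
  # selection default mutation rate: genome average over the growth phase
  cfg <- sim_config("selection", donor_age_years = 68)
  expect_equal(cfg$mutation_rate, 1.1e-8 / 30)
  expect_identical(n_adult_cycles(cfg), 1255)
  expect_identical(n_adult_cycles(sim_config("selection", donor_age_years = 73)), 1369)
})

test_that("growth phase produces the expected mutational load", {
  cfg <- toy_cfg(mu = 0)
  expect_identical(nrow(simulate_growth_phase(cfg)), 0L)

  # G = 1 at mu = 0.5: one Poisson(1) layer of half-pool clones
  cfg1 <- toy_cfg(G = 1L, mu = 0.499)
  set.seed(4)
  reps <- replicate(3000, {
    cl <- simulate_growth_phase(cfg1)
    c(nrow(cl), if (nrow(cl)) cl$size[1] else NA)
  })
  expect_true(all(reps[2, ] %in% c(1, NA)))
  expect_equal(mean(reps[1, ]), 2 * 0.499, tolerance = 0.05)

  # each of the G division layers contributes mu to the mutant fraction
  cfgG <- toy_cfg(G = 10L, mu = 1e-3)
  set.seed(8)
  fr <- replicate(3000, sum(simulate_growth_phase(cfgG)$size) / 2^10)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 10 * 1e-3), 3 * se)
})

test_that("adult dynamics are a critical or supercritical branching process", {
  # martingale: at sym_bias 1/2 the expected clone mass is conserved
  cfg <- toy_cfg(mu = 0, G = 20L)
  clones <- data.frame(origin = 0, size = rep(16, 3000), position = runif(3000))
  set.seed(15)
  out <- simulate_adult_phase(clones, cfg, cycles = 20)
  mass0 <- sum(clones$size)
  se <- sd(c(out$size, rep(0, nrow(clones) - nrow(out)))) * sqrt(nrow(clones))
  expect_lt(abs(sum(out$size) - mass0), 3 * se)

  # supercritical: mean size (2 p)^T from single cells
  cfg2 <- toy_cfg(model = "selection", mu = 0, sym_bias = 0.5025, G = 20L)
  n <- 1e5
  clones <- data.frame(origin = 0, size = rep(1, n), position = runif(n))
  set.seed(16)
  out <- simulate_adult_phase(clones, cfg2, cycles = 100)
  finals <- c(out$size, rep(0, n - nrow(out)))
  target <- (2 * 0.5025)^100
  expect_lt(abs(mean(finals) - target), 3 * sd(finals) / sqrt(n))
})

test_that("a zero-bias selection model is the hot-spot model", {
  cfg_h <- toy_cfg("hotspot", mu = 5e-4)
  cfg_s <- cfg_h; cfg_s$model <- "selection"
  a <- simulate_testis_reps(cfg_h, 500, seed = 99)
  b <- simulate_testis_reps(cfg_s, 500, seed = 99)
  expect_identical(a, b)
})

test_that("rendering conserves mutant cells over the piece partition", {
  cfg <- toy_cfg(G = 10L)
  expect_identical(render_testis(data.frame(origin = integer(),
                                            size = numeric(),
                                            position = numeric()),
                                 cfg)$avg_freq, 0)
  # one clone exactly filling one arc
  clones <- data.frame(origin = 0, size = 2^10 / 4, position = 0.25)
  r <- render_testis(clones, cfg)
  expect_equal(r$piece_freqs, c(0, cfg$ploidy_factor, 0, 0))
  # conservation for arbitrary clone sets
  set.seed(12)
  for (i in 1:10) {
    k <- sample(1:20, 1)
    clones <- data.frame(origin = 0, size = sample(1:200, k, TRUE),
                         position = runif(k))
    r <- render_testis(clones, cfg)
    expect_equal(sum(r$piece_freqs) * (2^10 / 4) / cfg$ploidy_factor,
                 sum(clones$size), tolerance = 1e-9)
    expect_equal(r$avg_freq, cfg$ploidy_factor * sum(clones$size) / 2^10)
    expect_identical(r$max_piece_freq, max(r$piece_freqs))
  }
})

test_that("identical seeds reproduce simulations bit for bit", {
  cfg <- toy_cfg(mu = 2e-3)
  a <- simulate_testis_reps(cfg, 200, seed = 31)
  b <- simulate_testis_reps(cfg, 200, seed = 31)
  expect_identical(a, b)
  r1 <- simulate_testis(cfg, seed = 77)
  r2 <- simulate_testis(cfg, seed = 77)
  expect_identical(r1, r2)
})

test_that("the stepwise simulator flags unphysical parameter regimes", {
  cfg <- toy_cfg(G = 4L, mu = 0, cycles = 50, model = "selection",
                 sym_bias = 0.95)
  clones <- data.frame(origin = 0, size = 8, position = 0.1)
  set.seed(40)
  expect_error(simulate_adult_phase(clones, cfg, cycles = 50),
               "parameter regime")
})

test_that("parameter fitting recovers a known mutation rate", {
  # self-generated observed average at a known hot-spot rate
  cfg <- toy_cfg(G = 16L, cycles = 60, mu = NULL)
  mu_star <- 1e-4
  cfg_true <- cfg; cfg_true$mutation_rate <- mu_star
  obs <- mean(simulate_testis_reps(cfg_true, 3000, seed = 50)$avg_freq)
  cfg$rng_seed <- 51
  fit <- fit_parameter(cfg, obs, n_reps = 800)
  expect_lt(abs(fit$theta - mu_star) / mu_star, 0.2)
  expect_gt(fit$matched_fraction, 0)
  expect_true(all(fit$profile$matched_fraction[fit$profile$pruned] == 0))
})

test_that("fit failure raises a classed condition with diagnostics", {
  cfg <- toy_cfg(G = 6L, cycles = 5, mu = NULL)
  cfg$rng_seed <- 1
  # an observed average above the ploidy ceiling can never be matched
  expect_error(fit_parameter(cfg, 0.6, n_reps = 50, grid_decades = 1),
               class = "spermosaic_fit_failure")
})

test_that("the Monte-Carlo maximum test behaves as a one-sided exceedance test", {
  cfg <- toy_cfg(G = 8L, cycles = 10, mu = 5e-3)
  cfg$rng_seed <- 60
  obs_avg <- expected_avg_freq(cfg)
  # observed maximum 0: every matched simulation with any mutant exceeds it
  mc0 <- mc_test(cfg, 5e-3, obs_avg, 0, n_matched = 300, batch_reps = 2000)
  expect_equal(mc0$p_value, mean(mc0$matched_max > 0))
  expect_gt(mc0$p_value, 0.99)
  # monotone non-increasing in the observed maximum; 1 at 0 given mutants
  ps <- vapply(c(0, 1e-3, 1e-2, 0.2, 1),
               function(om) mean(mc0$matched_max > om), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps[5], 0)  # observed max above any simulation
  # budget exhaustion carries the partial result
  err <- tryCatch(
    mc_test(cfg, 5e-3, obs_avg * 50, 0, n_matched = 100, batch_reps = 100,
            max_sims = 200),
    spermosaic_budget_error = function(e) e)
  expect_s3_class(err, "spermosaic_budget_error")
  expect_true(err$partial$n_sims <= 300)
})

test_that("the fitted-model object exposes the standard methods", {
  fit <- germ_fit(observed_avg = 1e-2, observed_max = 5e-2, donor_age = 14,
                  model = "hotspot", n_pieces = 4,
                  config = toy_cfg(G = 8L, cycles = 10, mu = NULL),
                  fit_reps = 300, n_matched = 300, seed = 70)
  expect_s3_class(fit, "germ_fit")
  expect_named(coef(fit), "mutation_rate")
  expect_output(print(fit), "hotspot model fit")
  s <- summary(fit)
  expect_s3_class(s, "summary.germ_fit")
  expect_true(s$p_value >= 0 && s$p_value <= 1)
  sims <- simulate(fit, nsim = 50, seed = 3)
  expect_identical(nrow(sims), 50L)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
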