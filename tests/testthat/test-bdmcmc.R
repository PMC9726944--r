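test_that("birth-death likelihood matches hand computation and scaling identities", {
  lf <- data.frame(ts = 10, te = 4, extant = FALSE)
  rates <- list(window = c(12, 2), shifts = numeric(0), lambda = 0.2, mu = 0.1)
  expect_equal(bd_loglik(lf, rates), log(0.2) + log(0.1) - 0.3 * 6,
               tolerance = 1e-6)
  # doubling both rates: + n_orig log2 + n_ext log2 - extra integral
  r2 <- rates; r2$lambda <- 0.4; r2$mu <- 0.2
  expect_equal(bd_loglik(lf, r2) - bd_loglik(lf, rates),
               2 * log(2) - 0.3 * 6, tolerance = 1e-10)
  # extant lineages contribute no extinction term
  lf2 <- data.frame(ts = 10, te = 2, extant = TRUE)
  expect_equal(bd_loglik(lf2, rates), log(0.2) - 0.3 * 8, tolerance = 1e-10)
  # non-positive rate on an interval containing an event is a rejected state
  r3 <- list(window = c(12, 2), shifts = 6, lambda = c(0.2, 0), mu = c(0.1, 0.1))
  lf3 <- data.frame(ts = 5, te = 3, extant = FALSE)
  expect_identical(bd_loglik(lf3, r3), -Inf)
})

test_that("birth-death likelihood agrees with a brute-force D(t) oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    ts <- runif(n, 6, 12)
    te <- ts - runif(n, 0.5, 5)
    te <- pmax(te, 2.001)
    extant <- runif(n) < 0.2
    lf <- data.frame(ts = ts, te = te, extant = extant)
    k <- sample(1:3, 1)
    shifts <- sort(runif(k, 2.5, 11.5), decreasing = TRUE)
    rates <- list(window = c(12, 2), shifts = shifts,
                  lambda = runif(k + 1, 0.05, 0.5),
                  mu = runif(k + 1, 0.05, 0.5))
    # independent route: partition time by every edge and lifespan bound,
    # count D(t) at segment midpoints, and accumulate rate * D * width
    cuts <- sort(unique(c(12, 2, shifts, ts, te)), decreasing = TRUE)
    integral <- 0
    for (j in seq_len(length(cuts) - 1)) {
      mid <- (cuts[j] + cuts[j + 1]) / 2
      D <- sum(ts >= mid & te < mid)
      lam <- rates$lambda[sum(c(12, shifts) >= mid)]
      mu <- rates$mu[sum(c(12, shifts) >= mid)]
      integral <- integral + (lam + mu) * D * (cuts[j] - cuts[j + 1])
    }
    ev <- sum(log(rates$lambda[vapply(ts, function(t)
      sum(c(12, shifts) > t), 1L)])) +
      sum(log(rates$mu[vapply(te[!extant], function(t)
        sum(c(12, shifts) > t), 1L)]))
    expect_equal(bd_loglik(lf, rates), ev - integral, tolerance = 1e-9)
  }
})

test_that("chains are reproducible under a fixed seed and respect support", {
  sc <- simulate_scenario("constant", seed = 4)
  series <- true_age_series(sc$occurrences)
  win <- c(259.51, 208.5)
  cfg <- quick_cfg(win, seed = 9, n_gen = 5000L, thin = 50L)
  p1 <- suppressMessages(run_rjmcmc(series, preservation_model("hpp", 1), cfg))
  p2 <- suppressMessages(run_rjmcmc(series, preservation_model("hpp", 1), cfg))
  expect_identical(p1$lambda, p2$lambda)
  expect_identical(p1$loglik, p2$loglik)
  expect_identical(p1$lifespans$ts, p2$lifespans$ts)

  # posterior mean Ts never younger than the oldest occurrence
  oldest <- vapply(series$ages, max, 1)
  expect_true(all(colMeans(p1$lifespans$ts) >= oldest))
  newest <- vapply(series$ages, min, 1)
  ext <- !series$extant
  expect_true(all(colMeans(p1$lifespans$te[, ext, drop = FALSE]) <=
                    newest[ext]))
})

test_that("with the likelihood disabled the sampler reproduces its prior", {
  ser <- taxon_series(list(a = c(250, 240), b = c(245, 230)))
  win <- c(259.51, 208.5)
  cfg <- mcmc_config(n_generations = 150000, sampling_interval = 20,
                     window = win, edge_window = win, min_dt = 0.01,
                     seed = 4)
  p <- suppressWarnings(suppressMessages(
    run_rjmcmc(ser, preservation_model("hpp", 1), cfg, prior_only = TRUE)))
  lam <- p$lambda[, 1]
  # rates carry an Exp(1) prior
  expect_equal(mean(lam), 1, tolerance = 0.05)
  expect_equal(var(lam), 1, tolerance = 0.1)
  # shift counts carry a Poisson(1) prior
  expect_equal(mean(p$k_lambda), 1, tolerance = 0.1)
  expect_equal(mean(p$k_mu == 0), exp(-1), tolerance = 0.05)
})

test_that("sampled shift times respect the edge window and minimum separation", {
  sc <- simulate_scenario("pulse", seed = 3)
  series <- true_age_series(sc$occurrences)
  win <- c(283.5, 242)
  cfg <- quick_cfg(win, seed = 12, n_gen = 20000L, thin = 100L)
  p <- suppressMessages(run_rjmcmc(series, preservation_model("hpp", 1), cfg))
  sh <- rbind(p$shift_mu, p$shift_lambda)
  expect_true(all(sh$time <= cfg$edge_window[1] &
                    sh$time >= cfg$edge_window[2]))
  # pairwise min_dt within each sample and rate type
  by_samp <- split(p$shift_mu$time, p$shift_mu$sample)
  gaps <- unlist(lapply(by_samp, function(tt) {
    if (length(tt) < 2) return(numeric(0))
    abs(diff(sort(tt)))
  }))
  expect_true(all(gaps >= cfg$min_dt - 1e-9))
})

test_that("rate summaries reduce correctly and match a percentile oracle", {
  sc <- simulate_scenario("constant", seed = 4)
  series <- true_age_series(sc$occurrences)
  win <- c(259.51, 208.5)
  cfg <- quick_cfg(win, seed = 5, n_gen = 5000L, thin = 50L)
  p <- suppressMessages(run_bdcs(series, uniform_bins(win), cfg = cfg))
  s <- summarize_rates(p)
  expect_equal(s$net_mean, s$lambda_mean - s$mu_mean, tolerance = 1e-12)
  j <- 3L
  expect_equal(s$lambda_lo[j],
               unname(quantile(p$lambda[, j], 0.025)), tolerance = 1e-12)
  expect_equal(s$mu_hi[j],
               unname(quantile(p$mu[, j], 0.975)), tolerance = 1e-12)
  # single-draw degenerate summary
  p1 <- p
  p1$lambda <- p$lambda[1, , drop = FALSE]
  p1$mu <- p$mu[1, , drop = FALSE]
  s1 <- summarize_rates(p1)
  expect_equal(s1$lambda_lo, s1$lambda_hi)
  expect_equal(s1$lambda_mean, unname(p$lambda[1, ]))
})

test_that("shift Bayes factors follow the posterior/prior odds definition", {
  fake <- structure(list(
    shift_mu = data.frame(sample = 1:25, time = rep(250.5, 25)),
    shift_lambda = data.frame(sample = integer(0), time = numeric(0)),
    n_samples = 26L, edge_window = c(251, 250), nu = -log(0.8),
    min_dt = 2), class = "rate_posterior")
  # prior p = 1 - exp(-nu * w/W) = 0.2 (odds 1/4); posterior 25/26 (odds 25)
  bf <- shift_bayes_factor(fake, "mu", matrix(c(251, 250), nrow = 1))
  expect_equal(bf$log_bf, log(100), tolerance = 1e-10)

  # posterior frequency equal to prior frequency: log BF = 0
  fake2 <- fake
  fake2$n_samples <- 2L
  fake2$nu <- log(2)
  fake2$shift_mu <- data.frame(sample = 1L, time = 250.5)
  bf2 <- shift_bayes_factor(fake2, "mu", matrix(c(251, 250), nrow = 1))
  expect_equal(bf2$log_bf, 0, tolerance = 1e-10)

  # empty posterior frequency reported as a finite bound
  bf3 <- shift_bayes_factor(fake, "lambda", matrix(c(251, 250), nrow = 1))
  expect_true(is.finite(bf3$log_bf))
  expect_true(attr(bf3, "bounded"))
})

test_that("BDCS flags a rate change only when adjacent intervals separate", {
  sc <- simulate_scenario("pulse", seed = 6)
  series <- true_age_series(sc$occurrences)
  win <- c(283.5, 242)
  bins <- stage_bins(c(283.5, 273.01, 266.9, 259.51, 252, 247.2, 242))
  cfg <- quick_cfg(win, seed = 8, n_gen = 30000L, thin = 100L)
  p <- suppressMessages(run_bdcs(series, bins, cfg = cfg))
  sig <- bdcs_shift_significance(p, "mu")
  # the engineered five-fold extinction step at 252 separates the bins
  expect_true(sig$significant[sig$boundary > 249 & sig$boundary < 255])
})

test_that("stage-variable preservation and gamma heterogeneity are estimable", {
  win <- c(259.51, 208.5)
  bins <- uniform_bins(win, 6)
  sc <- simulate_scenario("constant", seed = 14)
  qb <- rep(c(0.5, 2), 3)
  pm_gen <- preservation_model("tpp", q_vector = qb, bins = bins)
  occ <- simulate_preservation(sc$lifespans, pm_gen, bins = bins, seed = 2)
  series <- true_age_series(occ)
  cfg <- quick_cfg(win, seed = 6, n_gen = 20000L, thin = 100L)
  p <- suppressMessages(run_bdcs(series, bins, pm_gen, cfg))
  qhat <- colMeans(p$q)
  # per-bin preservation recovers the engineered 4x contrast pattern
  expect_true(all(qhat[c(2, 4, 6)] > qhat[c(1, 3, 5)]))
  expect_equal(mean(qhat[c(2, 4, 6)]) / mean(qhat[c(1, 3, 5)]), 4,
               tolerance = 0.5)

  # gamma heterogeneity: heterogeneous record yields alpha well below the
  # near-homogeneous one
  pm_het <- preservation_model("hpp", q = 1, gamma = TRUE, alpha = 0.5)
  occ_het <- simulate_preservation(sc$lifespans, pm_het, bins = bins,
                                   seed = 3)
  ph <- suppressMessages(run_bdcs(true_age_series(occ_het), bins,
                                  pm_het, cfg))
  occ_hom <- simulate_preservation(sc$lifespans,
                                   preservation_model("hpp", q = 1),
                                   bins = bins, seed = 3)
  pm_fit <- preservation_model("hpp", q = 1, gamma = TRUE, alpha = 2)
  pg <- suppressMessages(run_bdcs(true_age_series(occ_hom), bins,
                                  pm_fit, cfg))
  expect_lt(mean(ph$alpha), mean(pg$alpha))
  expect_lt(mean(ph$alpha), 1.5)
})
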