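test_that("diversity-dependent rates follow the linear clamped form", {
  expect_equal(mcdd_rates(0.3, 0.1, 0, 0, 0.7), c(0.3, 0.1))
  expect_equal(mcdd_rates(0.3, 0.1, 0.5, 0, 0.4)[1], 0.24, tolerance = 1e-12)
  # positive interaction parameters raise extinction as diversity grows
  m_lo <- mcdd_rates(0.3, 0.1, 0, 0.0789, 0.2)[2]
  m_hi <- mcdd_rates(0.3, 0.1, 0, 0.0789, 0.9)[2]
  expect_gt(m_hi, m_lo)
  # clamping at zero
  expect_equal(mcdd_rates(0.3, 0.1, 3, 0, 0.5)[1], 0)
})

test_that("standing diversity matches a brute-force count on every grid point", {
  set.seed(31)
  lf <- data.frame(ts = runif(40, 250, 270), te = runif(40, 220, 245),
                   extant = FALSE)
  grid <- seq(269, 221, by = -0.5)
  tr <- diversity_trajectory(lf, grid)
  brute <- vapply(grid, function(t) {
    n <- 0L
    for (i in seq_len(nrow(lf))) {
      if (lf$ts[i] >= t && t > lf$te[i]) n <- n + 1L
    }
    n
  }, 1L)
  expect_equal(tr$mean, as.numeric(brute))
})

test_that("the full two-stage route runs from occurrence series to interactions", {
  sc <- simulate_scenario("mcdd", seed = 12)
  gl <- sc$guild_lifespans
  # fossilise both guilds and rebuild series (exact ages)
  series <- lapply(gl, function(lf) {
    occ <- simulate_preservation(lf, preservation_model("hpp", q = 1.5),
                                 bins = uniform_bins(c(270, 220), 10),
                                 seed = 1)
    true_age_series(occ)
  })
  cfg <- mcmc_config(n_generations = 6000L, sampling_interval = 30L,
                     seed = 7, window = c(270, 220),
                     edge_window = c(268, 222))
  p <- suppressMessages(
    run_mcdd(guild_series = series, window = c(270, 220), cfg = cfg))
  expect_s3_class(p, "mcdd_posterior")
  expect_equal(sort(p$guilds), sort(names(gl)))
  expect_equal(nrow(p$summary), length(gl)^2)
  expect_true(all(is.finite(p$summary$g_mu)))
})

test_that("positive interactions raise the realised per-lineage extinction rate", {
  # (total extinction *counts* can fall because the suppressed guild
  # shrinks; the per-lineage-time rate is the invariant quantity)
  base <- list(kind = "mcdd", guilds = c("g1", "g2"),
               lambda0 = c(0.3, 0.3), mu0 = c(0.15, 0.15),
               g_lambda = matrix(0, 2, 2), g_mu = matrix(0, 2, 2),
               norm = c(60, 60))
  comp <- base
  comp$g_mu[1, 2] <- 0.8
  death_rate <- function(rg, seeds) {
    vapply(seeds, function(s) {
      cfg <- simulation_config(c(260, 235), rg, n0 = 15L, min_taxa = 1L,
                               max_taxa = 5000L)
      g1 <- simulate_guild_system(cfg, seed = s)$g1
      sum(!g1$extant) / sum(g1$ts - g1$te)
    }, 1)
  }
  d0 <- death_rate(base, 1:25)
  d1 <- death_rate(comp, 101:125)
  expect_gt(mean(d1), mean(d0))
})

test_that("uncoupled guilds behave like independent clade simulations", {
  rg <- list(kind = "mcdd", guilds = c("g1", "g2"),
             lambda0 = c(0.25, 0.25), mu0 = c(0.12, 0.12),
             g_lambda = matrix(0, 2, 2), g_mu = matrix(0, 2, 2),
             norm = c(50, 50))
  cfg2 <- simulation_config(c(260, 240), rg, n0 = 10L, min_taxa = 1L,
                            max_taxa = 5000L)
  coupled <- vapply(1:20, function(s) {
    nrow(simulate_guild_system(cfg2, seed = s)$g1)
  }, 1)
  cfg1 <- simulation_config(
    c(260, 240), list(kind = "piecewise", shifts = numeric(0),
                      lambda = 0.25, mu = 0.12),
    n0 = 10L, min_taxa = 1L, max_taxa = 5000L)
  indep <- vapply(21:40, function(s) {
    nrow(simulate_clade(cfg1, seed = s))
  }, 1)
  expect_gt(wilcox.test(coupled, indep, exact = FALSE)$p.value, 0.01)
})

test_that("interaction networks emit only significant edges with sign semantics", {
  fake <- structure(list(summary = data.frame(
    from = c("a", "a", "b", "b"), to = c("a", "b", "a", "b"),
    g_lambda = c(0, 0.4, 0, 0), g_mu = c(0, 0, 0.3, -0.2),
    sig_lambda = c(FALSE, TRUE, FALSE, FALSE),
    sig_mu = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE), guilds = c("a", "b")),
    class = "mcdd_posterior")
  net <- interaction_network(fake)
  expect_equal(nrow(net), 3L)
  expect_lte(nrow(net), 2 * length(fake$guilds)^2)
  expect_equal(net$sign[net$from == "b" & net$rate_type == "mu" &
                          net$to == "a"], "negative")
  expect_equal(net$sign[net$from == "b" & net$to == "b"], "positive")
  fake$summary$sig_lambda <- FALSE
  fake$summary$sig_mu <- FALSE
  expect_equal(nrow(interaction_network(fake)), 0L)
})

test_that("with interactions frozen the per-guild baselines match independent fits", {
  sc <- simulate_scenario("mcdd", seed = 19)
  gl <- sc$guild_lifespans
  cfg <- mcmc_config(n_generations = 20000L, sampling_interval = 10L,
                     seed = 9)
  p <- run_mcdd(guild_lifespans = gl, window = c(270, 220), cfg = cfg,
                fix_g = TRUE)
  expect_true(all(p$draws[, grepl("^g", colnames(p$draws))] == 0))
  edges <- seq(270, 220, by = -1)
  for (i in seq_along(gl)) {
    cs <- fossildiv:::cell_stats(gl[[i]], edges)
    # conjugate constant-rate oracle under the Exp(0.1) baseline prior
    expect_equal(mean(p$draws[, paste0("lambda0_", i)]),
                 (sum(cs$B) + 1) / (sum(cs$L) + 0.1), tolerance = 0.05)
    expect_equal(mean(p$draws[, paste0("mu0_", i)]),
                 (sum(cs$E) + 1) / (sum(cs$L) + 0.1), tolerance = 0.05)
  }
})
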