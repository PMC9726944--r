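test_that("with zero extinction every simulated lineage survives the window", {
  cfg <- simulation_config(c(260, 245),
                           list(kind = "piecewise", shifts = numeric(0),
                                lambda = 0.15, mu = 1e-12),
                           n0 = 5L, min_taxa = 5L, max_taxa = 10000L)
  lf <- simulate_clade(cfg, seed = 1)
  expect_true(all(lf$extant))
  expect_true(all(lf$te == 245))
})

test_that("a critical birth-death process neither grows nor shrinks on average", {
  cfg <- simulation_config(c(260, 250),
                           list(kind = "piecewise", shifts = numeric(0),
                                lambda = 0.2, mu = 0.2),
                           n0 = 5L, min_taxa = 1L, max_taxa = 100000L)
  set.seed(99)
  alive_end <- vapply(1:200, function(s) {
    lf <- simulate_clade(cfg, seed = 1000 + s)
    sum(lf$extant)
  }, 1)
  expect_gt(mean(alive_end), 4)
  expect_lt(mean(alive_end), 6)
})

test_that("age-dependent longevities with shape 1 are exponential", {
  cfg <- simulation_config(c(400, 200),
                           list(kind = "ade", lambda = 0.05, phi = 1,
                                psi = 5),
                           n0 = 40L, min_taxa = 40L, max_taxa = 100000L)
  lf <- simulate_clade(cfg, seed = 8)
  # taxa born early enough that window truncation is negligible
  early <- lf[!lf$extant & lf$ts > 280, ]
  longev <- early$ts - early$te
  expect_gt(length(longev), 50)
  ks <- suppressWarnings(ks.test(longev, "pexp", rate = 1 / 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated histories are seeded and conditioned on clade size", {
  cfg <- simulation_config(c(260, 240),
                           list(kind = "piecewise", shifts = numeric(0),
                                lambda = 0.25, mu = 0.1),
                           n0 = 2L, min_taxa = 20L, max_taxa = 400L)
  a <- simulate_clade(cfg, seed = 5)
  b <- simulate_clade(cfg, seed = 5)
  expect_identical(a, b)
  expect_true(nrow(a) >= 20L && nrow(a) <= 400L)
  # an impossible acceptance band triggers the retry-cap error
  bad <- simulation_config(c(260, 259),
                           list(kind = "piecewise", shifts = numeric(0),
                                lambda = 0.01, mu = 0.01),
                           n0 = 1L, min_taxa = 500L, max_taxa = 600L,
                           max_retry = 5L)
  expect_error(simulate_clade(bad, seed = 1), "retry cap")
})

test_that("fossilisation respects the preservation regime", {
  lf <- data.frame(taxon = c("a", "b"), ts = c(255, 250), te = c(245, 244),
                   extant = FALSE)
  class(lf) <- c("lifespan_table", "data.frame")
  bins <- uniform_bins(c(259.51, 208.5), 20)
  # q = 0 (numerically tiny) gives an empty table
  empty <- simulate_preservation(lf, preservation_model("hpp", q = 1e-9),
                                 bins, seed = 1)
  expect_equal(nrow(empty), 0L)
  # Poisson concentration of total occurrence count around q * total lifespan
  big <- data.frame(taxon = paste0("t", 1:50),
                    ts = runif(50, 250, 258), te = runif(50, 215, 240),
                    extant = FALSE)
  class(big) <- c("lifespan_table", "data.frame")
  L <- sum(big$ts - big$te)
  occ <- simulate_preservation(big, preservation_model("hpp", q = 1), bins,
                               seed = 42)
  expect_lt(abs(nrow(occ) - L), 3 * sqrt(L))
  # every emitted stage interval contains its true point age
  truth <- attr(occ, "truth")
  expect_true(all(occ$min_age <= truth$true_ages + 1e-9 &
                    occ$max_age >= truth$true_ages - 1e-9))
})

test_that("hump-shaped fossilisation concentrates occurrences mid-lifespan", {
  lf <- data.frame(taxon = "a", ts = 250, te = 220, extant = FALSE)
  class(lf) <- c("lifespan_table", "data.frame")
  bins <- uniform_bins(c(259.51, 208.5), 40)
  occ <- simulate_preservation(lf, preservation_model("nhpp", q = 20), bins,
                               seed = 3)
  v <- (250 - attr(occ, "truth")$true_ages) / 30
  # Beta(2,2)-distributed relative positions have mean 1/2, sd ~0.224
  expect_equal(mean(v), 0.5, tolerance = 0.05)
  expect_lt(abs(sd(v) - sqrt(0.05)), 0.05)
})

test_that("a single coupled guild reduces to a plain clade simulation", {
  rg <- list(kind = "mcdd", guilds = "only",
             lambda0 = 0.25, mu0 = 0.1,
             g_lambda = matrix(0, 1, 1), g_mu = matrix(0, 1, 1),
             norm = 100)
  cfg <- simulation_config(c(260, 245), rg, n0 = 5L, min_taxa = 5L,
                           max_taxa = 5000L)
  gl <- simulate_guild_system(cfg, seed = 2)
  expect_length(gl, 1L)
  expect_true(all(gl$only$ts >= gl$only$te))
  # same seed reproduces the system exactly
  gl2 <- simulate_guild_system(cfg, seed = 2)
  expect_identical(gl$only, gl2$only)
})

test_that("scenario presets deliver the shapes downstream analyses expect", {
  sc <- simulate_scenario("pulse", seed = 1)
  expect_s3_class(sc$occurrences, "occurrence_table")
  expect_equal(sc$truth$shift_time, 252)
  # the engineered pulse kills most lineages after 252
  post <- sc$lifespans[sc$lifespans$ts < 252, ]
  expect_gt(nrow(sc$lifespans), 100)
  sm <- simulate_scenario("mbd", seed = 2)
  expect_length(sm$covariates, 4L)
  expect_true(all(vapply(sm$covariates, function(cv)
    all(cv$value >= 0 & cv$value <= 1), TRUE)))
})
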