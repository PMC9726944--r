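test_that("homogeneous preservation likelihood matches hand computation", {
  # 3 occurrences, lifespan 6 Myr, q = 0.5: 3 log(0.5) - 0.5 * 6
  expect_equal(hpp_loglik(c(9, 7, 5), ts = 10, te = 4, q = 0.5),
               3 * log(0.5) - 3, tolerance = 1e-6)
  # rate rescaling identity: ll(q) - ll(cq) = -n log c + (Ts-Te) q (c - 1)
  ages <- c(9, 7, 5)
  d <- hpp_loglik(ages, 10, 4, 1) - hpp_loglik(ages, 10, 4, exp(1))
  expect_equal(d, -3 + 6 * (exp(1) - 1), tolerance = 1e-10)
  expect_error(hpp_loglik(c(5), ts = 5, te = 5, q = 1), "lifespan")
  expect_error(hpp_loglik(c(12), ts = 10, te = 4, q = 1), "outside")
  expect_error(hpp_loglik(ages, 10, 4, q = 0), "q must be")
})

test_that("time-variable preservation likelihood matches hand computation and reduces to HPP", {
  bins <- stage_bins(c(10, 6, 2))
  # occurrences at 7 (q=1) and 5 (q=2); integral 1*3 + 2*3
  expect_equal(tpp_loglik(c(7, 5), ts = 9, te = 3, q_vector = c(1, 2),
                          bins = bins),
               log(1) + log(2) - 9, tolerance = 1e-6)
  # equal per-bin rates give exactly the homogeneous model
  expect_equal(tpp_loglik(c(7, 5), 9, 3, c(0.7, 0.7), bins),
               hpp_loglik(c(7, 5), 9, 3, 0.7))
  one <- stage_bins(c(10, 2))
  expect_equal(tpp_loglik(c(7, 5), 9, 3, 1.3, one),
               hpp_loglik(c(7, 5), 9, 3, 1.3))
  # relabelling bins changes nothing
  b2 <- stage_bins(c(10, 6, 2), labels = c("x", "y"))
  expect_equal(tpp_loglik(c(7, 5), 9, 3, c(1, 2), b2),
               tpp_loglik(c(7, 5), 9, 3, c(1, 2), bins))
  expect_error(tpp_loglik(c(7, 5), 11, 3, c(1, 2), bins), "coverage")
})

test_that("hump-shaped preservation integrates to q(Ts-Te) and favours mid-lifespan", {
  # flat hump (shape 1) is the homogeneous model
  expect_equal(nhpp_loglik(c(9, 7, 5), 10, 4, 0.5, shape = 1),
               hpp_loglik(c(9, 7, 5), 10, 4, 0.5))
  # a mid-lifespan occurrence scores higher than one near the edge
  mid <- nhpp_loglik(7, 10, 4, 1)
  edge <- nhpp_loglik(9.7, 10, 4, 1)
  expect_gt(mid, edge)
  # quadrature oracle: the intensity integrates to q (Ts - Te)
  q <- 0.8; ts <- 10; te <- 4
  intens <- function(t) q * dbeta((ts - t) / (ts - te), 2, 2)
  I <- integrate(intens, te, ts, rel.tol = 1e-10)$value
  expect_equal(I, q * (ts - te), tolerance = 1e-6)
  # full-density oracle built from the intensity directly
  ages <- c(8.5, 7, 6.2)
  oracle <- sum(log(intens(ages))) - I
  expect_equal(nhpp_loglik(ages, ts, te, q), oracle, tolerance = 1e-6)
})

test_that("gamma rate heterogeneity discretises and mixes correctly", {
  expect_equal(discretize_gamma(0.7, 1), 1)
  for (a in c(0.3, 1, 5)) {
    m <- discretize_gamma(a, 4)
    expect_equal(mean(m), 1, tolerance = 1e-8)
    expect_true(all(diff(m) > 0))
  }
  per_taxon <- function(m) {
    c(hpp_loglik(c(9, 7), 10, 4, 0.5 * m), hpp_loglik(c(6), 8, 5, 0.5 * m))
  }
  base <- sum(per_taxon(1))
  expect_equal(gamma_mixture_loglik(per_taxon, alpha = 2, K = 1), base)
  # very low heterogeneity converges to the base model
  expect_equal(gamma_mixture_loglik(per_taxon, alpha = 1e6, K = 4), base,
               tolerance = 1e-4)
  # mixture lies between the best and worst category
  m <- discretize_gamma(0.5, 4)
  lls <- vapply(m, function(mm) sum(per_taxon(mm)), 1)
  mix <- gamma_mixture_loglik(per_taxon, 0.5, 4)
  expect_gte(mix, min(lls))
  expect_lte(mix, max(lls))
})

test_that("preservation model comparison identifies the generating process", {
  win <- c(259.51, 208.5)
  bins <- uniform_bins(win, 10)
  # interior lifespans with homogeneous preservation (the model test's
  # range approximation is exercised without window-edge truncation)
  hits_hpp <- 0L
  for (i in 1:10) {
    set.seed(100 + i)
    n <- 200L
    ts <- runif(n, 232, 256)
    te <- pmax(ts - rexp(n, 1 / 8), 210)
    ages <- lapply(seq_len(n), function(j) {
      k <- rpois(1, 1.2 * (ts[j] - te[j]))
      runif(k, te[j], ts[j])
    })
    names(ages) <- paste0("t", seq_len(n))
    ser <- taxon_series(ages[vapply(ages, length, 1L) > 0])
    res <- pp_model_test(ser, bins)
    if (res$delta_aic[res$model == "hpp"] <= 2) hits_hpp <- hits_hpp + 1L
  }
  expect_gte(hits_hpp, 8L)

  hits_tpp <- 0L
  for (i in 1:10) {
    sc <- simulate_scenario("constant", seed = 200 + i)
    pm <- preservation_model("tpp", q_vector = rep(c(0.4, 2), 5), bins = bins)
    occ <- simulate_preservation(sc$lifespans, pm, bins = bins, seed = i)
    res <- pp_model_test(true_age_series(occ), bins)
    if (attr(res, "best") == "tpp") hits_tpp <- hits_tpp + 1L
  }
  expect_gte(hits_tpp, 8L)

  # restricting the candidate set returns the only candidate
  sc <- simulate_scenario("constant", seed = 300)
  res <- pp_model_test(true_age_series(sc$occurrences), bins, models = "nhpp")
  expect_equal(attr(res, "best"), "nhpp")

  expect_error(pp_model_test(taxon_series(list(a = 250, b = 240)), bins),
               ">= 2 taxa")
})

test_that("preservation model constructor enforces its invariants", {
  expect_error(preservation_model("hpp", q = -1), "> 0")
  expect_error(preservation_model("tpp", q_vector = NULL), "needs")
  expect_error(preservation_model("hpp", gamma = TRUE, alpha = 0), "alpha")
  pm <- preservation_model("tpp", q_vector = c(1, 2),
                           bins = stage_bins(c(10, 6, 2)))
  expect_equal(pm$kind, "tpp")
})
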