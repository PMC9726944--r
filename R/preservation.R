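#' Preservation model specification
#'
#' Describes the Poisson process by which a living taxon leaves fossil
#' occurrences. Three flavours are supported: a homogeneous Poisson process
#' (`hpp`, constant rate `q` over the lifespan), a non-homogeneous process
#' (`nhpp`, a symmetric hump over the lifespan so that preservation is
#' highest mid-lifespan), and a time-variable process (`tpp`, piecewise
#' constant within stage bins). Rates are expected occurrences per taxon
#' per Myr. Across-taxon rate heterogeneity can be added as a discretised
#' mean-one gamma mixture with `n_categories` classes.
#'
#' @param kind One of `"hpp"`, `"nhpp"`, `"tpp"`.
#' @param q Preservation rate (hpp/nhpp level parameter), > 0.
#' @param q_vector Per-bin preservation rates (tpp only), all > 0.
#' @param bins [stage_bins()] defining the tpp time frame.
#' @param gamma Logical: enable gamma-distributed rate heterogeneity.
#' @param alpha Gamma shape (> 0) when `gamma = TRUE` (estimated during
#'   MCMC; this value is the chain's starting point).
#' @param n_categories Number of discrete gamma categories (default 4).
#' @param beta_shape Shape of the symmetric beta hump used by the nhpp
#'   intensity (default 2; 1 reduces to the hpp).
#' @return An object of class `preservation_model`.
#' @export
preservation_model <- function(kind = c("nhpp", "hpp", "tpp"), q = 1,
                               q_vector = NULL, bins = NULL, gamma = FALSE,
                               alpha = 1, n_categories = 4L, beta_shape = 2) {
  kind <- match.arg(kind)
  if (kind == "tpp") {
    if (is.null(q_vector) || is.null(bins)) {
      stop("tpp needs q_vector and bins")
    }
    if (length(q_vector) != nrow(bins)) stop("one rate per bin required")
    if (any(q_vector <= 0)) stop("preservation rates must be > 0")
  } else {
    if (!is.numeric(q) || q <= 0) stop("q must be > 0")
  }
  if (gamma && (!is.numeric(alpha) || alpha <= 0)) stop("alpha must be > 0")
  if (n_categories < 1L) stop("n_categories must be >= 1")
  structure(list(kind = kind, q = q, q_vector = q_vector, bins = bins,
                 gamma = gamma, alpha = alpha,
                 n_categories = as.integer(n_categories),
                 beta_shape = beta_shape),
            class = "preservation_model")
}

check_lifespan <- function(ages, ts, te) {
  if (ts <= te && length(ages)) {
    stop("zero- or negative-length lifespan with occurrences")
  }
  if (length(ages) && (min(ages) < te || max(ages) > ts)) {
    stop("occurrence outside the lifespan [Te, Ts]")
  }
}

#' Homogeneous Poisson preservation log-likelihood
#'
#' For `n` occurrences of a taxon with lifespan `[Te, Ts]` sampled at
#' constant rate `q`, the log-likelihood is `n log q - q (Ts - Te)`
#' (occurrence times uniform over the lifespan; no conditioning on
#' observing at least one fossil, since lifespans are latent and sampled
#' jointly during inference).
#'
#' @param ages Numeric vector of point occurrence ages (Ma).
#' @param ts Origination time Ts (Ma), `ts >= max(ages)`.
#' @param te Extinction time Te (Ma), `te <= min(ages)`.
#' @param q Preservation rate (> 0), occurrences/taxon/Myr.
#' @return Log-likelihood (scalar).
#' @export
hpp_loglik <- function(ages, ts, te, q) {
  if (!is.numeric(q) || q <= 0) stop("q must be > 0")
  check_lifespan(ages, ts, te)
  length(ages) * log(q) - q * (ts - te)
}

#' Time-variable Poisson preservation log-likelihood
#'
#' Preservation rate is piecewise constant over stage bins: the
#' log-likelihood is the sum of `log q_bin(age)` over occurrences minus the
#' integral of the bin rates over the lifespan.
#'
#' @inheritParams hpp_loglik
#' @param q_vector Per-bin rates (one per bin, oldest first).
#' @param bins A [stage_bins()] object covering `[te, ts]`.
#' @return Log-likelihood (scalar).
#' @export
tpp_loglik <- function(ages, ts, te, q_vector, bins) {
  if (any(q_vector <= 0)) stop("preservation rates must be > 0")
  if (length(q_vector) != nrow(bins)) stop("one rate per bin required")
  check_lifespan(ages, ts, te)
  edges <- bin_edges(bins)
  if (ts > edges[1] || te < edges[length(edges)]) {
    stop("lifespan extends beyond bin coverage")
  }
  idx <- bin_of_age(ages, bins)
  ov <- drop(bin_overlap(te, ts, bins))
  sum(log(q_vector[idx])) - sum(q_vector * ov)
}

#' Non-homogeneous (hump-shaped) Poisson preservation log-likelihood
#'
#' Preservation intensity is `q * f(v)` where `v = (Ts - age)/(Ts - Te)` is
#' the relative position within the lifespan and `f` is a symmetric
#' `Beta(shape, shape)` density: preservation peaks mid-lifespan and
#' vanishes at origination and extinction. The intensity integrates to
#' `q * (Ts - Te)` over the lifespan, so `q` keeps its expected-occurrences
#' per-Myr interpretation. `shape = 1` gives a flat hump and reduces to
#' [hpp_loglik()].
#'
#' @inheritParams hpp_loglik
#' @param shape Beta shape parameter of the hump (default 2).
#' @return Log-likelihood (scalar).
#' @export
nhpp_loglik <- function(ages, ts, te, q, shape = 2) {
  if (!is.numeric(q) || q <= 0) stop("q must be > 0")
  check_lifespan(ages, ts, te)
  if (!length(ages)) return(-q * (ts - te))
  v <- (ts - ages) / (ts - te)
  sum(log(q) + stats::dbeta(v, shape, shape, log = TRUE)) - q * (ts - te)
}

#' Discretised mean-one gamma rate multipliers
#'
#' Category means of `K` equal-probability quantile bins of a
#' `Gamma(alpha, alpha)` distribution (mean 1), the standard discretisation
#' used for among-taxon rate heterogeneity.
#'
#' @param alpha Gamma shape (> 0).
#' @param K Number of categories (>= 1).
#' @return Numeric vector of `K` multipliers averaging 1.
#' @export
discretize_gamma <- function(alpha, K = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = K + 1L), alpha, alpha)
  # mean of a Gamma(a, a) over (b_k, b_{k+1}] = pgamma(b, a+1, a) difference
  p <- stats::pgamma(b, alpha + 1, alpha)
  K * diff(p)
}

#' Gamma-mixture preservation log-likelihood
#'
#' Averages each taxon's preservation likelihood over `K` discrete gamma
#' rate multipliers (equal-probability categories of a mean-one gamma with
#' shape `alpha`), then sums over taxa in log space. `K = 1` returns the
#' base model unchanged.
#'
#' @param per_taxon_loglik Function of one argument `m` (a rate multiplier)
#'   returning the vector of per-taxon log-likelihoods with `q` scaled by
#'   `m`.
#' @param alpha Gamma shape (> 0).
#' @param K Number of categories.
#' @return Total log-likelihood over taxa.
#' @export
gamma_mixture_loglik <- function(per_taxon_loglik, alpha, K = 4L) {
  m <- discretize_gamma(alpha, K)
  ll <- vapply(m, per_taxon_loglik, numeric(length(per_taxon_loglik(1))))
  ll <- matrix(ll, ncol = length(m))
  mx <- apply(ll, 1L, max)
  sum(mx + log(rowMeans(exp(ll - mx))))
}

#' Compare preservation models on a taxon series
#'
#' Fits the homogeneous, non-homogeneous (hump) and time-variable Poisson
#' preservation models by maximum likelihood and ranks them by AIC. As a
#' pragmatic pre-inference step, each taxon's lifespan is approximated from
#' its observed first and last occurrences, extended by the uniform
#' order-statistics range correction `L/(n-1)` on each side. Only taxa with
#' at least two distinct occurrence ages carry information and are used.
#'
#' @param series A `taxon_series`.
#' @param bins [stage_bins()] for the time-variable model.
#' @param models Character subset of `c("hpp", "nhpp", "tpp")` to fit.
#' @param shape Beta shape of the nhpp hump.
#' @return Data frame (one row per model) with log-likelihood, number of
#'   parameters, AIC and delta-AIC, sorted best-first; attribute `best`
#'   holds the winning model kind.
#' @export
pp_model_test <- function(series, bins, models = c("hpp", "nhpp", "tpp"),
                          shape = 2) {
  stopifnot(inherits(series, "taxon_series"))
  models <- match.arg(models, several.ok = TRUE)
  ages <- series$ages[vapply(series$ages, function(a) {
    length(a) >= 2L && diff(range(a)) > 0
  }, TRUE)]
  if (length(ages) < 2L) {
    stop("need >= 2 taxa with >= 2 distinct occurrence ages")
  }
  n <- vapply(ages, length, 1L)
  lo <- vapply(ages, min, 1); hi <- vapply(ages, max, 1)
  pad <- (hi - lo) / (n - 1L)
  ts <- hi + pad
  te <- pmax(lo - pad, 1e-8)
  # padded lifespans are clamped inside the binned window
  edges <- bin_edges(bins)
  ts <- pmax(pmin(ts, edges[1]), hi + 1e-6)
  te <- pmin(pmax(te, edges[length(edges)]), lo - 1e-6)
  L <- ts - te
  N <- sum(n)

  fits <- list()
  if ("hpp" %in% models) {
    qhat <- N / sum(L)
    fits$hpp <- list(loglik = N * log(qhat) - qhat * sum(L), k = 1L)
  }
  if ("nhpp" %in% models) {
    qhat <- N / sum(L)
    sumlogf <- sum(unlist(lapply(seq_along(ages), function(i) {
      stats::dbeta((ts[i] - ages[[i]]) / L[i], shape, shape, log = TRUE)
    })))
    fits$nhpp <- list(loglik = N * log(qhat) - qhat * sum(L) + sumlogf, k = 1L)
  }
  if ("tpp" %in% models) {
    edges <- bin_edges(bins)
    if (max(ts) > edges[1] || min(te) < edges[length(edges)]) {
      stop("approximated lifespans extend beyond bin coverage")
    }
    ov <- bin_overlap(te, ts, bins)          # taxa x bins
    Tb <- colSums(ov)
    nb <- tabulate(bin_of_age(unlist(ages), bins), nbins = nrow(bins))
    use <- Tb > 0
    qb <- ifelse(use, nb / pmax(Tb, 1e-12), 0)
    ll <- sum(nb[use & nb > 0] * log(qb[use & nb > 0])) - sum(qb[use] * Tb[use])
    fits$tpp <- list(loglik = ll, k = sum(use))
  }
  out <- data.frame(model = names(fits),
                    loglik = vapply(fits, `[[`, 1, "loglik"),
                    n_par = vapply(fits, `[[`, 1L, "k"),
                    stringsAsFactors = FALSE)
  out$aic <- 2 * out$n_par - 2 * out$loglik
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  attr(out, "best") <- out$model[1]
  out
}
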