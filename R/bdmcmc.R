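#' MCMC configuration
#'
#' Settings shared by the birth-death samplers. Defaults are desk-scale
#' (500k generations sampled every 500); production-scale settings are a
#' matter of raising `n_generations`.
#'
#' @param n_generations Total MCMC generations.
#' @param sampling_interval Record one sample every this many generations.
#' @param burnin_fraction Fraction of recorded samples discarded as
#'   burn-in (in `[0, 1)`).
#' @param seed Integer seed (applied by the run functions).
#' @param min_dt Minimum separation between two rate shifts (Myr).
#' @param edge_window Numeric pair `c(old, young)`: shifts are only
#'   searched inside this range, mitigating edge effects near the data
#'   window boundaries. `NULL` uses the full analysis window.
#' @param window Analysis window `c(old, young)` in Ma; `NULL` derives it
#'   from the stage bins.
#' @param rate_prior_rate Rate of the vague exponential prior on each
#'   origination/extinction rate value.
#' @param shift_prior_mean Poisson prior mean on the number of shifts, per
#'   rate type (reversible-jump model).
#' @param q_prior_shape Shape of the gamma prior on preservation rates
#'   (default 1.5); its rate parameter receives a vague exponential
#'   hyper-prior and is sampled.
#' @param q_hyper_rate Rate of the exponential hyper-prior.
#' @param ts_proposal Sliding-window half-width (Myr) for lifespan updates.
#' @param shift_move_sd Standard deviation (Myr) of shift-relocation moves.
#' @param grid_dt Spacing of the time grid on which posterior rates are
#'   recorded (reversible-jump model).
#' @param detection_correction Condition each observed taxon's
#'   preservation likelihood on leaving at least one fossil (divide by
#'   `1 - exp(-q m L)`). Ignored when `augment_missing` is on.
#' @param augment_missing Data-augment the lineages that left no fossil at
#'   all (default on). Unobserved short-lived taxa otherwise bias
#'   origination and extinction rates downward, since their birth and
#'   death events are missing from the fitted point pattern.
#' @return A `mcmc_config` list.
#' @export
mcmc_config <- function(n_generations = 500000L, sampling_interval = 500L,
                        burnin_fraction = 0.1, seed = NULL, min_dt = 2,
                        edge_window = c(295.0, 204.5), window = NULL,
                        rate_prior_rate = 1, shift_prior_mean = 1,
                        q_prior_shape = 1.5, q_hyper_rate = 1,
                        ts_proposal = 1.5, shift_move_sd = 3,
                        grid_dt = 0.5, detection_correction = FALSE,
                        augment_missing = TRUE) {
  stopifnot(min_dt > 0, burnin_fraction >= 0, burnin_fraction < 1)
  structure(list(n_generations = as.integer(n_generations),
                 sampling_interval = as.integer(sampling_interval),
                 burnin_fraction = burnin_fraction, seed = seed,
                 min_dt = min_dt, edge_window = edge_window, window = window,
                 rate_prior_rate = rate_prior_rate,
                 shift_prior_mean = shift_prior_mean,
                 q_prior_shape = q_prior_shape, q_hyper_rate = q_hyper_rate,
                 ts_proposal = ts_proposal, shift_move_sd = shift_move_sd,
                 grid_dt = grid_dt,
                 detection_correction = detection_correction,
                 augment_missing = augment_missing),
            class = "mcmc_config")
}

#' Birth-death log-likelihood for fully observed lifespans
#'
#' For lifespans `(Ts_i, Te_i)` under piecewise-constant origination rate
#' `lambda(t)` and extinction rate `mu(t)`, the log-likelihood is
#' `sum_i log lambda(Ts_i) + sum_{i extinct} log mu(Te_i)
#'  - integral of (lambda(t) + mu(t)) D(t) dt`,
#' with `D(t)` the number of lineages alive at `t`; the integral is exact
#' for piecewise-constant rates. A non-positive rate on an interval
#' containing an event yields `-Inf` (a rejected state), not an error.
#'
#' @param lifespans Data frame with columns `ts`, `te` and optionally
#'   `extant` (extant lifespans contribute no extinction term).
#' @param rates List with `window = c(old, young)`, `shifts` (descending
#'   interior shift times, possibly empty), `lambda`, `mu` (one value per
#'   interval, oldest first).
#' @return Log-likelihood (scalar).
#' @export
bd_loglik <- function(lifespans, rates) {
  edges <- c(rates$window[1], rates$shifts, rates$window[2])
  if (any(diff(edges) >= 0)) stop("shift times must lie inside the window, descending")
  lam <- rates$lambda; mu <- rates$mu
  k <- length(edges) - 1L
  stopifnot(length(lam) == k, length(mu) == k)
  ts <- lifespans$ts; te <- lifespans$te
  extant <- if (!is.null(lifespans$extant)) lifespans$extant else
    rep(FALSE, length(ts))
  if (any(ts > edges[1] | te < edges[k + 1] | ts <= te)) {
    stop("lifespans must lie within the window with ts > te")
  }
  itv <- function(t) pmax(1L, pmin(findInterval(-t, -edges), k))
  cum_l <- c(0, cumsum(lam * (edges[-(k + 1)] - edges[-1])))
  cum_m <- c(0, cumsum(mu * (edges[-(k + 1)] - edges[-1])))
  cum_at <- function(cum, vals, t) {
    j <- itv(t)
    cum[j] + vals[j] * (edges[j] - t)
  }
  ev_l <- lam[itv(ts)]
  ev_m <- mu[itv(te[!extant])]
  if (any(ev_l <= 0) || any(ev_m <= 0)) return(-Inf)
  integral <- sum(cum_at(cum_l, lam, te) - cum_at(cum_l, lam, ts)) +
    sum(cum_at(cum_m, mu, te) - cum_at(cum_m, mu, ts))
  sum(log(ev_l)) + sum(log(ev_m)) - integral
}

pres_kind_code <- function(pm) {
  match(pm$kind, c("hpp", "tpp", "nhpp")) - 1L
}

run_sampler <- function(series, bins, preservation, cfg, model,
                        prior_only = FALSE, grid = NULL) {
  stopifnot(inherits(series, "taxon_series"),
            inherits(preservation, "preservation_model"),
            inherits(cfg, "mcmc_config"))
  window <- cfg$window
  if (is.null(window)) window <- range(bin_edges(bins))[c(2, 1)]
  window <- as.numeric(window)
  edge <- cfg$edge_window
  if (is.null(edge)) edge <- window
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))

  occ <- unname(series$ages)
  if (!length(occ)) stop("empty taxon series")
  extant <- as.logical(series$extant[names(series$ages)])
  extant[is.na(extant)] <- FALSE
  all_ages <- unlist(occ)
  if (max(all_ages) > window[1] || min(all_ages) < window[2]) {
    stop("occurrences outside the analysis window")
  }
  fixed <- if (model == 0L) bins$min_age[-nrow(bins)] else numeric(0)
  pres_edges <- if (preservation$kind == "tpp") {
    bin_edges(preservation$bins)
  } else window
  if (is.null(grid)) {
    grid <- if (model == 0L) {
      (bins$max_age + bins$min_age) / 2
    } else {
      seq(window[1] - cfg$grid_dt / 2, window[2], by = -cfg$grid_dt)
    }
  }

  raw <- cpp_bdmcmc(occ, extant, window[1], window[2], model, fixed,
                    pres_kind_code(preservation), pres_edges,
                    isTRUE(preservation$gamma), preservation$n_categories,
                    preservation$beta_shape, cfg$q_prior_shape,
                    cfg$q_hyper_rate, cfg$rate_prior_rate,
                    cfg$shift_prior_mean, cfg$min_dt, edge[1], edge[2],
                    cfg$n_generations, cfg$sampling_interval,
                    cfg$ts_proposal, cfg$shift_move_sd, grid, prior_only,
                    isTRUE(cfg$detection_correction),
                    isTRUE(cfg$augment_missing))

  ns <- raw$n_samples
  nburn <- floor(cfg$burnin_fraction * ns)
  keep <- seq.int(nburn + 1L, ns)
  trim_shifts <- function(df) {
    df <- df[df$sample > nburn, , drop = FALSE]
    df$sample <- df$sample - nburn
    df
  }
  taxa <- names(series$ages)
  post <- list(
    model = if (model == 0L) "BDCS" else "RJMCMC",
    grid = grid, window = window, edge_window = edge,
    lambda = raw$lambda[keep, , drop = FALSE],
    mu = raw$mu[keep, , drop = FALSE],
    q = raw$q[keep, , drop = FALSE],
    alpha = raw$alpha[keep],
    loglik = raw$loglik[keep],
    k_lambda = raw$k_lambda[keep],
    k_mu = raw$k_mu[keep],
    n_aug = raw$n_aug[keep],
    shift_lambda = trim_shifts(raw$shift_lambda),
    shift_mu = trim_shifts(raw$shift_mu),
    lifespans = list(taxon = taxa, extant = extant,
                     ts = raw$ts[keep, , drop = FALSE],
                     te = raw$te[keep, , drop = FALSE]),
    nu = cfg$shift_prior_mean, min_dt = cfg$min_dt,
    n_samples = length(keep), replicate_id = series$replicate_id,
    cfg = cfg)
  class(post) <- "rate_posterior"
  post$ess <- c(loglik = ess(post$loglik),
                lambda_mean = ess(rowMeans(post$lambda)),
                mu_mean = ess(rowMeans(post$mu)))
  low <- post$ess[is.finite(post$ess)] < 200
  if (any(low)) {
    message("ESS below 200 for: ",
            paste(names(post$ess)[which(low)], collapse = ", "),
            " (chain may not have converged)")
  }
  post
}

#' Birth-death inference with shifts fixed at stage boundaries (BDCS)
#'
#' Joint MCMC over per-taxon origination/extinction times, per-bin
#' origination and extinction rates, and the preservation parameters, with
#' rate shifts constrained to the supplied stage boundaries. Rate values
#' carry vague exponential priors and are Gibbs-updated via gamma
#' conjugacy; lifespans move by reflected sliding-window proposals.
#'
#' @param series A `taxon_series`.
#' @param bins [stage_bins()] fixing the shift times.
#' @param preservation A [preservation_model()].
#' @param cfg A [mcmc_config()].
#' @return A `rate_posterior` (post burn-in samples of per-bin rates on the
#'   bin-midpoint grid, lifespan draws, preservation parameters, ESS).
#' @export
run_bdcs <- function(series, bins = permo_triassic_bins(),
                     preservation = preservation_model("hpp", q = 1),
                     cfg = mcmc_config()) {
  run_sampler(series, bins, preservation, cfg, model = 0L)
}

#' Birth-death inference with reversible-jump shift detection (RJMCMC)
#'
#' As [run_bdcs()] but the number and placement of origination and
#' extinction rate shifts (independent sets) are sampled by
#' trans-dimensional moves under a Poisson prior on the shift counts.
#' Proposed shift times respect the minimum separation `min_dt` and are
#' restricted to the edge window.
#'
#' @inheritParams run_bdcs
#' @param bins Stage bins; used only to derive the analysis window when
#'   `cfg$window` is `NULL` (and the preservation bins for a `tpp` model).
#' @param prior_only Internal validity check: replace the likelihood by a
#'   constant so the sampler must reproduce its prior.
#' @return A `rate_posterior` with rates recorded on a regular time grid
#'   plus the sampled shift times.
#' @export
run_rjmcmc <- function(series, preservation = preservation_model("hpp", q = 1),
                       cfg = mcmc_config(), bins = permo_triassic_bins(),
                       prior_only = FALSE) {
  run_sampler(series, bins, preservation, cfg, model = 1L,
              prior_only = prior_only)
}

#' @export
print.rate_posterior <- function(x, ...) {
  cat(sprintf("%s posterior: %d samples, %d taxa, window %.2f-%.2f Ma\n",
              x$model, x$n_samples, length(x$lifespans$taxon),
              x$window[1], x$window[2]))
  if (x$model == "RJMCMC") {
    cat(sprintf("  shift count modes: lambda %d, mu %d\n",
                as.integer(names(which.max(table(x$k_lambda)))),
                as.integer(names(which.max(table(x$k_mu))))))
  }
  cat(sprintf("  mean q = %.3f; min ESS = %.0f\n",
              mean(x$q), suppressWarnings(min(x$ess, na.rm = TRUE))))
  invisible(x)
}

#' Posterior mean and credible band of rates through time
#'
#' @param posterior A `rate_posterior` (burn-in already removed).
#' @param grid Optional time grid; defaults to the grid the sampler
#'   recorded (values at other times are taken from the nearest recorded
#'   grid point).
#' @return Data frame with, per grid time, posterior mean and equal-tailed
#'   95% interval of origination, extinction, and net diversification
#'   (origination minus extinction, computed per draw).
#' @export
summarize_rates <- function(posterior, grid = NULL) {
  stopifnot(inherits(posterior, "rate_posterior"))
  lam <- posterior$lambda; mu <- posterior$mu
  g <- posterior$grid
  if (!is.null(grid)) {
    idx <- vapply(grid, function(t) which.min(abs(g - t)), 1L)
    lam <- lam[, idx, drop = FALSE]
    mu <- mu[, idx, drop = FALSE]
    g <- grid
  }
  net <- lam - mu
  qs <- function(m, p) apply(m, 2L, stats::quantile, probs = p, names = FALSE)
  data.frame(time = g,
             lambda_mean = colMeans(lam), lambda_lo = qs(lam, 0.025),
             lambda_hi = qs(lam, 0.975),
             mu_mean = colMeans(mu), mu_lo = qs(mu, 0.025),
             mu_hi = qs(mu, 0.975),
             net_mean = colMeans(net), net_lo = qs(net, 0.025),
             net_hi = qs(net, 0.975))
}

#' Log Bayes factors for rate shifts in candidate time windows
#'
#' Compares the posterior odds that at least one shift falls inside a
#' window with the prior odds under the Poisson shift-count prior with
#' uniform placement over the edge window. Zero (or full) posterior
#' frequencies are reported as finite bounds using half a sample, never as
#' infinities.
#'
#' @param posterior A `rate_posterior` from [run_rjmcmc()].
#' @param rate `"mu"` or `"lambda"`.
#' @param windows Two-column matrix or data frame of candidate windows
#'   (older, younger).
#' @return Data frame with posterior/prior shift frequencies and `log_bf`
#'   per window; attribute `bounded` flags frequency bounds.
#' @export
shift_bayes_factor <- function(posterior, rate = c("mu", "lambda"), windows) {
  stopifnot(inherits(posterior, "rate_posterior"))
  rate <- match.arg(rate)
  sh <- if (rate == "mu") posterior$shift_mu else posterior$shift_lambda
  ns <- posterior$n_samples
  W <- posterior$edge_window[1] - posterior$edge_window[2]
  windows <- as.matrix(windows)
  eps <- 0.5 / ns
  out <- data.frame(older = windows[, 1], younger = windows[, 2])
  bounded <- logical(nrow(windows))
  out$p_post <- vapply(seq_len(nrow(windows)), function(i) {
    hit <- sh$time <= windows[i, 1] & sh$time >= windows[i, 2]
    length(unique(sh$sample[hit])) / ns
  }, 1)
  bounded <- out$p_post <= 0 | out$p_post >= 1
  out$p_post <- pmin(pmax(out$p_post, eps), 1 - eps)
  out$p_prior <- 1 - exp(-posterior$nu * (windows[, 1] - windows[, 2]) / W)
  out$log_bf <- log(out$p_post / (1 - out$p_post)) -
    log(out$p_prior / (1 - out$p_prior))
  attr(out, "bounded") <- bounded
  out
}

#' Detect significant rate shifts from a reversible-jump posterior
#'
#' Bins sampled shift times into small cells over the edge window, seeds
#' clusters at cells with positive evidence (log BF > `seed_threshold`),
#' merges cells closer than `min_dt`, and scores each merged cluster by
#' the Bayes factor of "at least one shift in the cluster window". Shifts
#' with log BF above `threshold` (default 6, strong support) are flagged
#' significant.
#'
#' @inheritParams shift_bayes_factor
#' @param threshold Log Bayes factor above which a shift is significant.
#' @param cell Cell width (Myr) for the shift-time histogram.
#' @param seed_threshold Per-cell log BF needed to seed a cluster.
#' @return Data frame with one row per detected shift: posterior mean
#'   `time`, cluster `log_bf`, and `significant`.
#' @export
significant_shifts <- function(posterior, rate = c("mu", "lambda"),
                               threshold = 6, cell = 0.5,
                               seed_threshold = 2) {
  stopifnot(inherits(posterior, "rate_posterior"))
  rate <- match.arg(rate)
  sh <- if (rate == "mu") posterior$shift_mu else posterior$shift_lambda
  empty <- data.frame(time = numeric(0), log_bf = numeric(0),
                      significant = logical(0))
  if (!nrow(sh)) return(empty)
  edges <- seq(posterior$edge_window[1], posterior$edge_window[2], by = -cell)
  if (edges[length(edges)] > posterior$edge_window[2]) {
    edges <- c(edges, posterior$edge_window[2])
  }
  cells <- cbind(older = edges[-length(edges)], younger = edges[-1])
  bf <- shift_bayes_factor(posterior, rate, cells)
  seeds <- which(bf$log_bf > seed_threshold)
  if (!length(seeds)) return(empty)
  centers <- (cells[, 1] + cells[, 2]) / 2
  cl <- cumsum(c(1, diff(centers[seeds]) < -(posterior$min_dt)))
  out <- do.call(rbind, lapply(split(seeds, cl), function(ix) {
    win <- c(max(cells[ix, 1]), min(cells[ix, 2]))
    b <- shift_bayes_factor(posterior, rate, matrix(win, nrow = 1))
    inwin <- sh$time <= win[1] & sh$time >= win[2]
    data.frame(time = mean(sh$time[inwin]), log_bf = b$log_bf,
               significant = b$log_bf > threshold)
  }))
  rownames(out) <- NULL
  out
}

#' Significant rate changes between adjacent bins of a BDCS posterior
#'
#' A boundary is flagged when the posterior mean rate of each adjacent bin
#' falls outside the 95% credible interval of the other.
#'
#' @inheritParams shift_bayes_factor
#' @return Data frame with one row per interior bin boundary.
#' @export
bdcs_shift_significance <- function(posterior, rate = c("mu", "lambda")) {
  stopifnot(inherits(posterior, "rate_posterior"), posterior$model == "BDCS")
  rate <- match.arg(rate)
  m <- if (rate == "mu") posterior$mu else posterior$lambda
  mn <- colMeans(m)
  lo <- apply(m, 2L, stats::quantile, 0.025, names = FALSE)
  hi <- apply(m, 2L, stats::quantile, 0.975, names = FALSE)
  k <- length(mn)
  if (k < 2L) return(data.frame(boundary = numeric(0), significant = logical(0)))
  older <- seq_len(k - 1L); younger <- older + 1L
  data.frame(
    boundary = (posterior$grid[older] + posterior$grid[younger]) / 2,
    significant = (mn[older] < lo[younger] | mn[older] > hi[younger]) &
      (mn[younger] < lo[older] | mn[younger] > hi[older]))
}

#' Per-taxon lifespan estimates from one replicate posterior
#'
#' @param posterior A `rate_posterior`.
#' @return Data frame `taxon`, `ts`, `te`, `extant` with posterior mean
#'   origination and extinction times.
#' @export
lifespan_estimates <- function(posterior) {
  stopifnot(inherits(posterior, "rate_posterior"))
  lf <- posterior$lifespans
  data.frame(taxon = lf$taxon, ts = colMeans(lf$ts), te = colMeans(lf$te),
             extant = lf$extant, stringsAsFactors = FALSE)
}

#' Average lifespan estimates across replicate posteriors
#'
#' Point estimates of Ts and Te are computed as the average of the
#' posterior samples within each replicate, then averaged across
#' replicates (`mean_first = TRUE`, the default). Alternatively the
#' replicate tables can be pooled before averaging.
#'
#' @param posteriors List of `rate_posterior` objects over the same taxa.
#' @param mean_first Average replicate means (default) rather than pooled
#'   draws.
#' @return Data frame `taxon`, `ts`, `te`, `extant`.
#' @export
lifespan_means <- function(posteriors, mean_first = TRUE) {
  tabs <- lapply(posteriors, lifespan_estimates)
  taxa <- tabs[[1]]$taxon
  stopifnot(all(vapply(tabs, function(t) identical(t$taxon, taxa), TRUE)))
  if (!mean_first) {
    ts <- do.call(rbind, lapply(posteriors, function(p) p$lifespans$ts))
    te <- do.call(rbind, lapply(posteriors, function(p) p$lifespans$te))
    return(data.frame(taxon = taxa, ts = colMeans(ts), te = colMeans(te),
                      extant = tabs[[1]]$extant, stringsAsFactors = FALSE))
  }
  data.frame(taxon = taxa,
             ts = rowMeans(vapply(tabs, `[[`, numeric(length(taxa)), "ts")),
             te = rowMeans(vapply(tabs, `[[`, numeric(length(taxa)), "te")),
             extant = tabs[[1]]$extant, stringsAsFactors = FALSE)
}
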