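#' Diversity-dependent guild rates
#'
#' Linear modulation of a guild's baseline rates by the normalised
#' standing diversities of all guilds:
#' `lambda_i(t) = max(0, lambda_i0 * (1 - sum_j glambda_ij Dhat_j(t)))`,
#' `mu_i(t) = max(0, mu_i0 * (1 + sum_j gmu_ij Dhat_j(t)))`.
#' A positive interaction parameter always encodes a negative
#' (diversity-dependent) effect: it lowers origination and raises
#' extinction of guild i as guild j diversifies. Rates are clamped at
#' zero.
#'
#' @param lambda0,mu0 Baseline rates of the focal guild (> 0).
#' @param g_lambda,g_mu Interaction parameter vectors (entry j = effect of
#'   guild j on the focal guild; includes the intra-guild term).
#' @param dhat Normalised diversities of all guilds at the evaluation
#'   time, each in `[0, 1]`.
#' @return Numeric pair `c(lambda, mu)`.
#' @export
mcdd_rates <- function(lambda0, mu0, g_lambda, g_mu, dhat) {
  c(max(0, lambda0 * (1 - sum(g_lambda * dhat))),
    max(0, mu0 * (1 + sum(g_mu * dhat))))
}

#' Multiple-clade diversity-dependence model
#'
#' Estimates, for each guild, baseline origination/extinction rates and
#' the full matrix of diversity-dependence parameters `g_lambda[i, j]`,
#' `g_mu[i, j]` (including intra-guild terms `i = j`) from guild-specific
#' lifespans and normalised diversity trajectories. Interactions are
#' significant when the posterior median differs from zero and the 95%
#' credible interval excludes zero.
#'
#' Two entry points: guild-specific occurrence series (lifespans are first
#' estimated per guild by a constant-rate [run_bdcs()] fit) or fixed
#' lifespan tables. Replicates (lists of series/lifespans) are analysed
#' independently and their posteriors pooled.
#'
#' @param guild_series Named list guild -> `taxon_series`, or a list of
#'   such lists (replicates). Alternatively `NULL` when
#'   `guild_lifespans` is given.
#' @param guild_lifespans Named list guild -> lifespan data frame, or a
#'   list of such lists (replicates).
#' @param window `c(older, younger)` Ma.
#' @param cfg A [mcmc_config()].
#' @param norm Optional named vector of diversity normalisation constants
#'   per guild; default is each guild's maximum diversity over the window.
#' @param preservation Preservation model for the lifespan-estimation
#'   stage.
#' @param grid_dt Trajectory/likelihood grid width, Myr.
#' @param fix_g Freeze all diversity-dependence parameters at 0
#'   (independent constant-rate fits per guild; a model-validation check).
#' @return An `mcdd_posterior`: pooled draw matrix, per-pair summary
#'   (median, 95% CI, significance), per-guild trajectories.
#' @export
run_mcdd <- function(guild_series = NULL, guild_lifespans = NULL, window,
                     cfg = mcmc_config(n_generations = 50000L,
                                       sampling_interval = 20L),
                     norm = NULL,
                     preservation = preservation_model("hpp", q = 1),
                     grid_dt = 1, fix_g = FALSE) {
  if (is.null(guild_series) == is.null(guild_lifespans)) {
    stop("supply exactly one of guild_series or guild_lifespans")
  }
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed))
  as_replicates <- function(x) if (is.data.frame(x[[1]]) ||
                                   inherits(x[[1]], "taxon_series")) list(x) else x
  if (!is.null(guild_series)) {
    reps <- as_replicates(guild_series)
    bins <- stage_bins(c(window[1], window[2]))
    sub_cfg <- cfg
    sub_cfg$seed <- NULL
    sub_cfg$window <- window
    reps <- lapply(reps, function(gs) {
      gs <- drop_empty_guilds(gs)
      lapply(gs, function(s) {
        lifespan_estimates(run_bdcs(s, bins, preservation, sub_cfg))
      })
    })
  } else {
    reps <- lapply(as_replicates(guild_lifespans), drop_empty_guilds)
  }
  guilds <- names(reps[[1]])
  G <- length(guilds)
  edges <- seq(window[1], window[2], by = -grid_dt)
  if (edges[length(edges)] > window[2]) edges <- c(edges, window[2])
  mid <- (edges[-length(edges)] + edges[-1]) / 2

  fit_one <- function(lf_list) {
    traj <- vapply(lf_list, function(lf) {
      vapply(mid, function(t) sum(lf$ts >= t & lf$te < t), 1)
    }, numeric(length(mid)))                    # cells x guilds
    nrm <- if (is.null(norm)) apply(traj, 2L, max) else
      unname(norm[guilds])
    dhat <- pmin(sweep(traj, 2L, pmax(nrm, 1), "/"), 1)
    cs <- lapply(lf_list, cell_stats, edges = edges)
    mcdd_mcmc(cs, dhat, cfg, fix_g)
  }
  draws <- do.call(rbind, lapply(reps, fit_one))

  pairs <- expand.grid(to = seq_len(G), from = seq_len(G))
  summ <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$to[r]; j <- pairs$from[r]
    gl <- draws[, sprintf("gl_%d_%d", i, j)]
    gm <- draws[, sprintf("gm_%d_%d", i, j)]
    data.frame(
      from = guilds[j], to = guilds[i],
      g_lambda = stats::median(gl),
      g_lambda_lo = unname(stats::quantile(gl, 0.025)),
      g_lambda_hi = unname(stats::quantile(gl, 0.975)),
      g_mu = stats::median(gm),
      g_mu_lo = unname(stats::quantile(gm, 0.025)),
      g_mu_hi = unname(stats::quantile(gm, 0.975)),
      stringsAsFactors = FALSE)
  }))
  summ$sig_lambda <- summ$g_lambda != 0 &
    (summ$g_lambda_lo > 0 | summ$g_lambda_hi < 0)
  summ$sig_mu <- summ$g_mu != 0 & (summ$g_mu_lo > 0 | summ$g_mu_hi < 0)
  traj_tables <- lapply(seq_len(G), function(i) {
    counts <- t(vapply(reps, function(lf_list) {
      vapply(mid, function(t) sum(lf_list[[i]]$ts >= t & lf_list[[i]]$te < t), 1)
    }, numeric(length(mid))))
    data.frame(time = mid, mean = colMeans(counts),
               lo95 = apply(counts, 2L, stats::quantile, 0.025, names = FALSE),
               hi95 = apply(counts, 2L, stats::quantile, 0.975, names = FALSE))
  })
  names(traj_tables) <- guilds
  post <- list(draws = draws, summary = summ, guilds = guilds,
               window = window, trajectories = traj_tables,
               n_replicates = length(reps))
  class(post) <- "mcdd_posterior"
  post
}

drop_empty_guilds <- function(gs) {
  size <- vapply(gs, function(s) {
    if (inherits(s, "taxon_series")) length(s$ages) else nrow(s)
  }, 1L)
  if (any(size == 0L)) {
    warning("empty guild(s) dropped: ",
            paste(names(gs)[size == 0L], collapse = ", "))
  }
  gs[size > 0L]
}

#' @export
print.mcdd_posterior <- function(x, ...) {
  cat(sprintf("MCDD posterior: %d guilds, %d replicate(s), window %.1f-%.1f Ma\n",
              length(x$guilds), x$n_replicates, x$window[1], x$window[2]))
  print(x$summary[, c("from", "to", "g_lambda", "sig_lambda", "g_mu",
                      "sig_mu")], digits = 3)
  invisible(x)
}

# Metropolis sampler: per-guild log-baselines and the g matrices; vague
# N(0, 1) priors on g, Exp(0.1) on baselines.
mcdd_mcmc <- function(cs, dhat, cfg, fix_g = FALSE) {
  G <- length(cs)
  l0 <- vapply(cs, function(c) max(sum(c$B) / max(sum(c$L), 1), 0.01), 1)
  m0 <- vapply(cs, function(c) max(sum(c$E) / max(sum(c$L), 1), 0.01), 1)
  gl <- matrix(0, G, G); gm <- matrix(0, G, G)
  ll_guild <- function(i, l0i, m0i, gli, gmi) {
    lam <- pmax(0, l0i * (1 - drop(dhat %*% gli)))
    mu <- pmax(0, m0i * (1 + drop(dhat %*% gmi)))
    B <- cs[[i]]$B; E <- cs[[i]]$E; L <- cs[[i]]$L
    if (any(lam == 0 & B > 0) || any(mu == 0 & E > 0)) return(-Inf)
    sum(B[B > 0] * log(lam[B > 0])) + sum(E[E > 0] * log(mu[E > 0])) -
      sum((lam + mu) * L)
  }
  cur <- vapply(seq_len(G), function(i) ll_guild(i, l0[i], m0[i], gl[i, ], gm[i, ]), 1)
  ns <- cfg$n_generations %/% cfg$sampling_interval
  cn <- c(paste0("lambda0_", 1:G), paste0("mu0_", 1:G),
          c(outer(1:G, 1:G, function(i, j) sprintf("gl_%d_%d", i, j))),
          c(outer(1:G, 1:G, function(i, j) sprintf("gm_%d_%d", i, j))))
  out <- matrix(NA_real_, ns, length(cn), dimnames = list(NULL, cn))
  rec <- 0L
  for (it in seq_len(cfg$n_generations)) {
    for (i in seq_len(G)) {
      l2 <- l0[i] * exp(stats::rnorm(1, 0, 0.1))
      new <- ll_guild(i, l2, m0[i], gl[i, ], gm[i, ])
      if (log(stats::runif(1)) < new - cur[i] - 0.1 * (l2 - l0[i]) +
          log(l2 / l0[i])) {
        l0[i] <- l2; cur[i] <- new
      }
      m2 <- m0[i] * exp(stats::rnorm(1, 0, 0.1))
      new <- ll_guild(i, l0[i], m2, gl[i, ], gm[i, ])
      if (log(stats::runif(1)) < new - cur[i] - 0.1 * (m2 - m0[i]) +
          log(m2 / m0[i])) {
        m0[i] <- m2; cur[i] <- new
      }
      if (fix_g) next
      for (j in seq_len(G)) {
        g2 <- gl[i, ]; g2[j] <- g2[j] + stats::rnorm(1, 0, 0.05)
        new <- ll_guild(i, l0[i], m0[i], g2, gm[i, ])
        if (log(stats::runif(1)) < new - cur[i] +
            (gl[i, j]^2 - g2[j]^2) / 2) {
          gl[i, ] <- g2; cur[i] <- new
        }
        g2 <- gm[i, ]; g2[j] <- g2[j] + stats::rnorm(1, 0, 0.05)
        new <- ll_guild(i, l0[i], m0[i], gl[i, ], g2)
        if (log(stats::runif(1)) < new - cur[i] +
            (gm[i, j]^2 - g2[j]^2) / 2) {
          gm[i, ] <- g2; cur[i] <- new
        }
      }
    }
    if (it %% cfg$sampling_interval == 0L && rec < ns) {
      rec <- rec + 1L
      out[rec, ] <- c(l0, m0, c(gl), c(gm))
    }
  }
  nburn <- floor(cfg$burnin_fraction * nrow(out))
  out[seq.int(nburn + 1L, nrow(out)), , drop = FALSE]
}

#' Significant interaction network of an MCDD posterior
#'
#' Emits one edge per significant diversity-dependence term. Positive
#' parameters are negative interactions (competition-like: diversity of
#' `from` lowers origination or raises extinction of `to`); negative
#' parameters are positive interactions (facilitation-like). Self-loops
#' are intra-guild diversity dependence.
#'
#' @param posterior An `mcdd_posterior`.
#' @return Data frame with columns `from`, `to`, `rate_type`, `sign`,
#'   `magnitude` (posterior median of g), `significant` (all `TRUE`).
#' @export
interaction_network <- function(posterior) {
  stopifnot(inherits(posterior, "mcdd_posterior"))
  s <- posterior$summary
  rows <- list()
  for (r in seq_len(nrow(s))) {
    if (s$sig_lambda[r]) {
      rows[[length(rows) + 1L]] <- data.frame(
        from = s$from[r], to = s$to[r], rate_type = "lambda",
        sign = if (s$g_lambda[r] > 0) "negative" else "positive",
        magnitude = s$g_lambda[r], significant = TRUE,
        stringsAsFactors = FALSE)
    }
    if (s$sig_mu[r]) {
      rows[[length(rows) + 1L]] <- data.frame(
        from = s$from[r], to = s$to[r], rate_type = "mu",
        sign = if (s$g_mu[r] > 0) "negative" else "positive",
        magnitude = s$g_mu[r], significant = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(from = character(0), to = character(0),
                      rate_type = character(0), sign = character(0),
                      magnitude = numeric(0), significant = logical(0)))
  }
  do.call(rbind, rows)
}
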