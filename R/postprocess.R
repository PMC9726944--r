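#' Extinction event window
#'
#' @param name Event name.
#' @param older,younger Boundaries in Ma (older > younger).
#' @return An `event_window` list.
#' @export
event_window <- function(name, older, younger) {
  stopifnot(older > younger)
  structure(list(name = name, older = older, younger = younger),
            class = "event_window")
}

#' Preset Permo-Triassic event windows
#'
#' The three extinction events resolved by the genus-level analyses:
#' Roadian/Wordian (~266.9 Ma), the latest Permian mass extinction
#' (Permo-Triassic boundary, 251.902 Ma) and Ladinian/Carnian (~237 Ma).
#' Each preset brackets its boundary age; boundaries are configurable via
#' [event_window()].
#'
#' @return Named list of `event_window` objects.
#' @export
permo_triassic_events <- function() {
  list(rw = event_window("Roadian/Wordian", 267.9, 265.9),
       lpme = event_window("LPME", 252.902, 250.902),
       lc = event_window("Ladinian/Carnian", 238.0, 236.0))
}

#' Severity of an extinction event: survivors and victims
#'
#' Classifies taxa against an event window using their mean origination
#' (`Ts_m`) and extinction (`Te_m`) times. Eligible taxa appeared before
#' the end of the event (`Ts_m` at least as old as the younger boundary)
#' and had not already vanished (`Te_m` not older than the older
#' boundary). Among those, survivors have `Te_m` younger than the younger
#' boundary and extinct taxa have `Te_m` inside the window. Percentages
#' are `100 * S / Tt` and `100 * E / Tt`. Boundary ties: a `Te_m` exactly
#' at the older boundary counts as inside the window; exactly at the
#' younger boundary counts as a survivor.
#'
#' @param lifespan_means Data frame with columns `ts`, `te` (replicate-mean
#'   lifespans, see [lifespan_means()]).
#' @param window An [event_window()].
#' @return A `severity_report` list: `Tt_gen`, `S_gen`, `E_gen`,
#'   `pct_extinct`, `pct_survivors`.
#' @export
severity <- function(lifespan_means, window) {
  stopifnot(inherits(window, "event_window"))
  ts <- lifespan_means$ts; te <- lifespan_means$te
  eligible <- ts >= window$younger & te <= window$older
  if (!any(eligible)) stop("no taxa present during the event window")
  te_e <- te[eligible]
  surv <- te_e <= window$younger     # tie at the younger boundary survives
  ext <- !surv                       # te within (younger, older]
  out <- list(event = window$name, Tt_gen = sum(eligible),
              S_gen = sum(surv), E_gen = sum(ext),
              pct_extinct = 100 * sum(ext) / sum(eligible),
              pct_survivors = 100 * sum(surv) / sum(eligible))
  class(out) <- "severity_report"
  out
}

#' @export
print.severity_report <- function(x, ...) {
  cat(sprintf("%s: %d taxa present, %d extinct (%.1f%%), %d survivors (%.1f%%)\n",
              x$event, x$Tt_gen, x$E_gen, x$pct_extinct, x$S_gen,
              x$pct_survivors))
  invisible(x)
}

#' Diversity trajectory from replicate lifespan estimates
#'
#' Counts lineages alive (`Ts >= t > Te`) at each grid time, per
#' replicate, and summarises the replicates by their mean and equal-tailed
#' 95% interval.
#'
#' @param lifespan_list List of lifespan data frames (columns `ts`, `te`),
#'   one per replicate, or a single data frame.
#' @param grid Numeric vector of times (Ma).
#' @return Data frame `time`, `mean`, `lo95`, `hi95` with attribute
#'   `counts` (replicates x grid matrix of integer counts).
#' @export
diversity_trajectory <- function(lifespan_list, grid) {
  if (is.data.frame(lifespan_list)) lifespan_list <- list(lifespan_list)
  if (!length(lifespan_list)) stop("need at least one replicate")
  counts <- t(vapply(lifespan_list, function(lf) {
    vapply(grid, function(t) sum(lf$ts >= t & lf$te < t), 1)
  }, numeric(length(grid))))
  out <- data.frame(time = grid, mean = colMeans(counts),
                    lo95 = apply(counts, 2L, stats::quantile, 0.025, names = FALSE),
                    hi95 = apply(counts, 2L, stats::quantile, 0.975, names = FALSE))
  attr(out, "counts") <- counts
  out
}

#' Fold change of a rate peak over background
#'
#' Ratio of the peak posterior mean rate inside an event window to the
#' mean rate over background times. The default background is the full
#' rate table minus a guard band of `pad` Myr around every declared event.
#'
#' @param rtt Rates-through-time table from [summarize_rates()].
#' @param event An [event_window()].
#' @param rate Column prefix: `"mu"`, `"lambda"` or `"net"`.
#' @param background_windows Optional two-column matrix of (older,
#'   younger) background windows; they must exclude all declared events.
#' @param events All declared events (used to build the default
#'   background).
#' @param pad Guard band (Myr) excluded around each event by the default
#'   background.
#' @return The fold factor (scalar).
#' @export
fold_change <- function(rtt, event, rate = "mu", background_windows = NULL,
                        events = list(event), pad = 2) {
  col <- paste0(rate, "_mean")
  stopifnot(col %in% names(rtt), inherits(event, "event_window"))
  tt <- rtt$time
  in_event <- tt <= event$older & tt >= event$younger
  if (!any(in_event)) stop("no grid points inside the event window")
  if (is.null(background_windows)) {
    bg <- rep(TRUE, length(tt))
    for (ev in events) {
      bg <- bg & !(tt <= ev$older + pad & tt >= ev$younger - pad)
    }
  } else {
    background_windows <- as.matrix(background_windows)
    bg <- rep(FALSE, length(tt))
    for (i in seq_len(nrow(background_windows))) {
      bg <- bg | (tt <= background_windows[i, 1] & tt >= background_windows[i, 2])
    }
    for (ev in events) {
      if (any(bg & tt <= ev$older & tt >= ev$younger)) {
        stop("background windows must exclude all declared events")
      }
    }
  }
  if (!any(bg)) stop("empty background")
  max(rtt[[col]][in_event]) / mean(rtt[[col]][bg])
}

#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-time based ESS using Geyer's initial positive sequence
#' estimator: `ESS = n / (1 + 2 * sum(rho_k))` with the sum truncated at
#' the first non-positive pair of adjacent autocorrelations. A constant
#' trace is degenerate and returns `NA` with a warning rather than a
#' number pretending convergence.
#'
#' @param trace Numeric vector of posterior draws of one parameter
#'   (burn-in already removed).
#' @return Estimated ESS (scalar), or `NA` for a degenerate trace.
#' @export
ess <- function(trace) {
  n <- length(trace)
  if (n < 10L) stop("trace shorter than 10 samples")
  if (stats::sd(trace) == 0 || !is.finite(stats::sd(trace))) {
    warning("degenerate (constant) trace; ESS undefined")
    return(NA_real_)
  }
  rho <- stats::acf(trace, lag.max = min(n - 1L, 2000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  npair <- floor(length(rho) / 2)
  tau <- 0
  for (m in seq_len(npair)) {
    g <- rho[2 * m - 1] + rho[2 * m]
    if (g <= 0) break
    tau <- tau + g
  }
  n / (1 + 2 * tau)
}

#' Convergence report over the traces of a posterior
#'
#' @param posterior A `rate_posterior`, `ade_posterior`, `mbd_posterior`
#'   or `mcdd_posterior`.
#' @param threshold ESS above which a parameter is considered converged.
#' @return Data frame `parameter`, `ess`, `converged`.
#' @export
convergence_report <- function(posterior, threshold = 200) {
  tr <- posterior_traces(posterior)
  e <- vapply(tr, function(x) suppressWarnings(ess(x)), 1)
  data.frame(parameter = names(tr), ess = e,
             converged = !is.na(e) & e >= threshold, row.names = NULL)
}

posterior_traces <- function(posterior) {
  if (inherits(posterior, "rate_posterior")) {
    list(loglik = posterior$loglik, lambda_mean = rowMeans(posterior$lambda),
         mu_mean = rowMeans(posterior$mu), q_mean = rowMeans(posterior$q))
  } else if (inherits(posterior, "ade_posterior")) {
    list(phi = posterior$draws[, "phi"], psi = posterior$draws[, "psi"])
  } else if (!is.null(posterior$draws)) {
    as.list(as.data.frame(posterior$draws))
  } else {
    stop("unsupported posterior object")
  }
}
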