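#' Run the full analysis pipeline from a YAML configuration
#'
#' Orchestrates simulate/read -> validate -> resample -> infer ->
#' post-process from a single configuration file, writing TSV outputs and
#' a run manifest (config hash, seeds, input digests, ESS summary, wall
#' time) into the output directory. Re-running with the same configuration
#' and seed reproduces the numeric outputs exactly.
#'
#' Recognised top-level keys: `seed`, `out`, `simulate` (`scenario`),
#' `data` (`occurrences` CSV path), `resample` (`n_replicates`,
#' `drop_singletons`), `infer` (`model` = `bdcs`/`rjmcmc`, `preservation`
#' = `hpp`/`nhpp`/`tpp`, `gamma`, `generations`, `sampling_interval`,
#' `min_dt`, `edge_window`, `window`), `post` (`severity` with `older`,
#' `younger`; `ltt`; `fold`). Unknown keys raise a schema error naming the
#' key.
#'
#' @param config Path to a YAML configuration file.
#' @return The output directory path, invisibly; outputs on disk.
#' @export
run_pipeline <- function(config) {
  cfg <- yaml::read_yaml(config)
  known <- c("seed", "out", "simulate", "data", "resample", "infer", "post")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key(s): ",
                        paste(bad, collapse = ", "))
  check_keys <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra)) stop("unknown configuration key(s) in ", where, ": ",
                            paste(extra, collapse = ", "))
  }
  check_keys(cfg$simulate, c("scenario", "phi"), "simulate")
  check_keys(cfg$data, "occurrences", "data")
  check_keys(cfg$resample, c("n_replicates", "drop_singletons"), "resample")
  check_keys(cfg$infer, c("model", "preservation", "gamma", "generations",
                          "sampling_interval", "min_dt", "edge_window",
                          "window"), "infer")
  check_keys(cfg$post, c("severity", "ltt", "fold"), "post")

  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- cfg$out %||% "fossildiv_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  inputs <- character(0)

  # --- data stage ---
  if (!is.null(cfg$simulate)) {
    sc <- simulate_scenario(cfg$simulate$scenario %||% "pulse",
                            seed = seed, phi = cfg$simulate$phi %||% 1)
    occ <- sc$occurrences
    occ_path <- file.path(out_dir, "occurrences.csv")
    write_occurrences(occ, occ_path)
    jsonlite::write_json(sc$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    window <- sc$truth$window
  } else if (!is.null(cfg$data)) {
    occ_path <- cfg$data$occurrences
    inputs <- c(inputs, occ_path)
    occ <- read_occurrences(occ_path)
    window <- NULL
  } else {
    stop("configuration needs a 'simulate' or 'data' section")
  }

  # --- resample ---
  n_rep <- cfg$resample$n_replicates %||% 10L
  series <- resample_ages(occ, n_rep, seed = seed + 1L)
  if (isTRUE(cfg$resample$drop_singletons)) {
    series <- lapply(series, function(s) suppressMessages(drop_singletons(s)))
  }

  # --- infer ---
  infer <- cfg$infer %||% list()
  window <- as.numeric(infer$window %||% window %||%
                         c(max(occ$max_age), min(occ$min_age)))
  mc <- mcmc_config(
    n_generations = infer$generations %||% 500000L,
    sampling_interval = infer$sampling_interval %||% 500L,
    min_dt = infer$min_dt %||% 2,
    edge_window = as.numeric(infer$edge_window %||% (window + c(-2, 2))),
    window = window)
  bins_in <- stage_bins(sort(unique(c(
    window, bin_edges(permo_triassic_bins())[
      bin_edges(permo_triassic_bins()) < window[1] &
        bin_edges(permo_triassic_bins()) > window[2]])),
    decreasing = TRUE))
  pm <- preservation_model(infer$preservation %||% "hpp", q = 1,
                           q_vector = rep(1, nrow(bins_in)), bins = bins_in,
                           gamma = isTRUE(infer$gamma))
  model <- infer$model %||% "rjmcmc"
  posts <- lapply(seq_along(series), function(r) {
    mc_r <- mc
    mc_r$seed <- seed + 100L + r
    if (model == "bdcs") run_bdcs(series[[r]], bins_in, pm, mc_r)
    else run_rjmcmc(series[[r]], pm, mc_r, bins_in)
  })
  grid <- posts[[1]]$grid
  lam <- do.call(rbind, lapply(posts, `[[`, "lambda"))
  mu <- do.call(rbind, lapply(posts, `[[`, "mu"))
  pooled <- posts[[1]]
  pooled$lambda <- lam
  pooled$mu <- mu
  rtt <- summarize_rates(pooled)
  utils::write.table(rtt, file.path(out_dir, "rates_through_time.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  lf <- lifespan_means(posts)
  utils::write.table(lf, file.path(out_dir, "lifespans.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  # --- post-process ---
  post <- cfg$post %||% list()
  if (!is.null(post$severity)) {
    ev <- event_window("event", post$severity$older, post$severity$younger)
    sv <- severity(lf, ev)
    utils::write.table(as.data.frame(sv[-1]),
                       file.path(out_dir, "severity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  if (isTRUE(post$ltt)) {
    reps <- lapply(posts, lifespan_estimates)
    ltt <- diversity_trajectory(reps, grid)
    utils::write.table(ltt, file.path(out_dir, "diversity.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  ess_summary <- do.call(rbind, lapply(seq_along(posts), function(r) {
    cbind(replicate = r, convergence_report(posts[[r]]))
  }))
  utils::write.table(ess_summary, file.path(out_dir, "ess.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  manifest <- list(
    config_file = normalizePath(config),
    config_md5 = unname(tools::md5sum(config)),
    seed = seed, package_version = as.character(utils::packageVersion("fossildiv")),
    input_digests = as.list(tools::md5sum(inputs)),
    n_replicates = n_rep, model = model,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    min_ess = min(ess_summary$ess, na.rm = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
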