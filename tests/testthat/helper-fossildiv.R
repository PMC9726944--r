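# shared builders for the test suite

toy_occurrences <- function() {
  occurrence_table(data.frame(
    occurrence_id = paste0("o", 1:6),
    taxon = c("Aus bus", "Aus bus", "Aus cus", "Dus eus", "Fam1", "Dus eus"),
    rank = c("species", "species", "species", "species", "family", "species"),
    genus = c("Aus", "Aus", "Aus", "Dus", NA, "Dus"),
    family = c("Aidae", "Aidae", "Aidae", "Didae", "Fam1", "Didae"),
    min_age = c(250, 248, 251, 249, 247, 246),
    max_age = c(252, 250, 254, 251, 249, 248),
    stringsAsFactors = FALSE))
}

quick_cfg <- function(window, seed = 1L, n_gen = 20000L, thin = 100L, ...) {
  mcmc_config(n_generations = n_gen, sampling_interval = thin,
              window = window,
              edge_window = window + c(-2, 2), seed = seed, ...)
}

# uniform synthetic "stage" bins inside a window
uniform_bins <- function(window, n = 10L) {
  stage_bins(seq(window[1], window[2], length.out = n + 1L))
}

expect_no_error <- function(expr) testthat::expect_error(expr, NA)
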