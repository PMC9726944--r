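#' Construct and validate an occurrence table
#'
#' An occurrence table holds one row per fossil occurrence: a specimen (or
#' set of specimens) from one stratigraphic horizon assigned to one taxon.
#' Ages are stratigraphic bounds in Ma before present (`max_age` is the
#' older bound). Validation enforces the table invariants: positive ages
#' with `max_age >= min_age`, non-empty taxon names, and a genus for every
#' species-rank row.
#'
#' @param df Data frame with columns `occurrence_id`, `taxon`, `rank`
#'   (one of `"species"`, `"genus"`, `"family"`), `min_age`, `max_age` and
#'   optionally `genus`, `family`, `clade`, `guild`, `extant`, `exclude`.
#' @return A validated data frame of class `occurrence_table`. Rows flagged
#'   in an `exclude` column (e.g. ichnotaxa or egg taxa) are dropped with a
#'   message.
#' @export
occurrence_table <- function(df) {
  req <- c("occurrence_id", "taxon", "rank", "min_age", "max_age")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("genus", "family", "clade", "guild")) {
    if (!col %in% names(df)) df[[col]] <- rep(NA_character_, nrow(df))
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & !nzchar(df[[col]])] <- NA_character_
  }
  if (!"extant" %in% names(df)) df$extant <- rep(FALSE, nrow(df))
  df$extant[is.na(df$extant)] <- FALSE
  if ("exclude" %in% names(df)) {
    drop <- !is.na(df$exclude) & as.logical(df$exclude)
    if (any(drop)) {
      message(sum(drop), " occurrence(s) dropped via the exclude flag")
      df <- df[!drop, , drop = FALSE]
    }
    df$exclude <- NULL
  }
  df$occurrence_id <- as.character(df$occurrence_id)
  df$taxon <- as.character(df$taxon)
  df$rank <- as.character(df$rank)
  df$min_age <- suppressWarnings(as.numeric(df$min_age))
  df$max_age <- suppressWarnings(as.numeric(df$max_age))

  bad_age <- !is.finite(df$min_age) | !is.finite(df$max_age) |
    df$min_age <= 0
  if (any(bad_age)) {
    stop("missing or invalid ages for occurrence(s): ",
         paste(df$occurrence_id[bad_age], collapse = ", "))
  }
  rev_age <- df$max_age < df$min_age
  if (any(rev_age)) {
    stop("max_age < min_age for occurrence(s): ",
         paste(df$occurrence_id[rev_age], collapse = ", "))
  }
  if (any(is.na(df$taxon) | !nzchar(df$taxon))) {
    stop("empty taxon name for occurrence(s): ",
         paste(df$occurrence_id[is.na(df$taxon) | !nzchar(df$taxon)],
               collapse = ", "))
  }
  bad_rank <- !df$rank %in% c("species", "genus", "family")
  if (any(bad_rank)) {
    stop("unknown rank for occurrence(s): ",
         paste(df$occurrence_id[bad_rank], collapse = ", "))
  }
  no_gen <- df$rank == "species" & is.na(df$genus)
  if (any(no_gen)) {
    stop("species-rank row(s) without a genus: ",
         paste(df$occurrence_id[no_gen], collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("occurrence_table", "data.frame")
  df
}

#' Read a fossil occurrence table from CSV
#'
#' Reads and validates a CSV of fossil occurrences (see [occurrence_table()]
#' for the column contract). If stage bins are supplied, every occurrence
#' interval must be covered by the binned window.
#'
#' @param path Path to a CSV file.
#' @param bins Optional [stage_bins()] object used to check age coverage.
#' @return An `occurrence_table`.
#' @examples
#' occ <- read_occurrences(system.file("extdata",
#'   "synthetic_occurrences.csv", package = "fossildiv"))
#' count_summary(occ)
#' @export
read_occurrences <- function(path, bins = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- occurrence_table(df)
  if (!is.null(bins)) {
    edges <- bin_edges(bins)
    out <- tab$max_age > edges[1] | tab$min_age < edges[length(edges)]
    if (any(out)) {
      stop("occurrence(s) outside the binned window: ",
           paste(tab$occurrence_id[out], collapse = ", "))
    }
  }
  tab
}

#' Write an occurrence table to CSV
#'
#' @param table An `occurrence_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Resample occurrence ages within their stratigraphic bounds
#'
#' Draws, for every occurrence, a point age uniformly between its minimum
#' and maximum stratigraphic age, producing replicate data sets that carry
#' the dating uncertainty through all downstream analyses.
#'
#' @param table An `occurrence_table`.
#' @param n_replicates Number of replicate data sets (>= 1).
#' @param seed Integer seed; the full replicate list is reproducible.
#' @return A list of `taxon_series` objects, one per replicate. Each maps
#'   taxon -> sorted (decreasing) point ages and records its replicate id.
#' @export
resample_ages <- function(table, n_replicates = 10L, seed = 1L) {
  stopifnot(inherits(table, "occurrence_table"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  set.seed(as.integer(seed))
  lapply(seq_len(n_replicates), function(r) {
    ages <- stats::runif(nrow(table), table$min_age, table$max_age)
    taxon_series(split(ages, table$taxon), replicate_id = r, seed = seed,
                 extant = tapply(table$extant, table$taxon, any))
  })
}

#' Construct a taxon series (one age-resampled replicate)
#'
#' @param ages Named list mapping taxon to a numeric vector of point ages
#'   (Ma); each taxon needs at least one age.
#' @param replicate_id Integer replicate index.
#' @param seed Seed the replicate was generated from (bookkeeping).
#' @param extant Optional named logical: taxa known to survive past the
#'   young edge of the study window (right-censored lifespans).
#' @return An object of class `taxon_series`.
#' @export
taxon_series <- function(ages, replicate_id = 1L, seed = NA_integer_,
                         extant = NULL) {
  if (!length(ages)) {
    ages <- list()
  } else {
    if (is.null(names(ages)) || any(!nzchar(names(ages)))) {
      stop("ages must be a named list (taxon -> ages)")
    }
    if (any(vapply(ages, length, 1L) < 1L)) stop("every taxon needs >= 1 age")
    ages <- lapply(ages, function(a) sort(as.numeric(a), decreasing = TRUE))
  }
  ext <- setNames(rep(FALSE, length(ages)), names(ages))
  if (!is.null(extant)) ext[names(extant)] <- as.logical(extant)
  structure(list(ages = ages, replicate_id = as.integer(replicate_id),
                 seed = seed, extant = ext),
            class = "taxon_series")
}

#' @export
print.taxon_series <- function(x, ...) {
  cat(sprintf("Taxon series (replicate %d): %d taxa, %d occurrences\n",
              x$replicate_id, length(x$ages),
              sum(vapply(x$ages, length, 1L))))
  invisible(x)
}

#' Remove singleton taxa from a taxon series
#'
#' Singletons (taxa known from exactly one occurrence) are a classical
#' sampling bias; removing them is a standard sensitivity analysis.
#'
#' @param series A `taxon_series`.
#' @return The filtered `taxon_series`, with attribute `n_removed`.
#' @export
drop_singletons <- function(series) {
  stopifnot(inherits(series, "taxon_series"))
  n <- vapply(series$ages, length, 1L)
  keep <- n > 1L
  removed <- sum(!keep)
  if (removed == length(series$ages) && removed > 0L) {
    warning("all taxa are singletons; series is empty after filtering")
  }
  out <- taxon_series(series$ages[keep], series$replicate_id, series$seed,
                      series$extant[keep])
  attr(out, "n_removed") <- removed
  message(removed, " singleton taxa removed")
  out
}

#' Aggregate an occurrence table to genus or family level
#'
#' Replaces the taxon identity of every occurrence by its genus or family.
#' Rows that cannot be resolved at the requested level but carry an identity
#' at a higher level are retained at that higher level (an occurrence with
#' an uncertain generic attribution but a known family is kept as a
#' family-level occurrence). Rows unresolvable at the requested or any
#' higher level are excluded with a diagnostic; the total occurrence count
#' is otherwise conserved.
#'
#' @param table An `occurrence_table`.
#' @param level `"genus"` or `"family"`.
#' @return An `occurrence_table` with attribute `excluded` (the dropped
#'   occurrence ids, possibly empty).
#' @export
aggregate_level <- function(table, level = c("genus", "family")) {
  stopifnot(inherits(table, "occurrence_table"))
  level <- match.arg(level)
  df <- as.data.frame(table)
  # genus identity: the genus column, or the taxon itself for genus-rank rows
  gid <- ifelse(df$rank == "genus" & is.na(df$genus), df$taxon, df$genus)
  fid <- ifelse(df$rank == "family" & is.na(df$family), df$taxon, df$family)
  if (level == "genus") {
    new_taxon <- gid
    new_rank <- rep("genus", nrow(df))
    fallback <- is.na(new_taxon) & !is.na(fid)
    new_taxon[fallback] <- fid[fallback]
    new_rank[fallback] <- "family"
  } else {
    new_taxon <- fid
    new_rank <- rep("family", nrow(df))
  }
  drop <- is.na(new_taxon)
  if (any(drop)) {
    message(sum(drop), " occurrence(s) unresolvable at the ", level,
            " level excluded: ",
            paste(df$occurrence_id[drop], collapse = ", "))
  }
  out <- df[!drop, , drop = FALSE]
  out$taxon <- new_taxon[!drop]
  out$rank <- new_rank[!drop]
  out$genus <- ifelse(out$rank == "genus", out$taxon, NA_character_)
  res <- occurrence_table(out)
  attr(res, "excluded") <- df$occurrence_id[drop]
  res
}

#' Summary counts of an occurrence table
#'
#' @param table An `occurrence_table`.
#' @return A list with `n_occurrences`, `n_species`, `n_genera`,
#'   `n_families` (distinct counts per rank; each occurrence counted once).
#' @export
count_summary <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  df <- as.data.frame(table)
  gid <- ifelse(df$rank == "genus" & is.na(df$genus), df$taxon, df$genus)
  fid <- ifelse(df$rank == "family" & is.na(df$family), df$taxon, df$family)
  list(n_occurrences = nrow(df),
       n_species = length(unique(df$taxon[df$rank == "species"])),
       n_genera = length(unique(gid[!is.na(gid)])),
       n_families = length(unique(fid[!is.na(fid)])))
}

#' Read a guild map from CSV
#'
#' @param path CSV with columns `taxon` and `guild`.
#' @return A `guild_map`: data frame mapping taxon to one of `herbivore`,
#'   `predator`, `generalist`, `detritivore_fungivore`, `unassigned`.
#' @export
read_guilds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  guild_map(df)
}

#' Construct a guild map
#'
#' @param df Data frame with columns `taxon`, `guild`.
#' @return A validated `guild_map` data frame.
#' @export
guild_map <- function(df) {
  if (!all(c("taxon", "guild") %in% names(df))) {
    stop("guild map needs columns taxon, guild")
  }
  valid <- c("herbivore", "predator", "generalist", "detritivore_fungivore",
             "unassigned")
  df$guild <- as.character(df$guild)
  df$guild[is.na(df$guild)] <- "unassigned"
  bad <- !df$guild %in% valid
  if (any(bad)) {
    stop("unknown guild label(s): ", paste(unique(df$guild[bad]), collapse = ", "))
  }
  out <- data.frame(taxon = as.character(df$taxon), guild = df$guild,
                    stringsAsFactors = FALSE)
  class(out) <- c("guild_map", "data.frame")
  out
}

#' Partition a taxon series by ecological guild
#'
#' Splits the assigned taxa of a series into guild-specific series. Under
#' the three-guild scheme, generalists and detritivores/fungivores are
#' merged into a single guild dubbed `"others"`. Unassigned taxa are
#' reported and excluded, never silently recoded.
#'
#' @param series A `taxon_series`.
#' @param guilds A `guild_map`.
#' @param scheme `"three"` (herbivores, predators, others) or `"four"`.
#' @return Named list mapping guild to `taxon_series`; attribute
#'   `unassigned` lists excluded taxa. Empty guilds are dropped with a
#'   warning.
#' @export
split_by_guild <- function(series, guilds, scheme = c("three", "four")) {
  stopifnot(inherits(series, "taxon_series"))
  scheme <- match.arg(scheme)
  g <- setNames(guilds$guild, guilds$taxon)
  taxa <- names(series$ages)
  lab <- unname(g[taxa])
  lab[is.na(lab)] <- "unassigned"
  if (scheme == "three") {
    lab[lab %in% c("generalist", "detritivore_fungivore")] <- "others"
  }
  unassigned <- taxa[lab == "unassigned"]
  if (length(unassigned)) {
    message(length(unassigned), " unassigned taxa excluded from guild split")
  }
  keep_lv <- if (scheme == "three") c("herbivore", "predator", "others") else
    c("herbivore", "predator", "generalist", "detritivore_fungivore")
  out <- list()
  for (lv in keep_lv) {
    tx <- taxa[lab == lv]
    if (!length(tx)) {
      warning("guild '", lv, "' is empty and omitted")
      next
    }
    out[[lv]] <- taxon_series(series$ages[tx], series$replicate_id,
                              series$seed, series$extant[tx])
  }
  attr(out, "unassigned") <- unassigned
  out
}
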