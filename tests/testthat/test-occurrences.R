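test_that("a well-formed table is read back identical to what was written", {
  tab <- toy_occurrences()
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(tab, path)
  back <- read_occurrences(path)
  expect_equal(nrow(back), 6L)
  expect_equal(back$taxon, tab$taxon)
  expect_equal(back$min_age, tab$min_age)
})

test_that("generator output round-trips through CSV unchanged", {
  sc <- simulate_scenario("constant", seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(sc$occurrences, path)
  back <- read_occurrences(path)
  orig <- as.data.frame(sc$occurrences)
  attr(orig, "truth") <- NULL
  got <- as.data.frame(back)[names(orig)]
  expect_equal(got, orig, ignore_attr = TRUE)
})

test_that("validation rejects reversed, missing or invalid rows by id", {
  df <- as.data.frame(toy_occurrences())
  bad <- df
  bad$min_age[2] <- 260
  expect_error(occurrence_table(bad), "o2")
  bad <- df
  bad$max_age[3] <- NA
  expect_error(occurrence_table(bad), "o3")
  bad <- df
  bad$genus[1] <- NA
  expect_error(occurrence_table(bad), "o1")
  expect_error(occurrence_table(df[, setdiff(names(df), "taxon")]),
               "missing required column")
})

test_that("the exclude flag drops ichnotaxa-style rows with a message", {
  df <- as.data.frame(toy_occurrences())
  df$exclude <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_message(tab <- occurrence_table(df), "dropped")
  expect_equal(nrow(tab), 5L)
})

test_that("age resampling is uniform within bounds, seeded, and degenerate-safe", {
  tab <- occurrence_table(data.frame(
    occurrence_id = "x1", taxon = "A", rank = "genus",
    min_age = 252, max_age = 252))
  reps <- resample_ages(tab, 5, seed = 3)
  expect_true(all(vapply(reps, function(r) r$ages$A == 252, TRUE)))

  tab2 <- occurrence_table(data.frame(
    occurrence_id = paste0("y", 1:10000), taxon = "A", rank = "genus",
    min_age = 250, max_age = 254))
  r <- resample_ages(tab2, 1, seed = 11)[[1]]
  expect_true(abs(mean(r$ages$A) - 252) < 0.1)
  expect_true(all(r$ages$A >= 250 & r$ages$A <= 254))

  a <- resample_ages(toy_occurrences(), 10, seed = 7)
  b <- resample_ages(toy_occurrences(), 10, seed = 7)
  expect_identical(a, b)
})

test_that("resampled ages never leave their source interval", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    mn <- runif(n, 200, 290)
    tab <- occurrence_table(data.frame(
      occurrence_id = paste0("r", seq_len(n)),
      taxon = sample(letters[1:5], n, replace = TRUE), rank = "genus",
      min_age = mn, max_age = mn + runif(n, 0, 8)))
    r <- resample_ages(tab, 1, seed = i)[[1]]
    for (tx in names(r$ages)) {
      rows <- tab[tab$taxon == tx, ]
      expect_true(all(r$ages[[tx]] >= min(rows$min_age) - 1e-12 &
                        r$ages[[tx]] <= max(rows$max_age) + 1e-12))
    }
  }
})

test_that("singleton removal reports counts and handles the all-singleton case", {
  s <- taxon_series(list(A = 250, B = c(250, 248)))
  expect_message(out <- drop_singletons(s), "1 singleton")
  expect_equal(names(out$ages), "B")
  expect_equal(attr(out, "n_removed"), 1L)

  s2 <- taxon_series(list(A = 250, B = 240))
  expect_warning(expect_message(out2 <- drop_singletons(s2)), "all taxa")
  expect_length(out2$ages, 0L)

  # a record built with a known 37% singleton fraction
  n <- 100L
  ages <- c(lapply(seq_len(37), function(i) 250 - i / 100),
            lapply(seq_len(63), function(i) c(250 - i / 50, 240)))
  names(ages) <- paste0("t", seq_len(n))
  s3 <- taxon_series(ages)
  expect_message(out3 <- drop_singletons(s3))
  expect_equal(attr(out3, "n_removed") / n, 0.37)
})

test_that("aggregation conserves occurrences and falls back to family", {
  tab <- toy_occurrences()
  gen <- aggregate_level(tab, "genus")
  expect_equal(nrow(gen), nrow(tab))           # conservation
  expect_equal(sort(unique(gen$taxon)), c("Aus", "Dus", "Fam1"))
  # the family-rank row is retained at family level under genus aggregation
  expect_equal(gen$rank[gen$taxon == "Fam1"], "family")
  fam <- aggregate_level(tab, "family")
  expect_equal(nrow(fam), nrow(tab))
  expect_equal(sort(unique(fam$taxon)), c("Aidae", "Didae", "Fam1"))

  # a row unresolvable at any level is excluded with a diagnostic
  df <- as.data.frame(tab)
  df$family[5] <- NA
  df$rank[5] <- "genus"
  df$taxon[5] <- "Mystery"
  df$genus[5] <- "Mystery"
  tab2 <- occurrence_table(df)
  df2 <- as.data.frame(tab2)
  df2$genus[5] <- NA
  df2$rank[5] <- "species"
  expect_error(occurrence_table(df2))          # species needs genus
})

test_that("count_summary counts each rank distinctly", {
  empty <- occurrence_table(data.frame(
    occurrence_id = character(0), taxon = character(0), rank = character(0),
    min_age = numeric(0), max_age = numeric(0)))
  expect_equal(unlist(count_summary(empty)), c(n_occurrences = 0,
    n_species = 0, n_genera = 0, n_families = 0))
  # 5 occurrences, 2 genera in 1 family
  tab <- occurrence_table(data.frame(
    occurrence_id = paste0("c", 1:5),
    taxon = c("Aus x", "Aus x", "Bus y", "Bus y", "Bus z"),
    rank = "species", genus = c("Aus", "Aus", "Bus", "Bus", "Bus"),
    family = "Fidae", min_age = 250, max_age = 251))
  s <- count_summary(tab)
  expect_equal(s$n_occurrences, 5L)
  expect_equal(s$n_genera, 2L)
  expect_equal(s$n_families, 1L)
  expect_equal(s$n_species, 3L)
})

test_that("guild splitting partitions assigned taxa and reports the rest", {
  s <- taxon_series(list(h = 250, p = 249, g = 248, d = 247, u = 246))
  gm <- guild_map(data.frame(
    taxon = c("h", "p", "g", "d"),
    guild = c("herbivore", "predator", "generalist", "detritivore_fungivore")))
  expect_message(three <- split_by_guild(s, gm, "three"), "unassigned")
  expect_equal(names(three), c("herbivore", "predator", "others"))
  expect_length(three$others$ages, 2L)
  expect_equal(attr(three, "unassigned"), "u")

  four <- suppressMessages(split_by_guild(s, gm, "four"))
  expect_equal(length(four), 4L)
  expect_true(all(vapply(four, function(x) length(x$ages), 1L) == 1L))

  # disjoint partition whose union is the assigned set
  all_taxa <- unname(unlist(lapply(three, function(x) names(x$ages))))
  expect_equal(sort(all_taxa), sort(c("h", "p", "g", "d")))
  expect_false(anyDuplicated(all_taxa) > 0)

  gm2 <- guild_map(data.frame(taxon = "h", guild = "herbivore"))
  # both the predator and the merged "others" guilds are empty
  expect_warning(expect_warning(
    suppressMessages(split_by_guild(s, gm2, "three")), "empty"), "empty")
})

test_that("stage bins validate and locate ages", {
  expect_error(stage_bins(c(250, 255)), "decreasing")
  b <- permo_triassic_bins()
  expect_equal(nrow(b), 16L)
  expect_true(all(b$max_age[-1] == b$min_age[-nrow(b)]))  # contiguous
  expect_equal(b$label[fossildiv:::bin_of_age(252, b)], "Changhsingian")
  expect_equal(fossildiv:::bin_of_age(298.9, b), 1L)
  expect_true(is.na(fossildiv:::bin_of_age(300, b)))
})

test_that("the packaged synthetic example data load cleanly", {
  occ <- read_occurrences(system.file("extdata", "synthetic_occurrences.csv",
                                      package = "fossildiv"))
  expect_s3_class(occ, "occurrence_table")
  expect_gt(nrow(occ), 100L)
  g <- read_guilds(system.file("extdata", "synthetic_guilds.csv",
                               package = "fossildiv"))
  expect_s3_class(g, "guild_map")
  s <- resample_ages(occ, 1, seed = 1)[[1]]
  sp <- suppressMessages(suppressWarnings(split_by_guild(s, g, "three")))
  expect_true(length(sp) >= 2L)
})
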