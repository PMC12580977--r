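toy_table <- function() {
  data.frame(
    species = c("PC 36:4", "PC 34:1", "PC 32:0",
                "PI 34:2", "PG 36:2", "PE 34:1"),
    class = c("PC", "PC", "PC", "PI", "PG", "PE"),
    ion_mode = c("positive", "positive", "positive",
                 "negative", "negative", "negative"),
    intensity = c(10, 5, 1, 80, 40, 8),
    sample = "mix",
    stringsAsFactors = FALSE)
}

test_that("group-max normalization gives the reference species exactly 1", {
  out <- normalize_by_group_max(toy_table())
  expect_equal(out$intensity[out$species == "PC 36:4"], 1)
  expect_equal(out$intensity[out$species == "PI 34:2"], 1)
  expect_equal(out$intensity[out$ion_mode == "positive"], c(1, 0.5, 0.1))
  # single species in a group
  one <- data.frame(species = "PA 34:1", class = "PA", ion_mode = "negative",
                    intensity = 7, sample = "s")
  expect_equal(normalize_by_group_max(one)$intensity, 1)
})

test_that("groups are normalized independently: within-group ratios survive, cross-group ratios do not", {
  tab <- toy_table()
  out <- normalize_by_group_max(tab)
  pos <- tab$ion_mode == "positive"
  expect_equal(out$intensity[pos] / out$intensity[pos][1],
               tab$intensity[pos] / tab$intensity[pos][1])
  # raw cross-group ratio PC 36:4 / PI 34:2 was 1/8; after normalization 1/1
  expect_false(isTRUE(all.equal(
    out$intensity[out$species == "PC 36:4"] /
      out$intensity[out$species == "PI 34:2"],
    tab$intensity[tab$species == "PC 36:4"] /
      tab$intensity[tab$species == "PI 34:2"])))
  # ordering by intensity preserved within each group
  for (g in c("positive", "negative")) {
    idx <- out$ion_mode == g
    expect_equal(order(out$intensity[idx]), order(tab$intensity[idx]))
  }
})

test_that("normalization is idempotent and per-group scale invariant", {
  out <- normalize_by_group_max(toy_table())
  expect_equal(normalize_by_group_max(out), out)
  scaled <- toy_table()
  scaled$intensity[scaled$ion_mode == "negative"] <-
    scaled$intensity[scaled$ion_mode == "negative"] * 37.5
  expect_equal(normalize_by_group_max(scaled)$intensity, out$intensity)
})

test_that("degenerate and malformed tables raise typed errors", {
  zero <- toy_table()
  zero$intensity[zero$ion_mode == "negative"] <- 0
  err <- tryCatch(normalize_by_group_max(zero), error = function(e) e)
  expect_s3_class(err, "laurdanGP_normalization_error")
  expect_match(conditionMessage(err), "negative")  # names the group
  neg <- toy_table(); neg$intensity[1] <- -1
  expect_error(normalize_by_group_max(neg), class = "laurdanGP_input_error")
  expect_error(normalize_by_group_max(toy_table()[, -4]),
               class = "laurdanGP_parse_error")
})

test_that("strict reference labels are enforced when provided", {
  refs <- c(positive = "PC 36:4", negative = "PI 34:2")
  expect_no_error(normalize_by_group_max(toy_table(), references = refs))
  swapped <- toy_table()
  swapped$intensity[swapped$species == "PG 36:2"] <- 500
  expect_error(normalize_by_group_max(swapped, references = refs),
               class = "laurdanGP_normalization_error")
})

test_that("two-table comparison surfaces depleted species", {
  start <- toy_table()
  disc <- toy_table()
  disc <- disc[disc$species != "PE 34:1", ]      # depleted in the disc
  disc$sample <- "disc"
  diffs <- abundance_difference(disc, start)
  pe <- diffs[diffs$species == "PE 34:1", ]
  expect_equal(pe$relative_a, 0)
  expect_equal(pe$difference, -0.1)              # 8 / 80 in the start mix
  # identical tables difference to zero
  same <- abundance_difference(start, start)
  expect_true(all(same$difference == 0))
})

test_that("species tables survive a TSV round trip", {
  path <- tempfile(fileext = ".tsv")
  write_species_table(toy_table(), path)
  back <- read_species_table(path)
  expect_equal(back$intensity, toy_table()$intensity)
  expect_equal(back$species, toy_table()$species)
  # provenance header present
  expect_match(readLines(path)[1], "^# laurdanGP")
})
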