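test_that("plot design validation enforces vocabularies and uniqueness", {
  d <- toy_design()
  out <- as_plot_design(d)
  expect_s3_class(out, "tbl_df")
  expect_equal(levels(out$climate), trait_vocab()$climate)

  bad <- d; bad$climate[1] <- "tropical"
  expect_error(as_plot_design(bad), "tropical",
               class = "traitpart_validation_error")
  dup <- d; dup$plot_id[2] <- dup$plot_id[1]
  expect_error(as_plot_design(dup), class = "traitpart_integrity_error")
  # removing every arid x all_herbivores plot empties a design cell
  gap <- d[!(d$climate == "arid" & d$treatment == "all_herbivores"), ]
  expect_error(as_plot_design(gap), "arid",
               class = "traitpart_validation_error")
})

test_that("abundance validation names the offending plot and species", {
  expect_error(
    as_abundance(toy_abundance(cover = c(50, 30, -1, 5))),
    "p1.*species c",
    class = "traitpart_validation_error"
  )
  dup <- dplyr::bind_rows(toy_abundance(), toy_abundance()[1, ])
  expect_error(as_abundance(dup), class = "traitpart_integrity_error")
})

test_that("trait table rejects duplicates and non-positive values", {
  tr <- tibble::tibble(species = "a", plot_id = "p1", trait = "SLA",
                       value = 10)
  expect_silent(as_trait_table(tr))
  expect_error(as_trait_table(dplyr::mutate(tr, value = 0)),
               class = "traitpart_validation_error")
  expect_error(as_trait_table(dplyr::bind_rows(tr, tr)),
               class = "traitpart_integrity_error")
  expect_error(as_trait_table(dplyr::mutate(tr, trait = "height")),
               class = "traitpart_validation_error")
  expect_error(as_trait_table(tr[, 1:3]), "value",
               class = "traitpart_schema_error")
})

test_that("pooled trait records equal the mean over occupied plots", {
  tr <- tibble::tibble(
    species = c("a", "a", "a", "b"),
    plot_id = c("p1", "p2", "p3", "p1"),
    trait = "SLA",
    value = c(10, 20, 30, 5)
  )
  ab <- tibble::tibble(plot_id = c("p1", "p2", "p3", "p1"),
                       species = c("a", "a", "a", "b"),
                       cover = c(10, 10, 0, 10))
  pooled <- add_pooled_traits(tr, ab)
  pa <- pooled$value[pooled$plot_id == "POOLED" & pooled$species == "a"]
  # plot p3 has zero cover for a, so only p1 and p2 count
  expect_equal(pa, mean(c(10, 20)))
  # without abundance information every measured plot counts
  pooled2 <- add_pooled_traits(tr)
  expect_equal(pooled2$value[pooled2$plot_id == "POOLED" &
                               pooled2$species == "a"], 20)
})

test_that("common-species filter retains the minimal cover-ranked prefix", {
  ab <- toy_abundance()                      # covers 50, 30, 15, 5
  out <- filter_common_species(ab, 0.9)
  expect_setequal(out$species, c("a", "b", "c"))  # cumulative 95%
  expect_equal(filter_common_species(ab, 1.0)$species, ab$species)
  one <- toy_abundance(species = "only", cover = 40)
  expect_equal(filter_common_species(one, 0.5)$species, "only")
  # boundary: two equal species, threshold exactly one species's share
  tie <- toy_abundance(species = c("x", "y"), cover = c(50, 50))
  expect_equal(filter_common_species(tie, 0.5)$species, "x")
})

test_that("filter is idempotent and per-plot relative", {
  set.seed(11)
  ab <- tibble::tibble(
    plot_id = rep(c("p1", "p2"), each = 6),
    species = rep(letters[1:6], 2),
    cover = c(runif(6, 0, 30), runif(6, 0, 3))  # very different totals
  )
  once <- filter_common_species(ab, 0.9)
  twice <- filter_common_species(once, 0.9)
  expect_equal(twice, once)
  # p2's small absolute covers survive because the rule is per-plot relative
  expect_true(any(once$plot_id == "p2"))
})

test_that("CSV round trip preserves values and reconciliation reports gaps", {
  com <- sim_community(sim_config(seed = 9))
  dir <- withr::local_tempdir()
  write_community_data(com, dir)
  back <- read_community_data(file.path(dir, "plots.csv"),
                              file.path(dir, "abundance.csv"),
                              file.path(dir, "traits.csv"))
  expect_equal(back$design, com$design)
  expect_equal(back$abundance, com$abundance)
  expect_equal(back$traits, com$traits)
  expect_equal(nrow(back$reconciliation), 0)

  # drop one species from traits -> reconciliation lists it
  tr2 <- com$traits[com$traits$species != "sp001", ]
  readr::write_csv(tr2, file.path(dir, "traits.csv"))
  back2 <- read_community_data(file.path(dir, "plots.csv"),
                               file.path(dir, "abundance.csv"),
                               file.path(dir, "traits.csv"))
  expect_equal(back2$reconciliation$species, "sp001")
  expect_equal(back2$reconciliation$issue, "no_traits")
})

test_that("YAML column mapping renames deposited-style columns", {
  com <- sim_community(sim_config(seed = 9))
  dir <- withr::local_tempdir()
  write_community_data(com, dir)
  ab <- readr::read_csv(file.path(dir, "abundance.csv"),
                        show_col_types = FALSE)
  names(ab) <- c("Plot", "Taxon", "PctCover")
  readr::write_csv(ab, file.path(dir, "abundance.csv"))
  yaml::write_yaml(
    list(abundance = list(plot_id = "Plot", species = "Taxon",
                          cover = "PctCover")),
    file.path(dir, "map.yml")
  )
  back <- read_community_data(file.path(dir, "plots.csv"),
                              file.path(dir, "abundance.csv"),
                              file.path(dir, "traits.csv"),
                              mapping = file.path(dir, "map.yml"))
  expect_equal(back$abundance, com$abundance)
})
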