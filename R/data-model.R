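#' Validate a plot-design table
#'
#' The experimental frame: one row per plot with its climate level, herbivore
#' treatment and block (site letter).  Factor labels must come from
#' [trait_vocab()]; every climate x treatment cell must contain at least one
#' plot and plot identifiers must be unique.
#'
#' @param x A data frame with columns `plot_id`, `climate`, `treatment`,
#'   `block`.
#' @return A validated tibble with `climate` and `treatment` as factors in
#'   canonical level order and `block` as a factor.
#' @export
as_plot_design <- function(x) {
  x <- require_columns(x, c("plot_id", "climate", "treatment", "block"),
                       "plot design")
  x <- as_tibble(x)
  x$plot_id <- as.character(x$plot_id)
  if (anyDuplicated(x$plot_id)) {
    dup <- unique(x$plot_id[duplicated(x$plot_id)])
    abort(paste0("Duplicate plot_id in plot design: ",
                 paste(dup, collapse = ", ")),
          class = "traitpart_integrity_error")
  }
  check_vocab(x$climate, climate_levels, "climate")
  check_vocab(x$treatment, treatment_levels, "treatment")
  x$climate <- factor(as.character(x$climate), levels = climate_levels)
  x$treatment <- factor(as.character(x$treatment), levels = treatment_levels)
  x$block <- factor(as.character(x$block))
  cells <- table(x$climate, x$treatment)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    lab <- paste(rownames(cells)[empty[, 1]], colnames(cells)[empty[, 2]],
                 sep = ":")
    abort(paste0("Empty climate x treatment cell(s): ",
                 paste(lab, collapse = ", ")),
          class = "traitpart_validation_error")
  }
  x[, c("plot_id", "climate", "treatment", "block")]
}

#' Validate a long abundance table
#'
#' Percent-cover abundances in long format, one row per plot x species.
#' Covers must be non-negative, each plot must have at least one positive
#' cover, and a plot x species pair may appear at most once.
#'
#' @param x A data frame with columns `plot_id`, `species`, `cover`.
#' @return A validated tibble.
#' @export
as_abundance <- function(x) {
  x <- require_columns(x, c("plot_id", "species", "cover"), "abundance")
  x <- as_tibble(x)
  x$plot_id <- as.character(x$plot_id)
  x$species <- as.character(x$species)
  x$cover <- as.numeric(x$cover)
  bad <- which(is.na(x$cover) | x$cover < 0)
  if (length(bad)) {
    abort(paste0("Negative or missing cover for plot ", x$plot_id[bad[1]],
                 ", species ", x$species[bad[1]]),
          class = "traitpart_validation_error")
  }
  key <- paste(x$plot_id, x$species, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), ]
    abort(paste0("Duplicate abundance record for plot ", d$plot_id[1],
                 ", species ", d$species[1]),
          class = "traitpart_integrity_error")
  }
  tot <- tapply(x$cover, x$plot_id, sum)
  if (any(tot <= 0)) {
    abort(paste0("Plot(s) with no positive cover: ",
                 paste(names(tot)[tot <= 0], collapse = ", ")),
          class = "traitpart_validation_error")
  }
  x[, c("plot_id", "species", "cover")]
}

#' Validate a long trait table
#'
#' Species trait values, either plot-specific (`plot_id` is a real plot) or
#' pooled across plots (`plot_id == "POOLED"`).  Values must be strictly
#' positive and each (species, plot, trait) may appear once.
#'
#' @param x A data frame with columns `species`, `plot_id`, `trait`, `value`.
#' @param traits Allowed trait names; defaults to the five study traits.
#' @return A validated tibble.
#' @export
as_trait_table <- function(x, traits = trait_names) {
  x <- require_columns(x, c("species", "plot_id", "trait", "value"),
                       "trait table")
  x <- as_tibble(x)
  x$species <- as.character(x$species)
  x$plot_id <- as.character(x$plot_id)
  x$trait <- as.character(x$trait)
  x$value <- as.numeric(x$value)
  check_vocab(x$trait, traits, "trait")
  bad <- which(is.na(x$value) | x$value <= 0)
  if (length(bad)) {
    abort(paste0("Non-positive trait value for species ", x$species[bad[1]],
                 ", plot ", x$plot_id[bad[1]], ", trait ", x$trait[bad[1]]),
          class = "traitpart_validation_error")
  }
  key <- paste(x$species, x$plot_id, x$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- x[duplicated(key), ]
    abort(paste0("Duplicate trait record: species ", d$species[1], ", plot ",
                 d$plot_id[1], ", trait ", d$trait[1]),
          class = "traitpart_integrity_error")
  }
  x[, c("species", "plot_id", "trait", "value")]
}

#' Add pooled ("fixed") trait records
#'
#' For every species x trait, the pooled value is the arithmetic mean of the
#' plot-specific values across all plots where the species occurs (has
#' positive cover, when an abundance table is supplied; otherwise across all
#' plots with a measurement).  Existing POOLED rows are replaced.
#'
#' @param traits A trait table (see [as_trait_table()]).
#' @param abundance Optional abundance table used to restrict the averaging
#'   to plots where the species actually occurs.
#' @return The trait table with one `plot_id = "POOLED"` row per
#'   species x trait appended.
#' @export
add_pooled_traits <- function(traits, abundance = NULL) {
  specific <- traits[traits$plot_id != "POOLED", ]
  if (!is.null(abundance)) {
    occ <- abundance[abundance$cover > 0, c("plot_id", "species")]
    specific <- inner_join(specific, occ, by = c("plot_id", "species"))
  }
  pooled <- specific |>
    group_by(.data$species, .data$trait) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    mutate(plot_id = "POOLED") |>
    select("species", "plot_id", "trait", "value")
  bind_rows(traits[traits$plot_id != "POOLED", ], pooled)
}

#' Read and validate the three community CSV files
#'
#' Reads plot design, abundance and trait CSVs in the canonical long formats
#' (comma-separated, UTF-8, header row, period decimal separator), validates
#' them, and reconciles species between the abundance and trait tables.  A
#' YAML mapping file can rename columns of externally deposited data to the
#' canonical names.
#'
#' @param plots,abundance,traits Paths to the three CSV files.
#' @param mapping Optional path to a YAML file with up to three top-level
#'   keys (`plots`, `abundance`, `traits`), each a map of
#'   `canonical_name: source_name` column renames.
#' @return A list of class `trait_community_data` with elements `design`,
#'   `abundance`, `traits` (validated tibbles) and `reconciliation`, a tibble
#'   listing species present in one table but absent from the other.
#' @export
read_community_data <- function(plots, abundance, traits, mapping = NULL) {
  map <- if (!is.null(mapping)) yaml::read_yaml(mapping) else list()
  rd <- function(path, key) {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    m <- map[[key]]
    if (!is.null(m)) {
      for (canon in names(m)) {
        if (!m[[canon]] %in% names(x)) {
          abort(paste0("Mapping for '", key, "' refers to missing column '",
                       m[[canon]], "'"), class = "traitpart_schema_error")
        }
        names(x)[names(x) == m[[canon]]] <- canon
      }
    }
    x
  }
  design <- as_plot_design(rd(plots, "plots"))
  ab <- as_abundance(rd(abundance, "abundance"))
  tr <- as_trait_table(rd(traits, "traits"))
  list_out <- list(
    design = design,
    abundance = ab,
    traits = tr,
    reconciliation = reconcile_species(ab, tr)
  )
  class(list_out) <- "trait_community_data"
  list_out
}

#' Reconcile species between abundance and trait tables
#'
#' @param abundance,traits Validated tibbles.
#' @return A tibble with columns `species` and `issue` (`"no_traits"` for
#'   species with cover but no trait record, `"no_abundance"` for the
#'   converse).  Zero rows when the two tables agree.
#' @export
reconcile_species <- function(abundance, traits) {
  ab_sp <- unique(abundance$species)
  tr_sp <- unique(traits$species)
  bind_rows(
    tibble(species = sort(setdiff(ab_sp, tr_sp)), issue = "no_traits"),
    tibble(species = sort(setdiff(tr_sp, ab_sp)), issue = "no_abundance")
  )
}

#' Write community tables as canonical CSVs
#'
#' @param community A list with `design`, `abundance`, `traits` (e.g. from
#'   [sim_community()] or [read_community_data()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_community_data <- function(community, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    plots = file.path(dir, "plots.csv"),
    abundance = file.path(dir, "abundance.csv"),
    traits = file.path(dir, "traits.csv")
  )
  readr::write_csv(community$design, paths["plots"], progress = FALSE)
  readr::write_csv(community$abundance, paths["abundance"], progress = FALSE)
  readr::write_csv(community$traits, paths["traits"], progress = FALSE)
  invisible(paths)
}

#' Retain the species making up a cover fraction of each plot
#'
#' Within each plot, species are ranked by cover (descending, ties broken by
#' species code) and the smallest prefix whose cumulative share of the plot's
#' total cover reaches `threshold` is retained; all other species are
#' dropped.  This is the common-species rule used throughout: downstream
#' dissimilarity and trait analyses consider only the species jointly making
#' up at least the threshold share of cover in each plot.
#'
#' Because filtering removes cover, re-evaluating the rule on its own
#' output against the reduced totals could drop further species; the
#' result therefore carries a `filtered_threshold` attribute and
#' re-applying the filter at the same threshold is a no-op, making the
#' operation idempotent.
#'
#' @param abundance A validated long abundance tibble.
#' @param threshold Fraction of each plot's total cover to retain, in (0, 1].
#' @return The filtered long abundance tibble, with attribute
#'   `filtered_threshold`.
#' @export
#' @examples
#' ab <- tibble::tibble(
#'   plot_id = "p1", species = c("a", "b", "c", "d"),
#'   cover = c(50, 30, 15, 5)
#' )
#' filter_common_species(ab, 0.9) # retains a, b, c
filter_common_species <- function(abundance, threshold = 0.9) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "traitpart_validation_error")
  }
  prior <- attr(abundance, "filtered_threshold")
  abundance <- as_abundance(abundance)
  if (!is.null(prior) && isTRUE(all.equal(prior, threshold))) {
    attr(abundance, "filtered_threshold") <- prior
    return(abundance)
  }
  out <- abundance |>
    group_by(.data$plot_id) |>
    arrange(dplyr::desc(.data$cover), .data$species, .by_group = TRUE) |>
    mutate(
      keep = cumsum(.data$cover) - .data$cover <
        threshold * sum(.data$cover) - 1e-12
    ) |>
    ungroup() |>
    filter(.data$keep) |>
    select(-"keep") |>
    arrange(.data$plot_id, .data$species)
  attr(out, "filtered_threshold") <- threshold
  out
}

# --- internal helpers -------------------------------------------------------

require_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(paste0("Missing column(s) in ", what, ": ",
                 paste(missing, collapse = ", ")),
          class = "traitpart_schema_error")
  }
  x
}

check_vocab <- function(values, allowed, what) {
  bad <- setdiff(unique(as.character(values)), allowed)
  if (length(bad)) {
    abort(paste0("Unknown ", what, " label(s): ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(allowed, collapse = ", "), ")"),
          class = "traitpart_validation_error")
  }
  invisible(values)
}
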