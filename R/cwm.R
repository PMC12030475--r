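#' Community-weighted mean of a trait for one plot
#'
#' CWM = sum over species of w_i * t_i, with w_i the species' share of the
#' summed cover over species that have a trait value.  Species lacking a
#' trait value are dropped from both the numerator and the weights; the
#' fraction of cover lost that way is reported.
#'
#' @param cover Non-negative cover values, one per species.
#' @param values Trait values aligned with `cover`; `NA` marks a missing
#'   value.
#' @param normalize If `TRUE` (default) weights are relative abundances; if
#'   `FALSE` the raw summed cover is used (sensitivity check; the value then
#'   scales with total cover).
#' @return The weighted mean, with attribute `coverage_loss` giving the
#'   fraction of total cover belonging to species without trait values.
#' @export
#' @examples
#' community_weighted_mean(c(50, 30, 20), c(10, 20, 30)) # 17
community_weighted_mean <- function(cover, values, normalize = TRUE) {
  stopifnot(length(cover) == length(values))
  if (any(cover < 0, na.rm = TRUE)) {
    abort("negative cover", class = "traitpart_validation_error")
  }
  ok <- !is.na(values) & cover > 0
  total <- sum(cover)
  if (!any(ok) || total <= 0) {
    abort("no species with both positive cover and a trait value",
          class = "traitpart_validation_error")
  }
  w <- cover[ok]
  if (normalize) w <- w / sum(w)
  out <- sum(w * values[ok])
  attr(out, "coverage_loss") <- 1 - sum(cover[ok]) / total
  out
}

#' Community-weighted means under specific, fixed and ITV conventions
#'
#' For every plot x trait computes the CWM from plot-specific trait values
#' (`specific`, total community trait expression), from pooled per-species
#' averages (`fixed`, the species-turnover component) and their difference
#' (`itv = specific - fixed`, computed by subtraction, never independently).
#'
#' @param abundance Long abundance tibble (validated by [as_abundance()]).
#' @param traits Long trait tibble with plot-specific rows and, optionally,
#'   `plot_id = "POOLED"` rows; pooled rows are derived with
#'   [add_pooled_traits()] when absent.
#' @param threshold Common-species cover threshold applied per plot before
#'   weighting (see [filter_common_species()]); `NULL` to skip filtering.
#' @param normalize Passed to [community_weighted_mean()].
#' @param trait_plot_map Optional tibble (`plot_id`, `trait_plot_id`)
#'   directing which plot's trait measurements feed each plot's specific
#'   CWM; defaults to the identity mapping.
#' @param warn_loss Warn when more than this fraction of a plot's cover
#'   belongs to species without trait values (default 0.2).
#' @return A tibble with columns `plot_id`, `trait`, `convention`
#'   (`"specific"`, `"fixed"`, `"itv"`), `value` and `coverage_loss`.  Plot x
#'   trait combinations with no trait data under a convention are omitted.
#' @export
cwm_table <- function(abundance, traits, threshold = 0.9, normalize = TRUE,
                      trait_plot_map = NULL, warn_loss = 0.2) {
  abundance <- as_abundance(abundance)
  traits <- as_trait_table(traits)
  if (!is.null(threshold)) {
    abundance <- filter_common_species(abundance, threshold)
  }
  if (!any(traits$plot_id == "POOLED")) {
    traits <- add_pooled_traits(traits, abundance)
  }
  specific_tr <- traits[traits$plot_id != "POOLED", ]
  pooled_tr <- traits[traits$plot_id == "POOLED",
                      c("species", "trait", "value")]

  ab <- abundance
  if (is.null(trait_plot_map)) {
    ab$trait_plot_id <- ab$plot_id
  } else {
    ab <- left_join(ab, trait_plot_map, by = "plot_id")
    if (any(is.na(ab$trait_plot_id))) {
      abort("trait_plot_map does not cover every plot",
            class = "traitpart_validation_error")
    }
  }

  all_traits <- unique(traits$trait)
  spec_val <- specific_tr |>
    rename(trait_plot_id = "plot_id", specific = "value")
  fix_val <- pooled_tr |> rename(fixed = "value")

  grid <- tidyr::expand_grid(
    ab[, c("plot_id", "species", "cover", "trait_plot_id")],
    trait = all_traits
  ) |>
    left_join(spec_val, by = c("species", "trait_plot_id", "trait")) |>
    left_join(fix_val, by = c("species", "trait"))

  one_conv <- function(df, col, convention) {
    df |>
      group_by(.data$plot_id, .data$trait) |>
      summarise(
        value = if (any(!is.na(.data[[col]]) & .data$cover > 0)) {
          as.numeric(community_weighted_mean(.data$cover, .data[[col]],
                                             normalize = normalize))
        } else NA_real_,
        coverage_loss = {
          ok <- !is.na(.data[[col]]) & .data$cover > 0
          1 - sum(.data$cover[ok]) / sum(.data$cover)
        },
        .groups = "drop"
      ) |>
      filter(!is.na(.data$value)) |>
      mutate(convention = convention)
  }
  spec_cwm <- one_conv(grid, "specific", "specific")
  fix_cwm <- one_conv(grid, "fixed", "fixed")
  itv <- inner_join(
    spec_cwm |> select("plot_id", "trait", specific = "value"),
    fix_cwm |> select("plot_id", "trait", fixed = "value",
                      "coverage_loss"),
    by = c("plot_id", "trait")
  ) |>
    mutate(value = .data$specific - .data$fixed, convention = "itv") |>
    select("plot_id", "trait", "value", "coverage_loss", "convention")

  out <- bind_rows(spec_cwm, fix_cwm, itv) |>
    select("plot_id", "trait", "convention", "value", "coverage_loss") |>
    arrange(.data$plot_id, .data$trait,
            match(.data$convention, c("specific", "fixed", "itv")))
  high <- out |> filter(.data$coverage_loss > warn_loss) |>
    distinct(.data$plot_id, .data$trait)
  if (nrow(high)) {
    warn(paste0("More than ", round(100 * warn_loss),
                "% cover lacks trait values for ", nrow(high),
                " plot x trait combination(s), e.g. plot ", high$plot_id[1],
                ", trait ", high$trait[1]))
  }
  out
}

#' Pivot a CWM table to one column per convention
#'
#' @param cwm A tibble from [cwm_table()].
#' @return A tibble with columns `plot_id`, `trait`, `specific`, `fixed`,
#'   `itv`.
#' @export
cwm_wide <- function(cwm) {
  tidyr::pivot_wider(cwm[, c("plot_id", "trait", "convention", "value")],
                     names_from = "convention", values_from = "value")
}
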