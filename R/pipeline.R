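#' Run the full analysis pipeline
#'
#' Executes, in order: common-species filter, CWM computation (specific,
#' fixed, ITV), functional-diversity indices, turnover/ITV variance
#' decomposition, Jaccard/ANOSIM dissimilarity tests, and AICc model
#' selection with marginal-means contrasts for every CWM and FD response.
#' Input is either a community object (from [sim_community()] or
#' [read_community_data()]) or a simulation config.
#'
#' @param community A `trait_community`/`trait_community_data` list with
#'   `design`, `abundance`, `traits`; `NULL` to simulate from `config`.
#' @param config A [sim_config()] used when `community` is `NULL`.
#' @param threshold Common-species cover threshold.
#' @param n_permutations,seed Permutation count and seed for the ANOSIM
#'   stage.
#' @param decompose_traits Traits to decompose; defaults to those with
#'   plot-specific measurements (traits available only as pooled records
#'   cannot separate turnover from ITV and are skipped).
#' @param out_dir If non-`NULL`, write every stage output as CSV/JSON under
#'   this directory.
#' @return An object of class `trait_pipeline`: list with `cwm`, `fd`,
#'   `decomposition`, `dissimilarity`, `anosim`, `selection` (per-response
#'   tidy tables), `contrasts`, and `manifest` (stage, rows, seconds,
#'   content hash, seed, package version).
#' @export
run_pipeline <- function(community = NULL, config = NULL, threshold = 0.9,
                         n_permutations = 999, seed = 1L,
                         decompose_traits = NULL, out_dir = NULL) {
  if (is.null(community)) {
    community <- sim_community(config %||% sim_config(seed = seed))
  }
  design <- as_plot_design(community$design)
  abundance <- as_abundance(community$abundance)
  traits <- as_trait_table(community$traits)

  manifest <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    manifest[[length(manifest) + 1]] <<- tibble(
      stage = name,
      rows = if (is.data.frame(res)) nrow(res) else NA_integer_,
      seconds = round(proc.time()[["elapsed"]] - t0, 3),
      hash = hash(res)
    )
    res
  }

  filtered <- stage("filter", filter_common_species(abundance, threshold))
  cwm <- stage("cwm", cwm_table(abundance, traits, threshold = threshold))
  fd <- stage("fd", fd_indices(abundance, traits, threshold = threshold))

  if (is.null(decompose_traits)) {
    specific_traits <- unique(traits$trait[traits$plot_id != "POOLED"])
    decompose_traits <- intersect(unique(cwm$trait), specific_traits)
  }
  decomposition <- stage("decomposition",
                         decompose_cwm(cwm, design,
                                       traits = decompose_traits))
  dissimilarity <- stage("dissimilarity",
                         jaccard_matrix(abundance, threshold))
  anosim <- stage("anosim",
                  run_study_anosims(abundance, design, threshold,
                                    n_permutations, seed))

  responses <- cwm_wide(cwm) |>
    select("plot_id", "trait", "specific") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "specific")
  fd_resp <- fd[, c("plot_id", "fric", "feve", "fdiv", "fdis")]
  model_data <- design |>
    inner_join(responses, by = "plot_id") |>
    inner_join(fd_resp, by = "plot_id")
  resp_cols <- setdiff(names(model_data),
                       c("plot_id", "climate", "treatment", "block"))
  selections <- list(); contrast_rows <- list(); fits <- list()
  selection <- stage("models", {
    for (resp in resp_cols) {
      if (anyNA(model_data[[resp]])) next
      sel <- fit_trait_models(model_data, resp)
      fits[[resp]] <- sel
      selections[[resp]] <- tidy(sel) |> mutate(response = resp, .before = 1)
      ct <- marginal_means_contrasts(sel)
      if (nrow(ct$contrasts)) {
        contrast_rows[[resp]] <- ct$contrasts |>
          mutate(response = resp, .before = 1)
      }
    }
    bind_rows(selections)
  })
  contrasts <- if (length(contrast_rows)) bind_rows(contrast_rows)
  else tibble()

  manifest_tbl <- bind_rows(manifest) |>
    mutate(seed = seed, package_version = as.character(
      utils::packageVersion("traitpart")))

  out <- structure(list(
    cwm = cwm, fd = fd, decomposition = decomposition,
    dissimilarity = dissimilarity, anosim = anosim,
    selection = selection, contrasts = contrasts, fits = fits,
    design = design, manifest = manifest_tbl
  ), class = "trait_pipeline")

  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

write_pipeline <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(x$cwm, file.path(dir, "cwm.csv"), progress = FALSE)
  readr::write_csv(x$fd, file.path(dir, "fd.csv"), progress = FALSE)
  readr::write_csv(tidy(x$decomposition),
                   file.path(dir, "decomposition.csv"), progress = FALSE)
  diss <- as.data.frame(x$dissimilarity)
  diss <- cbind(plot_id = rownames(diss), diss)
  readr::write_csv(diss, file.path(dir, "dissimilarity.csv"),
                   progress = FALSE)
  jsonlite::write_json(x$anosim, file.path(dir, "anosim.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  readr::write_csv(x$selection, file.path(dir, "selection.csv"),
                   progress = FALSE)
  if (nrow(x$contrasts)) {
    readr::write_csv(x$contrasts, file.path(dir, "contrasts.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.trait_pipeline <- function(x, ...) {
  cat("trait_pipeline:", nrow(x$design), "plots\n")
  print(x$manifest[, c("stage", "rows", "seconds")])
  invisible(x)
}
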