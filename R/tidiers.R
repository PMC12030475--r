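#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a decomposition into a publication-style contribution table
#'
#' One row per trait x term with the percentage contributions of species
#' turnover, ITV and their covariation to the total (specific) CWM sum of
#' squares.
#'
#' @param x A `cwm_decomposition`.
#' @param ... Unused.
#' @return A tibble: `trait`, `term`, `turnover_pct`, `itv_pct`, `cov_pct`,
#'   `total_pct`.
#' @export
tidy.cwm_decomposition <- function(x, ...) {
  x$table[, c("trait", "term", "turnover_pct", "itv_pct", "cov_pct",
              "total_pct")]
}

#' One-row summary per trait of a decomposition
#'
#' @param x A `cwm_decomposition`.
#' @param ... Unused.
#' @return A tibble with the total-row percentages per trait.
#' @export
glance.cwm_decomposition <- function(x, ...) {
  x$table |>
    filter(.data$term == "total") |>
    select("trait", "turnover_pct", "itv_pct", "cov_pct", "total_pct")
}

#' Tidy an ANOSIM result
#'
#' @param x A `trait_anosim`.
#' @param ... Unused.
#' @return A one-row tibble with `R`, `p`, `n_permutations`, `method`.
#' @export
tidy.trait_anosim <- function(x, ...) {
  tibble(R = x$R, p = x$p, n_permutations = x$n_permutations,
         method = x$method)
}

#' Tidy a model-selection result
#'
#' @param x A `trait_model_selection`.
#' @param ... Unused.
#' @return The per-candidate table: model, formula, k, logLik, AIC, AICc,
#'   delta_AICc, singular, converged, chosen.
#' @export
tidy.trait_model_selection <- function(x, ...) {
  x$table[, c("model", "formula", "transform", "k", "logLik", "AIC", "AICc",
              "delta_AICc", "singular", "converged", "chosen")]
}

#' One-row summary of a model selection
#'
#' @param x A `trait_model_selection`.
#' @param ... Unused.
#' @return A one-row tibble describing the chosen model.
#' @export
glance.trait_model_selection <- function(x, ...) {
  x$table |> filter(.data$chosen) |>
    select("model", "transform", "k", "logLik", "AICc") |>
    mutate(response = x$response, .before = 1)
}

#' Tidy the contrasts of a fitted trait model
#'
#' @param x A `trait_contrasts`.
#' @param ... Unused.
#' @return The contrast tibble (estimate, SE, df, adjusted p per pair).
#' @export
tidy.trait_contrasts <- function(x, ...) x$contrasts

#' @export
print.trait_anosim <- function(x, ...) {
  cat("ANOSIM: R =", format(x$R, digits = 4), ", p =",
      format(x$p, digits = 4), "(", x$method, ",", x$n_permutations,
      "permutations )\n")
  invisible(x)
}

#' @export
print.cwm_decomposition <- function(x, ...) {
  cat("CWM variance decomposition (% of total specific SS):\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
print.trait_model_selection <- function(x, ...) {
  cat("AICc model selection for", x$response, "- chosen:", x$chosen, "\n")
  print(x$table[, c("model", "k", "AICc", "delta_AICc", "singular",
                    "chosen")])
  invisible(x)
}
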