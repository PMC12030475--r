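#' Candidate mixed-model specifications for one response
#'
#' The five marginality-respecting fixed-effect structures — intercept only,
#' climate, treatment, climate + treatment, climate * treatment — each with
#' a random intercept for block (site letter).  Leaf-area and seed-mass
#' CWMs are modelled on the log scale (`transform = "auto"`), matching the
#' usual variance-stabilising treatment of these right-skewed traits.
#'
#' @param response Response column name (e.g. `"LA"`, `"feve"`).
#' @param transform `"auto"` (log for responses whose trait part is `LA` or
#'   `seed_mass`, identity otherwise), `"identity"` or `"log"`.
#' @return A tibble with columns `model` (label), `fixed` (list of fixed
#'   terms), `formula` (character) and `transform`.
#' @export
candidate_models <- function(response,
                             transform = c("auto", "identity", "log")) {
  transform <- match.arg(transform)
  if (transform == "auto") {
    transform <- if (grepl("^(LA|seed_mass)($|_)", response)) "log"
    else "identity"
  }
  fixed_sets <- list(
    intercept = character(0),
    climate = "climate",
    treatment = "treatment",
    additive = c("climate", "treatment"),
    interaction = c("climate", "treatment", "climate:treatment")
  )
  lhs <- if (transform == "log") paste0("log(`", response, "`)")
  else paste0("`", response, "`")
  tibble(
    model = names(fixed_sets),
    fixed = unname(fixed_sets),
    formula = vapply(fixed_sets, function(fx) {
      rhs <- if (length(fx)) paste(fx, collapse = " + ") else "1"
      paste0(lhs, " ~ ", rhs, " + (1 | block)")
    }, character(1)),
    transform = transform
  )
}

#' Small-sample corrected AIC
#'
#' AICc = AIC + 2k(k + 1) / (n - k - 1); converges to AIC as n grows.
#'
#' @param aic AIC value.
#' @param k Number of estimated parameters (fixed effects + random-effect
#'   variance + residual variance).
#' @param n Number of observations.
#' @return The corrected criterion (`Inf` when n <= k + 1).
#' @export
#' @examples
#' aicc(100, 3, 27) # 101.0435
aicc <- function(aic, k, n) {
  if (n <= k + 1) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the candidate set and select a model by AICc
#'
#' Fits every candidate by maximum likelihood (ML, not REML, so likelihoods
#' are comparable across fixed-effect structures), computes AICc, and
#' selects the minimum-AICc model — except that any model within 2 AICc
#' units of the minimum with fewer parameters supersedes it.  Singular
#' random-effect variances are flagged but the model is retained;
#' non-converging candidates are flagged and excluded.
#'
#' @param data Data frame with `climate`, `treatment`, `block` and the
#'   response column.
#' @param response Response column name.
#' @param transform Passed to [candidate_models()].
#' @return An object of class `trait_model_selection`: list with `table`
#'   (per-candidate k, logLik, AIC, AICc, delta, flags, chosen), `fits`
#'   (named list of `lmerMod` fits), `chosen`, `response`, `transform`.
#' @export
fit_trait_models <- function(data, response, transform = "auto") {
  data <- as.data.frame(data)
  if (!response %in% names(data)) {
    abort(paste0("response column '", response, "' not found"),
          class = "traitpart_schema_error")
  }
  if (anyNA(data[[response]])) {
    abort(paste0("missing values in response '", response, "'"),
          class = "traitpart_validation_error")
  }
  cand <- candidate_models(response, transform)
  if (cand$transform[1] == "log" && any(data[[response]] <= 0)) {
    bad <- data$plot_id[data[[response]] <= 0]
    abort(paste0("log transform requires positive response; offending ",
                 "plot(s): ", paste(bad, collapse = ", ")),
          class = "traitpart_validation_error")
  }
  n <- nrow(data)
  rows <- list(); fits <- list()
  for (i in seq_len(nrow(cand))) {
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(as.formula(cand$formula[i]),
                                      data = data, REML = FALSE)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      rows[[i]] <- tibble(model = cand$model[i], k = NA_integer_,
                          logLik = NA_real_, AIC = NA_real_, AICc = NA_real_,
                          singular = NA, converged = FALSE)
      next
    }
    k <- length(lme4::fixef(fit)) + 2L  # + RE variance + residual variance
    ll <- as.numeric(logLik(fit))
    a <- -2 * ll + 2 * k
    rows[[i]] <- tibble(
      model = cand$model[i], k = k, logLik = ll, AIC = a,
      AICc = aicc(a, k, n), singular = lme4::isSingular(fit),
      converged = TRUE
    )
    fits[[cand$model[i]]] <- fit
  }
  tab <- bind_rows(rows)
  tab <- left_join(cand[, c("model", "formula", "transform")], tab,
                   by = "model")
  usable <- tab[tab$converged %in% TRUE, ]
  if (nrow(usable) == 0) {
    abort("no candidate model converged", class = "traitpart_fit_error")
  }
  chosen <- select_by_aicc(usable)
  tab$delta_AICc <- tab$AICc - min(usable$AICc)
  tab$chosen <- tab$model == chosen
  structure(list(table = tab, fits = fits, chosen = chosen,
                 response = response, transform = cand$transform[1],
                 data = data),
            class = "trait_model_selection")
}

#' Apply the AICc tie rule to a candidate table
#'
#' The minimum-AICc model is chosen unless a model within 2 AICc units has
#' fewer parameters, in which case the fewest-parameter such model wins
#' (ties on k broken by AICc).
#'
#' @param tab A data frame with columns `model`, `AICc`, `k`.
#' @return The chosen model label.
#' @export
select_by_aicc <- function(tab) {
  near <- tab[tab$AICc - min(tab$AICc) < 2, ]
  near <- near[order(near$k, near$AICc), ]
  near$model[1]
}

#' Estimated marginal means and pairwise contrasts for the chosen model
#'
#' Marginal means per level of each fixed factor in the chosen model
#' (averaged over the other factor with equal weights) and all pairwise
#' contrasts within each factor; when the interaction is present the
#' contrasts are additionally computed within each level of the other
#' factor.  The chosen model is refitted by REML before inference (ML
#' variance estimates are biased low and would make the contrasts
#' anti-conservative; ML is only needed for the AICc comparison).
#' P-values use Satterthwaite degrees of freedom and a Tukey multiplicity
#' adjustment within each contrast family; means of log-transformed
#' responses are reported back-transformed.
#'
#' @param selection A `trait_model_selection` from [fit_trait_models()].
#' @param adjust Multiplicity adjustment passed to `emmeans::contrast()`.
#' @return An object of class `trait_contrasts`: list with `emmeans` and
#'   `contrasts` tibbles and the `response`.  Both are empty (zero rows)
#'   for an intercept-only chosen model.
#' @export
marginal_means_contrasts <- function(selection, adjust = "tukey") {
  stopifnot(inherits(selection, "trait_model_selection"))
  fit <- suppressMessages(
    update(selection$fits[[selection$chosen]], REML = TRUE)
  )
  fixed <- candidate_models(selection$response, selection$transform)
  fixed <- fixed$fixed[fixed$model == selection$chosen][[1]]
  factors <- intersect(c("climate", "treatment"), fixed)
  has_int <- "climate:treatment" %in% fixed
  em_rows <- list(); ct_rows <- list()
  for (f in factors) {
    other <- setdiff(factors, f)
    em <- emmeans::emmeans(fit, specs = f, lmer.df = "satterthwaite")
    em_rows[[f]] <- as_tibble(summary(em, type = "response")) |>
      mutate(factor = f, by = NA_character_, .before = 1)
    ct_rows[[f]] <- as_tibble(summary(
      emmeans::contrast(em, method = "pairwise", adjust = adjust)
    )) |>
      mutate(factor = f, by = NA_character_, .before = 1)
    if (has_int && length(other)) {
      emb <- emmeans::emmeans(fit, specs = f, by = other,
                              lmer.df = "satterthwaite")
      ct_rows[[paste(f, other, sep = "|")]] <- as_tibble(summary(
        emmeans::contrast(emb, method = "pairwise", adjust = adjust)
      )) |>
        mutate(factor = f, by = other,
               by_level = as.character(.data[[other]]), .before = 1) |>
        select(-dplyr::all_of(other))
    }
  }
  structure(list(
    emmeans = if (length(em_rows)) bind_rows(em_rows) else tibble(),
    contrasts = if (length(ct_rows)) bind_rows(ct_rows) else tibble(),
    response = selection$response,
    chosen = selection$chosen
  ), class = "trait_contrasts")
}
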