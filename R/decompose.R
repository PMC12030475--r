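#' Sequential (Type I) two-way sums of squares
#'
#' Fits `response ~ climate + treatment + climate:treatment` and returns the
#' sequential sums of squares in that order, plus residual and total rows.
#' With a balanced design the ordering is immaterial.
#'
#' @param data A data frame with columns `climate`, `treatment` and the
#'   response.
#' @param response Name of the response column.
#' @return A tibble with columns `term` (`climate`, `treatment`,
#'   `climate:treatment`, `residuals`, `total`), `df` and `ss`.  When some
#'   climate x treatment cell has no replication the interaction is
#'   confounded with the residual; the result carries attribute
#'   `interaction_confounded = TRUE`.
#' @export
two_way_ss <- function(data, response) {
  data <- as.data.frame(data)
  for (f in c("climate", "treatment")) {
    if (length(unique(data[[f]])) < 2) {
      abort(paste0("factor '", f, "' has fewer than 2 levels"),
            class = "traitpart_validation_error")
    }
  }
  if (anyNA(data[[response]])) {
    abort(paste0("missing response values in '", response, "'"),
          class = "traitpart_validation_error")
  }
  fml <- as.formula(paste0("`", response,
                           "` ~ climate + treatment + climate:treatment"))
  fit <- lm(fml, data = data)
  a <- anova(fit)
  terms_out <- c("climate", "treatment", "climate:treatment", "Residuals")
  ss <- setNames(a[["Sum Sq"]][match(terms_out, rownames(a))], terms_out)
  df <- setNames(a[["Df"]][match(terms_out, rownames(a))], terms_out)
  ss[is.na(ss)] <- 0
  df[is.na(df)] <- 0
  out <- tibble(
    term = c("climate", "treatment", "climate:treatment", "residuals",
             "total"),
    df = c(unname(df), sum(df)),
    ss = c(unname(ss), sum(ss))
  )
  attr(out, "interaction_confounded") <- df[["Residuals"]] == 0
  if (df[["Residuals"]] == 0) {
    warn("no within-cell replication: interaction confounded with residual")
  }
  out
}

#' Decompose CWM variation into turnover, ITV and covariation
#'
#' Runs the two-way ANOVA on each of the three CWM responses — specific
#' (total variation), fixed (species turnover) and ITV — and, per term,
#' computes the covariation as SS_specific - SS_fixed - SS_itv.  Relative
#' contributions are expressed as percentages of the specific ANOVA's total
#' sum of squares, the normalisation under which the rows and columns of the
#' contribution table are coherent.  A positive covariation means turnover
#' and intraspecific shifts select for the same trait values; negative means
#' they conflict.
#'
#' @param cwm A CWM table from [cwm_table()] containing all three
#'   conventions for the requested traits.
#' @param design A plot design (see [as_plot_design()]).
#' @param traits Traits to decompose; defaults to every trait having all
#'   three conventions.  Traits lacking plot-specific measurements (only
#'   POOLED records, so specific and ITV cannot be formed) are excluded.
#' @param mode `"anova"` for the plain decomposition or `"permutation"` to
#'   additionally compute term p-values by freely permuting each response
#'   across plots.
#' @param n_perm,seed Permutation count and seed for `mode = "permutation"`.
#' @return An object of class `cwm_decomposition`: a list with `table`
#'   (long tibble: trait, term, df and the four SS and four percentage
#'   columns), `pvalues` (tibble or `NULL`) and `mode`.  Use [tidy()] for a
#'   publication-shaped contribution table.
#' @export
decompose_cwm <- function(cwm, design, traits = NULL,
                          mode = c("anova", "permutation"),
                          n_perm = 999, seed = 1L) {
  mode <- match.arg(mode)
  design <- as_plot_design(design)
  wide <- cwm_wide(cwm)
  have_all <- !is.na(wide$specific) & !is.na(wide$fixed) & !is.na(wide$itv)
  wide <- wide[have_all, ]
  if (is.null(traits)) traits <- unique(wide$trait)
  missing_tr <- setdiff(traits, unique(wide$trait))
  if (length(missing_tr)) {
    abort(paste0("No complete specific/fixed/itv rows for trait(s): ",
                 paste(missing_tr, collapse = ", ")),
          class = "traitpart_validation_error")
  }

  res <- list(); pv <- list()
  for (tr in traits) {
    w <- wide[wide$trait == tr, ]
    plots_per_conv <- nrow(w)
    missing_plots <- setdiff(design$plot_id, w$plot_id)
    extra_plots <- setdiff(w$plot_id, design$plot_id)
    if (length(extra_plots)) {
      abort(paste0("CWM plots absent from design for trait ", tr, ": ",
                   paste(extra_plots, collapse = ", ")),
            class = "traitpart_validation_error")
    }
    if (length(missing_plots)) {
      abort(paste0("Plot sets differ between conventions/design for trait ",
                   tr, "; missing: ", paste(missing_plots, collapse = ", ")),
            class = "traitpart_validation_error")
    }
    dat <- inner_join(design, w, by = "plot_id")
    ss <- list(
      specific = two_way_ss(dat, "specific"),
      fixed = two_way_ss(dat, "fixed"),
      itv = two_way_ss(dat, "itv")
    )
    total_spec <- ss$specific$ss[ss$specific$term == "total"]
    tab <- tibble(
      trait = tr,
      term = ss$specific$term,
      df = ss$specific$df,
      ss_specific = ss$specific$ss,
      ss_turnover = ss$fixed$ss,
      ss_itv = ss$itv$ss,
      ss_cov = ss$specific$ss - ss$fixed$ss - ss$itv$ss
    ) |>
      mutate(
        turnover_pct = 100 * .data$ss_turnover / total_spec,
        itv_pct = 100 * .data$ss_itv / total_spec,
        cov_pct = 100 * .data$ss_cov / total_spec,
        total_pct = 100 * .data$ss_specific / total_spec
      )
    res[[tr]] <- tab
    if (mode == "permutation") {
      pv[[tr]] <- permute_term_pvalues(dat, tr, n_perm, seed)
    }
  }
  structure(list(
    table = bind_rows(res),
    pvalues = if (mode == "permutation") bind_rows(pv) else NULL,
    mode = mode
  ), class = "cwm_decomposition")
}

# Term p-values by freely permuting each response across plots; the test
# statistic is the term's sequential F.
permute_term_pvalues <- function(dat, tr, n_perm, seed) {
  set.seed(seed)
  terms3 <- c("climate", "treatment", "climate:treatment")
  out <- list()
  for (conv in c("specific", "fixed", "itv")) {
    obs <- term_f(dat, conv)
    exceed <- rep(0, 3)
    y <- dat[[conv]]
    for (b in seq_len(n_perm)) {
      dat[[conv]] <- sample(y)
      exceed <- exceed + (term_f(dat, conv) >= obs - 1e-12)
    }
    dat[[conv]] <- y
    out[[conv]] <- tibble(
      trait = tr, convention = conv, term = terms3,
      f = obs, p_perm = (1 + exceed) / (n_perm + 1)
    )
  }
  bind_rows(out)
}

term_f <- function(dat, response) {
  a <- anova(lm(as.formula(paste0("`", response,
                                  "` ~ climate + treatment + climate:treatment")),
                data = dat))
  ms <- a[["Sum Sq"]] / a[["Df"]]
  resid_ms <- ms[length(ms)]
  if (!is.finite(resid_ms) || resid_ms <= 0) resid_ms <- NA_real_
  (ms / resid_ms)[seq_len(3)]
}
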