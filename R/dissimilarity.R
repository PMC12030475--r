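#' Jaccard dissimilarity between plots
#'
#' Applies the common-species filter, binarises the retained covers to
#' presence/absence, and computes d(i, j) = 1 - |S_i intersect S_j| /
#' |S_i union S_j| for every pair of plots.
#'
#' @param abundance Long abundance tibble.
#' @param threshold Common-species cover threshold (`NULL` to skip
#'   filtering).
#' @return A symmetric plot x plot matrix with zero diagonal.
#' @export
#' @examples
#' ab <- tibble::tibble(
#'   plot_id = rep(c("p1", "p2"), each = 3),
#'   species = c("A", "B", "C", "B", "C", "D"),
#'   cover = 10
#' )
#' jaccard_matrix(ab, threshold = NULL) # off-diagonal 0.5
jaccard_matrix <- function(abundance, threshold = 0.9) {
  abundance <- as_abundance(abundance)
  if (!is.null(threshold)) {
    abundance <- filter_common_species(abundance, threshold)
  }
  abundance <- abundance[abundance$cover > 0, ]
  sets <- split(abundance$species, abundance$plot_id)
  if (any(lengths(sets) == 0)) {
    abort(paste0("plot(s) with empty retained species set: ",
                 paste(names(sets)[lengths(sets) == 0], collapse = ", ")),
          class = "traitpart_validation_error")
  }
  plots <- names(sets)
  n <- length(plots)
  m <- matrix(0, n, n, dimnames = list(plots, plots))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      m[i, j] <- m[j, i] <- 1 - inter / uni
    }
  }
  m
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test comparing between-group and within-group
#' community dissimilarities.  All off-diagonal dissimilarities are ranked
#' (mid-ranks for ties) and R = (mean between-group rank - mean within-group
#' rank) / (M / 2) with M = n(n-1)/2; R near 1 means groups are completely
#' dissimilar.  Significance comes from permuting group labels: exhaustively
#' when the number of distinct label arrangements is at most `exact_limit`,
#' otherwise by `n_permutations` random permutations.
#'
#' @param d Symmetric dissimilarity matrix (or `dist`).
#' @param grouping Factor-like vector of group labels, one per row of `d`.
#' @param n_permutations Random permutations when exhaustive enumeration is
#'   not used.
#' @param seed Seed for the random permutations.
#' @param exact_limit Enumerate all distinct arrangements when their count
#'   is at most this value.
#' @return An object of class `trait_anosim` with elements `R`, `p`,
#'   `n_permutations`, `method` (`"exact"` or `"sampled"`), `grouping` and
#'   `seed`.
#' @export
anosim_test <- function(d, grouping, n_permutations = 999, seed = 1L,
                        exact_limit = 10000) {
  d <- as.matrix(d)
  n <- nrow(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) {
    abort("grouping length must match the dissimilarity matrix",
          class = "traitpart_validation_error")
  }
  sizes <- table(grouping)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("need at least 2 groups, each with at least 2 members",
          class = "traitpart_validation_error")
  }
  pair_i <- row(d)[lower.tri(d)]
  pair_j <- col(d)[lower.tri(d)]
  dv <- d[lower.tri(d)]
  if (diff(range(dv)) < 1e-15) {
    warn("constant dissimilarities; R = 0")
    return(structure(list(R = 0, p = 1, n_permutations = 0,
                          method = "degenerate", grouping = grouping,
                          seed = seed), class = "trait_anosim"))
  }
  r <- rank(dv)  # mid-ranks for ties
  m <- length(dv)
  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (m / 2)
  }
  obs <- r_stat(grouping)

  n_arrange <- multinomial_count(sizes)
  if (!is.na(n_arrange) && n_arrange <= exact_limit) {
    perms <- enumerate_group_assignments(as.integer(sizes))
    labs <- levels(grouping)
    stats <- vapply(perms, function(a) r_stat(labs[a]), numeric(1))
    p <- mean(stats >= obs - 1e-12)
    method <- "exact"
    n_used <- length(perms)
  } else {
    set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_permutations)) {
      if (r_stat(sample(grouping)) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- (1 + cnt) / (n_permutations + 1)
    method <- "sampled"
    n_used <- n_permutations
  }
  structure(list(R = obs, p = p, n_permutations = n_used, method = method,
                 grouping = grouping, seed = seed),
            class = "trait_anosim")
}

#' The study's four ANOSIM analyses
#'
#' One test grouping all plots by climate, and one test per climate grouping
#' its plots by herbivore treatment.
#'
#' @param abundance Long abundance tibble.
#' @param design Plot design (see [as_plot_design()]).
#' @param threshold Common-species cover threshold for [jaccard_matrix()].
#' @param n_permutations,seed Passed to [anosim_test()].
#' @return A tibble with one row per analysis: `scope`, `grouping`, `R`,
#'   `p`, `n_permutations`, `method`.
#' @export
run_study_anosims <- function(abundance, design, threshold = 0.9,
                              n_permutations = 999, seed = 1L) {
  design <- as_plot_design(design)
  d <- jaccard_matrix(abundance, threshold)
  design <- design[match(rownames(d), design$plot_id), ]
  if (anyNA(design$plot_id)) {
    abort("abundance contains plots absent from the design",
          class = "traitpart_validation_error")
  }
  res <- list(tidy_anosim(
    anosim_test(d, design$climate, n_permutations, seed),
    scope = "all_plots", grouping = "climate"
  ))
  for (cl in levels(design$climate)) {
    idx <- which(design$climate == cl)
    res[[length(res) + 1]] <- tidy_anosim(
      anosim_test(d[idx, idx], design$treatment[idx], n_permutations, seed),
      scope = cl, grouping = "treatment"
    )
  }
  bind_rows(res)
}

tidy_anosim <- function(x, scope, grouping) {
  tibble(scope = scope, grouping = grouping, R = x$R, p = x$p,
         n_permutations = x$n_permutations, method = x$method)
}

multinomial_count <- function(sizes) {
  lv <- lgamma(sum(sizes) + 1) - sum(lgamma(sizes + 1))
  if (lv > log(.Machine$integer.max) + 10) return(NA_real_)
  round(exp(lv))
}

# All distinct assignments of group ids (1..k with given sizes) to n
# positions, as a list of integer vectors.
enumerate_group_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list(integer(n))
  open <- list(seq_len(n))
  for (g in seq_along(sizes)[-length(sizes)]) {
    nxt_out <- list(); nxt_open <- list()
    for (s in seq_along(out)) {
      pos <- open[[s]]
      picks <- combn(length(pos), sizes[g])
      for (cc in seq_len(ncol(picks))) {
        a <- out[[s]]
        a[pos[picks[, cc]]] <- g
        nxt_out[[length(nxt_out) + 1]] <- a
        nxt_open[[length(nxt_open) + 1]] <- pos[-picks[, cc]]
      }
    }
    out <- nxt_out; open <- nxt_open
  }
  k <- length(sizes)
  lapply(seq_along(out), function(s) {
    a <- out[[s]]
    a[open[[s]]] <- k
    a
  })
}
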