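#' Build a functional trait space for one community
#'
#' Places the community's species in a d-dimensional coordinate space and
#' attaches relative-abundance weights.  The default path computes
#' range-normalised Gower dissimilarities among species and embeds them by
#' principal coordinates with the Cailliez additive correction for negative
#' eigenvalues, retaining at most `min(S - 1, number of traits)` axes.  The
#' alternative path uses the (optionally z-scored) trait matrix directly
#' with Euclidean geometry.
#'
#' @param traits Numeric matrix of species (rows) x traits (columns); no
#'   missing entries.
#' @param weights Non-negative abundance weights, one per species; they are
#'   normalised to sum to 1.
#' @param geometry `"gower_pcoa"` (default) or `"euclidean"`.
#' @param standardize For the Euclidean path, z-score each trait first
#'   (default `TRUE`; the Gower path range-normalises by construction).
#' @return A list of class `trait_space`: `points` (species x axes
#'   coordinate matrix), `weights`, `geometry`, `axes_used`, `degenerate`
#'   (all species functionally identical) and `provenance`.
#' @export
trait_space <- function(traits, weights = NULL,
                        geometry = c("gower_pcoa", "euclidean"),
                        standardize = TRUE) {
  geometry <- match.arg(geometry)
  traits <- as.matrix(traits)
  if (nrow(traits) == 0 || anyNA(traits)) {
    abort("trait matrix must be non-empty with no missing entries",
          class = "traitpart_validation_error")
  }
  s <- nrow(traits)
  if (is.null(weights)) weights <- rep(1, s)
  if (length(weights) != s || any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be non-negative with positive total",
          class = "traitpart_validation_error")
  }
  weights <- weights / sum(weights)

  if (geometry == "euclidean") {
    pts <- traits
    if (standardize) {
      sds <- apply(pts, 2, sd)
      keep <- sds > 0
      pts <- scale(pts[, keep, drop = FALSE])
      attr(pts, "scaled:center") <- NULL
      attr(pts, "scaled:scale") <- NULL
    }
    degenerate <- nrow(pts) > 0 &&
      (ncol(pts) == 0 || all(dist(pts) < 1e-12))
    return(structure(list(
      points = pts, weights = weights, geometry = geometry,
      axes_used = ncol(pts), degenerate = degenerate,
      provenance = list(distance = "euclidean",
                        standardized = standardize)
    ), class = "trait_space"))
  }

  d <- gower_dist(traits)
  if (s == 1) {
    pts <- matrix(0, 1, 1, dimnames = list(rownames(traits), NULL))
    return(structure(list(points = pts, weights = weights,
                          geometry = geometry, axes_used = 1L,
                          degenerate = TRUE,
                          provenance = list(distance = "gower")),
                     class = "trait_space"))
  }
  if (all(d < 1e-12)) {
    pts <- matrix(0, s, 1, dimnames = list(rownames(traits), NULL))
    return(structure(list(points = pts, weights = weights,
                          geometry = geometry, axes_used = 1L,
                          degenerate = TRUE,
                          provenance = list(distance = "gower")),
                     class = "trait_space"))
  }
  k <- min(s - 1, ncol(traits))
  pts <- suppressWarnings(cmdscale(d, k = k, add = TRUE)$points)
  rownames(pts) <- rownames(traits)
  structure(list(
    points = pts, weights = weights, geometry = geometry,
    axes_used = ncol(pts), degenerate = FALSE,
    provenance = list(distance = "gower", embedding = "pcoa_cailliez",
                      axes_requested = k)
  ), class = "trait_space")
}

#' Range-normalised Gower dissimilarity between species
#'
#' For quantitative traits the Gower dissimilarity is the mean over traits
#' of |x_i - x_j| / range(trait); traits with zero range carry no
#' information and are excluded from the mean.
#'
#' @param traits Numeric species x trait matrix.
#' @return A `dist` object.
#' @export
gower_dist <- function(traits) {
  traits <- as.matrix(traits)
  rng <- apply(traits, 2, function(v) diff(range(v)))
  use <- rng > 0
  if (!any(use)) {
    return(stats::as.dist(matrix(0, nrow(traits), nrow(traits))))
  }
  scaled <- sweep(traits[, use, drop = FALSE], 2, rng[use], "/")
  stats::dist(scaled, method = "manhattan") / sum(use)
}
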