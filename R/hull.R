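# Exact convex-hull volume and vertex identification in arbitrary (small)
# dimension, by enumeration of supporting hyperplanes.  Intended for the
# species counts found in vegetation plots (tens of points, <= 5-6 axes);
# complexity is choose(n, d) * n per call.

#' Convex-hull volume of a point cloud
#'
#' Computes the d-dimensional volume of the convex hull of `x` exactly, by
#' decomposing the hull into pyramids over its facets; facet measures are
#' obtained recursively (shoelace formula in 2-D, interval length in 1-D).
#'
#' @param x Numeric matrix, points in rows.
#' @param tol Relative tolerance for coplanarity tests.
#' @return The hull volume, or `NA` with attribute `reason` when the points
#'   do not span the space (fewer than d + 1 points, or affinely dependent).
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' hull_volume(sq) # 1
hull_volume <- function(x, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n == 0 || d == 0) return(undefined_value("no points"))
  if (d == 1) return(max(x) - min(x))
  if (n <= d) return(undefined_value("fewer points than dimension + 1"))
  scale <- max(1, max(abs(x)))
  ctr <- colMeans(x)
  if (qr(sweep(x, 2, ctr), tol = 1e-12)$rank < d) {
    return(undefined_value("points affinely dependent"))
  }
  if (d == 2) return(shoelace_area(x))
  facets <- hull_facets(x, tol * scale)
  vol <- 0
  for (f in facets) {
    h <- abs(sum(f$normal * ctr) - f$offset)
    pts <- x[f$idx, , drop = FALSE]
    area <- facet_measure(pts, tol)
    vol <- vol + area * h / d
  }
  vol
}

#' Indices of the convex-hull vertices of a point cloud
#'
#' @inheritParams hull_volume
#' @return Integer vector of row indices of `x` that are hull vertices, or
#'   `NA` with a `reason` attribute for degenerate input.
#' @export
hull_vertices <- function(x, tol = 1e-9) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n == 0 || d == 0) return(undefined_value("no points"))
  if (d == 1) return(sort(unique(c(which.min(x[, 1]), which.max(x[, 1])))))
  scale <- max(1, max(abs(x)))
  ctr <- colMeans(x)
  if (qr(sweep(x, 2, ctr), tol = 1e-12)$rank < d || n <= d) {
    return(undefined_value("points do not span the space"))
  }
  if (d == 2) return(sort(grDevices::chull(x[, 1], x[, 2])))
  facets <- hull_facets(x, tol * scale)
  verts <- integer(0)
  for (f in facets) {
    pts <- x[f$idx, , drop = FALSE]
    sub <- facet_vertices(pts, tol)
    verts <- c(verts, f$idx[sub])
  }
  sort(unique(verts))
}

undefined_value <- function(reason) {
  structure(NA_real_, reason = reason)
}

shoelace_area <- function(x) {
  h <- grDevices::chull(x[, 1], x[, 2])
  px <- x[h, 1]; py <- x[h, 2]
  abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
}

# Enumerate the supporting hyperplanes (facet-defining) of conv(x), d >= 3.
# Returns a list of (normal, offset, idx) with idx the points on the plane.
hull_facets <- function(x, tol_abs) {
  n <- nrow(x); d <- ncol(x)
  subsets <- combn(n, d)
  seen <- character(0)
  facets <- list()
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    P <- x[idx, , drop = FALSE]
    M <- sweep(P[-1, , drop = FALSE], 2, P[1, ])
    qrM <- qr(t(M), tol = 1e-12)
    if (qrM$rank != d - 1) next  # degenerate subset
    Q <- qr.Q(qrM, complete = TRUE)
    nrm <- Q[, d]
    off <- sum(nrm * P[1, ])
    side <- x %*% nrm - off
    if (all(side <= tol_abs)) {
      # keep orientation
    } else if (all(side >= -tol_abs)) {
      nrm <- -nrm; off <- -off; side <- -side
    } else {
      next
    }
    key <- paste(round(c(nrm, off) / max(1, abs(off), max(abs(nrm))), 7),
                 collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    facets[[length(facets) + 1]] <-
      list(normal = nrm, offset = off, idx = which(abs(side) <= tol_abs))
  }
  facets
}

# (d-1)-measure of a facet's point set, computed in an orthonormal basis of
# the facet's hyperplane.
facet_measure <- function(pts, tol) {
  proj <- project_to_affine_hull(pts)
  if (ncol(proj) == 0) return(0)
  v <- hull_volume(proj, tol)
  if (is.na(v)) 0 else v
}

facet_vertices <- function(pts, tol) {
  proj <- project_to_affine_hull(pts)
  if (ncol(proj) == 0) return(seq_len(nrow(pts))[1])
  v <- hull_vertices(proj, tol)
  if (anyNA(v)) seq_len(nrow(pts)) else v
}

# Coordinates of pts in an orthonormal basis of their affine hull.
project_to_affine_hull <- function(pts) {
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  sv <- svd(cpts)
  r <- sum(sv$d > 1e-10 * max(sv$d, 1))
  cpts %*% sv$v[, seq_len(r), drop = FALSE]
}
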