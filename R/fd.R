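#' Functional richness: convex-hull volume of the trait space
#'
#' The volume of the convex hull of the community's species coordinates
#' (abundance-free).  Undefined — flagged, not fabricated — when the number
#' of species is at most the number of axes or the points are affinely
#' dependent; a true point-community (all species functionally identical)
#' has FRic 0.
#'
#' @param space A [trait_space()].
#' @return Hull volume (>= 0), or `NA` with attribute `reason`.
#' @export
fd_fric <- function(space) {
  stopifnot(inherits(space, "trait_space"))
  if (space$degenerate) return(0)
  hull_volume(space$points)
}

#' Functional evenness: regularity of abundance along the trait-space MST
#'
#' Branches of the minimum spanning tree joining species i and j are
#' weighted EW = dist(i, j) / (w_i + w_j) and normalised to PEW = EW / sum
#' EW; FEve = (sum min(PEW, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1)).  Perfectly
#' regular spacing and abundance gives 1.
#'
#' @param space A [trait_space()].
#' @return Value in \[0, 1\], or `NA` with attribute `reason` when S < 3 or
#'   the space is degenerate.
#' @export
fd_feve <- function(space) {
  stopifnot(inherits(space, "trait_space"))
  s <- nrow(space$points)
  if (s < 3) return(undefined_value("fewer than 3 species"))
  if (space$degenerate) return(undefined_value("degenerate trait space"))
  d <- as.matrix(dist(space$points))
  edges <- mst_edges(d)
  ew <- d[edges] / (space$weights[edges[, 1]] + space$weights[edges[, 2]])
  if (sum(ew) <= 0) return(undefined_value("all MST branches zero"))
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional divergence: abundance-weighted spread from the hull centre
#'
#' With G the centroid of the convex-hull vertices, dG_i the distance of
#' species i to G and d-bar their unweighted mean, FDiv =
#' (sum w_i (dG_i - d-bar) + d-bar) / (sum w_i |dG_i - d-bar| + d-bar).
#' Communities whose abundant species sit far from the centre approach 1.
#'
#' @param space A [trait_space()].
#' @return Value in \[0, 1\], or `NA` with attribute `reason` when the hull
#'   (hence its vertex set) is undefined.
#' @export
fd_fdiv <- function(space) {
  stopifnot(inherits(space, "trait_space"))
  if (space$degenerate) return(undefined_value("degenerate trait space"))
  v <- hull_vertices(space$points)
  if (anyNA(v)) return(undefined_value(attr(v, "reason")))
  g <- colMeans(space$points[v, , drop = FALSE])
  dg <- sqrt(colSums((t(space$points) - g)^2))
  dbar <- mean(dg)
  if (dbar <= 0) return(undefined_value("all species at the hull centre"))
  dd <- sum(space$weights * (dg - dbar))
  dabs <- sum(space$weights * abs(dg - dbar))
  (dd + dbar) / (dabs + dbar)
}

#' Functional dispersion: weighted mean distance to the weighted centroid
#'
#' FDis = sum w_i dist(x_i, c) with c = sum w_i x_i, the abundance-weighted
#' centroid.  Zero iff all abundance-bearing species coincide.
#'
#' @param space A [trait_space()].
#' @return Value >= 0.
#' @export
fd_fdis <- function(space) {
  stopifnot(inherits(space, "trait_space"))
  ctr <- colSums(space$points * space$weights)
  sum(space$weights * sqrt(colSums((t(space$points) - ctr)^2)))
}

#' Functional diversity indices per plot
#'
#' Applies the common-species filter, builds a trait space per plot from the
#' chosen trait convention, and computes FRic, FEve, FDiv and FDis.
#' Species missing any trait value for a plot are excluded from that plot's
#' space.
#'
#' @param abundance Long abundance tibble.
#' @param traits Long trait tibble; `convention = "specific"` uses each
#'   plot's own measurements, `"fixed"` the pooled per-species averages.
#' @param threshold Common-species cover threshold (`NULL` to skip).
#' @param convention `"specific"` or `"fixed"`.
#' @param geometry,standardize Passed to [trait_space()].
#' @return A tibble with one row per plot: the four indices, the species
#'   count, axes used and a `note` column flagging undefined values.
#' @export
fd_indices <- function(abundance, traits, threshold = 0.9,
                       convention = c("specific", "fixed"),
                       geometry = c("gower_pcoa", "euclidean"),
                       standardize = TRUE) {
  convention <- match.arg(convention)
  geometry <- match.arg(geometry)
  abundance <- as_abundance(abundance)
  traits <- as_trait_table(traits)
  if (!is.null(threshold)) {
    abundance <- filter_common_species(abundance, threshold)
  }
  if (convention == "fixed" && !any(traits$plot_id == "POOLED")) {
    traits <- add_pooled_traits(traits, abundance)
  }
  plots <- unique(abundance$plot_id)
  rows <- lapply(plots, function(p) {
    ab <- abundance[abundance$plot_id == p & abundance$cover > 0, ]
    tr <- if (convention == "specific") {
      traits[traits$plot_id == p, ]
    } else {
      traits[traits$plot_id == "POOLED", ]
    }
    wide <- tidyr::pivot_wider(tr[, c("species", "trait", "value")],
                               names_from = "trait", values_from = "value")
    wide <- wide[complete.cases(wide), ]
    m <- inner_join(ab, wide, by = "species")
    if (nrow(m) == 0) {
      return(tibble(plot_id = p, fric = NA_real_, feve = NA_real_,
                    fdiv = NA_real_, fdis = NA_real_, species_count = 0L,
                    axes_used = NA_integer_, note = "no species with traits"))
    }
    x <- as.matrix(m[, setdiff(names(wide), "species"), drop = FALSE])
    rownames(x) <- m$species
    sp <- trait_space(x, m$cover, geometry = geometry,
                      standardize = standardize)
    fric <- fd_fric(sp); feve <- fd_feve(sp); fdiv <- fd_fdiv(sp)
    notes <- c(
      if (is.na(fric)) paste0("FRic: ", attr(fric, "reason")),
      if (is.na(feve)) paste0("FEve: ", attr(feve, "reason")),
      if (is.na(fdiv)) paste0("FDiv: ", attr(fdiv, "reason"))
    )
    tibble(
      plot_id = p, fric = as.numeric(fric), feve = as.numeric(feve),
      fdiv = as.numeric(fdiv), fdis = as.numeric(fd_fdis(sp)),
      species_count = nrow(m), axes_used = sp$axes_used,
      note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_
    )
  })
  bind_rows(rows)
}

# Prim's algorithm; returns a 2-column matrix of edge endpoints.
mst_edges <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  edges <- matrix(0L, n - 1, 2)
  best <- d[1, ]
  parent <- rep(1L, n)
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[k, ] <- c(parent[j], j)
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < best
    best[upd] <- d[j, upd]
    parent[upd] <- j
  }
  edges
}
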