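# Small hand-built fixtures and independent oracle implementations used
# across the test files.  Oracles deliberately use different code paths
# (explicit loops, direct formulas) from the package implementation.

toy_design <- function() {
  tibble::tibble(
    plot_id = sprintf("p%02d", 1:27),
    climate = rep(c("arid", "intermediate", "mesic"), each = 9),
    treatment = rep(rep(c("all_herbivores", "wildlife_only",
                          "no_herbivores"), each = 3), times = 3),
    block = rep(LETTERS[1:9], each = 3)
  )
}

toy_abundance <- function(plot = "p1",
                          species = c("a", "b", "c", "d"),
                          cover = c(50, 30, 15, 5)) {
  tibble::tibble(plot_id = plot, species = species, cover = cover)
}

# Naive CWM: explicit loop over species, no dplyr.
oracle_cwm <- function(cover, values) {
  keep <- which(!is.na(values) & cover > 0)
  w <- cover[keep] / sum(cover[keep])
  total <- 0
  for (i in seq_along(keep)) total <- total + w[i] * values[keep[i]]
  total
}

# Naive group-mean two-way decomposition for a balanced design.
oracle_two_way_ss <- function(y, climate, treatment) {
  gm <- mean(y)
  mc <- tapply(y, climate, mean)
  mt <- tapply(y, treatment, mean)
  mct <- tapply(y, interaction(climate, treatment), mean)
  cell <- interaction(climate, treatment)
  ss_c <- sum((mc[climate] - gm)^2)
  ss_t <- sum((mt[treatment] - gm)^2)
  ss_ct <- sum((mct[cell] - mc[climate] - mt[treatment] + gm)^2)
  ss_res <- sum((y - mct[cell])^2)
  c(climate = ss_c, treatment = ss_t, interaction = ss_ct,
    residuals = ss_res, total = sum((y - gm)^2))
}

# Direct formula evaluations of the FD indices on raw coordinates.
oracle_fdis <- function(points, w) {
  w <- w / sum(w)
  ctr <- rep(0, ncol(points))
  for (i in seq_len(nrow(points))) ctr <- ctr + w[i] * points[i, ]
  s <- 0
  for (i in seq_len(nrow(points))) {
    s <- s + w[i] * sqrt(sum((points[i, ] - ctr)^2))
  }
  s
}

oracle_feve <- function(points, w) {
  w <- w / sum(w)
  s <- nrow(points)
  d <- as.matrix(dist(points))
  # MST via vegan for an independent path
  tr <- vegan::spantree(as.dist(d))
  ew <- numeric(s - 1)
  for (k in 2:s) {
    i <- k; j <- tr$kid[k - 1]
    ew[k - 1] <- d[i, j] / (w[i] + w[j])
  }
  pew <- ew / sum(ew)
  thr <- 1 / (s - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

oracle_fdiv_2d <- function(points, w) {
  w <- w / sum(w)
  hull <- grDevices::chull(points)
  g <- colMeans(points[hull, , drop = FALSE])
  dg <- apply(points, 1, function(p) sqrt(sum((p - g)^2)))
  dbar <- mean(dg)
  (sum(w * (dg - dbar)) + dbar) / (sum(w * abs(dg - dbar)) + dbar)
}

# Shoelace polygon area of the 2-D convex hull.
oracle_hull_area_2d <- function(points) {
  h <- grDevices::chull(points)
  p <- points[h, , drop = FALSE]
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  abs(s) / 2
}

oracle_jaccard <- function(sa, sb) {
  1 - length(intersect(sa, sb)) / length(union(sa, sb))
}
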