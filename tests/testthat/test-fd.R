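euclid_space <- function(points, w = NULL) {
  trait_space(points, w, geometry = "euclidean", standardize = FALSE)
}

test_that("FRic closed forms: unit square, degenerate lines, cubes", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fd_fric(euclid_space(sq)), 1.0)
  line <- cbind(0:2, 0:2)   # collinear in 2-D
  expect_true(is.na(fd_fric(euclid_space(line))))
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(hull_volume(cube), 1.0)
  simplex <- rbind(diag(3), c(0, 0, 0))
  expect_equal(hull_volume(simplex), 1 / 6, tolerance = 1e-12)
  # interior points change nothing
  expect_equal(hull_volume(rbind(cube, c(0.5, 0.5, 0.5))), 1.0)
})

test_that("hull volume and vertices agree with the 2-D shoelace oracle", {
  set.seed(14)
  for (i in 1:50) {
    pts <- matrix(rnorm(2 * sample(4:9, 1)), ncol = 2)
    expect_equal(hull_volume(pts), oracle_hull_area_2d(pts),
                 tolerance = 1e-10)
    expect_setequal(hull_vertices(pts), grDevices::chull(pts))
  }
})

test_that("3-D hull volume matches a Monte Carlo estimate", {
  set.seed(3)
  pts <- matrix(rnorm(18), ncol = 3)
  v <- hull_volume(pts)
  # hit-or-miss estimate: point inside iff it is no new hull vertex
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  box <- prod(hi - lo)
  n_mc <- 4000
  rnd <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]),
               runif(n_mc, lo[3], hi[3]))
  inside <- vapply(seq_len(n_mc), function(i) {
    !((nrow(pts) + 1) %in% hull_vertices(rbind(pts, rnd[i, ])))
  }, logical(1))
  expect_equal(v, box * mean(inside), tolerance = 0.1)
})

test_that("FEve closed forms and bounds", {
  # 3 equally spaced collinear species, equal abundances -> 1
  pts <- cbind(c(0, 1, 2))
  expect_equal(fd_feve(euclid_space(pts, rep(1, 3))), 1.0)
  # two coincident + one distant, equal weights -> 0
  clump <- cbind(c(0, 0, 10))
  expect_equal(fd_feve(euclid_space(clump, rep(1, 3))), 0.0)
  expect_true(is.na(fd_feve(euclid_space(cbind(c(0, 1)), c(1, 1)))))
  set.seed(5)
  for (i in 1:25) {
    pts <- matrix(rnorm(2 * sample(3:8, 1)), ncol = 2)
    v <- fd_feve(euclid_space(pts, runif(nrow(pts), 0.5, 2)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("FDiv closed forms and bounds", {
  # square: all species equidistant from the hull centre -> 1
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(fd_fdiv(euclid_space(sq, rep(1, 4))), 1.0)
  # two-cluster toy with unequal weights equals the direct formula
  pts <- rbind(c(0, 0), c(0.1, 0), c(5, 0), c(5, 1), c(2, 0.5))
  w <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  expect_equal(fd_fdiv(euclid_space(pts, w)), oracle_fdiv_2d(pts, w),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:25) {
    pts <- matrix(rnorm(2 * sample(4:8, 1)), ncol = 2)
    v <- fd_fdiv(euclid_space(pts, runif(nrow(pts), 0.5, 2)))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("FDis closed forms: single species 0, two species d/2", {
  expect_equal(fd_fdis(euclid_space(cbind(3), 5)), 0)
  two <- rbind(c(0, 0), c(3, 4))   # distance 5
  expect_equal(fd_fdis(euclid_space(two, c(1, 1))), 2.5)
  # unequal weights: brute-force oracle
  set.seed(7)
  for (i in 1:25) {
    pts <- matrix(rnorm(3 * 5), ncol = 3)
    w <- runif(5)
    expect_equal(fd_fdis(euclid_space(pts, w)), oracle_fdis(pts, w),
                 tolerance = 1e-12)
  }
})

test_that("indices agree with brute-force oracles on random communities", {
  skip_if_not_installed("vegan")
  set.seed(99)
  for (i in 1:200) {
    s <- sample(4:8, 1)
    d <- sample(2:3, 1)
    pts <- matrix(rnorm(s * d), ncol = d)
    w <- runif(s, 0.2, 2)
    space <- euclid_space(pts, w)
    expect_equal(fd_fdis(space), oracle_fdis(pts, w), tolerance = 1e-10)
    expect_equal(fd_feve(space), oracle_feve(pts, w), tolerance = 1e-10)
    if (d == 2) {
      expect_equal(fd_fric(space), oracle_hull_area_2d(pts),
                   tolerance = 1e-10)
      expect_equal(fd_fdiv(space), oracle_fdiv_2d(pts, w),
                   tolerance = 1e-10)
    }
  }
})

test_that("FDis and FEve are rigid-motion invariant; FRic rotation
           invariant", {
  set.seed(42)
  pts <- matrix(rnorm(12), ncol = 2)
  w <- runif(6)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- pts %*% rot + matrix(c(3, -2), 6, 2, byrow = TRUE)
  for (f in list(fd_fdis, fd_feve, fd_fric)) {
    expect_equal(f(euclid_space(moved, w)), f(euclid_space(pts, w)),
                 tolerance = 1e-10)
  }
})

test_that("zero-abundance species affect FRic only outside the hull,
           never FDis", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  w <- c(1, 1, 1, 1)
  base_fric <- fd_fric(euclid_space(pts, w))
  base_fdis <- fd_fdis(euclid_space(pts, w))
  inside <- rbind(pts, c(0.5, 0.5))
  outside <- rbind(pts, c(3, 0.5))
  expect_equal(fd_fric(euclid_space(inside, c(w, 0))), base_fric)
  expect_gt(fd_fric(euclid_space(outside, c(w, 0))), base_fric)
  expect_equal(fd_fdis(euclid_space(inside, c(w, 0))), base_fdis)
  expect_equal(fd_fdis(euclid_space(outside, c(w, 0))), base_fdis)
})

test_that("degenerate spaces are flagged, not fabricated", {
  same <- matrix(1, 4, 2)
  sp <- euclid_space(same, rep(1, 4))
  expect_true(sp$degenerate)
  expect_equal(fd_fric(sp), 0)       # a true point-community
  expect_true(is.na(fd_feve(sp)))
  expect_true(is.na(fd_fdiv(sp)))
  expect_equal(fd_fdis(sp), 0)
})

test_that("FDis is zero iff all abundance-bearing species coincide", {
  pts <- rbind(c(0, 0), c(0, 0), c(5, 5))
  expect_equal(fd_fdis(euclid_space(pts, c(1, 2, 0))), 0)
  expect_gt(fd_fdis(euclid_space(pts, c(1, 2, 1))), 0)
})
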