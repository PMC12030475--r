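test_that("Jaccard definition: shared, identical and disjoint sets", {
  ab <- dplyr::bind_rows(
    toy_abundance("p1", c("A", "B", "C"), 10),
    toy_abundance("p2", c("B", "C", "D"), 10),
    toy_abundance("p3", c("A", "B", "C"), 5),
    toy_abundance("p4", c("X", "Y"), 20)
  )
  d <- jaccard_matrix(ab, threshold = NULL)
  expect_equal(d["p1", "p2"], 0.5)      # 1 - 2/4
  expect_equal(d["p1", "p3"], 0)
  expect_equal(d["p1", "p4"], 1)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), setNames(rep(0, 4), rownames(d)))
})

test_that("Jaccard on a 5-plot fixture matches set-arithmetic oracle and
           vegan", {
  skip_if_not_installed("vegan")
  set.seed(33)
  ab <- dplyr::bind_rows(lapply(1:5, function(i) {
    sp <- sample(letters[1:10], sample(3:7, 1))
    toy_abundance(paste0("p", i), sp, runif(length(sp), 1, 30))
  }))
  d <- jaccard_matrix(ab, threshold = NULL)
  sets <- split(ab$species, ab$plot_id)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(d[i, j], oracle_jaccard(sets[[i]], sets[[j]]))
  }
  pa <- (tidyr::pivot_wider(ab, names_from = species, values_from = cover,
                            values_fill = 0)[, -1] > 0) * 1
  dv <- as.matrix(vegan::vegdist(pa, method = "jaccard", binary = TRUE))
  expect_equal(unname(d), unname(dv), tolerance = 1e-12)
})

test_that("the 90% filter changes retained sets before binarizing", {
  ab <- dplyr::bind_rows(
    toy_abundance("p1", c("A", "B", "rare"), c(80, 15, 5)),
    toy_abundance("p2", c("A", "B", "rare2"), c(80, 15, 5))
  )
  expect_equal(jaccard_matrix(ab, threshold = 0.9)["p1", "p2"], 0)
  expect_equal(jaccard_matrix(ab, threshold = NULL)["p1", "p2"], 0.5)
})

test_that("ANOSIM complete separation gives R = 1", {
  # two groups, every between-pair dissimilarity exceeds every within-pair
  d <- matrix(0.9, 6, 6)
  d[1:3, 1:3] <- 0.1; d[4:6, 4:6] <- 0.2
  diag(d) <- 0
  g <- rep(c("u", "v"), each = 3)
  res <- anosim_test(d, g)
  expect_equal(res$R, 1)
  expect_equal(res$method, "exact")  # choose(6,3)/... = 20 arrangements
  expect_lte(res$p, 0.1)
})

test_that("ANOSIM matches a hand-ranked 6-plot toy and vegan", {
  skip_if_not_installed("vegan")
  set.seed(44)
  x <- matrix(rnorm(12), 6, 2)
  d <- as.matrix(dist(x))
  g <- rep(c("u", "v"), 3)
  res <- anosim_test(d, g)
  # hand computation: rank all 15 pairs, average between vs within
  dv <- d[lower.tri(d)]
  r <- rank(dv)
  same <- outer(g, g, "==")[lower.tri(d)]
  hand <- (mean(r[!same]) - mean(r[same])) / (15 / 2)
  expect_equal(res$R, hand, tolerance = 1e-12)
  veg <- vegan::anosim(as.dist(d), g, permutations = 99)
  expect_equal(res$R, unname(veg$statistic), tolerance = 1e-12)
})

test_that("R is invariant to monotone transforms of the dissimilarities", {
  set.seed(45)
  x <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(x))
  g <- rep(c("u", "v"), each = 5)
  r1 <- anosim_test(d, g)$R
  expect_equal(anosim_test(sqrt(d), g)$R, r1, tolerance = 1e-12)
  expect_equal(anosim_test(d^3, g)$R, r1, tolerance = 1e-12)
  expect_equal(anosim_test(log1p(d), g)$R, r1, tolerance = 1e-12)
})

test_that("exact enumeration is used for small designs and is seeded
           otherwise", {
  d <- as.matrix(dist(matrix(rnorm(18), 9, 2)))
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anosim_test(d, g)
  expect_equal(res$method, "exact")
  expect_equal(res$n_permutations, 1680)  # 9! / (3!3!3!)
  big <- as.matrix(dist(matrix(rnorm(54), 27, 2)))
  gb <- rep(c("a", "b", "c"), each = 9)
  r1 <- anosim_test(big, gb, n_permutations = 199, seed = 3)
  r2 <- anosim_test(big, gb, n_permutations = 199, seed = 3)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$method, "sampled")
  expect_gte(r1$p, 1 / 200)
})

test_that("degenerate inputs error or warn as specified", {
  d <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  expect_error(anosim_test(d, c("a", "a", "a", "b")),
               class = "traitpart_validation_error")
  dc <- matrix(1, 4, 4); diag(dc) <- 0
  expect_warning(res <- anosim_test(dc, rep(c("a", "b"), 2)), "constant")
  expect_equal(res$R, 0)
})

test_that("null p-values are approximately uniform (calibration)", {
  # 10 plots in two groups of 5: 252 distinct arrangements, exact test
  set.seed(501)
  n_sim <- 500
  p <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    d <- as.matrix(dist(matrix(rnorm(20), 10, 2)))
    p[i] <- anosim_test(d, rep(c("u", "v"), each = 5))$p
  }
  expect_gte(mean(p <= 0.05), 0.03)
  expect_lte(mean(p <= 0.05), 0.07)
})

test_that("study suite: one climate test and three treatment tests", {
  com <- sim_community(sim_config(pool_overlap = 0, seed = 6))
  res <- run_study_anosims(com$abundance, com$design, seed = 2)
  expect_equal(nrow(res), 4)
  expect_equal(res$scope, c("all_plots", "arid", "intermediate", "mesic"))
  # disjoint pools: climate-grouped R at the maximum
  expect_gt(res$R[1], 0.95)
  # identical communities everywhere
  com1 <- sim_community(sim_regime("itv_only", seed = 6))
  # identical species sets everywhere: constant dissimilarities, R = 0
  res1 <- suppressWarnings(
    run_study_anosims(com1$abundance, com1$design, threshold = NULL,
                      seed = 2)
  )
  expect_equal(res1$R, rep(0, 4))
})
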