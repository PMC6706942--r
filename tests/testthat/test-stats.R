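test_that("Bray-Curtis matches its definition and the vegan reference", {
  expect_equal(bray_curtis(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(bray_curtis(c(1, 0, 0), c(0, 2, 3)), 1)   # disjoint supports
  expect_equal(bray_curtis(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  expect_equal(bray_curtis(numeric(3) + 0, numeric(3) + 0), 0)  # all-zero
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")

  skip_if_not_installed("vegan")
  set.seed(41)
  m <- matrix(runif(5 * 8), nrow = 5)
  mine <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unname(mine), unname(ref), tolerance = 1e-12)
})

test_that("on relative-frequency vectors Bray-Curtis is half the L1 distance", {
  set.seed(42)
  for (i in 1:10) {
    p <- runif(12); p <- p / sum(p)
    q <- runif(12); q <- q / sum(q)
    expect_equal(bray_curtis(p, q), sum(abs(p - q)) / 2, tolerance = 1e-12)
  }
})

test_that("PERMANOVA recovers R2 = 1 when within-group distances vanish", {
  d <- matrix(0.7, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0
  diag(d) <- 0
  res <- permanova(d, rep(c("u", "v"), each = 3), n_permutations = 99)
  expect_equal(res$r_squared, 1)
  expect_true(is.infinite(res$pseudo_F))
  expect_lte(res$p_value, 1)
})

test_that("pseudo-F and R2 agree with vegan::adonis2 on random data", {
  skip_if_not_installed("vegan")
  set.seed(43)
  m <- matrix(runif(9 * 6), nrow = 9)
  g <- rep(c("a", "b", "c"), each = 3)
  d <- bray_curtis_matrix(m)
  mine <- permanova(d, g, n_permutations = 49)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 49)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$r_squared, ref$R2[1], tolerance = 1e-10)
})

test_that("permutation p agrees with the exhaustive-enumeration oracle", {
  # hand-built N=6 matrix with two clear groups: exact p over the 20
  # distinct assignments is 2/20 = 0.1 (the observed split and its mirror)
  set.seed(44)
  pts <- rbind(matrix(rnorm(9, 0, 0.05), 3), matrix(rnorm(9, 1, 0.05), 3))
  d <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b"), each = 3)
  p_exact <- oracle_exact_p(d, g)
  expect_equal(p_exact, 0.1)
  res <- permanova(d, g, n_permutations = 4999, seed = 7)
  expect_lt(abs(res$p_value - p_exact), 0.015)  # 3 binomial SE at m = 4999
})

test_that("pseudo-F matches the direct-definition oracle and object order", {
  set.seed(45)
  m <- matrix(runif(8 * 5), nrow = 8)
  g <- rep(c("a", "b"), each = 4)
  d <- bray_curtis_matrix(m)
  res <- permanova(d, g, n_permutations = 9)
  expect_equal(res$pseudo_F, oracle_permanova_f(d, g), tolerance = 1e-12)
  # invariance to a relabeling permutation of object order
  perm <- sample(8)
  res2 <- permanova(d[perm, perm], g[perm], n_permutations = 9)
  expect_equal(res2$pseudo_F, res$pseudo_F, tolerance = 1e-12)
  expect_equal(res2$r_squared, res$r_squared, tolerance = 1e-12)
})

test_that("p-values are bit-reproducible given permutations and seed", {
  set.seed(46)
  m <- matrix(runif(10 * 6), nrow = 10)
  g <- rep(c("a", "b"), each = 5)
  d <- bray_curtis_matrix(m)
  p1 <- permanova(d, g, n_permutations = 199, seed = 123)$p_value
  p2 <- permanova(d, g, n_permutations = 199, seed = 123)$p_value
  expect_identical(p1, p2)
})

test_that("PERMANOVA rejects degenerate groupings", {
  d <- bray_curtis_matrix(matrix(runif(12), 4))
  expect_error(permanova(d, rep("a", 4), 9), "two groups")
  expect_error(permanova(d[1:2, 1:2], c("a", "b"), 9), "at least 3")
})

test_that("PCA matches prcomp up to the fixed sign convention", {
  set.seed(47)
  m <- matrix(runif(10 * 8), nrow = 10)
  mine <- pca_profiles(m, n_components = 3)
  ref <- prcomp(m, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    expect_equal(abs(mine$scores[, j]), abs(ref$x[, j]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # sign convention: the largest-magnitude loading is positive
    expect_gt(mine$loadings[which.max(abs(mine$loadings[, j])), j], 0)
  }
  expect_equal(mine$explained_variance_ratio,
               (ref$sdev^2 / sum(ref$sdev^2))[1:3], tolerance = 1e-9)
})

test_that("PCA handles collinear and duplicated inputs", {
  base <- c(1, 2, 3)
  m <- rbind(base, 2 * base, 3.5 * base)
  expect_warning(res <- pca_profiles(m, n_components = 2), "truncated")
  expect_equal(res$explained_variance_ratio[1], 1, tolerance = 1e-9)

  set.seed(48)
  m2 <- matrix(runif(4 * 5), nrow = 4)
  dup <- m2[rep(1:4, each = 2), ]
  res2 <- pca_profiles(dup, n_components = 2)
  expect_equal(res2$scores[seq(1, 8, 2), ], res2$scores[seq(2, 8, 2), ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("nearest-centroid classification with lexicographic tie-break", {
  refs <- data.frame(
    label = c("freshwater", "freshwater", "marine", "marine"),
    acid_fraction = c(0.30, 0.32, 0.52, 0.50),
    neutral_fraction = c(0.06, 0.04, 0.05, 0.05),
    basic_fraction = c(0.50, 0.52, 0.30, 0.32))
  hit <- classify_habitat(c(0.31, 0.05, 0.51), refs)
  expect_equal(hit$label, "freshwater")
  expect_gt(hit$margin, 0)

  # equidistant centroids: deterministic tie-break to the smaller label
  refs2 <- data.frame(label = c("aa", "bb"),
                      acid_fraction = c(0.4, 0.6),
                      neutral_fraction = c(0.1, 0.1),
                      basic_fraction = c(0.5, 0.3))
  tie <- classify_habitat(c(0.5, 0.1, 0.4), refs2)
  expect_equal(tie$label, "aa")
  expect_equal(tie$margin, 0)

  expect_error(classify_habitat(c(0.3, 0.3, 0.4), data.frame()), "non-empty")
})

test_that("classifier separates synthetic habitats from spectrum aggregates", {
  cohort <- generate_cohort(n_per_habitat = 8, delta = 1.0, n_proteins = 150,
                            seed = 49)
  aggs <- t(vapply(cohort$proteomes, function(p) {
    acid_neutral_basic(bin_spectrum(protein_pi(p)$pI))
  }, numeric(3)))
  refs <- data.frame(label = cohort$metadata$habitat,
                     acid_fraction = aggs[, 1], neutral_fraction = aggs[, 2],
                     basic_fraction = aggs[, 3])
  # leave-one-out accuracy
  hits <- vapply(seq_len(nrow(refs)), function(i) {
    classify_habitat(aggs[i, ], refs[-i, ])$label == refs$label[i]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
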