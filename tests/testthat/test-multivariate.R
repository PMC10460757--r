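# Cohort matrix assembly, z-scaling, complete-linkage clustering with
# cophenetic validation, and PCA of the parameter space.

mk_minutely <- function(m, id) {
  df <- as.data.frame(m)
  names(df) <- c("abp", "icp", "cpp", "rso2", "prx", "pax", "rac", "amp",
                 "cox", "cox_a")
  df <- cbind(t_min = seq_len(nrow(df)) * 60, df)
  attr(df, "subject_id") <- id
  class(df) <- c("cvr_minutely", "data.frame")
  df
}

rand_minutely <- function(n, id, seed) {
  set.seed(seed)
  mk_minutely(matrix(rnorm(n * 10), n, 10), id)
}

test_that("cohort matrix pools complete rows and counts dropped ones per subject", {
  a <- rand_minutely(10, "a", 1)
  b <- rand_minutely(10, "b", 2)
  b$cox[3] <- NA
  cm <- build_cohort_matrix(list(a, b))
  expect_equal(nrow(cm), 19)
  expect_equal(as.vector(attr(cm, "dropped")), c(0L, 1L))
  expect_equal(colnames(cm),
               c("ABP", "ICP", "CPP", "rSO2", "PRx", "PAx", "RAC", "AMP",
                 "COx", "COx_a"))
})

test_that("complete-case retention matches the direct count under random missingness", {
  set.seed(3)
  m <- matrix(rnorm(1000 * 10), 1000, 10)
  m[sample(length(m), length(m) %/% 10)] <- NA
  mt <- mk_minutely(m, "s")
  expected <- sum(complete.cases(m))
  cm <- build_cohort_matrix(list(mt))
  expect_equal(nrow(cm), expected)
  expect_equal(sum(attr(cm, "dropped")), 1000 - expected)
})

test_that("scaling gives zero-mean unit-SD columns (sample SD) and is idempotent", {
  s <- scale_columns(cbind(a = c(1, 2, 3), b = c(5, 1, 0)))
  expect_equal(s$x[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  set.seed(4)
  m <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  s1 <- scale_columns(m)
  expect_true(all(abs(colMeans(s1$x)) < 1e-9))
  expect_true(all(abs(apply(s1$x, 2, sd) - 1) < 1e-9))
  s2 <- scale_columns(s1$x)
  expect_equal(unclass(s1$x), unclass(s2$x), tolerance = 1e-12,
               ignore_attr = TRUE)
  m[, 2] <- 7
  expect_error(scale_columns(m), "constant column.*b")
})

test_that("duplicated parameter columns merge first at height zero", {
  set.seed(5)
  m <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("p1", "p2", "p3")))
  m <- cbind(m, p1_copy = m[, 1])
  # direct distances (no scaling: a duplicate would be constant-ratio safe)
  s <- structure(list(x = m), class = "cvr_scaled")
  cl <- cluster_parameters(s)
  first <- cl$hclust$merge[1, ]
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(cl$hclust$labels[-first], c("p1", "p1_copy"))
  cm <- as.matrix(cl$cophenetic)
  expect_equal(cm["p1", "p1_copy"], 0)
})

test_that("cophenetic correlation is exactly 1 on ultrametric distances", {
  # 3 points with d12 = 1, d13 = d23 = 2 realised on the line-free design
  x <- cbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(4 - 0.25)))
  d <- dist(t(x))
  expect_equal(as.vector(d), c(1, 2, 2), tolerance = 1e-12)
  s <- structure(list(x = x), class = "cvr_scaled")
  cl <- cluster_parameters(s)
  expect_equal(cl$coph_cor, 1, tolerance = 1e-12)
})

test_that("distance between z-scored columns follows sqrt(2(n-1)(1-r))", {
  set.seed(6)
  n <- 400
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  z <- rnorm(n)
  s <- scale_columns(cbind(x = x, y = y, z = z))
  d <- as.matrix(dist(t(s$x)))
  r <- cor(cbind(x, y, z))
  for (p in list(c("x", "y"), c("x", "z"), c("y", "z")))
    expect_equal(d[p[1], p[2]],
                 sqrt(2 * (n - 1) * (1 - r[p[1], p[2]])),
                 tolerance = 1e-9)
})

test_that("complete-linkage merge heights equal brute-force maxima", {
  set.seed(7)
  for (k in 4:6) {
    m <- matrix(rnorm(40 * k), 40, k,
                dimnames = list(NULL, paste0("c", 1:k)))
    s <- scale_columns(m)
    cl <- cluster_parameters(s)
    expect_equal(sort(cl$hclust$height), sort(brute_complete_heights(s$x)),
                 tolerance = 1e-9)
    expect_true(all(diff(cl$hclust$height) >= -1e-12))
  }
})

test_that("clustering is invariant to row order; PCA scores are row-equivariant", {
  set.seed(8)
  m <- matrix(rnorm(600), 60, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  perm <- sample(60)
  s1 <- scale_columns(m)
  s2 <- scale_columns(m[perm, ])
  c1 <- cluster_parameters(s1)
  c2 <- cluster_parameters(s2)
  expect_equal(as.matrix(c1$cophenetic), as.matrix(c2$cophenetic),
               tolerance = 1e-9)
  expect_equal(c1$coph_cor, c2$coph_cor, tolerance = 1e-9)
  p1 <- run_pca(s1)
  p2 <- run_pca(s2)
  expect_equal(p2$scores[order(perm), ], p1$scores, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PCA variance fractions sum to 1 and eigenvalue sum equals the column count", {
  set.seed(9)
  s <- scale_columns(matrix(rnorm(2000), 200, 10,
                            dimnames = list(NULL, paste0("p", 1:10))))
  pc <- run_pca(s)
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-9)
  expect_equal(sum(pc$eigenvalues), 10, tolerance = 1e-9)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_true(all(pc$eigenvalues >= -1e-12))
  # sign convention: dominant loading of each component is positive
  for (j in 1:10)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
})

test_that("perfectly correlated column pair loads entirely on PC1", {
  set.seed(10)
  x <- rnorm(500)
  s <- scale_columns(cbind(a = x, b = 2 * x + 3))
  pc <- run_pca(s)
  expect_equal(pc$var_frac[1], 1, tolerance = 1e-12)
  # near-isotropic pair splits variance evenly
  s2 <- scale_columns(cbind(a = rnorm(5000), b = rnorm(5000)))
  pc2 <- run_pca(s2)
  expect_equal(pc2$var_frac[1], 0.5, tolerance = 0.05)
})

test_that("reconstruction from all components reproduces the scaled matrix", {
  set.seed(11)
  s <- scale_columns(matrix(rnorm(10000), 1000, 10,
                            dimnames = list(NULL, paste0("p", 1:10))))
  pc <- run_pca(s)
  rec <- pc$scores %*% t(pc$loadings)
  expect_lt(max(abs(rec - s$x)), 1e-9)
})

test_that("proximity report flags index co-clustering driven by a shared latent factor", {
  set.seed(12)
  n <- 500
  latent <- rnorm(n)
  press <- rnorm(n)
  m <- cbind(abp = press + 0.2 * rnorm(n), icp = 0.5 * press + rnorm(n),
             cpp = press + 0.3 * rnorm(n), rso2 = rnorm(n),
             prx = latent + 0.3 * rnorm(n), pax = latent + 0.3 * rnorm(n),
             rac = latent + 0.3 * rnorm(n), amp = rnorm(n),
             cox = latent + 0.3 * rnorm(n), cox_a = latent + 0.3 * rnorm(n))
  mt <- mk_minutely(m, "s")
  s <- scale_columns(build_cohort_matrix(list(mt)))
  pr <- proximity_report(cluster_parameters(s), run_pca(s))
  expect_true(pr$indices_co_cluster)
  expect_lt(pr$max_within_index, pr$min_index_to_other)
  # independent noise columns should not co-cluster
  set.seed(13)
  m2 <- matrix(rnorm(n * 10), n, 10)
  mt2 <- mk_minutely(m2, "s2")
  s2 <- scale_columns(build_cohort_matrix(list(mt2)))
  pr2 <- proximity_report(cluster_parameters(s2), run_pca(s2))
  expect_false(pr2$indices_co_cluster)
})
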