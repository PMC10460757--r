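# Gap interpolation, differencing, stationarity screening, VAR fitting,
# order selection and impulse responses.

mk_tri <- function(abp, icp = abp, rso2 = abp, differenced = FALSE) {
  out <- data.frame(t_10s = (seq_along(abp) - 1) * 10, abp = abp,
                    icp = icp, rso2 = rso2)
  attr(out, "differenced") <- differenced
  attr(out, "subject_id") <- "tst"
  class(out) <- c("cvr_triseries", "data.frame")
  out
}

test_that("interior gaps interpolate linearly; edge gaps are trimmed", {
  ts <- mk_tri(c(1, NA, 3), c(0, NA, NA, 6, 5)[1:3], c(5, 5, 5))
  out <- interpolate_gaps(mk_tri(c(1, NA, 3)))
  expect_equal(out$abp, c(1, 2, 3))
  out2 <- interpolate_gaps(mk_tri(c(NA, 5, 6)))
  expect_equal(out2$abp, c(5, 6))
  expect_equal(nrow(out2), 2)
  out3 <- interpolate_gaps(mk_tri(c(0, NA, NA, 6)))
  expect_equal(out3$abp, c(0, 2, 4, 6))
  expect_error(interpolate_gaps(mk_tri(c(NA, NA, 1))), "fewer than 2")
})

test_that("differencing drops one row, flags the series and is invertible", {
  ts <- mk_tri(c(1, 3, 6), c(2, 2, 2), c(0, 1, 0))
  d <- difference_series(ts)
  expect_equal(d$abp, c(2, 3))
  expect_equal(d$icp, c(0, 0))
  expect_true(attr(d, "differenced"))
  expect_error(difference_series(d), "already differenced")
  init <- attr(d, "initial")
  expect_equal(cumsum(c(init[["abp"]], d$abp)), ts$abp)
})

test_that("stationarity verdicts separate white noise, random walks and their differences", {
  set.seed(20)
  verdicts <- sapply(1:40, function(i) {
    wn <- mk_tri(rnorm(1000))
    rw <- mk_tri(cumsum(rnorm(1000)))
    drw <- difference_series(rw)
    c(wn = all(test_stationarity(wn)$stationary),
      rw = any(test_stationarity(rw)$stationary),
      drw = all(test_stationarity(drw)$stationary))
  })
  expect_gte(mean(verdicts["wn", ]), 0.9)
  expect_lte(mean(verdicts["rw", ]), 0.1)
  expect_gte(mean(verdicts["drw", ]), 0.9)
  expect_error(test_stationarity(mk_tri(rnorm(20))), "too short")
})

test_that("least squares recovers known VAR coefficients", {
  set.seed(21)
  A <- list(diag(c(0.5, 0.3, 0.2)))
  y <- sim_var_process(A, 10000)
  m <- fit_var(y, 1)
  expect_lt(max(abs(m$A[[1]] - A[[1]])), 0.05)
  expect_lt(max(abs(m$intercept)), 0.05)
  expect_lt(max(abs(m$sigma - diag(3))), 0.1)
  # zero-coefficient process
  y0 <- sim_var_process(list(matrix(0, 3, 3)), 10000)
  m0 <- fit_var(y0, 1)
  expect_lt(max(abs(m0$A[[1]])), 0.05)
})

test_that("fitted residuals are orthogonal to the regressors", {
  set.seed(22)
  y <- sim_var_process(list(diag(c(0.4, 0.2, 0.1))), 2000)
  m <- fit_var(y, 2)
  p <- m$order
  n <- nrow(y)
  X <- cbind(1, y[(p):(n - 1), ], y[(p - 1):(n - 2), ])
  expect_lt(max(abs(crossprod(X, m$residuals))), 1e-8)
})

test_that("coefficient RMSE shrinks like 1/sqrt(n)", {
  set.seed(23)
  A <- list(matrix(c(0.4, 0.1, 0, 0, 0.3, 0.1, 0.1, 0, 0.2), 3, 3,
                   byrow = TRUE))
  ns <- c(500, 2000, 8000)
  rmse <- sapply(ns, function(n) {
    sqrt(mean(replicate(8, {
      m <- fit_var(sim_var_process(A, n), 1)
      mean((m$A[[1]] - A[[1]])^2)
    })))
  })
  slope <- coef(lm(log(rmse) ~ log(ns)))[2]
  expect_lt(slope, -0.3)
  expect_gt(slope, -0.7)
})

test_that("AIC order selection recovers a known order and degrades gracefully on noise", {
  set.seed(24)
  A1 <- matrix(c(0.4, 0.1, 0, 0, 0.3, 0.1, 0.1, 0, 0.2), 3, 3,
               byrow = TRUE)
  A2 <- diag(c(-0.25, -0.2, -0.15))
  hits <- replicate(10, {
    y <- sim_var_process(list(A1, A2), 5000)
    select_var_order(y, orders = 1:8)$order_aic == 2
  })
  expect_gte(mean(hits), 0.9)
  elbows <- replicate(10, {
    y <- sim_var_process(list(matrix(0, 3, 3)), 1500)
    select_var_order(y, orders = 1:8)$order_elbow == 1
  })
  expect_gte(mean(elbows), 0.9)
})

test_that("the residual log-determinant is non-increasing in model order", {
  set.seed(25)
  y <- sim_var_process(list(diag(c(0.5, 0.4, 0.3))), 1200)
  pmax_ <- 6
  lds <- sapply(1:pmax_, function(p) {
    d <- cvreact:::var_design(y, p, from = pmax_ + 1L)
    log(det(cvreact:::var_fit_ls(d$Y, d$X, p, 3)$sigma_ml))
  })
  expect_true(all(diff(lds) < 1e-10))
})

test_that("cohort pooling reduces to the single-subject fit and is replication-invariant", {
  set.seed(26)
  y <- sim_var_process(list(diag(c(0.4, 0.3, 0.2))), 800)
  single <- fit_var(y, 3)
  pooled1 <- fit_cohort_var(list(y), 3)
  expect_equal(pooled1$A, single$A, tolerance = 1e-10)
  expect_equal(pooled1$sigma, single$sigma, tolerance = 1e-10)
  pooled2 <- fit_cohort_var(list(y, y), 3)
  expect_equal(pooled2$A, single$A, tolerance = 1e-10)
  expect_equal(pooled2$n_obs, 2L * single$n_obs)
})

test_that("pooled estimation over many short subjects recovers shared dynamics", {
  set.seed(27)
  A <- list(matrix(c(0.4, 0.1, 0, 0, 0.3, 0.1, 0.1, 0, 0.2), 3, 3,
                   byrow = TRUE))
  ys <- lapply(1:20, function(i) sim_var_process(A, 500))
  m <- fit_cohort_var(ys, 1)
  expect_lt(max(abs(m$A[[1]] - A[[1]])), 0.03)
})

test_that("an embedded AR(1) has the closed-form impulse response 0.5^k", {
  m <- structure(list(order = 1, intercept = rep(0, 3),
                      A = list(diag(c(0.5, 0, 0))), sigma = diag(3),
                      n_obs = 100, var_names = c("abp", "icp", "rso2")),
                 class = "cvr_var")
  irf <- orthogonal_irf(m, boot = 0)
  expect_equal(irf$responses$abp$point, 0.5^(0:10), tolerance = 1e-10)
  expect_equal(irf$responses$icp$point, rep(0, 11), tolerance = 1e-12)
  # all-zero dynamics: response only at lag 0
  m0 <- m; m0$A <- list(matrix(0, 3, 3))
  irf0 <- orthogonal_irf(m0, boot = 0)
  expect_equal(irf0$responses$abp$point[-1], rep(0, 10))
})

test_that("IRFs agree with a brute-force companion-matrix oracle and lag-0 equals chol(sigma)", {
  set.seed(28)
  for (rep_ in 1:5) {
    A <- list(matrix(runif(9, -0.3, 0.3), 3, 3))
    S <- crossprod(matrix(rnorm(9), 3, 3)) + diag(3) * 0.5
    m <- structure(list(order = 1, intercept = rep(0, 3), A = A,
                        sigma = S, n_obs = 100,
                        var_names = c("abp", "icp", "rso2")),
                   class = "cvr_var")
    irf <- orthogonal_irf(m, boot = 0)
    oracle <- companion_irf(A, S, 1, 10)
    got <- rbind(irf$responses$abp$point, irf$responses$icp$point,
                 irf$responses$rso2$point)
    expect_equal(got, oracle, tolerance = 1e-10, ignore_attr = TRUE)
    L <- t(chol(S))
    expect_equal(got[, 1], L[, 1], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("stable-model responses decay to zero and unstable models are rejected", {
  m <- structure(list(order = 1, intercept = rep(0, 3),
                      A = list(diag(c(0.8, 0.6, 0.4))), sigma = diag(3),
                      n_obs = 100, var_names = c("abp", "icp", "rso2")),
                 class = "cvr_var")
  irf <- orthogonal_irf(m, horizon = 50, boot = 0)
  expect_lt(abs(irf$responses$abp$point[51]), 1e-3)
  m_bad <- m; m_bad$A <- list(diag(c(1.01, 0.5, 0.5)))
  expect_error(orthogonal_irf(m_bad, boot = 0), "not stable")
})

test_that("bootstrap bands contain the point estimate and are seed-reproducible", {
  set.seed(29)
  y <- sim_var_process(list(diag(c(0.5, 0.3, 0.2))), 600)
  m <- fit_var(y, 1)
  i1 <- orthogonal_irf(m, boot = 50, seed = 7)
  i2 <- orthogonal_irf(m, boot = 50, seed = 7)
  expect_identical(i1$responses, i2$responses)
  for (nm in names(i1$responses)) {
    r <- i1$responses[[nm]]
    expect_true(all(r$lower <= r$point + 1e-12))
    expect_true(all(r$upper >= r$point - 1e-12))
  }
})

test_that("identical curves are judged similar, sign-flipped ones are not", {
  curve <- data.frame(lag = 0:10,
                      point = c(1, 0.8, -0.5, -0.2, 0.3, 0.1, -0.05,
                                0.02, 0.01, 0, 0),
                      lower = NA_real_, upper = NA_real_)
  s_same <- irf_similarity(curve, curve)
  expect_equal(s_same$curve_correlation, 1, tolerance = 1e-12)
  expect_true(s_same$similar)
  flipped <- curve; flipped$point <- -curve$point
  s_flip <- irf_similarity(curve, flipped)
  expect_equal(s_flip$curve_correlation, -1, tolerance = 1e-12)
  expect_false(s_flip$similar)
  short <- curve[1:8, ]
  expect_error(irf_similarity(curve, short), "horizon")
})
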