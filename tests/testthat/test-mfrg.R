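test_that("inverse normal transform is rank-based, symmetric and centered", {
  z3 <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(z3[2], 0)
  expect_equal(z3[1], -z3[3])
  # invariance to strictly monotone transforms
  set.seed(2)
  x <- rlnorm(40)
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(log(x)))
  expect_equal(inverse_normal_transform(x),
               inverse_normal_transform(rank(x)))
  expect_equal(mean(inverse_normal_transform(x)), 0, tolerance = 1e-10)
  # ties share the average-rank quantile
  zt <- inverse_normal_transform(c(5, 5, 1, 9))
  expect_equal(zt[1], zt[2])
  expect_error(inverse_normal_transform(rep(1, 5)),
               class = "mfrg_degenerate_trait")
  expect_error(inverse_normal_transform(c(1, 2)), class = "mfrg_bad_input")
})

test_that("transformed lognormal samples are close to standard normal", {
  crit <- 1.358 / sqrt(100)   # KS 5% critical value at n = 100
  pass <- vapply(1:20, function(s) {
    set.seed(s)
    z <- inverse_normal_transform(rlnorm(100))
    max(abs(ecdf(z)(sort(z)) - pnorm(sort(z)))) < crit
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("design matrix has the documented column layout", {
  set.seed(3)
  n <- 20
  xi <- matrix(rnorm(n), n, 1); eta <- matrix(rnorm(n), n, 1)
  d <- build_design(xi, eta)
  expect_equal(ncol(d$W), 4)
  expect_equal(unname(d$W[, 4]), unname(xi[, 1] * eta[, 1]))
  # J = 2, L = 3: six product columns in (1,1),(1,2),(1,3),(2,1),(2,2),(2,3)
  xi <- matrix(rnorm(2 * n), n, 2); eta <- matrix(rnorm(3 * n), n, 3)
  V <- matrix(rnorm(2 * n), n, 2)
  d <- build_design(xi, eta, V)
  expect_equal(ncol(d$W), 1 + 2 + 2 + 3 + 6)
  expect_equal(colnames(d$W)[d$gamma_cols],
               c("g1.1", "g1.2", "g1.3", "g2.1", "g2.2", "g2.3"))
  k <- 0
  for (j in 1:2) for (l in 1:3) {
    k <- k + 1
    expect_identical(unname(d$W[, d$gamma_cols[k]]),
                     unname(xi[, j] * eta[, l]))
  }
  expect_equal(crossprod(d$W), t(d$W) %*% d$W)  # dense cross-product check
})

test_that("zero-noise data are interpolated exactly", {
  set.seed(5)
  n <- 60
  xi <- matrix(rnorm(2 * n), n, 2); eta <- matrix(rnorm(2 * n), n, 2)
  d <- build_design(xi, eta)
  B0 <- matrix(rnorm(ncol(d$W) * 2), ncol(d$W), 2)
  Y <- d$W %*% B0
  fit <- mfrg_fit(d, Y)
  # phenotypes are centered internally, so the intercept row absorbs the
  # column means; all other coefficients are recovered exactly
  expect_equal(unname(fit$B_hat[-1, ]), unname(B0[-1, ]), tolerance = 1e-8)
  expect_equal(fit$Sigma_hat, matrix(0, 2, 2), tolerance = 1e-10)
  expect_equal(unname(fit$gamma_hat),
               unname(B0[d$gamma_cols, , drop = FALSE]), tolerance = 1e-8)
})

test_that("K = 1 residual covariance is RSS/n and Wald equals the classical form", {
  set.seed(7)
  n <- 80
  xi <- matrix(rnorm(2 * n), n, 2); eta <- matrix(rnorm(2 * n), n, 2)
  d <- build_design(xi, eta)
  y <- matrix(rnorm(n), n, 1)
  fit <- mfrg_fit(d, y)
  yc <- y - mean(y)
  ls <- lm.fit(d$W, yc)
  expect_equal(fit$Sigma_hat[1, 1], sum(ls$residuals^2) / n,
               tolerance = 1e-10)
  # classical single-response Wald with the MLE error variance
  WtWi <- solve(crossprod(d$W))
  gam <- ls$coefficients[d$gamma_cols]
  M <- WtWi[d$gamma_cols, d$gamma_cols]
  oracle <- drop(t(gam) %*% solve(fit$Sigma_hat[1, 1] * M, gam))
  t <- wald_test(fit)
  expect_equal(t$statistic, oracle, tolerance = 1e-8)
  expect_equal(t$df, 4L)
  expect_equal(t$p.value, pchisq(oracle, 4, lower.tail = FALSE))
})

test_that("Kronecker covariance equals the brute-force construction", {
  set.seed(9)
  n <- 30
  xi <- matrix(rnorm(2 * n), n, 2); eta <- matrix(rnorm(2 * n), n, 2)
  d <- build_design(xi, eta)
  Y <- matrix(rnorm(2 * n), n, 2)
  fit <- mfrg_fit(d, Y)
  W <- d$W
  A <- solve(crossprod(W), t(W))[d$gamma_cols, , drop = FALSE]
  K <- fit$K
  brute <- (diag(K) %x% A) %*% (fit$Sigma_hat %x% diag(n)) %*%
    (diag(K) %x% t(A))
  expect_equal(unname(interaction_covariance(fit)), unname(brute),
               tolerance = 1e-10)
  expect_equal(unname(fit$AAt), unname(A %*% t(A)), tolerance = 1e-10)
  # and gamma_hat = A Y (on centered Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  expect_equal(unname(fit$gamma_hat), unname(A %*% Yc), tolerance = 1e-10)
})

test_that("null interaction block gives statistic 0 and p = 1", {
  set.seed(11)
  n <- 50
  xi <- matrix(rnorm(n), n, 1); eta <- matrix(rnorm(n), n, 1)
  d <- build_design(xi, eta)
  fit <- mfrg_fit(d, matrix(rnorm(n * 2), n, 2))
  fit$gamma_hat[] <- 0
  t <- wald_test(fit)
  expect_equal(t$statistic, 0)
  expect_equal(t$p.value, 1)
})

test_that("LRT vanishes without interaction signal and equals the log-likelihood oracle", {
  set.seed(13)
  n <- 60; K <- 2
  xi <- matrix(rnorm(2 * n), n, 2); eta <- matrix(rnorm(2 * n), n, 2)
  d <- build_design(xi, eta)
  # response generated from the reduced model, then Gamma columns zeroed in
  # the design: full and reduced fits coincide
  d0 <- d
  d0$W[, d$gamma_cols] <- 0
  Y <- matrix(rnorm(n * K), n, K)
  t0 <- suppressWarnings(lrt_test(d0, Y))
  expect_equal(t0$statistic, 0, tolerance = 1e-8)
  # oracle: twice the difference of maximized Gaussian log-likelihoods
  t1 <- lrt_test(d, Y)
  loglik <- function(res, Sigma) {
    n <- nrow(res)
    -n / 2 * determinant(Sigma)$modulus[1] -
      sum(diag(solve(Sigma, crossprod(res)))) / 2 -
      n * ncol(res) / 2 * log(2 * pi)
  }
  Yc <- sweep(Y, 2, colMeans(Y))
  full <- lm.fit(d$W, Yc); red <- lm.fit(d$W[, -d$gamma_cols], Yc)
  Sf <- crossprod(full$residuals) / n; Sr <- crossprod(red$residuals) / n
  expect_equal(t1$statistic,
               2 * (loglik(full$residuals, Sf) - loglik(red$residuals, Sr)),
               tolerance = 1e-8)
  expect_equal(t1$df, 2 * 2 * 2)
})

test_that("LRT is non-negative on random fixtures", {
  set.seed(17)
  for (i in 1:50) {
    n <- 40
    d <- build_design(matrix(rnorm(n * 2), n, 2), matrix(rnorm(n * 2), n, 2))
    Y <- matrix(rnorm(n * 2), n, 2)
    expect_gte(lrt_test(d, Y)$statistic, 0)
  }
})

test_that("both statistics are invariant to invertible trait recombination", {
  fx <- make_pair_fixture(n = 150, K = 3, seed = 19)
  set.seed(20)
  Tmat <- matrix(rnorm(9), 3, 3) + diag(3)
  m1 <- mfrg(fx$g1, fx$g2, fx$Y, method = "both")
  m2 <- mfrg(fx$g1, fx$g2, fx$Y %*% Tmat, method = "both")
  expect_equal(m1$tests$wald$statistic, m2$tests$wald$statistic,
               tolerance = 1e-8)
  expect_equal(m1$tests$lrt$statistic, m2$tests$lrt$statistic,
               tolerance = 1e-8)
})

test_that("statistic is invariant to sample permutation, sign flips and gene order", {
  fx <- make_pair_fixture(n = 120, K = 2, seed = 23)
  base <- mfrg(fx$g1, fx$g2, fx$Y)
  # consistent permutation of all inputs
  set.seed(24)
  pi <- sample(nrow(fx$Y))
  perm <- mfrg(subset_rows(fx$g1, pi), subset_rows(fx$g2, pi),
               fx$Y[pi, , drop = FALSE])
  expect_equal(perm$statistic, base$statistic, tolerance = 1e-8)
  # flipping an eigenfunction sign leaves the quadratic form unchanged
  f1 <- fit_fpca(fx$g1); f2 <- fit_fpca(fx$g2)
  flip <- f1$scores; flip[, 1] <- -flip[, 1]
  t_flip <- wald_test(mfrg_fit(build_design(flip, f2$scores), fx$Y))
  expect_equal(t_flip$statistic, base$statistic, tolerance = 1e-8)
  # swapping gene 1 and gene 2 relabels the Gamma block only
  swap <- mfrg(fx$g2, fx$g1, fx$Y)
  expect_equal(swap$statistic, base$statistic, tolerance = 1e-8)
})

test_that("statistics are invariant to rotation within tied eigenvalue blocks", {
  fx <- make_pair_fixture(n = 100, K = 2, seed = 29)
  f1 <- fit_fpca(fx$g1); f2 <- fit_fpca(fx$g2)
  # rotate the first two score columns by an arbitrary orthogonal matrix, as
  # an eigensolver might under exactly tied eigenvalues
  th <- 0.7
  R <- diag(f1$n_components)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  t_rot <- wald_test(mfrg_fit(build_design(f1$scores %*% R, f2$scores), fx$Y))
  t_base <- wald_test(mfrg_fit(build_design(f1$scores, f2$scores), fx$Y))
  expect_equal(t_rot$statistic, t_base$statistic, tolerance = 1e-8)
})

test_that("pseudo-inverse path agrees with the plain path on full-rank fits", {
  fx <- make_pair_fixture(n = 90, K = 2, seed = 31)
  fit <- mfrg_fit(build_design(fit_fpca(fx$g1)$scores,
                               fit_fpca(fx$g2)$scores), fx$Y)
  t_solve <- wald_test(fit)
  # direct dense computation through the assembled Lambda
  v <- as.numeric(fit$gamma_hat)
  dense <- drop(t(v) %*% solve(interaction_covariance(fit), v))
  expect_equal(t_solve$statistic, dense, tolerance = 1e-8)
  # forcing the pseudo-inverse branch (cond_max = 1) must reduce df, warn,
  # and still produce a finite statistic
  expect_warning(t_pinv <- wald_test(fit, cond_max = 1),
                 class = "mfrg_rank_warning")
  expect_lt(t_pinv$df, t_solve$df)
})

test_that("collinear interaction columns are dropped with df reduced", {
  set.seed(33)
  n <- 50
  xi <- matrix(rnorm(n * 2), n, 2)
  xi[, 2] <- xi[, 1]              # duplicated component
  eta <- matrix(rnorm(n * 2), n, 2)
  d <- build_design(xi, eta)
  Y <- matrix(rnorm(n * 2), n, 2)
  expect_warning(fit <- mfrg_fit(d, Y), class = "mfrg_rank_warning")
  expect_lt(fit$q, 4)
  t <- wald_test(fit)
  expect_equal(t$df, fit$q * 2L)
})

test_that("Wald and LRT statistics converge to each other as n grows", {
  # both are chi-square(K*J*L) asymptotically; their gap shrinks with n
  gap <- vapply(c(200, 1000, 5000), function(n) {
    mean(vapply(1:15, function(b) {
      fx <- make_pair_fixture(n = n, K = 2, seed = 1000 * b + n)
      m <- mfrg(fx$g1, fx$g2, fx$Y, method = "both")
      abs(m$tests$wald$statistic - m$tests$lrt$statistic)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
})

test_that("missing phenotypes are dropped listwise and covariates enter the design", {
  fx <- make_pair_fixture(n = 100, K = 2, seed = 37)
  V <- cbind(age = rnorm(100), sex = rbinom(100, 1, 0.5))
  Ym <- fx$Y
  Ym[c(3, 50), 1] <- NA
  m <- mfrg(fx$g1, fx$g2, Ym, covariates = V)
  expect_equal(m$fit$n, 98)
  expect_true(all(c("age", "sex") %in% rownames(coef(m))))
  # accessors are consistent
  expect_equal(dim(residuals(m)), c(98, 2))
  expect_equal(vcov(m), interaction_covariance(m$fit))
})
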