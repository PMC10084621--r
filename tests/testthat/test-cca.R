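make_xy <- function(n = 50, p = 4, q = 3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  Y <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, paste0("y", 1:q)))
  Y[, 1] <- Y[, 1] + 0.8 * X[, 1]   # give the sets some shared structure
  list(X = X, Y = Y)
}

test_that("a shared variable yields a perfect first canonical correlation", {
  d <- make_xy()
  X <- cbind(d$X, shared = d$Y[, 1])
  fit <- fit_cca(X, d$Y)
  expect_equal(unname(fit$rho[1]), 1, tolerance = 1e-10)
})

test_that("the number of axes equals the smaller set size", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), 60, 5)
  Y <- matrix(rnorm(60 * 3), 60, 3)
  fit <- fit_cca(X, Y)
  expect_equal(fit$m, 3)
  expect_length(fit$rho, 3)
  expect_equal(dim(fit$x_scores), c(60L, 3L))
})

test_that("canonical correlations match the brute-force eigen oracle", {
  # fixed small integer instance
  X <- matrix(c(1, 3, 5, 2, 8, 4, 7, 6,
                2, 1, 9, 4, 3, 8, 5, 7), 8, 2)
  Y <- matrix(c(4, 1, 6, 3, 9, 2, 8, 5,
                1, 5, 2, 7, 4, 6, 3, 9), 8, 2)
  fit <- fit_cca(X, Y)
  expect_equal(unname(fit$rho), cca_eigen_oracle(X, Y), tolerance = 1e-8)

  # and on 50 random instances of varying shape
  for (s in 1:50) {
    set.seed(s)
    n <- sample(15:40, 1); p <- sample(2:4, 1); q <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    Y <- matrix(rnorm(n * q), n, q)
    fit <- fit_cca(X, Y)
    expect_equal(unname(fit$rho), cca_eigen_oracle(X, Y), tolerance = 1e-8)
    expect_equal(unname(fit$rho),
                 unname(stats::cancor(scale(X), scale(Y))$cor),
                 tolerance = 1e-8)
  }
})

test_that("canonical correlations are invariant to invertible transforms", {
  d <- make_xy(seed = 7)
  fit0 <- fit_cca(d$X, d$Y)
  set.seed(8)
  A <- matrix(rnorm(16), 4, 4); B <- matrix(rnorm(9), 3, 3)
  while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4, 4)
  while (abs(det(B)) < 0.1) B <- matrix(rnorm(9), 3, 3)
  fit1 <- fit_cca(d$X %*% A, d$Y)
  fit2 <- fit_cca(d$X, sweep(d$Y %*% B, 2, c(3, -1, 10), "+"))
  expect_equal(unname(fit0$rho), unname(fit1$rho), tolerance = 1e-8)
  expect_equal(unname(fit0$rho), unname(fit2$rho), tolerance = 1e-8)
})

test_that("scores have unit variance, reproduce rho, and are orthogonal", {
  d <- make_xy(seed = 9)
  fit <- fit_cca(d$X, d$Y)
  expect_equal(unname(apply(fit$x_scores, 2, var)), rep(1, fit$m),
               tolerance = 1e-10)
  expect_equal(unname(apply(fit$y_scores, 2, var)), rep(1, fit$m),
               tolerance = 1e-10)
  for (k in seq_len(fit$m))
    expect_equal(cor(fit$x_scores[, k], fit$y_scores[, k]),
                 unname(fit$rho[k]), tolerance = 1e-10)
  cu <- cor(fit$x_scores); cv <- cor(fit$y_scores)
  expect_lt(max(abs(cu[upper.tri(cu)])), 1e-8)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
})

test_that("cross-loadings equal loadings scaled by the canonical correlation", {
  d <- make_xy(seed = 10)
  fit <- fit_cca(d$X, d$Y)
  for (k in seq_len(fit$m)) {
    expect_equal(fit$x_cross_loadings[, k], fit$x_loadings[, k] * fit$rho[k],
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(fit$y_cross_loadings[, k], fit$y_loadings[, k] * fit$rho[k],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("permuting input rows permutes the scores identically", {
  d <- make_xy(seed = 11)
  rownames(d$X) <- rownames(d$Y) <- sprintf("i%02d", 1:50)
  fit <- fit_cca(d$X, d$Y)
  perm <- sample(50)
  fitp <- fit_cca(d$X[perm, ], d$Y[perm, ])
  expect_equal(fitp$x_scores, fit$x_scores[perm, ], tolerance = 1e-8)
  expect_equal(unname(fitp$rho), unname(fit$rho), tolerance = 1e-10)
})

test_that("degenerate inputs raise informative errors", {
  d <- make_xy()
  X <- cbind(d$X, dup = d$X[, 1])
  expect_error(fit_cca(X, d$Y), "rank deficient")
  expect_error(fit_cca(d$X[1:6, ], d$Y[1:6, ]), "more individuals")
})

test_that("Wilks ladder reduces to the classical correlation F-test", {
  r <- 0.5; N <- 20
  w <- wilks_ladder(r, N, 1, 1)
  expect_equal(w$df1, 1)
  expect_equal(w$df2, 18)
  expect_equal(w$F, r^2 / (1 - r^2) * (N - 2), tolerance = 1e-12)

  w0 <- wilks_ladder(c(0, 0), 30, 3, 2)
  expect_equal(w0$lambda, c(1, 1))
  expect_equal(w0$F, c(0, 0))
  expect_equal(w0$p_value, c(1, 1))

  expect_error(wilks_ladder(c(1, 0.2), 30, 3, 2), "\\[0, 1\\)")
})

test_that("analytic ladder p-value agrees with a permutation null", {
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- matrix(rnorm(n * 2), n, 2)
  fit <- fit_cca(X, Y)
  obs <- -sum(log(1 - fit$rho^2))   # monotone in Wilks' lambda for k = 1
  null_stat <- vapply(1:2000, function(i) {
    r <- cca_eigen_oracle(X, Y[sample(n), ])
    -sum(log(1 - r^2))
  }, numeric(1))
  p_perm <- (1 + sum(null_stat >= obs)) / 2001
  expect_lt(abs(fit$wilks$p_value[1] - p_perm), 0.05)
})

test_that("loading flags use a strict absolute threshold", {
  d <- make_xy(seed = 12)
  fit <- fit_cca(d$X, d$Y)
  tab <- significant_loadings(fit, threshold = 0.30)
  expect_equal(tab$significant, abs(tab$loading) > 0.30)
  # boundary: exactly 0.30 is not flagged
  fit2 <- fit
  fit2$x_loadings[1, 1] <- 0.30
  tab2 <- significant_loadings(fit2, threshold = 0.30)
  expect_false(tab2$significant[tab2$set == "phenotype" &
                                  tab2$variable == "x1" & tab2$axis == 1])
  expect_true(any(tab$significant[tab$loading < -0.3 | tab$loading > 0.3]))
})

test_that("canonical_scores joins ids and both variates per axis", {
  d <- make_xy(seed = 13)
  rownames(d$X) <- rownames(d$Y) <- sprintf("i%02d", 1:50)
  fit <- fit_cca(d$X, d$Y)
  sc <- canonical_scores(fit)
  expect_equal(names(sc),
               c("individual_id", "CCp1", "CCe1", "CCp2", "CCe2", "CCp3", "CCe3"))
  expect_equal(cor(sc$CCp1, sc$CCe1), unname(fit$rho[1]), tolerance = 1e-10)
  expect_equal(sc$individual_id, sprintf("i%02d", 1:50))
})
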