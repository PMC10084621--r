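#' Code environmental factors as a binary 0/1 matrix
#'
#' Fixed, documented coding so canonical weight signs are reproducible:
#' latitude high = 0 / central = 1; temperature 20 = 0 / 24 = 1; predator cue
#' absent = 0 / present = 1.  Canonical correlations themselves are invariant
#' to this choice; the signs of loadings are not.
#'
#' @param pheno a `phenotype_table`.
#' @return numeric matrix (individuals x 3) with columns `latitude`,
#'   `temperature`, `predator` and `rownames` the individual ids.
#' @export
code_environment <- function(pheno) {
  m <- cbind(latitude = as.numeric(pheno$latitude == "central"),
             temperature = as.numeric(pheno$temperature == 24),
             predator = as.numeric(pheno$predator == "present"))
  rownames(m) <- pheno$individual_id
  m
}

# symmetric inverse square root via eigendecomposition; errors on rank
# deficiency and names the offending column
.inv_sqrt <- function(S, label) {
  e <- eigen(S, symmetric = TRUE)
  tol <- max(dim(S)) * sqrt(.Machine$double.eps) * max(abs(e$values))
  if (any(e$values < tol)) {
    w <- abs(e$vectors[, which.min(e$values)])
    stopf("%s set is rank deficient after centering (dependent column: '%s')",
          label, colnames(S)[which.max(w)])
  }
  e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
}

#' Fit a canonical correlation analysis between two variable sets
#'
#' Both sets are standardized (mean 0, unit sample variance), then the
#' canonical structure is obtained from the singular value decomposition of
#' the whitened cross-covariance \eqn{\Sigma_{xx}^{-1/2}\Sigma_{xy}
#' \Sigma_{yy}^{-1/2}}: the singular values are the canonical correlations
#' and the transformed singular vectors the canonical weights.  Canonical
#' scores are scaled to unit sample variance; loadings are the correlations
#' of each variable with its own set's scores and cross-loadings with the
#' other set's scores.  Each axis is oriented so that the y-set weight of
#' largest magnitude is positive (canonical signs are otherwise arbitrary).
#'
#' @param X numeric matrix of phenotypic variables (individuals x p).
#' @param Y numeric matrix of environmental variables (individuals x q).
#' @return an object of class `cca_fit` with components `rho` (canonical
#'   correlations), `x_weights`, `y_weights` (for the standardized
#'   variables), `x_scores`, `y_scores`, `x_loadings`, `y_loadings`,
#'   `x_cross_loadings`, `y_cross_loadings`, `p`, `q`, `m`, `N` and `wilks`
#'   (the significance ladder from [wilks_ladder()]).
#' @seealso [wilks_ladder()], [significant_loadings()], [canonical_scores()]
#' @export
fit_cca <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  N <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (N <= p + q)
    stopf("need more individuals (%d) than variables (p + q = %d)", N, p + q)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(q))
  sx <- apply(X, 2, stats::sd); sy <- apply(Y, 2, stats::sd)
  if (any(sx == 0))
    stopf("constant column '%s' in the x set", colnames(X)[which(sx == 0)[1]])
  if (any(sy == 0))
    stopf("constant column '%s' in the y set", colnames(Y)[which(sy == 0)[1]])
  Xs <- scale(X); Ys <- scale(Y)

  Sxx <- stats::cov(Xs); Syy <- stats::cov(Ys); Sxy <- stats::cov(Xs, Ys)
  Kx <- .inv_sqrt(Sxx, "x"); Ky <- .inv_sqrt(Syy, "y")
  sv <- svd(Kx %*% Sxy %*% Ky)
  m <- min(p, q)
  rho <- pmin(pmax(sv$d[seq_len(m)], 0), 1)
  A <- Kx %*% sv$u[, seq_len(m), drop = FALSE]  # x weights (standardized scale)
  B <- Ky %*% sv$v[, seq_len(m), drop = FALSE]

  # orient each axis: y weight of largest |.| made positive
  for (k in seq_len(m)) {
    flip <- sign(B[which.max(abs(B[, k])), k])
    if (flip < 0) { A[, k] <- -A[, k]; B[, k] <- -B[, k] }
  }
  U <- Xs %*% A; V <- Ys %*% B
  # unit sample variance per score column
  U <- sweep(U, 2, apply(U, 2, stats::sd), "/")
  V <- sweep(V, 2, apply(V, 2, stats::sd), "/")
  axis_names <- paste0("axis", seq_len(m))
  dimnames(A) <- list(colnames(X), axis_names)
  dimnames(B) <- list(colnames(Y), axis_names)
  dimnames(U) <- list(rownames(X), axis_names)
  dimnames(V) <- list(rownames(Y), axis_names)

  res <- structure(list(
    rho = stats::setNames(rho, axis_names),
    x_weights = A, y_weights = B,
    x_scores = U, y_scores = V,
    x_loadings = stats::cor(X, U), y_loadings = stats::cor(Y, V),
    x_cross_loadings = stats::cor(X, V), y_cross_loadings = stats::cor(Y, U),
    p = p, q = q, m = m, N = N,
    coding = "binary 0/1 (high/20 °C/absent = 0)"), class = "cca_fit")
  # a perfect correlation degenerates the ladder (lambda = 0); leave it out
  res$wilks <- if (all(rho < 1 - 1e-12)) wilks_ladder(rho, N, p, q) else NULL
  res
}

#' Wilks' lambda significance ladder with Rao's F approximation
#'
#' Tests the joint significance of canonical correlations k..m for each k,
#' using \eqn{\Lambda_k = \prod_{i \ge k} (1 - \rho_i^2)} and Rao's
#' F approximation.  With \eqn{p' = p-k+1}, \eqn{q' = q-k+1}:
#' \eqn{s = \sqrt{(p'^2 q'^2 - 4) / (p'^2 + q'^2 - 5)}} (taken as 1 when the
#' denominator vanishes or \eqn{p'q' \le 3}), \eqn{t = (N-1) - (p+q+1)/2}
#' computed from the original set sizes at every rung,
#' \eqn{df_1 = p'q'}, \eqn{df_2 = s\,t - p'q'/2 + 1} and
#' \eqn{F = \frac{1-\Lambda_k^{1/s}}{\Lambda_k^{1/s}} \cdot \frac{df_2}{df_1}}.
#'
#' @param rho canonical correlations, descending, each in \[0, 1).
#' @param N number of individuals.
#' @param p,q number of variables in the two sets.
#' @return data.frame of class `wilks_ladder`, one row per rung k, with
#'   columns `k`, `rho`, `rho_sq`, `lambda`, `s`, `df1`, `df2` (unrounded),
#'   `F` and `p_value`.
#' @export
wilks_ladder <- function(rho, N, p, q) {
  m <- length(rho)
  stopifnot(m >= 1, N > p + q)
  if (any(rho < 0 | rho >= 1))
    stopf("canonical correlations must lie in [0, 1); got %.4g",
          rho[which(rho < 0 | rho >= 1)[1]])
  if (is.unsorted(rev(rho))) stopf("canonical correlations must be descending")
  t_ <- (N - 1) - (p + q + 1) / 2
  out <- data.frame(k = seq_len(m), rho = as.numeric(rho),
                    rho_sq = as.numeric(rho)^2, lambda = NA_real_,
                    s = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    F = NA_real_, p_value = NA_real_)
  for (k in seq_len(m)) {
    pp <- p - k + 1; qq <- q - k + 1
    lam <- prod(1 - rho[k:m]^2)
    den <- pp^2 + qq^2 - 5
    s <- if (den == 0 || pp * qq <= 3) 1 else sqrt((pp^2 * qq^2 - 4) / den)
    df1 <- pp * qq
    df2 <- s * t_ - df1 / 2 + 1
    lam_s <- lam^(1 / s)
    Fstat <- (1 - lam_s) / lam_s * df2 / df1
    out[k, c("lambda", "s", "df1", "df2", "F", "p_value")] <-
      c(lam, s, df1, df2, Fstat,
        stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  }
  class(out) <- c("wilks_ladder", "data.frame")
  out
}

#' Flag loadings exceeding the practical-significance threshold
#'
#' With large samples (N > 200) a canonical loading is conventionally read as
#' meaningful when its absolute value exceeds 0.30; the comparison is strict.
#'
#' @param fit a `cca_fit`.
#' @param threshold absolute loading cut-off, default 0.30.
#' @return data.frame with columns `set` ("phenotype"/"environment"),
#'   `variable`, `axis`, `loading`, `cross_loading`, `significant`.
#' @export
significant_loadings <- function(fit, threshold = 0.30) {
  stopifnot(inherits(fit, "cca_fit"))
  one <- function(L, CL, set) {
    data.frame(set = set,
               variable = rep(rownames(L), ncol(L)),
               axis = rep(seq_len(ncol(L)), each = nrow(L)),
               loading = as.vector(L), cross_loading = as.vector(CL),
               significant = abs(as.vector(L)) > threshold,
               stringsAsFactors = FALSE)
  }
  rbind(one(fit$x_loadings, fit$x_cross_loadings, "phenotype"),
        one(fit$y_loadings, fit$y_cross_loadings, "environment"))
}

#' Extract per-individual canonical scores
#'
#' @param fit a `cca_fit`.
#' @return data.frame with `individual_id` and, per axis k, `CCp<k>`
#'   (phenotype-set score) and `CCe<k>` (environment-set score).
#' @export
canonical_scores <- function(fit) {
  stopifnot(inherits(fit, "cca_fit"))
  ids <- rownames(fit$x_scores) %||% as.character(seq_len(fit$N))
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(fit$m)) {
    out[[paste0("CCp", k)]] <- fit$x_scores[, k]
    out[[paste0("CCe", k)]] <- fit$y_scores[, k]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.cca_fit <- function(x, ...) {
  cat(sprintf("Canonical correlation analysis: p = %d, q = %d, N = %d\n",
              x$p, x$q, x$N))
  cat("Canonical correlations:", paste(sprintf("%.3f", x$rho), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.cca_fit <- function(object, loading_threshold = 0.30, ...) {
  structure(list(fit = object,
                 wilks = object$wilks,
                 loadings = significant_loadings(object, loading_threshold)),
            class = "summary.cca_fit")
}

#' @export
print.summary.cca_fit <- function(x, ...) {
  print(x$fit)
  w <- x$wilks
  if (is.null(w)) {
    cat("\nWilks' lambda ladder unavailable (a canonical correlation is 1)\n")
    return(invisible(x))
  }
  cat("\nWilks' lambda ladder (rungs k..m):\n")
  disp <- data.frame(k = w$k, lambda = round(w$lambda, 2),
                     Rc = round(w$rho, 2), Rc_sq = round(w$rho_sq, 2),
                     F = round(w$F, 2), df1 = w$df1, df2 = round(w$df2),
                     p = signif(w$p_value, 3))
  print(disp, row.names = FALSE)
  sig <- x$loadings[x$loadings$significant, ]
  cat(sprintf("\n%d loading(s) exceed |%.2f|\n", nrow(sig), 0.30))
  invisible(x)
}

#' @export
coef.cca_fit <- function(object, set = c("x", "y"), ...) {
  set <- match.arg(set)
  if (set == "x") object$x_weights else object$y_weights
}

#' @export
plot.cca_fit <- function(x, axis = 1, ...) {
  plot(x$x_scores[, axis], x$y_scores[, axis],
       xlab = sprintf("CCp%d (phenotype score)", axis),
       ylab = sprintf("CCe%d (environment score)", axis),
       main = sprintf("Canonical axis %d (rho = %.2f)", axis, x$rho[axis]),
       ...)
  graphics::abline(stats::lm(x$y_scores[, axis] ~ x$x_scores[, axis]),
                   lty = 2)
  invisible(x)
}
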