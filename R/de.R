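# Negative-binomial two-group differential expression: CPM filtering, TMM
# normalization, conditional-likelihood dispersion estimation with
# weighted-likelihood shrinkage, exact conditional test, BH adjustment.

#' Filter weakly expressed genes
#'
#' Keeps genes whose counts-per-million exceed `min_cpm` (strictly) in at
#' least `min_samples` samples; by default `min_samples` is the size of the
#' smaller group.
#'
#' @param counts genes x samples count matrix.
#' @param groups factor/character of length ncol(counts) with two levels.
#' @param min_cpm CPM threshold, default 1.
#' @param min_samples minimum number of samples above threshold.
#' @return the filtered count matrix.
#' @export
filter_low_expression <- function(counts, groups, min_cpm = 1,
                                  min_samples = NULL) {
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("sample with zero library size")
  g <- table(groups)
  if (length(g) != 2) stopf("need exactly two groups, got %d", length(g))
  if (is.null(min_samples)) min_samples <- min(g)
  cpm <- t(t(counts) / lib) * 1e6
  keep <- rowSums(cpm > min_cpm) >= min_samples
  if (!any(keep))
    stopf("no gene passes CPM > %g in >= %d samples; lower the thresholds",
          min_cpm, min_samples)
  counts[keep, , drop = FALSE]
}

# weighted trimmed mean of M-values between one sample and the reference
.tmm_one <- function(obs, ref, lib_obs, lib_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  obs <- obs[keep]; ref <- ref[keep]
  p_o <- obs / lib_obs; p_r <- ref / lib_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)   # average ranks: invariant to gene order
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep2)) return(1)
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values composition-correction factors.  The reference
#' sample is the one whose upper-quartile CPM is closest to the mean upper
#' quartile.  M values (log2 expression ratios) and A values (average log2
#' abundance) are computed over genes nonzero in both samples; 30% of each M
#' tail and 5% of each A tail are trimmed; the factor is 2 to the
#' precision-weighted mean of the surviving M values (inverse binomial
#' variance weights).  Factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @param logratio_trim,sum_trim trim fractions per tail.
#' @return data.frame of class `norm_factors` with `sample`, `lib_size`,
#'   `factor`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stopf("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0))
    stopf("sample '%s' has zero library size",
          colnames(counts)[which(lib == 0)[1]])
  uq <- apply(t(t(counts) / lib), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(i)
    .tmm_one(counts[, i], counts[, ref], lib[i], lib[ref],
             logratio_trim, sum_trim), numeric(1))
  f <- f / geomean(f)
  out <- data.frame(sample = colnames(counts) %||% seq_along(lib),
                    lib_size = lib, factor = f, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("norm_factors", "data.frame")
  out
}

# NB conditional log-likelihood of a group of counts given their sum, for
# equal library sizes; vectorized over genes.  y: genes x samples matrix.
.cond_ll <- function(y, r) {
  # r = 1/phi may be scalar or per-gene vector
  n <- ncol(y)
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

# vectorized golden-section maximization of f (vector-valued) on log scale
.golden_max <- function(f, lower, upper, n_genes, iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- rep(log(lower), n_genes); b <- rep(log(upper), n_genes)
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(exp(c_)); fd <- f(exp(d_))
  for (i in seq_len(iter)) {
    go_right <- fc < fd
    a <- ifelse(go_right, c_, a)
    b <- ifelse(go_right, b, d_)
    c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
    fc <- f(exp(c_)); fd <- f(exp(d_))
  }
  exp((a + b) / 2)
}

#' Estimate common and tagwise NB dispersions
#'
#' Counts are first rescaled to a common (geometric-mean) effective library
#' and rounded, making samples exchangeable within a group; the dispersion is
#' then estimated by maximizing the conditional log-likelihood of each
#' group's counts given the group sum.  The common dispersion maximizes the
#' likelihood summed over all genes; tagwise dispersions maximize each
#' gene's likelihood plus `prior_df` times the average per-gene likelihood
#' (weighted-likelihood empirical-Bayes shrinkage toward the common value).
#' Optimization is golden-section search on log dispersion in \[1e-4, 10\].
#'
#' @param counts filtered genes x samples count matrix.
#' @param groups two-level grouping of the samples.
#' @param norm optional [tmm_factors()] result (computed if missing).
#' @param prior_df shrinkage weight, default 10.
#' @return list of class `dispersion_model` with `common`, `tagwise`,
#'   `prior_df` and the `pseudo` (equalized, rounded) counts used.
#' @export
estimate_dispersions <- function(counts, groups, norm = NULL, prior_df = 10) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stopf("need exactly two groups")
  if (any(table(groups) < 2))
    stopf("each group needs >= 2 samples for dispersion estimation")
  if (is.null(norm)) norm <- tmm_factors(counts)
  eff <- norm$lib_size * norm$factor
  L_star <- geomean(eff)
  scaled <- t(t(counts) * (L_star / eff))   # equalized, unrounded
  pseudo <- round(scaled)
  g1 <- pseudo[, groups == levels(groups)[1], drop = FALSE]
  g2 <- pseudo[, groups == levels(groups)[2], drop = FALSE]
  ll_gene <- function(phi) {
    r <- 1 / phi        # scalar or per-gene vector; recycles down gene rows
    .cond_ll(g1, r) + .cond_ll(g2, r)
  }
  G <- nrow(counts)
  phi_common <- .golden_max(function(phi) sum(ll_gene(phi[1])), 1e-4, 10, 1)
  # common-likelihood contribution lbar(phi) = mean_g l_g(phi) is a smooth 1-D
  # function; tabulate it once and spline so the per-gene search stays O(G)
  grid <- seq(log(1e-4), log(10), length.out = 120)
  lbar_fun <- stats::splinefun(grid,
                               vapply(grid, function(lp) mean(ll_gene(exp(lp))),
                                      numeric(1)))
  obj <- function(phi) ll_gene(phi) + prior_df * lbar_fun(log(phi))
  tagwise <- .golden_max(obj, 1e-4, 10, G)
  structure(list(common = phi_common,
                 tagwise = stats::setNames(tagwise, rownames(counts)),
                 prior_df = prior_df, pseudo = pseudo, scaled = scaled,
                 lib_common = L_star, groups = groups),
            class = "dispersion_model")
}

#' Exact negative-binomial test for a two-group contrast
#'
#' Per gene, the group sums of the library-equalized pseudo-counts are
#' compared by the conditional distribution of the high-group sum given the
#' total: with per-sample NB(mu, phi) counts the conditional pmf is free of
#' mu, so it is enumerated exactly.  The two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one.  Log2
#' fold changes (high vs low group) use normalized group means with a
#' proportional prior count of 0.125 per group.  P-values are BH-adjusted
#' over all tested genes.
#'
#' @param counts filtered genes x samples count matrix (raw counts; columns
#'   must include every contrast id).
#' @param contrast a `contrast` from [select_extremes()], or a list with
#'   `high_ids`/`low_ids`.
#' @param model optional `dispersion_model` fitted on the contrast samples
#'   (computed if missing).
#' @param prior_df passed to [estimate_dispersions()] when `model` is NULL.
#' @return data.frame of class `de_result`: `gene`, `logFC`, `logCPM`,
#'   `p_value`, `fdr`, with attributes `axis`/`basis` from the contrast.
#' @export
exact_test <- function(counts, contrast, model = NULL, prior_df = 10) {
  counts <- as.matrix(counts)
  ids <- c(contrast$high_ids, contrast$low_ids)
  miss <- setdiff(ids, colnames(counts))
  if (length(miss))
    stopf("contrast individual '%s' absent from the count matrix", miss[1])
  sub <- counts[, ids, drop = FALSE]
  groups <- factor(rep(c("high", "low"),
                       c(length(contrast$high_ids), length(contrast$low_ids))),
                   levels = c("high", "low"))
  if (is.null(model)) model <- estimate_dispersions(sub, groups,
                                                    prior_df = prior_df)
  pseudo <- model$pseudo
  if (!is.null(colnames(pseudo))) {
    s_high <- intersect(ids[groups == "high"], colnames(pseudo))
    s_low <- intersect(ids[groups == "low"], colnames(pseudo))
  } else {
    s_high <- which(groups == "high"); s_low <- which(groups == "low")
  }
  n1 <- length(s_high); n2 <- length(s_low)
  s1 <- rowSums(pseudo[, s_high, drop = FALSE])
  s2 <- rowSums(pseudo[, s_low, drop = FALSE])
  u1 <- rowSums(model$scaled[, s_high, drop = FALSE])
  u2 <- rowSums(model$scaled[, s_low, drop = FALSE])
  phi <- model$tagwise
  pv <- vapply(seq_len(nrow(pseudo)), function(g)
    .exact_nb_p(s1[g], s2[g], n1, n2, phi[g]), numeric(1))
  # fold changes and abundance from the unrounded equalized counts
  # (rounding is needed only for the integer conditional test)
  m1 <- u1 / n1; m2 <- u2 / n2
  prior <- 0.125 * model$lib_common / 1e6   # 0.125 counts per million
  logFC <- log2((m1 + prior) / (m2 + prior))
  logCPM <- log2(((u1 + u2) / (n1 + n2) + 0.25) / model$lib_common * 1e6)
  out <- data.frame(gene = rownames(pseudo) %||% seq_len(nrow(pseudo)),
                    logFC = logFC, logCPM = logCPM, p_value = pv,
                    fdr = stats::p.adjust(pv, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "axis") <- contrast$axis
  attr(out, "basis") <- contrast$basis
  class(out) <- c("de_result", "data.frame")
  out
}

# conditional two-sided exact NB p-value for observed high-group sum s1 with
# total t = s1 + s2; the conditional pmf over x = 0..t is
#   P(x) proportional to choose-like Gamma terms with sizes n1/phi, n2/phi
.exact_nb_p <- function(s1, s2, n1, n2, phi) {
  t_ <- s1 + s2
  if (t_ == 0) return(1)
  if (phi < 1e-10) phi <- 1e-10
  r1 <- n1 / phi; r2 <- n2 / phi
  x <- 0:t_
  logp <- lgamma(x + r1) - lgamma(x + 1) + lgamma(t_ - x + r2) -
    lgamma(t_ - x + 1)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  sum(p[p <= p[s1 + 1] * (1 + 1e-10)])
}

#' @export
print.de_result <- function(x, n = 10, fdr = 0.05, ...) {
  cat(sprintf("de_result: %d genes tested, %d at FDR < %g\n",
              nrow(x), sum(x$fdr < fdr), fdr))
  top <- x[order(x$p_value), ][seq_len(min(n, nrow(x))), ]
  print(as.data.frame(top), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full two-group DE analysis for one contrast
#'
#' Convenience wrapper: subset the counts to the contrast individuals,
#' filter, normalize, estimate dispersions and run the exact test.
#'
#' @inheritParams exact_test
#' @param min_cpm,min_samples passed to [filter_low_expression()].
#' @return a `de_result`.
#' @export
de_analysis <- function(counts, contrast, min_cpm = 1, min_samples = NULL,
                        prior_df = 10) {
  ids <- c(contrast$high_ids, contrast$low_ids)
  miss <- setdiff(ids, colnames(counts))
  if (length(miss))
    stopf("contrast individual '%s' absent from the count matrix", miss[1])
  sub <- as.matrix(counts)[, ids, drop = FALSE]
  groups <- factor(rep(c("high", "low"),
                       c(length(contrast$high_ids), length(contrast$low_ids))),
                   levels = c("high", "low"))
  filtered <- filter_low_expression(sub, groups, min_cpm, min_samples)
  exact_test(filtered, contrast, prior_df = prior_df)
}
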