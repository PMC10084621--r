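nb_matrix <- function(G, n, mu, phi, seed = 1, lib = NULL) {
  set.seed(seed)
  base <- if (length(mu) == 1) rep(mu, G) else mu
  m <- matrix(rnbinom(G * n, mu = base, size = 1 / phi), G,
              dimnames = list(sprintf("g%04d", 1:G), sprintf("s%02d", 1:n)))
  m
}

two_group_contrast <- function(n1, n2) {
  list(axis = 1, basis = "CCp",
       high_ids = sprintf("s%02d", seq_len(n1)),
       low_ids = sprintf("s%02d", n1 + seq_len(n2)))
}

test_that("expression filter keeps genes by CPM in enough samples", {
  lib <- 1e6
  counts <- rbind(zero = c(0, 0, 0, 0),
                  strong = c(100, 100, 100, 100),
                  rare = c(40, 0, 0, 0))
  counts <- rbind(counts, filler = lib - colSums(counts))
  colnames(counts) <- paste0("s", 1:4)
  groups <- c("a", "a", "b", "b")
  kept <- filter_low_expression(counts, groups, min_cpm = 1)
  expect_true("strong" %in% rownames(kept))       # 100 CPM everywhere
  expect_false("zero" %in% rownames(kept))
  expect_false("rare" %in% rownames(kept))        # above threshold in 1 < 2 samples
  # min_cpm = 0 with min_samples = 1: only the all-zero gene is removed
  kept0 <- filter_low_expression(counts, groups, min_cpm = 0, min_samples = 1)
  expect_setequal(rownames(kept0), c("strong", "rare", "filler"))
})

test_that("TMM factors are 1 for identical or rescaled compositions", {
  m <- nb_matrix(500, 1, 200, 0.05, seed = 2)
  counts <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  expect_equal(tmm_factors(counts)$factor, rep(1, 3), tolerance = 1e-12)
  counts2 <- cbind(s1 = m[, 1], s2 = 2L * m[, 1], s3 = m[, 1])
  expect_equal(tmm_factors(counts2)$factor, rep(1, 3), tolerance = 1e-12)
})

test_that("a contaminated sample gets a factor below 1, matching a direct recomputation", {
  set.seed(3)
  G <- 1000
  mu <- rlnorm(G, log(100), 0.7)
  draw <- function() rnbinom(G, mu = mu, size = 10)
  contaminated <- draw()
  hot <- sample(G, G / 10)
  contaminated[hot] <- contaminated[hot] * 8L   # 10% high-count contaminants
  counts <- cbind(s1 = draw(), s2 = draw(), s3 = contaminated)
  rownames(counts) <- sprintf("g%04d", 1:G)
  nf <- tmm_factors(counts)
  f3 <- nf$factor[3]
  expect_lt(f3, 1)

  # independent recomputation of the trimmed weighted mean against the
  # upper-quartile reference sample
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(cc) quantile(cc / sum(cc), 0.75))
  iref <- which.min(abs(uq - mean(uq)))
  o <- counts[, 3]; r <- counts[, iref]
  keep <- o > 0 & r > 0
  M <- log2((o[keep] / lib[3]) / (r[keep] / lib[iref]))
  A <- 0.5 * (log2(o[keep] / lib[3]) + log2(r[keep] / lib[iref]))
  w <- (lib[3] - o[keep]) / (lib[3] * o[keep]) +
    (lib[iref] - r[keep]) / (lib[iref] * r[keep])
  n <- length(M)
  sel <- rank(M) > n * 0.3 & rank(M) <= n * 0.7 &
    rank(A) > n * 0.05 & rank(A) <= n * 0.95
  f_direct <- 2^(sum((M / w)[sel]) / sum((1 / w)[sel]))
  # compare relative to the reference sample's factor
  expect_lt(abs(f3 / nf$factor[iref] - f_direct), 0.02)

  if (requireNamespace("edgeR", quietly = TRUE)) {
    fe <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_lt(abs(f3 - fe[3]), 0.05)   # same method, independent code path
  }
})

test_that("dispersion estimation recovers the simulation truth", {
  groups <- rep(c("a", "b"), each = 10)
  # Poisson data: common dispersion collapses toward zero
  set.seed(4)
  pois <- matrix(rpois(2000 * 20, lambda = rlnorm(2000, log(50), 1)), 2000,
                 dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:20)))
  mp <- estimate_dispersions(pois, groups)
  expect_lt(mp$common, 0.01)

  nb <- nb_matrix(2000, 20, rlnorm(2000, log(50), 1), phi = 0.2, seed = 5)
  mn <- estimate_dispersions(nb, groups)
  expect_gt(mn$common, 0.15)
  expect_lt(mn$common, 0.25)

  # infinite prior collapses tagwise onto the common value
  m_inf <- estimate_dispersions(nb, groups, prior_df = 1e8)
  expect_equal(unname(m_inf$tagwise), rep(m_inf$common, 2000),
               tolerance = 0.02)

  expect_error(estimate_dispersions(nb[, 1:3], c("a", "a", "b")),
               ">= 2 samples")

  if (requireNamespace("edgeR", quietly = TRUE)) {
    y <- edgeR::DGEList(nb, group = groups)
    y <- edgeR::calcNormFactors(y)
    y <- edgeR::estimateCommonDisp(y)
    expect_lt(abs(mn$common - y$common.dispersion), 0.03)
  }
})

test_that("exact test p-values match the conditional-enumeration oracle", {
  set.seed(6)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    s1 <- sample(0:120, 1); s2 <- sample(0:(200 - min(s1, 120)), 1)
    phi <- runif(1, 0.01, 0.8)
    expect_equal(ccadeg:::.exact_nb_p(s1, s2, n1, n2, phi),
                 exact_nb_oracle(s1, s2, n1, n2, phi), tolerance = 1e-10)
  }
})

test_that("a clear two-group split is called with the right sign", {
  counts <- rbind(hit = c(0, 0, 0, 0, 50, 60, 55, 45),
                  flat = rep(30, 8))
  counts <- rbind(counts, matrix(rpois(200 * 8, 30), 200))
  rownames(counts)[3:202] <- sprintf("bg%03d", 1:200)
  colnames(counts) <- sprintf("s%02d", 1:8)
  de <- de_analysis(counts, two_group_contrast(4, 4), min_cpm = 0,
                    min_samples = 1)
  hit <- de[de$gene == "hit", ]
  expect_lt(hit$p_value, 1e-6)
  expect_lt(hit$logFC, -3)   # first (high) group has zero counts
})

test_that("swapping group labels flips logFC and preserves p-values", {
  counts <- nb_matrix(300, 12, 80, 0.1, seed = 7)
  ct <- two_group_contrast(6, 6)
  swapped <- list(axis = 1, basis = "CCp",
                  high_ids = ct$low_ids, low_ids = ct$high_ids)
  de1 <- de_analysis(counts, ct)
  de2 <- de_analysis(counts, swapped)
  expect_equal(de1$p_value, de2$p_value, tolerance = 1e-12)
  expect_equal(de1$logFC, -de2$logFC, tolerance = 1e-12)
})

test_that("doubling all counts leaves logFC essentially unchanged", {
  counts <- nb_matrix(300, 8, 60, 0.1, seed = 8)
  ct <- two_group_contrast(4, 4)
  de1 <- de_analysis(counts, ct)
  de2 <- de_analysis(2L * counts, ct)
  expect_lt(max(abs(de1$logFC - de2$logFC)), 0.01)
})

test_that("null data give uniform p-values and BH keeps its guarantees", {
  counts <- nb_matrix(2000, 20, rlnorm(2000, log(50), 1), 0.2, seed = 9)
  de <- de_analysis(counts, two_group_contrast(10, 10))
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  expect_true(all(de$fdr >= de$p_value))
  expect_equal(de$fdr, p.adjust(de$p_value, "BH"))
  # row order of the input does not change per-gene results
  perm <- sample(nrow(counts))
  de_p <- de_analysis(counts[perm, ], two_group_contrast(10, 10))
  expect_equal(de_p[match(de$gene, de_p$gene), "fdr"], de$fdr,
               tolerance = 1e-12)
})
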