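# shared fixture builders; everything is generated in code at test time

toy_phenotype_df <- function(n = 3) {
  data.frame(
    individual_id = sprintf("ind%02d", seq_len(n)),
    pond_id = rep(c("h_p1", "c_p1"), length.out = n),
    latitude = rep(c("high", "central"), length.out = n),
    temperature = rep(c(20, 24), length.out = n),
    predator = rep(c("absent", "present"), length.out = n),
    maternal_line = sprintf("f%02d", seq_len(n)),
    mass = seq(4, 6, length.out = n),
    head_width = seq(0.9, 1.1, length.out = n),
    wing_pad = seq(1.8, 2.2, length.out = n),
    dev_time = seq(20L, 20L + n - 1L),
    stringsAsFactors = FALSE)
}

write_toy_counts <- function(path, counts = NULL, chrom = NULL,
                             comment = TRUE) {
  if (is.null(counts)) {
    counts <- matrix(c(5L, 10L, 0L, 3L, 7L, 2L), nrow = 2, byrow = TRUE,
                     dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  }
  if (is.null(chrom)) chrom <- rep("1", nrow(counts))
  df <- data.frame(Geneid = rownames(counts), Chr = chrom, Start = 1,
                   End = 1000, Strand = "+", Length = 1000)
  df <- cbind(df, as.data.frame(counts))
  con <- file(path, "w")
  if (comment) writeLines("# Program:featureCounts v2.0.3", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

# OBO text for a linear is_a chain t1 <- t2 <- ... <- tn (child points at the
# previous term), single namespace
chain_obo <- function(path, n = 5, ns = "biological_process") {
  ids <- sprintf("GO:%07d", seq_len(n))
  blocks <- vapply(seq_len(n), function(i) {
    isa <- if (i > 1) sprintf("is_a: %s ! parent", ids[i - 1]) else ""
    paste(c("[Term]", sprintf("id: %s", ids[i]),
            sprintf("name: term%d", i), sprintf("namespace: %s", ns),
            isa, ""), collapse = "\n")
  }, character(1))
  writeLines(c("format-version: 1.2", "", blocks), path)
  ids
}

# minimal hand-built design table of arbitrary size (balanced temperature)
flat_design <- function(n) {
  as_phenotype_table(data.frame(
    individual_id = sprintf("i%05d", seq_len(n)),
    pond_id = "p1", latitude = "high",
    temperature = rep(c(20, 24), length.out = n),
    predator = "absent", maternal_line = "f1",
    stringsAsFactors = FALSE))
}

# de_result-like table for overlap tests
fake_de <- function(genes, logfc, fdr) {
  out <- data.frame(gene = genes, logFC = logfc, logCPM = 5,
                    p_value = fdr, fdr = fdr, stringsAsFactors = FALSE)
  class(out) <- c("de_result", "data.frame")
  out
}

# independent hypergeometric upper tail by direct summation of point masses
hyper_upper_oracle <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# independent conditional NB exact-test oracle: builds the conditional pmf
# from dnbinom products at an arbitrary mu (the conditional law is free of
# mu) and sums outcomes no more likely than the observed split
exact_nb_oracle <- function(s1, s2, n1, n2, phi, mu = 7.3) {
  t_ <- s1 + s2
  x <- 0:t_
  num <- stats::dnbinom(x, size = n1 / phi, mu = n1 * mu) *
    stats::dnbinom(t_ - x, size = n2 / phi, mu = n2 * mu)
  p <- num / sum(num)
  sum(p[p <= p[s1 + 1] * (1 + 1e-10)])
}

# brute-force canonical correlations: eigenvalues of Sxx^-1 Sxy Syy^-1 Syx
cca_eigen_oracle <- function(X, Y) {
  Sxx <- stats::cov(X); Syy <- stats::cov(Y)
  Sxy <- stats::cov(X, Y); Syx <- t(Sxy)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% Syx
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
  sqrt(pmax(ev[seq_len(min(ncol(X), ncol(Y)))], 0))
}
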