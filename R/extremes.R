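#' Select extreme individuals on a canonical axis
#'
#' Builds a two-group contrast from the `n_tail` individuals with the highest
#' and the `n_tail` with the lowest canonical scores on one axis of one
#' variate (CCp = phenotype set, CCe = environment set).  Ties at a tail
#' boundary are broken by ascending individual id, so selection is
#' deterministic.
#'
#' @param scores data.frame from [canonical_scores()].
#' @param axis canonical axis number.
#' @param basis `"CCp"` or `"CCe"`.
#' @param n_tail individuals per tail, default 10.
#' @return list of class `contrast` with `axis`, `basis`, `high_ids`,
#'   `low_ids`.
#' @export
select_extremes <- function(scores, axis = 1, basis = c("CCp", "CCe"),
                            n_tail = 10) {
  basis <- match.arg(basis)
  col <- paste0(basis, axis)
  if (!col %in% names(scores)) stopf("no score column '%s'", col)
  s <- scores[[col]]
  if (any(!is.finite(s))) stopf("non-finite canonical scores")
  N <- length(s)
  if (2 * n_tail > N)
    stopf("2 * n_tail = %d exceeds the %d scored individuals", 2 * n_tail, N)
  ids <- as.character(scores$individual_id)
  ord <- order(s, ids)                      # ascending score, ties by id
  structure(list(axis = axis, basis = basis,
                 high_ids = sort(ids[rev(ord)[seq_len(n_tail)]]),
                 low_ids = sort(ids[ord[seq_len(n_tail)]])),
            class = "contrast")
}

#' @export
print.contrast <- function(x, ...) {
  cat(sprintf("contrast: %s axis %d, %d vs %d individuals\n",
              x$basis, x$axis, length(x$high_ids), length(x$low_ids)))
  invisible(x)
}

#' Intersect two DEG lists directionally into candidate genes
#'
#' A gene is an `up` candidate when it passes the FDR threshold in both the
#' CCp- and the CCe-based analysis with positive log fold change (higher in
#' the high-score group) in both; `down` symmetrically.  Genes significant
#' in both but with opposite signs are excluded and reported.
#'
#' @param de_ccp,de_cce `de_result` tables over the same gene universe.
#' @param fdr FDR threshold, default 0.05.
#' @return list of class `candidate_genes` with `axis` (taken from the
#'   inputs when present), `up`, `down`, `discordant` (character vectors)
#'   and `table` (per-candidate logFC/FDR from both analyses).
#' @export
directional_overlap <- function(de_ccp, de_cce, fdr = 0.05) {
  if (!setequal(de_ccp$gene, de_cce$gene))
    stopf("the two DE analyses cover different gene universes")
  b <- de_cce[match(de_ccp$gene, de_cce$gene), ]
  a <- de_ccp
  sig <- a$fdr < fdr & b$fdr < fdr
  up <- sig & a$logFC > 0 & b$logFC > 0
  down <- sig & a$logFC < 0 & b$logFC < 0
  disc <- sig & (sign(a$logFC) * sign(b$logFC) < 0)
  keep <- up | down
  structure(list(
    axis = attr(de_ccp, "axis"),
    up = a$gene[up], down = a$gene[down], discordant = a$gene[disc],
    n_sig_ccp = sum(a$fdr < fdr), n_sig_cce = sum(b$fdr < fdr),
    table = data.frame(gene = a$gene[keep],
                       direction = ifelse(up[keep], "up", "down"),
                       logfc_ccp = a$logFC[keep], logfc_cce = b$logFC[keep],
                       fdr_ccp = a$fdr[keep], fdr_cce = b$fdr[keep],
                       stringsAsFactors = FALSE)),
    class = "candidate_genes")
}

#' @export
print.candidate_genes <- function(x, ...) {
  cat(sprintf("candidate genes: %d up, %d down (%d discordant excluded)\n",
              length(x$up), length(x$down), length(x$discordant)))
  invisible(x)
}
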