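# GO annotation transfer, true-path propagation, hypergeometric enrichment
# and level-based functional categorization.

#' Normalize a gene name for cross-species matching
#'
#' Lowercases, strips punctuation/whitespace and removes a trailing
#' "-like" suffix, so e.g. `"Catalase-LIKE"` and `"catalase"` match.
#'
#' @param x character vector of gene names.
#' @return normalized names.
#' @export
normalize_gene_name <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("[- ]?like$", "", x)
  gsub("[^a-z0-9]+", "", x)
}

#' Transfer GO annotations by multi-species consensus
#'
#' A target gene receives a GO-term set S when at least `min_species`
#' distinct reference species carry a gene with the same normalized name and
#' exactly the set S.  Sets are counted separately, so one divergent species
#' does not spoil an otherwise qualifying consensus.  Unmatched genes stay
#' unannotated.
#'
#' @param target_genes data.frame with columns `gene` (id) and `name`
#'   (gene name used for matching).
#' @param reference a `reference_annotation` from [read_reference()].
#' @param min_species required number of distinct supporting species,
#'   default 3.
#' @return an `annotation_set`: named list gene id -> character vector of GO
#'   ids (attribute `propagated` FALSE).
#' @export
transfer_annotations <- function(target_genes, reference, min_species = 3) {
  stopifnot(all(c("gene", "name") %in% names(target_genes)),
            nrow(reference) > 0, min_species >= 1)
  ref_key <- normalize_gene_name(reference$gene_name)
  set_key <- vapply(reference$go_terms, paste, character(1), collapse = ";")
  ann <- list()
  tgt_key <- normalize_gene_name(target_genes$name)
  for (i in seq_len(nrow(target_genes))) {
    rows <- which(ref_key == tgt_key[i])
    if (!length(rows)) next
    # distinct species per identical GO set
    support <- tapply(reference$species[rows], set_key[rows],
                      function(s) length(unique(s)))
    ok <- names(support)[support >= min_species]
    if (!length(ok)) next
    best <- ok[which.max(support[ok])]    # ties: most-supported set wins
    ann[[target_genes$gene[i]]] <- strsplit(best, ";", fixed = TRUE)[[1]]
  }
  structure(ann, propagated = FALSE, class = "annotation_set")
}

#' Close annotations under is_a ancestry (true-path rule)
#'
#' Augments each gene's term set with every is_a ancestor within the same
#' namespace.  Idempotent.
#'
#' @param ann named list gene -> GO ids (or an `annotation_set`).
#' @param onto an `ontology_graph`.
#' @return the propagated `annotation_set` (attribute `propagated` TRUE).
#' @export
propagate <- function(ann, onto) {
  stopifnot(inherits(onto, "ontology_graph"))
  terms <- unique(unlist(ann, use.names = FALSE))
  unknown <- setdiff(terms, onto$terms$id)
  if (length(unknown))
    stopf("annotation names term '%s' absent from the ontology", unknown[1])
  # ancestors via graph reachability (edges point child -> parent)
  anc <- lapply(igraph::ego(onto$graph, order = .Machine$integer.max,
                            nodes = terms, mode = "out"),
                function(v) names(v))
  names(anc) <- terms
  out <- lapply(ann, function(ts)
    sort(unique(unlist(anc[ts], use.names = FALSE))))
  structure(out, propagated = TRUE, class = "annotation_set")
}

#' Hypergeometric GO-term enrichment
#'
#' Per namespace, every term annotated to at least `min_term_size`
#' background genes and at least one candidate gene is tested with the
#' hypergeometric upper tail \eqn{P(X \ge k)} for k of n candidates carrying
#' the term against K of N annotated background genes.  P-values are
#' BH-adjusted within namespace.  Background and counts are defined over
#' annotated genes only (unannotated genes are untestable).
#'
#' @param candidates character vector of candidate gene ids.
#' @param background character vector of background gene ids (the gene
#'   universe; will be intersected with the annotated genes).
#' @param ann a propagated `annotation_set`.
#' @param onto an `ontology_graph` (for term namespaces and names).
#' @param fdr significance threshold, default 0.05.
#' @param min_term_size minimum background genes per tested term, default 3.
#' @return data.frame of class `enrichment_result`: `term`, `name`,
#'   `namespace`, `k`, `K`, `n`, `N_bg`, `p_value`, `fdr`, `significant`.
#' @export
enrich <- function(candidates, background, ann, onto, fdr = 0.05,
                   min_term_size = 3) {
  stopifnot(inherits(onto, "ontology_graph"))
  if (!isTRUE(attr(ann, "propagated")))
    warnf("annotation set is not propagated; enrichment will ignore ancestor terms")
  if (!all(candidates %in% background))
    stopf("candidates must be a subset of the background")
  ns_of <- stats::setNames(onto$terms$namespace, onto$terms$id)
  name_of <- stats::setNames(onto$terms$name, onto$terms$id)
  bg <- intersect(background, names(ann))
  cand <- intersect(candidates, bg)
  out <- NULL
  for (ns in unique(onto$terms$namespace)) {
    keep_term <- function(ts) ts[ns_of[ts] == ns]
    bg_terms <- lapply(ann[bg], keep_term)
    bg_ns <- bg[lengths(bg_terms) > 0]
    if (!length(bg_ns)) next
    K_tab <- table(unlist(bg_terms, use.names = FALSE))
    cand_ns <- intersect(cand, bg_ns)
    k_tab <- table(unlist(lapply(ann[cand_ns], keep_term), use.names = FALSE))
    testable <- names(K_tab)[K_tab >= min_term_size & names(K_tab) %in% names(k_tab)]
    if (!length(testable)) next
    N_bg <- length(bg_ns); n <- length(cand_ns)
    k <- as.integer(k_tab[testable]); K <- as.integer(K_tab[testable])
    p <- stats::phyper(k - 1, K, N_bg - K, n, lower.tail = FALSE)
    out <- rbind(out, data.frame(
      term = testable, name = unname(name_of[testable]), namespace = ns,
      k = k, K = K, n = n, N_bg = N_bg, p_value = p,
      fdr = stats::p.adjust(p, method = "BH"), stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(term = character(0), name = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N_bg = integer(0),
                      p_value = numeric(0), fdr = numeric(0))
  out$significant <- out$fdr < fdr
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Functional categorization at a fixed ontology depth
#'
#' Counts, per namespace, how many of the given genes map to each term at
#' depth `level` below the namespace root (depth = shortest is_a path from
#' the root; the root itself is depth 0).  A gene annotated to a deeper term
#' is counted under every depth-`level` ancestor it reaches
#' (multi-membership over the DAG).
#'
#' @param genes character vector of gene ids.
#' @param ann a propagated `annotation_set`.
#' @param onto an `ontology_graph`.
#' @param level depth from the namespace root, default 2.
#' @return data.frame `term`, `name`, `namespace`, `count`.
#' @export
categorize <- function(genes, ann, onto, level = 2) {
  stopifnot(inherits(onto, "ontology_graph"), level >= 0)
  depth <- term_depths(onto)
  at_level <- names(depth)[depth == level]
  counts <- vapply(at_level, function(tm)
    sum(vapply(ann[intersect(genes, names(ann))],
               function(ts) tm %in% ts, logical(1))), integer(1))
  name_of <- stats::setNames(onto$terms$name, onto$terms$id)
  ns_of <- stats::setNames(onto$terms$namespace, onto$terms$id)
  out <- data.frame(term = at_level, name = unname(name_of[at_level]),
                    namespace = unname(ns_of[at_level]),
                    count = unname(counts), stringsAsFactors = FALSE)
  out <- out[order(out$namespace, -out$count), ]
  rownames(out) <- NULL
  out
}

#' Depth of every term below its namespace root
#'
#' @param onto an `ontology_graph`.
#' @return named integer vector: term id -> shortest is_a path length to a
#'   root (a term with no parent) of its namespace.
#' @export
term_depths <- function(onto) {
  roots <- setdiff(onto$terms$id, onto$edges$child)
  d <- igraph::distances(onto$graph, v = onto$terms$id, to = roots,
                         mode = "out")
  depth <- apply(d, 1, min)
  stats::setNames(as.integer(depth), onto$terms$id)
}
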