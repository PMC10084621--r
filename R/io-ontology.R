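#' Read an OBO 1.2 ontology file
#'
#' Minimal reader for `[Term]` stanzas: keeps `id`, `name`, `namespace` and
#' `is_a` parent links; obsolete terms are dropped.  Only `is_a` edges are
#' used (the conservative default for annotation propagation); `part_of` and
#' other relationships are ignored.
#'
#' @param path path to an OBO file.
#' @return an `ontology_graph`: list with `terms` (data.frame id/name/
#'   namespace) and `edges` (data.frame child/parent), plus an igraph
#'   representation in `graph` (edges point child -> parent).
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) stopf("ontology file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  starts <- c(grep("^\\[", lines), length(lines) + 1L)
  term_starts <- grep("^\\[Term\\]$", lines)
  ids <- names <- namespaces <- character(0)
  children <- parents <- character(0)
  for (s in term_starts) {
    e <- starts[starts > s][1] - 1L
    block <- lines[(s + 1L):e]
    get1 <- function(key) {
      m <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(m)) sub(paste0("^", key, ": "), "", m[1]) else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    ids <- c(ids, id)
    names <- c(names, get1("name"))
    namespaces <- c(namespaces, get1("namespace"))
    isa <- grep("^is_a: ", block, value = TRUE)
    if (length(isa)) {
      pa <- sub("^is_a: +([^ !]+).*$", "\\1", isa)
      children <- c(children, rep(id, length(pa)))
      parents <- c(parents, pa)
    }
  }
  as_ontology_graph(
    terms = data.frame(id = ids, name = names, namespace = namespaces,
                       stringsAsFactors = FALSE),
    edges = data.frame(child = children, parent = parents,
                       stringsAsFactors = FALSE))
}

#' Construct and validate an ontology graph
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent` (is_a links).
#' @return an `ontology_graph`.
#' @export
as_ontology_graph <- function(terms, edges) {
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)),
            all(c("child", "parent") %in% names(edges)))
  if (anyDuplicated(terms$id))
    stopf("duplicate term id: %s", terms$id[anyDuplicated(terms$id)])
  unknown <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unknown))
    stopf("is_a edge references unknown term(s): %s",
          paste(utils::head(unknown, 3), collapse = ", "))
  ok_ns <- c("biological_process", "cellular_component", "molecular_function")
  bad <- which(!terms$namespace %in% ok_ns)
  if (length(bad))
    stopf("term %s has unknown namespace '%s'", terms$id[bad[1]],
          terms$namespace[bad[1]])
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = terms$id)
  if (nrow(edges) && !igraph::is_dag(g))
    stopf("is_a relation contains a cycle; the ontology must be acyclic")
  structure(list(terms = terms, edges = edges, graph = g),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("ontology_graph: %d terms, %d is_a edges (%s)\n",
              nrow(x$terms), nrow(x$edges),
              paste(sprintf("%s: %d", names(table(x$terms$namespace)),
                            table(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

#' Read a gene-to-GO annotation mapping
#'
#' Two-column tab-separated file (`gene_id`, `go_id`), one pair per line,
#' optional header.  Pairs naming a term absent from the ontology are dropped
#' with a warning, since public annotation builds routinely lag the OBO.
#'
#' @param path path to the TSV.
#' @param ontology optional `ontology_graph` to validate term ids against.
#' @return named list: gene id -> character vector of GO term ids.
#' @export
read_annotation <- function(path, ontology = NULL) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("gene_id", "go_id"))
  if (identical(tolower(df$gene_id[1]), "gene_id")) df <- df[-1, , drop = FALSE]
  if (!is.null(ontology)) {
    known <- df$go_id %in% ontology$terms$id
    if (any(!known)) {
      warnf("dropping %d annotation pair(s) naming term(s) absent from the ontology (e.g. %s)",
            sum(!known), df$go_id[!known][1])
      df <- df[known, , drop = FALSE]
    }
  }
  split(df$go_id, df$gene_id)
}

#' Read a multi-species reference annotation table
#'
#' Tab-separated with header `species`, `gene_name`, `function`, `go_terms`;
#' `go_terms` holds semicolon-separated GO ids and must be nonempty.
#'
#' @param path path to the TSV.
#' @return a data.frame of class `reference_annotation` with list-column
#'   `go_terms`.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stopf("reference file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species", "gene_name", "function", "go_terms")
  for (col in need)
    if (!col %in% names(df)) stopf("missing required column '%s'", col)
  go <- strsplit(as.character(df$go_terms), ";", fixed = TRUE)
  go <- lapply(go, function(v) sort(unique(trimws(v[nzchar(trimws(v))]))))
  empty <- which(!lengths(go))
  if (length(empty)) stopf("empty go_terms at row %d", empty[1])
  out <- data.frame(species = df$species, gene_name = df$gene_name,
                    function_desc = df[["function"]],
                    stringsAsFactors = FALSE)
  out$go_terms <- go
  class(out) <- c("reference_annotation", "data.frame")
  out
}
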