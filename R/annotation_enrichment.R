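# Over-representation analysis of gene lists against a user-supplied
# annotation map (e.g. GO molecular-function terms). The statistic is the
# plain upper-tail hypergeometric test with Benjamini-Hochberg adjustment:
# an auditable, reproducible stand-in for web-based enrichment services.

#' Read an annotation map from a two-column TSV
#'
#' @param path TSV with columns `term` and `gene` (one row per
#'   term-gene link; a header row is required).
#' @param universe Optional character vector of all annotated genes; by
#'   default the union of all mapped genes.
#' @return An `annotation_map` as produced by [annotation_map()].
#' @export
read_annotation_map <- function(path, universe = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("term", "gene") %in% names(tab))) {
    stop("annotation TSV must have columns: term, gene", call. = FALSE)
  }
  annotation_map(split(tab$gene, tab$term), universe)
}

#' Construct an annotation map
#'
#' @param terms Named list: term -> character vector of gene identifiers.
#'   Gene identifiers are opaque strings; no symbol conversion is done.
#' @param universe All annotated genes; defaults to the union of the term
#'   sets. Every term set must be a non-empty subset of the universe.
#' @return A list of class `annotation_map` with elements `terms` and
#'   `universe`.
#' @export
annotation_map <- function(terms, universe = NULL) {
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(lengths(terms) == 0)) {
    stop("annotation terms must be non-empty", call. = FALSE)
  }
  if (is.null(universe)) universe <- unique(unlist(terms))
  universe <- unique(as.character(universe))
  stray <- setdiff(unlist(terms), universe)
  if (length(stray) > 0) {
    stop("gene(s) annotated but absent from universe: ",
         paste(head(stray, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_map")
}

#' Hypergeometric over-representation test
#'
#' For each term with gene set of size K in a universe of size N, and a
#' query of size n overlapping the term in k genes, computes the
#' upper-tail hypergeometric p-value P(X >= k) with
#' X ~ Hypergeom(N, K, n), then Benjamini-Hochberg q-values across terms.
#' Query genes outside the universe are dropped with a message. Results
#' are sorted by p-value with term name as the deterministic tie-break.
#'
#' @param query Character vector of gene identifiers.
#' @param annot An [annotation_map()].
#' @return A tibble with columns `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, sorted by (`p_value`, `term`).
#' @export
enrich <- function(query, annot) {
  stopifnot(inherits(annot, "annotation_map"))
  if (length(annot$universe) == 0) {
    stop("annotation universe is empty", call. = FALSE)
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, annot$universe)
  if (length(outside) > 0) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, annot$universe)
  }
  N <- length(annot$universe)
  n <- length(query)
  res <- tibble::tibble(
    term = names(annot$terms),
    K = unname(lengths(annot$terms)),
    k = vapply(annot$terms, function(g) length(intersect(query, g)),
               integer(1), USE.NAMES = FALSE),
    n = n, N = N
  )
  # P(X >= k) = upper tail at k-1
  res$p_value <- phyper(res$k - 1, res$K, res$N - res$K, res$n,
                        lower.tail = FALSE)
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term), c("term", "k", "K", "n", "N",
                                             "p_value", "q_value")]
  tibble::as_tibble(res)
}
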