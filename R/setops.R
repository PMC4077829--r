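# Set algebra over tissue callsets.
#
# All comparisons are exact on variant keys: a "tissue-specific" SNV is one
# found in tissue A but not tissue B when the pair is compared, though it
# may be shared with third tissues. The common-to-all core — keys present
# in every tissue — is read as germline or very early embryonic variation.

#' Tissue-specific variant keys of one pairwise comparison
#'
#' Returns the keys present in `a` but absent from `b` (set difference
#' `keys(a) \ keys(b)`): the SNVs specific to `a` in this pair. Annotations
#' for the returned keys remain retrievable from `a`'s record table.
#'
#' @param a,b [tissue_callset()] objects.
#' @return Character vector of variant keys.
#' @export
pairwise_unique <- function(a, b) {
  stopifnot(inherits(a, "tissue_callset"), inherits(b, "tissue_callset"))
  setdiff(callset_keys(a), callset_keys(b))
}

#' Pairwise tissue-specific SNV count matrix
#'
#' For tissues i, j the entry `M[i, j]` is the number of SNVs found in
#' tissue i but not in tissue j; both orientations are reported (the two
#' off-diagonal entries of a pair generally differ) and the diagonal is 0.
#' The set-difference identity `M[i,j] - M[j,i] = |keys_i| - |keys_j|`
#' holds for every pair.
#'
#' @param callsets List of [tissue_callset()] objects with unique tissue
#'   names; row/column order follows the input order.
#' @param use_abbrev Label rows/columns with abbreviations (default) rather
#'   than full tissue names.
#' @return Integer matrix with tissue labels as dimnames.
#' @export
pairwise_matrix <- function(callsets, use_abbrev = TRUE) {
  stopifnot(length(callsets) >= 2)
  names_ <- vapply(callsets, function(x) x$tissue, character(1))
  if (anyDuplicated(names_)) {
    stop("duplicate tissue names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "),
         call. = FALSE)
  }
  labels <- if (use_abbrev) {
    vapply(callsets, function(x) x$abbrev, character(1))
  } else names_
  keysets <- lapply(callsets, callset_keys)
  n <- length(callsets)
  m <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) m[i, j] <- length(setdiff(keysets[[i]], keysets[[j]]))
    }
  }
  m
}

#' Variant keys common to every tissue
#'
#' N-way intersection of the callsets' key sets. On real data this core is
#' interpreted as inherited or very early (zygotic/embryonic) variation,
#' since a variant present in every tissue must predate the separation of
#' their lineages.
#'
#' @param callsets List of at least two [tissue_callset()] objects.
#' @return Character vector of variant keys.
#' @export
common_to_all <- function(callsets) {
  stopifnot(length(callsets) >= 2)
  Reduce(intersect, lapply(callsets, callset_keys))
}

jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Germ-layer sharing summary
#'
#' Quantifies how much more SNV sharing occurs between tissues of the same
#' embryonic germ layer than across layers. For every tissue pair the
#' Jaccard index of the key sets is computed; pairs are then grouped into
#' within-layer (per layer) and cross-layer, and the group means compared.
#' Mutations acquired at the germ-layer stage of development are shared by
#' exactly that layer's tissues, so a lineage signal shows up as
#' within-layer mean > cross-layer mean.
#'
#' @param callsets List of [tissue_callset()] objects.
#' @param layer_map Optional tibble from [load_layer_map()] used to fill in
#'   layers for callsets whose `layer` is `"unknown"`; by default each
#'   callset's own `layer` field is used.
#' @return A list of class `sharing_summary`: `n_common_all`, `pairs`
#'   (tibble of per-pair Jaccard indices with layer annotation),
#'   `within_layer` (named mean Jaccard per layer), `cross_layer` (mean),
#'   `within_gt_cross` (logical flag).
#' @export
layer_sharing_summary <- function(callsets, layer_map = NULL) {
  stopifnot(length(callsets) >= 2)
  layers <- vapply(callsets, function(x) x$layer, character(1))
  tissues <- vapply(callsets, function(x) x$tissue, character(1))
  if (!is.null(layer_map)) {
    hit <- match(tissues, layer_map$tissue)
    layers <- ifelse(layers == "unknown" & !is.na(hit),
                     layer_map$layer[hit], layers)
  }
  if (any(layers == "unknown")) {
    stop("tissue(s) without a germ layer: ",
         paste(tissues[layers == "unknown"], collapse = ", "), call. = FALSE)
  }
  keysets <- lapply(callsets, callset_keys)
  combs <- utils::combn(length(callsets), 2)
  pairs <- tibble::tibble(
    tissue_a = tissues[combs[1, ]], tissue_b = tissues[combs[2, ]],
    layer_a = layers[combs[1, ]], layer_b = layers[combs[2, ]],
    jaccard = vapply(seq_len(ncol(combs)), function(k) {
      jaccard_index(keysets[[combs[1, k]]], keysets[[combs[2, k]]])
    }, double(1))
  )
  pairs$same_layer <- pairs$layer_a == pairs$layer_b
  within <- vapply(sort(unique(layers)), function(l) {
    sel <- pairs$same_layer & pairs$layer_a == l
    if (!any(sel)) NA_real_ else mean(pairs$jaccard[sel], na.rm = TRUE)
  }, double(1))
  cross <- mean(pairs$jaccard[!pairs$same_layer], na.rm = TRUE)
  structure(
    list(n_common_all = length(common_to_all(callsets)),
         pairs = pairs, within_layer = within, cross_layer = cross,
         within_gt_cross = isTRUE(mean(pairs$jaccard[pairs$same_layer],
                                       na.rm = TRUE) > cross)),
    class = "sharing_summary"
  )
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("<sharing_summary> %d SNVs common to all tissues\n",
              x$n_common_all))
  cat("mean within-layer Jaccard:",
      paste(names(x$within_layer), round(x$within_layer, 4),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("mean cross-layer Jaccard: %.4f (within > cross: %s)\n",
              x$cross_layer, x$within_gt_cross))
  invisible(x)
}

#' Write a pairwise matrix as TSV
#'
#' @param m Matrix from [pairwise_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairwise_matrix <- function(m, path) {
  df <- tibble::as_tibble(m, rownames = "tissue")
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
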