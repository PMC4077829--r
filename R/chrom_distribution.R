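# Per-chromosome distribution of SNVs and its relation to chromosome
# features (length in Mb, exon count, protein-coding gene count).
#
# The central empirical question these summaries address: is the number of
# SNVs on a chromosome driven by its physical length, or by how much of it
# codes for protein? Correlations are computed explicitly (Pearson and
# Spearman) so the claim is testable rather than visual.

#' Count SNVs per chromosome
#'
#' Tallies variant keys by chromosome against a feature table, reporting
#' raw counts, percentage of the total, and density per megabase.
#' Chromosomes with zero variants are reported as 0, never omitted, so
#' results across tissues are always over the same chromosome universe.
#'
#' @param keys Character vector of variant keys (see [variant_key()]).
#' @param table A [load_chrom_table()] feature table.
#' @return A tibble of class `chrom_counts` with columns `chrom`, `n_snv`,
#'   `pct_of_total`, `density_per_mb`. When `keys` is empty the percentage
#'   column is `NA` and the attribute `pct_defined` is `FALSE`.
#' @export
count_per_chromosome <- function(keys, table) {
  stopifnot(inherits(table, "chrom_feature_table"))
  chrom <- if (length(keys) > 0) parse_variant_key(keys)$chrom else character()
  missing <- setdiff(unique(chrom), table$chrom)
  if (length(missing) > 0) {
    stop("variant(s) on chromosome(s) absent from feature table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- as.integer(table(factor(chrom, levels = table$chrom)))
  total <- sum(n)
  out <- tibble::tibble(
    chrom = table$chrom,
    n_snv = n,
    pct_of_total = if (total > 0) 100 * n / total else NA_real_,
    density_per_mb = n / table$length_mb
  )
  structure(out, class = c("chrom_counts", class(out)),
            pct_defined = total > 0)
}

#' Correlate per-chromosome SNV counts with a chromosome feature
#'
#' Computes Pearson and Spearman correlation between `n_snv` and one of
#' `length_mb`, `exon_count` or `coding_gene_count` across chromosomes.
#' An exclusion list supports dropping chromosomes whose variant diversity
#' is known to behave differently (X, with diversity below autosomes, is
#' the usual candidate; Y carries almost no exome content).
#'
#' @param counts A `chrom_counts` tibble from [count_per_chromosome()].
#' @param table The matching [load_chrom_table()] table.
#' @param feature One of `"length_mb"`, `"exon_count"`,
#'   `"coding_gene_count"`.
#' @param exclude Chromosome labels to drop before correlating
#'   (default `"Y"`).
#' @return A list of class `feature_correlation`: `feature`, `pearson_r`,
#'   `spearman_rho`, `n` (chromosomes used), `defined` (FALSE when either
#'   vector is constant, in which case the coefficients are `NA`).
#' @export
correlate_with_feature <- function(counts, table,
                                   feature = c("coding_gene_count",
                                               "length_mb", "exon_count"),
                                   exclude = "Y") {
  feature <- match.arg(feature)
  stopifnot(inherits(counts, "chrom_counts"),
            inherits(table, "chrom_feature_table"))
  exclude <- normalize_chrom(exclude)
  keep <- !counts$chrom %in% exclude
  if (sum(keep) < 3) {
    stop("need at least 3 chromosomes after exclusion", call. = FALSE)
  }
  x <- counts$n_snv[keep]
  y <- table[[feature]][match(counts$chrom[keep], table$chrom)]
  defined <- stats::sd(x) > 0 && stats::sd(y) > 0
  structure(
    list(feature = feature,
         pearson_r = if (defined) cor(x, y, method = "pearson") else NA_real_,
         spearman_rho = if (defined) cor(x, y, method = "spearman") else NA_real_,
         n = sum(keep), defined = defined),
    class = "feature_correlation"
  )
}

#' @export
print.feature_correlation <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<feature_correlation> n_snv ~ %s over %d chromosomes: Pearson r = %.3f, Spearman rho = %.3f\n",
                x$feature, x$n, x$pearson_r, x$spearman_rho))
  } else {
    cat(sprintf("<feature_correlation> n_snv ~ %s: undefined (constant input)\n",
                x$feature))
  }
  invisible(x)
}

#' Compare two tissues' per-chromosome SNV distributions
#'
#' Per-chromosome differences between two count tables over the same
#' chromosome universe, ranked by absolute difference to surface the
#' chromosomes where the two tissues diverge most.
#'
#' @param counts_a,counts_b `chrom_counts` tibbles from
#'   [count_per_chromosome()] over the same chromosome set.
#' @return A tibble with columns `chrom`, `n_a`, `n_b`, `diff`
#'   (`n_b - n_a`), `abs_diff`, `rel_diff` (`diff / n_a`, `NA` when
#'   `n_a = 0`), and `rank` (1 = largest absolute difference).
#' @export
compare_tissue_distributions <- function(counts_a, counts_b) {
  stopifnot(inherits(counts_a, "chrom_counts"),
            inherits(counts_b, "chrom_counts"))
  if (!identical(counts_a$chrom, counts_b$chrom)) {
    stop("chromosome universes differ between the two count tables",
         call. = FALSE)
  }
  d <- counts_b$n_snv - counts_a$n_snv
  tibble::tibble(
    chrom = counts_a$chrom,
    n_a = counts_a$n_snv,
    n_b = counts_b$n_snv,
    diff = d,
    abs_diff = abs(d),
    rel_diff = ifelse(counts_a$n_snv > 0, d / counts_a$n_snv, NA_real_),
    rank = rank(-abs(d), ties.method = "min")
  )
}
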