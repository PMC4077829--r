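# Read-depth stratification and developmental-timing heuristics.
#
# Two independent per-variant signals are separated here: the sequencing
# depth tier (DP20/DP50/DP100 — a coverage property) and the estimated
# fraction of cells carrying the variant (derived from the variant allele
# fraction — the lineage signal). A variant carried by many cells of the
# sample was acquired early, on or before the expansion of that lineage.

#' Stratify variants by depth tier
#'
#' Counts variants with depth at or above each tier. Tiers are cumulative
#' and inclusive: DP20 means "covered by at least 20 reads", so counts are
#' non-increasing along increasing tiers. Records with absent depth cannot
#' be placed in any tier and are excluded from all counts.
#'
#' @param x A [tissue_callset()], or a numeric vector of depths.
#' @param tiers Strictly increasing depth thresholds (default 20, 50, 100).
#' @return A tibble of class `stratum_counts` with columns `tier` and
#'   `n_at_tier`.
#' @export
stratify_by_depth <- function(x, tiers = c(20, 50, 100)) {
  if (length(tiers) == 0) stop("tiers must be non-empty", call. = FALSE)
  if (any(diff(tiers) <= 0)) {
    stop("tiers must be strictly increasing", call. = FALSE)
  }
  dp <- if (inherits(x, "tissue_callset")) x$records$dp else as.numeric(x)
  dp <- dp[!is.na(dp)]
  out <- tibble::tibble(
    tier = as.integer(tiers),
    n_at_tier = vapply(tiers, function(t) sum(dp >= t), integer(1))
  )
  structure(out, class = c("stratum_counts", class(out)))
}

#' Estimate the fraction of cells carrying a variant
#'
#' The fraction of cells in a sample bearing an SNV is inferred from the
#' fraction of reads bearing it: with `ploidy` copies of the locus per
#' cell and `mutant_copies` mutant alleles per carrier cell, a carrier
#' fraction f yields an expected variant allele fraction (VAF) of
#' `f * mutant_copies / ploidy`, so f is estimated as
#' `min(1, vaf * ploidy / mutant_copies)`. With the diploid heterozygous
#' defaults, a clonal heterozygous variant (VAF 0.5) maps to fraction 1.
#'
#' @param alt_depth Reads supporting the alternate allele (vectorised).
#' @param dp Total reads at the site; must be > 0.
#' @param ploidy Copies of the locus per cell (default 2).
#' @param mutant_copies Mutant alleles per carrier cell (default 1).
#' @return A tibble of class `cell_fraction_estimate` with columns
#'   `alt_depth`, `dp`, `vaf`, `ploidy`, `mutant_copies`, `fraction`.
#' @export
estimate_cell_fraction <- function(alt_depth, dp, ploidy = 2,
                                   mutant_copies = 1) {
  if (any(dp <= 0)) {
    stop("dp must be > 0: VAF is undefined without reads", call. = FALSE)
  }
  if (any(alt_depth < 0 | alt_depth > dp)) {
    stop("alt_depth must satisfy 0 <= alt_depth <= dp", call. = FALSE)
  }
  vaf <- alt_depth / dp
  out <- tibble::tibble(
    alt_depth = alt_depth, dp = dp, vaf = vaf,
    ploidy = ploidy, mutant_copies = mutant_copies,
    fraction = pmin(1, vaf * ploidy / mutant_copies)
  )
  structure(out, class = c("cell_fraction_estimate", class(out)))
}

#' Cells per sample from DNA mass
#'
#' Divides the DNA mass of a sample by the DNA mass of one cell. The
#' default per-cell mass, 6.4e-12 g, is the DNA content of a diploid male
#' somatic cell in G1. The result is also reported rounded to one
#' significant figure, the conventional order-of-magnitude statement
#' (3e-6 g of input DNA corresponds to 468,750, i.e. about 5e5 cells).
#'
#' @param sample_mass_g DNA mass of the sample in grams (> 0).
#' @param per_cell_mass_g DNA mass per cell in grams (> 0; default
#'   6.4e-12).
#' @return A list with `cells` (exact ratio) and `cells_rounded` (one
#'   significant figure).
#' @export
cells_from_dna_mass <- function(sample_mass_g, per_cell_mass_g = 6.4e-12) {
  if (any(sample_mass_g <= 0) || any(per_cell_mass_g <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  cells <- sample_mass_g / per_cell_mass_g
  list(cells = cells, cells_rounded = signif(cells, 1))
}

#' Classify variants as early or late developmental candidates
#'
#' A heuristic two-signal classifier: a variant is an `"early-candidate"`
#' iff it is deeply covered (`dp >= early_tier`) AND its estimated carrier
#' cell fraction reaches `min_cell_fraction`; otherwise it is a
#' `"late-candidate"`. Depth alone is a property of coverage, not of
#' lineage; the cell-fraction floor supplies the lineage evidence. The
#' labels are candidates, not validated inferences.
#'
#' @param dp Total depth (vectorised).
#' @param alt_depth Alt-supporting reads.
#' @param early_tier Depth tier for "highly covered" (default 100).
#' @param min_cell_fraction Carrier-fraction floor (default 0.25; a
#'   package default, not an empirically derived threshold).
#' @param ploidy,mutant_copies Passed to [estimate_cell_fraction()].
#' @return Character vector of `"early-candidate"` / `"late-candidate"`.
#' @export
timing_class <- function(dp, alt_depth, early_tier = 100,
                         min_cell_fraction = 0.25, ploidy = 2,
                         mutant_copies = 1) {
  est <- estimate_cell_fraction(alt_depth, dp, ploidy, mutant_copies)
  ifelse(dp >= early_tier & est$fraction >= min_cell_fraction,
         "early-candidate", "late-candidate")
}
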