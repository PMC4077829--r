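# Fixture builders shared by the unit tests. All synthetic data are
# generated in code under fixed seeds; nothing is read from disk except
# the package's own shipped tables.

# A minimal callset from bare keys on chr1 (positions 1, 2, ...).
callset_from_keys <- function(keys, tissue = "T", abbrev = tissue,
                              layer = "unknown") {
  if (length(keys) == 0) {
    return(tissue_callset(tissue = tissue, abbrev = abbrev, layer = layer))
  }
  parsed <- parse_variant_key(keys)
  parsed$dp <- 50L
  parsed$alt_depth <- 25L
  parsed$func_class <- "exonic"
  tissue_callset(parsed, tissue = tissue, abbrev = abbrev, layer = layer)
}

# n random keys over the default chromosome table, unique.
random_keys <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- load_chrom_table()
  idx <- sample.int(nrow(tab), n, replace = TRUE)
  pos <- sample.int(1e7, n, replace = TRUE)
  while (anyDuplicated(paste(idx, pos))) {
    dup <- duplicated(paste(idx, pos))
    pos[dup] <- sample.int(1e7, sum(dup), replace = TRUE)
  }
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- ifelse(ref == "A", "G", "A")
  variant_key(tab$chrom[idx], pos, ref, alt)
}

# Random records spanning passing, failing and missing annotation values,
# for exercising the hard filter against a brute-force oracle.
random_filter_records <- function(n, seed = 1) {
  set.seed(seed)
  na_mask <- function(x, p = 0.2) {
    x[runif(length(x)) < p] <- NA
    x
  }
  dp <- sample(0:150, n, replace = TRUE)
  tibble::tibble(
    chrom = "1", pos = seq_len(n), ref = "A", alt = "G",
    dp = dp,
    alt_depth = vapply(dp, function(d) sample(0:max(d, 0), 1), integer(1)),
    qd = na_mask(runif(n, 0, 10)),
    fs = na_mask(runif(n, 0, 120)),
    mq = na_mask(runif(n, 0, 70)),
    haplotype_score = na_mask(runif(n, 0, 26)),
    mq_rank_sum = na_mask(runif(n, -25, 5)),
    read_pos_rank_sum = na_mask(runif(n, -16, 5)),
    func_class = sample(c("exonic", "non-exonic", "unknown"), n,
                        replace = TRUE)
  )
}

# Independent straight-line re-check of the hard-filter rules: one record
# at a time, one explicit comparison per criterion, NA passes.
oracle_hard_filter_pass <- function(rec, min_dp = 20) {
  pass <- logical(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    if (!is.na(rec$dp[i]) && rec$dp[i] < min_dp) ok <- FALSE
    if (!is.na(rec$qd[i]) && rec$qd[i] < 2.0) ok <- FALSE
    if (!is.na(rec$fs[i]) && rec$fs[i] > 60.0) ok <- FALSE
    if (!is.na(rec$mq[i]) && rec$mq[i] < 35.0) ok <- FALSE
    if (!is.na(rec$haplotype_score[i]) && rec$haplotype_score[i] > 13.0) {
      ok <- FALSE
    }
    if (!is.na(rec$mq_rank_sum[i]) && rec$mq_rank_sum[i] < -12.5) ok <- FALSE
    if (!is.na(rec$read_pos_rank_sum[i]) &&
        rec$read_pos_rank_sum[i] < -8.0) ok <- FALSE
    pass[i] <- ok
  }
  pass
}

# Exact upper-tail hypergeometric probability by combinatorial summation,
# independent of stats::phyper.
oracle_hyper_upper <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  if (length(i) == 0 || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# A tiny layer map for fast simulations.
small_layer_map <- function() {
  tibble::tibble(
    tissue = c("Cortex", "Skin", "Blood", "Muscle", "Liver", "Gut"),
    abbrev = c("Cx", "Sk", "Bl", "Mu", "Li", "Gu"),
    layer = c("ectoderm", "ectoderm", "mesoderm", "mesoderm",
              "endoderm", "endoderm")
  )
}
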