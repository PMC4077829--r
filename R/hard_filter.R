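# GATK-style hard filtering of SNV calls.
#
# A record passes iff it clears every record-local threshold; absent
# annotations pass their criterion (standard hard-filter semantics: the
# rank-sum statistics are undefined at, e.g., homozygous-alt sites, and an
# undefined statistic is no evidence against the call).

CRITERIA_ORDER <- c("DP", "QD", "FS", "MQ", "HaplotypeScore",
                    "MQRankSum", "ReadPosRankSum")

#' Hard-filter thresholds
#'
#' Threshold set for record-local hard filtering of SNV calls. The defaults
#' are the classic UnifiedGenotyper-era values: a call fails when QD < 2.0,
#' FS > 60.0, MQ < 35.0, HaplotypeScore > 13.0, MQRankSum < -12.5 or
#' ReadPosRankSum < -8.0, or when total depth falls below the chosen
#' coverage tier. Depth tiers of 10, 20, 50 and 100 reads are the
#' conventional strata; the depth comparison is inclusive (`dp >= min_dp`,
#' i.e. DP20 means "covered by at least 20 reads").
#'
#' @param min_dp Minimum total depth (default 20).
#' @param min_qd Fail when quality-by-depth is below this (default 2.0).
#' @param max_fs Fail when Fisher strand bias exceeds this (default 60.0).
#' @param min_mq Fail when mapping quality is below this (default 35.0).
#' @param max_haplotype_score Fail above this (default 13.0).
#' @param min_mq_rank_sum Fail below this (default -12.5).
#' @param min_read_pos_rank_sum Fail below this (default -8.0).
#' @param apply_annotation_filters Apply the six non-depth criteria
#'   (default `TRUE`); set `FALSE` to filter on depth alone.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_dp = 20, min_qd = 2.0, max_fs = 60.0,
                              min_mq = 35.0, max_haplotype_score = 13.0,
                              min_mq_rank_sum = -12.5,
                              min_read_pos_rank_sum = -8.0,
                              apply_annotation_filters = TRUE) {
  vals <- c(min_dp, min_qd, max_fs, min_mq, max_haplotype_score,
            min_mq_rank_sum, min_read_pos_rank_sum)
  if (any(!is.finite(vals)) || min_dp < 0) {
    stop("thresholds must be finite and min_dp >= 0", call. = FALSE)
  }
  structure(
    list(min_dp = min_dp, min_qd = min_qd, max_fs = max_fs, min_mq = min_mq,
         max_haplotype_score = max_haplotype_score,
         min_mq_rank_sum = min_mq_rank_sum,
         min_read_pos_rank_sum = min_read_pos_rank_sum,
         apply_annotation_filters = isTRUE(apply_annotation_filters)),
    class = "filter_thresholds"
  )
}

# Per-criterion pass matrix; NA annotations pass. Rows = records.
criterion_pass_matrix <- function(rec, th) {
  pass_or_na <- function(x, ok) is.na(x) | ok
  m <- cbind(
    DP = pass_or_na(rec$dp, rec$dp >= th$min_dp),
    QD = pass_or_na(rec$qd, rec$qd >= th$min_qd),
    FS = pass_or_na(rec$fs, rec$fs <= th$max_fs),
    MQ = pass_or_na(rec$mq, rec$mq >= th$min_mq),
    HaplotypeScore = pass_or_na(rec$haplotype_score,
                                rec$haplotype_score <= th$max_haplotype_score),
    MQRankSum = pass_or_na(rec$mq_rank_sum,
                           rec$mq_rank_sum >= th$min_mq_rank_sum),
    ReadPosRankSum = pass_or_na(rec$read_pos_rank_sum,
                                rec$read_pos_rank_sum >= th$min_read_pos_rank_sum)
  )
  if (!th$apply_annotation_filters) {
    m[, setdiff(CRITERIA_ORDER, "DP")] <- TRUE
  }
  m
}

#' Apply hard filters to a callset
#'
#' Keeps exactly the records that clear every criterion in `thresholds`.
#' Pass/fail is record-local and order-independent; for reporting, the
#' first failing criterion of each rejected record is tallied in the fixed
#' order DP, QD, FS, MQ, HaplotypeScore, MQRankSum, ReadPosRankSum, so the
#' exclusive first-failure counts plus `n_pass` always sum to `n_input`.
#'
#' @param callset A [tissue_callset()].
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with elements `callset` (the filtered `tissue_callset`)
#'   and `report` (a `filter_report` list: `n_input`, `n_pass`,
#'   `first_fail` per-criterion counts, `n_missing` per-field NA counts).
#' @export
apply_hard_filters <- function(callset, thresholds = filter_thresholds()) {
  stopifnot(inherits(callset, "tissue_callset"),
            inherits(thresholds, "filter_thresholds"))
  rec <- callset$records
  if (nrow(rec) == 0) {
    report <- structure(
      list(n_input = 0L, n_pass = 0L,
           first_fail = setNames(integer(length(CRITERIA_ORDER)),
                                 CRITERIA_ORDER),
           n_missing = setNames(integer(length(INFO_NUMERIC)),
                                names(INFO_NUMERIC))),
      class = "filter_report")
    return(list(callset = callset, report = report))
  }
  m <- criterion_pass_matrix(rec, thresholds)
  pass <- rowSums(m) == ncol(m)
  first_fail_idx <- apply(!m, 1, function(f) if (any(f)) which(f)[1] else NA_integer_)
  first_fail <- vapply(seq_along(CRITERIA_ORDER),
                       function(i) sum(first_fail_idx == i, na.rm = TRUE),
                       integer(1))
  names(first_fail) <- CRITERIA_ORDER
  n_missing <- vapply(names(INFO_NUMERIC), function(col) sum(is.na(rec[[col]])),
                      integer(1))
  report <- structure(
    list(n_input = nrow(rec), n_pass = sum(pass), first_fail = first_fail,
         n_missing = n_missing),
    class = "filter_report"
  )
  list(callset = set_records(callset, rec[pass, ]), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d of %d records pass\n", x$n_pass, x$n_input))
  ff <- x$first_fail[x$first_fail > 0]
  if (length(ff) > 0) {
    cat("first failures:",
        paste(names(ff), ff, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Restrict a callset to exonic SNVs
#'
#' Keeps only records with `func_class == "exonic"`. Records of unknown
#' class are dropped and their count reported via a message, since an
#' exome-focused analysis cannot place them.
#'
#' @param callset A [tissue_callset()].
#' @return The exonic-only `tissue_callset`.
#' @export
select_exonic <- function(callset) {
  stopifnot(inherits(callset, "tissue_callset"))
  rec <- callset$records
  n_unknown <- sum(rec$func_class == "unknown" | is.na(rec$func_class))
  if (n_unknown > 0) {
    message(n_unknown, " record(s) of unknown functional class dropped from '",
            callset$tissue, "'")
  }
  keep <- !is.na(rec$func_class) & rec$func_class == "exonic"
  set_records(callset, rec[keep, ])
}
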