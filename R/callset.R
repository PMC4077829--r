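#' @importFrom rlang .data %||%
#' @importFrom stats runif rpois rbinom rnorm cor p.adjust phyper setNames
#' @importFrom utils head
NULL

ANNOTATION_FIELDS <- c("qd", "fs", "mq", "haplotype_score",
                       "mq_rank_sum", "read_pos_rank_sum")

RECORD_COLUMNS <- c("chrom", "pos", "ref", "alt", "key", "dp", "alt_depth",
                    ANNOTATION_FIELDS, "func_class", "db_id")

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix so that the two common hg19 dialects
#' (`"chr1"` and `"1"`) compare equal. All internal bookkeeping uses the
#' stripped form; VCF and TSV output re-attaches the prefix.
#'
#' @param chrom Character vector of chromosome labels.
#' @return Character vector without the `"chr"` prefix.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
normalize_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

#' Emit chromosome labels with the "chr" prefix
#'
#' @param chrom Character vector of (normalized or prefixed) labels.
#' @return Character vector with a single `"chr"` prefix.
#' @export
denormalize_chrom <- function(chrom) {
  paste0("chr", normalize_chrom(chrom))
}

#' Build variant keys
#'
#' A variant key is the identity of a bi-allelic SNV: normalized chromosome,
#' 1-based position, reference allele and single alternate allele, encoded as
#' `"chrom:pos:ref>alt"`. Keys are the unit of all set algebra in the
#' package; genotype/zygosity is deliberately not part of the identity, so
#' two tissues share a variant iff their keys are equal.
#'
#' @param chrom Chromosome labels (any dialect; normalized internally).
#' @param pos 1-based positions (>= 1).
#' @param ref Reference allele strings (non-empty).
#' @param alt Alternate allele strings (non-empty, != ref).
#' @return Character vector of keys.
#' @export
#' @examples
#' variant_key("chr1", 12345, "A", "G")
variant_key <- function(chrom, pos, ref, alt) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("variant positions must be integers >= 1", call. = FALSE)
  }
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(!nzchar(ref)) || any(!nzchar(alt))) {
    stop("ref and alt alleles must be non-empty", call. = FALSE)
  }
  if (any(ref == alt)) {
    stop("alt allele must differ from ref", call. = FALSE)
  }
  paste0(normalize_chrom(chrom), ":", pos, ":", ref, ">", alt)
}

#' Parse variant keys back into their components
#'
#' @param key Character vector of keys produced by [variant_key()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- regmatches(key, regexec("^([^:]+):([0-9]+):([^>]+)>(.+)$", key))
  bad <- vapply(parts, length, integer(1)) != 5L
  if (any(bad)) {
    stop("malformed variant key: ", key[bad][1], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  tibble::tibble(
    chrom = m[, 2], pos = as.integer(m[, 3]), ref = m[, 4], alt = m[, 5]
  )
}

empty_records <- function() {
  tibble::tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), key = character(), dp = integer(),
    alt_depth = integer(), qd = double(), fs = double(), mq = double(),
    haplotype_score = double(), mq_rank_sum = double(),
    read_pos_rank_sum = double(), func_class = character(),
    db_id = character()
  )
}

#' Construct a tissue callset
#'
#' A `tissue_callset` bundles one tissue's called SNVs (a record table keyed
#' by variant key) with its name, short label and embryonic germ layer.
#' Record columns: `chrom`, `pos`, `ref`, `alt`, `key`, `dp` (total depth),
#' `alt_depth`, the six hard-filter annotations (`qd`, `fs`, `mq`,
#' `haplotype_score`, `mq_rank_sum`, `read_pos_rank_sum`), `func_class`
#' (one of `"exonic"`, `"non-exonic"`, `"unknown"`), and an optional
#' external `db_id`. Missing annotations are `NA`, never 0: absence is an
#' explicit state that hard filtering treats as passing.
#'
#' @param records Data frame of variant records; missing columns are filled
#'   with `NA`, and `key` is derived from the coordinate columns if absent.
#' @param tissue Tissue name (e.g. `"Blood"`).
#' @param abbrev Short label (e.g. `"Bl"`); defaults to `tissue`.
#' @param layer Germ layer: `"ectoderm"`, `"mesoderm"`, `"endoderm"` or
#'   `"unknown"`.
#' @return An object of class `tissue_callset`.
#' @export
tissue_callset <- function(records = empty_records(), tissue, abbrev = tissue,
                           layer = "unknown") {
  layer <- match.arg(layer, c("ectoderm", "mesoderm", "endoderm", "unknown"))
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0) {
    records$chrom <- normalize_chrom(records$chrom)
    if (!"key" %in% names(records)) {
      records$key <- variant_key(records$chrom, records$pos,
                                 records$ref, records$alt)
    }
  }
  proto <- empty_records()
  for (col in setdiff(RECORD_COLUMNS, names(records))) {
    records[[col]] <- rep(proto[[col]][NA_integer_], length.out = nrow(records))
  }
  records <- records[RECORD_COLUMNS]
  records$pos <- as.integer(records$pos)
  records$dp <- as.integer(records$dp)
  records$alt_depth <- as.integer(records$alt_depth)
  x <- structure(
    list(tissue = tissue, abbrev = abbrev, layer = layer, records = records),
    class = "tissue_callset"
  )
  validate_callset(x)
}

validate_callset <- function(x) {
  rec <- x$records
  if (anyDuplicated(rec$key)) {
    stop("duplicate variant keys in callset '", x$tissue, "'", call. = FALSE)
  }
  if (nrow(rec) > 0) {
    if (any(rec$pos < 1L, na.rm = TRUE)) {
      stop("positions must be >= 1", call. = FALSE)
    }
    bad_depth <- !is.na(rec$dp) & !is.na(rec$alt_depth) &
      (rec$alt_depth > rec$dp | rec$alt_depth < 0L | rec$dp < 0L)
    if (any(bad_depth)) {
      stop("alt_depth must satisfy 0 <= alt_depth <= dp", call. = FALSE)
    }
  }
  x
}

#' Variant keys of a callset
#'
#' @param x A `tissue_callset`.
#' @return Character vector of variant keys.
#' @export
callset_keys <- function(x) {
  stopifnot(inherits(x, "tissue_callset"))
  x$records$key
}

#' Number of records in a callset
#'
#' @param x A `tissue_callset`.
#' @return Integer count.
#' @export
callset_size <- function(x) nrow(x$records)

#' @export
print.tissue_callset <- function(x, ...) {
  cat(sprintf("<tissue_callset> %s (%s, %s): %d SNVs\n",
              x$tissue, x$abbrev, x$layer, nrow(x$records)))
  if (nrow(x$records) > 0) print(utils::head(x$records, 5))
  invisible(x)
}

# Replace a callset's record table, revalidating.
set_records <- function(x, records) {
  x$records <- tibble::as_tibble(records)
  validate_callset(x)
}
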