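# VCF and fixture-table I/O.
#
# Callsets travel as VCF 4.2 with per-site INFO annotations:
#   DP, ALTDP, QD, FS, MQ, HaplotypeScore, MQRankSum, ReadPosRankSum, FUNC.
# Reading is delegated to vcfR; writing emits the same schema
# deterministically (sorted by chrom, pos) so that read/write round-trips
# are the identity on keys and annotations.

INFO_NUMERIC <- c(
  dp = "DP", alt_depth = "ALTDP", qd = "QD", fs = "FS", mq = "MQ",
  haplotype_score = "HaplotypeScore", mq_rank_sum = "MQRankSum",
  read_pos_rank_sum = "ReadPosRankSum"
)

#' Read a per-tissue SNV callset from a VCF file
#'
#' Parses a VCF 4.x file into a [tissue_callset()]. Only single-nucleotide
#' substitutions are retained: indels and multi-nucleotide substitutions are
#' dropped, matching an SNV-only analysis. Multi-allelic sites are split
#' into one bi-allelic record per alternate allele (site-level INFO values
#' are carried onto every split record). Records without a `DP` annotation
#' are kept with depth marked absent (`NA`) and counted in a warning.
#'
#' @param path Path to a VCF file.
#' @param tissue,abbrev,layer Tissue metadata passed to [tissue_callset()].
#' @param split_multiallelic Split `ALT=G,T` sites into two records
#'   (default `TRUE`). When `FALSE`, multi-allelic sites are dropped so the
#'   bi-allelic key invariant still holds.
#' @param func_tag INFO tag holding the functional class (default `"FUNC"`);
#'   the class is always read, never computed.
#' @return A `tissue_callset` with unique bi-allelic SNV keys.
#' @export
read_callset <- function(path, tissue, abbrev = tissue, layer = "unknown",
                         split_multiallelic = TRUE, func_tag = "FUNC") {
  if (!file.exists(path)) {
    stop("VCF file not found: ", path, call. = FALSE)
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    return(tissue_callset(empty_records(), tissue, abbrev, layer))
  }
  info <- lapply(INFO_NUMERIC, function(tag) {
    suppressWarnings(vcfR::extract.info(vcf, element = tag, as.numeric = TRUE))
  })
  func <- vcfR::extract.info(vcf, element = func_tag)
  func[is.na(func)] <- "unknown"
  func[!func %in% c("exonic", "non-exonic", "unknown")] <- "unknown"

  site <- tibble::tibble(
    chrom = normalize_chrom(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = toupper(fix[, "REF"]),
    alt_field = fix[, "ALT"],
    db_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                   NA_character_, fix[, "ID"]),
    func_class = func
  )
  for (col in names(INFO_NUMERIC)) site[[col]] <- info[[col]]

  alts <- strsplit(site$alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (split_multiallelic) {
    idx <- rep(seq_len(nrow(site)), n_alt)
    rec <- site[idx, ]
    rec$alt <- toupper(unlist(alts))
  } else {
    rec <- site[n_alt == 1L, ]
    rec$alt <- toupper(unlist(alts[n_alt == 1L]))
  }
  rec$alt_field <- NULL
  # SNVs only: single-base ref and alt, and an actual substitution
  rec <- rec[nchar(rec$ref) == 1L & nchar(rec$alt) == 1L &
               rec$ref != rec$alt, , drop = FALSE]
  rec <- rec[!duplicated(variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)), ]

  n_missing_dp <- sum(is.na(rec$dp))
  if (n_missing_dp > 0) {
    warning(n_missing_dp, " record(s) in '", path,
            "' lack a DP annotation; depth kept as absent", call. = FALSE)
  }
  rec$dp <- as.integer(rec$dp)
  rec$alt_depth <- as.integer(rec$alt_depth)
  tissue_callset(rec, tissue, abbrev, layer)
}

format_info_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "g", digits = 15))
}

#' Write a tissue callset to a VCF file
#'
#' Emits a VCF 4.2 file sorted by (chromosome, position), with all depth and
#' filter annotations as INFO fields. Output is deterministic for a fixed
#' callset. Chromosomes are written with a `"chr"` prefix.
#'
#' @param callset A [tissue_callset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_callset <- function(callset, path) {
  stopifnot(inherits(callset, "tissue_callset"))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=mosaicsnv;tissue=%s;abbrev=%s;layer=%s",
            callset$tissue, callset$abbrev, callset$layer),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=ALTDP,Number=1,Type=Integer,Description=\"Reads supporting ALT\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias (phred)\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=HaplotypeScore,Number=1,Type=Float,Description=\"Haplotype score\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank-sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank-sum\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  rec <- callset$records
  lines <- header
  if (nrow(rec) > 0) {
    ord <- order(chrom_sort_rank(rec$chrom), rec$pos, rec$ref, rec$alt)
    rec <- rec[ord, ]
    info_parts <- cbind(
      DP = format_info_num(rec$dp), ALTDP = format_info_num(rec$alt_depth),
      QD = format_info_num(rec$qd), FS = format_info_num(rec$fs),
      MQ = format_info_num(rec$mq),
      HaplotypeScore = format_info_num(rec$haplotype_score),
      MQRankSum = format_info_num(rec$mq_rank_sum),
      ReadPosRankSum = format_info_num(rec$read_pos_rank_sum),
      FUNC = rec$func_class
    )
    info <- apply(info_parts, 1, function(row) {
      keep <- !is.na(row)
      if (!any(keep)) return(".")
      paste(paste0(colnames(info_parts)[keep], "=", row[keep]),
            collapse = ";")
    })
    lines <- c(lines, paste(
      denormalize_chrom(rec$chrom), rec$pos,
      ifelse(is.na(rec$db_id), ".", rec$db_id),
      rec$ref, rec$alt, ".", ".", info, sep = "\t"
    ))
  }
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write VCF to '", path, "'",
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

# Sort rank for chromosome labels: 1..22 numerically, then X, Y, then others.
chrom_sort_rank <- function(chrom) {
  chrom <- normalize_chrom(chrom)
  num <- suppressWarnings(as.integer(chrom))
  ifelse(!is.na(num), num,
         ifelse(chrom == "X", 23L, ifelse(chrom == "Y", 24L, 25L)))
}

default_chrom_set <- function() c(as.character(1:22), "X", "Y")

#' Load a chromosome feature table
#'
#' Reads a TSV with columns `chrom`, `length_mb`, `exon_count`,
#' `coding_gene_count` — the denominators for all per-chromosome
#' distribution statistics. The package ships an hg19-derived fixture
#' (`system.file("extdata", "chrom_features.tsv", package = "mosaicsnv")`).
#'
#' @param path TSV path; defaults to the shipped hg19 table.
#' @param chrom_set Allowed chromosome labels (normalized); rows outside the
#'   set are rejected. Default 1-22, X, Y.
#' @return A tibble of class `chrom_feature_table`.
#' @export
load_chrom_table <- function(path = system.file("extdata",
                                                "chrom_features.tsv",
                                                package = "mosaicsnv"),
                             chrom_set = default_chrom_set()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "length_mb", "exon_count", "coding_gene_count")
  if (!all(need %in% names(tab))) {
    stop("chromosome table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tab$chrom <- normalize_chrom(tab$chrom)
  unknown <- setdiff(tab$chrom, chrom_set)
  if (length(unknown) > 0) {
    stop("chromosome(s) outside the configured set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in c("length_mb", "exon_count", "coding_gene_count")) {
    bad <- which(!is.finite(tab[[col]]) | tab[[col]] <= 0)
    if (length(bad) > 0) {
      stop("non-positive ", col, " in chromosome table row ", bad[1],
           " (", tab$chrom[bad[1]], ")", call. = FALSE)
    }
  }
  if (anyDuplicated(tab$chrom)) {
    stop("duplicate chromosome rows in table", call. = FALSE)
  }
  structure(tibble::as_tibble(tab[need]),
            class = c("chrom_feature_table", class(tibble::tibble())))
}

#' Load a tissue-to-germ-layer map
#'
#' Reads a TSV with columns `tissue`, `abbrev`, `layer`. The shipped
#' default covers the 16 tissues of a whole-body autopsy series and their
#' embryonic germ layer of origin; two colliding short labels are
#' disambiguated as `SpC` (spinal cord) and `SuC` (suprarrenal cortex).
#'
#' @param path TSV path; defaults to the shipped map.
#' @return A tibble with one row per tissue.
#' @export
load_layer_map <- function(path = system.file("extdata", "tissue_layers.tsv",
                                              package = "mosaicsnv")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("tissue", "abbrev", "layer")
  if (!all(need %in% names(tab))) {
    stop("layer map must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$layer), c("ectoderm", "mesoderm", "endoderm"))
  if (length(bad) > 0) {
    stop("unknown germ layer(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$tissue) || anyDuplicated(tab$abbrev)) {
    stop("duplicate tissue names or abbreviations in layer map",
         call. = FALSE)
  }
  tibble::as_tibble(tab[need])
}
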