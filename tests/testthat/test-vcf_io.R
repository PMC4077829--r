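vcf_lines <- function(...) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=ALTDP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    ...)
}

write_tmp_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

test_that("multi-allelic sites split into one bi-allelic SNV per alt", {
  path <- write_tmp_vcf(vcf_lines(
    "chr1\t100\t.\tA\tG,T\t.\t.\tDP=30;QD=12.5;FUNC=exonic"
  ))
  cs <- read_callset(path, tissue = "Blood", split_multiallelic = TRUE)
  expect_equal(sort(callset_keys(cs)), c("1:100:A>G", "1:100:A>T"))
  expect_equal(cs$records$dp, c(30L, 30L))
  cs2 <- read_callset(path, tissue = "Blood", split_multiallelic = FALSE)
  expect_equal(callset_size(cs2), 0)
})

test_that("indels and MNVs are excluded; only SNVs are kept", {
  path <- write_tmp_vcf(vcf_lines(
    "chr1\t100\t.\tA\tAT\t.\t.\tDP=30;FUNC=exonic",
    "chr1\t200\t.\tAC\tGT\t.\t.\tDP=30;FUNC=exonic",
    "chr1\t300\t.\tC\tG\t.\t.\tDP=30;FUNC=exonic"
  ))
  cs <- read_callset(path, tissue = "Blood")
  expect_equal(callset_keys(cs), "1:300:C>G")
  expect_true(all(nchar(cs$records$ref) == 1 & nchar(cs$records$alt) == 1))
})

test_that("records without DP are kept with absent depth and a warning", {
  path <- write_tmp_vcf(vcf_lines(
    "chr1\t100\t.\tA\tG\t.\t.\tQD=5;FUNC=exonic"
  ))
  expect_warning(cs <- read_callset(path, tissue = "Blood"), "DP")
  expect_equal(callset_size(cs), 1)
  expect_true(is.na(cs$records$dp))
  expect_false(is.na(cs$records$qd))
})

test_that("write/read round-trip is the identity on keys and annotations", {
  set.seed(42)
  keys <- random_keys(40)
  parsed <- parse_variant_key(keys)
  parsed$dp <- sample(10:200, 40, replace = TRUE)
  parsed$alt_depth <- pmin(parsed$dp, sample(0:80, 40, replace = TRUE))
  parsed$qd <- round(runif(40, 0, 30), 2)
  parsed$fs <- round(runif(40, 0, 80), 2)
  parsed$mq_rank_sum <- round(runif(40, -15, 5), 3)
  parsed$func_class <- sample(c("exonic", "non-exonic"), 40, replace = TRUE)
  cs <- tissue_callset(parsed, tissue = "Kidney", abbrev = "Ki",
                       layer = "mesoderm")
  path <- tempfile(fileext = ".vcf")
  write_callset(cs, path)
  back <- read_callset(path, tissue = "Kidney", abbrev = "Ki",
                       layer = "mesoderm")
  expect_setequal(callset_keys(back), callset_keys(cs))
  ord <- match(callset_keys(cs), callset_keys(back))
  expect_equal(back$records$dp[ord], cs$records$dp)
  expect_equal(back$records$qd[ord], cs$records$qd)
  expect_equal(back$records$fs[ord], cs$records$fs)
  expect_equal(back$records$mq_rank_sum[ord], cs$records$mq_rank_sum)
  expect_equal(back$records$func_class[ord], cs$records$func_class)
})

test_that("written VCFs are sorted, deterministic, and valid when empty", {
  cs <- callset_from_keys(c("2:500:A>G", "1:900:C>T", "1:100:A>G"),
                          tissue = "Skin")
  path <- tempfile(fileext = ".vcf")
  write_callset(cs, path)
  lines <- readLines(path)
  data_lines <- grep("^[^#]", lines, value = TRUE)
  expect_length(data_lines, 3)
  coords <- do.call(rbind, strsplit(data_lines, "\t"))[, 1:2]
  expect_equal(coords[, 1], c("chr1", "chr1", "chr2"))
  expect_equal(as.integer(coords[, 2]), c(100L, 900L, 500L))

  path2 <- tempfile(fileext = ".vcf")
  write_callset(cs, path2)
  expect_identical(readLines(path2), lines)

  empty <- tissue_callset(tissue = "None")
  path3 <- tempfile(fileext = ".vcf")
  write_callset(empty, path3)
  expect_equal(callset_size(read_callset(path3, tissue = "None")), 0)
})

test_that("chromosome labels are normalized on input, prefixed on output", {
  expect_equal(variant_key("chr1", 5, "A", "G"), variant_key("1", 5, "A", "G"))
  expect_equal(denormalize_chrom(c("1", "chrX")), c("chr1", "chrX"))
})

test_that("the shipped chromosome table loads and is validated", {
  tab <- load_chrom_table()
  expect_equal(nrow(tab), 24)
  expect_setequal(tab$chrom, c(as.character(1:22), "X", "Y"))
  expect_true(all(tab$length_mb > 0 & tab$exon_count > 0 &
                    tab$coding_gene_count > 0))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tlength_mb\texon_count\tcoding_gene_count",
               "chr1\t249.25\t0\t2058"), bad)
  expect_error(load_chrom_table(bad), "exon_count")

  alien <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tlength_mb\texon_count\tcoding_gene_count",
               "chrMT\t0.016\t37\t13"), alien)
  expect_error(load_chrom_table(alien), "MT")
})

test_that("the default layer map reproduces the published assignments", {
  map <- load_layer_map()
  expect_equal(nrow(map), 16)
  lay <- function(t) map$layer[map$tissue == t]
  expect_equal(lay("Blood"), "mesoderm")
  expect_equal(lay("Adipose Tissue"), "ectoderm")
  expect_equal(lay("Liver"), "endoderm")
  expect_setequal(map$tissue[map$layer == "endoderm"],
                  c("Liver", "Pancreas", "Small Intestine", "Thyroid"))
  # colliding short labels are shipped disambiguated
  expect_setequal(map$abbrev[map$tissue %in%
                               c("Spinal Cord", "Suprarrenal Cortex")],
                  c("SpC", "SuC"))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("tissue\tabbrev\tlayer", "Gland\tGl\tneuroderm"), bad)
  expect_error(load_layer_map(bad), "neuroderm")
})

test_that("callsets enforce key uniqueness and depth invariants", {
  rec <- parse_variant_key(c("1:10:A>G", "1:10:A>G"))
  expect_error(tissue_callset(rec, tissue = "X"), "duplicate")
  rec2 <- parse_variant_key("1:10:A>G")
  rec2$dp <- 10L
  rec2$alt_depth <- 20L
  expect_error(tissue_callset(rec2, tissue = "X"), "alt_depth")
  expect_error(variant_key("1", 5, "A", "A"), "differ")
  expect_error(variant_key("1", 0, "A", "G"), ">= 1")
})
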