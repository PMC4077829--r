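# Synthetic developmental-mosaicism generator.
#
# The generative model is a depth-3 lineage tree, zygote -> germ layers ->
# tissues. Mutations are acquired at five stages and propagate to every
# tissue descending from the node where they arose:
#   germline / zygotic : carried by all tissues, cell fraction 1
#   layer              : carried by one germ layer's tissues, fraction 1
#   founder            : one tissue, fraction 1 (tissue-founder lineage)
#   late               : one tissue, fraction in (0, 0.5) — a subclone
# Observation then emulates ~50x exome sequencing: per tissue and variant,
# total depth is Poisson(coverage), alt reads are Binomial(depth,
# cell_fraction * mutant_copies / ploidy), and a variant is called when it
# clears minimal alt-read and VAF thresholds. There are no false-positive
# calls by default, so a called variant never escapes its truth scope.

#' Build a lineage tree from a layer map
#'
#' Constructs the rooted zygote -> germ-layer -> tissue tree implied by a
#' tissue-to-layer map. Deterministic: leaves appear in map order.
#'
#' @param layer_map Tibble from [load_layer_map()].
#' @return A list of class `lineage_tree`: `root`, `layers` (named list of
#'   tissue-name vectors), `tissues` (the map tibble).
#' @export
build_lineage_tree <- function(layer_map = load_layer_map()) {
  need <- c("tissue", "abbrev", "layer")
  stopifnot(all(need %in% names(layer_map)))
  bad <- setdiff(unique(layer_map$layer),
                 c("ectoderm", "mesoderm", "endoderm"))
  if (length(bad) > 0) {
    stop("tissue(s) with unknown layer: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  layers <- split(layer_map$tissue, layer_map$layer)
  structure(
    list(root = "zygote", layers = layers,
         tissues = tibble::as_tibble(layer_map[need])),
    class = "lineage_tree"
  )
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("<lineage_tree> zygote ->", length(x$layers), "germ layers ->",
      nrow(x$tissues), "tissues\n")
  for (l in names(x$layers)) {
    cat(" ", l, ":", paste(x$layers[[l]], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Simulation configuration
#'
#' Parameters of the developmental-mosaicism generator. Stage counts are
#' Poisson means; chromosome placement is multinomial with weights
#' proportional to per-chromosome protein-coding gene counts by default,
#' reflecting the empirical association between coding-gene content and
#' exonic SNV load. Coverage defaults to 50x, the depth of a typical
#' exome run. The per-stage means are package choices sized to give
#' non-degenerate pairwise tissue-specific counts; no published per-stage
#' mutation rates exist at this resolution.
#'
#' @param n_germline Expected germline + zygotic variants (default 12000).
#' @param n_per_layer Expected germ-layer variants per layer (default 300).
#' @param n_founder_per_tissue Expected tissue-founder variants per tissue
#'   (default 100).
#' @param n_late_per_tissue Expected late-somatic variants per tissue
#'   (default 200).
#' @param late_fraction_dist Function `n -> n` cell fractions in (0, 1) for
#'   late variants; default uniform on (0, 0.5).
#' @param coverage_mean Mean sequencing depth (default 50).
#' @param min_alt_reads Minimum alt reads to call (default 3).
#' @param min_vaf Minimum VAF to call (default 0.05).
#' @param ploidy,mutant_copies Locus copies per cell and mutant alleles per
#'   carrier cell (defaults 2 and 1: diploid heterozygous).
#' @param chrom_weights Placement weights, one per chromosome of the
#'   feature table; `NULL` (default) means proportional to
#'   `coding_gene_count`.
#' @param fail_inject_rate Probability that a called record receives one
#'   failing filter annotation (default 0; an option for stress-testing
#'   the hard filter, not part of the base model).
#' @param seed Optional integer seed fixing the whole simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_germline = 12000, n_per_layer = 300,
                       n_founder_per_tissue = 100, n_late_per_tissue = 200,
                       late_fraction_dist = function(n) runif(n, 0, 0.5),
                       coverage_mean = 50, min_alt_reads = 3,
                       min_vaf = 0.05, ploidy = 2, mutant_copies = 1,
                       chrom_weights = NULL, fail_inject_rate = 0,
                       seed = NULL) {
  means <- c(n_germline, n_per_layer, n_founder_per_tissue,
             n_late_per_tissue, coverage_mean)
  if (any(means < 0)) stop("all rate means must be >= 0", call. = FALSE)
  if (min_vaf < 0 || min_vaf >= 1) {
    stop("min_vaf must lie in [0, 1)", call. = FALSE)
  }
  stopifnot(is.function(late_fraction_dist))
  structure(
    list(n_germline = n_germline, n_per_layer = n_per_layer,
         n_founder_per_tissue = n_founder_per_tissue,
         n_late_per_tissue = n_late_per_tissue,
         late_fraction_dist = late_fraction_dist,
         coverage_mean = coverage_mean, min_alt_reads = min_alt_reads,
         min_vaf = min_vaf, ploidy = ploidy, mutant_copies = mutant_copies,
         chrom_weights = chrom_weights,
         fail_inject_rate = fail_inject_rate, seed = seed),
    class = "sim_config"
  )
}

BASES <- c("A", "C", "G", "T")

# Draw n variant sites: chromosome multinomial on weights, position uniform
# on the chromosome, random substitution. chrom:pos collisions are redrawn
# so keys are unique within the truth set.
draw_sites <- function(n, table, weights) {
  if (n == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
  }
  len_bp <- round(table$length_mb * 1e6)
  idx <- sample.int(nrow(table), n, replace = TRUE, prob = weights)
  pos <- as.integer(ceiling(runif(n) * len_bp[idx]))
  for (i in 1:100) {
    dup <- duplicated(paste0(idx, ":", pos))
    if (!any(dup)) break
    idx[dup] <- sample.int(nrow(table), sum(dup), replace = TRUE,
                           prob = weights)
    pos[dup] <- as.integer(ceiling(runif(sum(dup)) * len_bp[idx[dup]]))
  }
  ref_idx <- sample.int(4, n, replace = TRUE)
  alt_idx <- (ref_idx - 1L + sample.int(3, n, replace = TRUE)) %% 4L + 1L
  tibble::tibble(chrom = table$chrom[idx], pos = pos,
                 ref = BASES[ref_idx], alt = BASES[alt_idx])
}

#' Simulate the true mutation set of one individual
#'
#' Draws per-stage variant counts from Poisson distributions with the
#' configured means, places each variant on a chromosome (multinomially,
#' weights proportional to coding-gene counts by default) and at a uniform
#' position, and assigns its lineage scope: germline/zygotic variants to
#' all tissues, layer variants to one germ layer's tissues, founder and
#' late variants to a single tissue. Keys are unique; the draw is fully
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @param tree A [build_lineage_tree()] tree.
#' @param table A [load_chrom_table()] feature table.
#' @return A tibble of class `truth_set` with columns `key`, `chrom`,
#'   `pos`, `ref`, `alt`, `stage`, `scope` (list of tissue names),
#'   `cell_fraction`.
#' @export
simulate_truth <- function(config, tree, table = load_chrom_table()) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "lineage_tree"),
            inherits(table, "chrom_feature_table"))
  weights <- config$chrom_weights %||% table$coding_gene_count
  if (length(weights) != nrow(table)) {
    stop("chrom_weights must have one entry per chromosome of the table",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  all_tissues <- tree$tissues$tissue
  layer_names <- names(tree$layers)

  n_gz <- rpois(1, config$n_germline)
  n_germ <- rbinom(1, n_gz, 0.5)  # germline vs zygotic label split
  n_layer <- rpois(length(layer_names), config$n_per_layer)
  n_founder <- rpois(length(all_tissues), config$n_founder_per_tissue)
  n_late <- rpois(length(all_tissues), config$n_late_per_tissue)

  stage <- c(rep("germline", n_germ), rep("zygotic", n_gz - n_germ),
             rep("layer", sum(n_layer)), rep("founder", sum(n_founder)),
             rep("late", sum(n_late)))
  scope <- c(
    rep(list(all_tissues), n_gz),
    rep(tree$layers[layer_names], times = n_layer),
    rep(as.list(all_tissues), times = n_founder),
    rep(as.list(all_tissues), times = n_late)
  )
  n_total <- length(stage)
  cf <- rep(1, n_total)
  if (sum(n_late) > 0) {
    late_cf <- config$late_fraction_dist(sum(n_late))
    if (any(late_cf <= 0 | late_cf >= 1)) {
      stop("late_fraction_dist must return fractions in (0, 1)",
           call. = FALSE)
    }
    cf[stage == "late"] <- late_cf
  }
  sites <- draw_sites(n_total, table, weights)
  truth <- tibble::tibble(
    key = if (n_total > 0) variant_key(sites$chrom, sites$pos, sites$ref,
                                       sites$alt) else character(),
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    stage = stage, scope = scope, cell_fraction = cf
  )
  structure(truth, class = c("truth_set", class(truth)))
}

# Synthetic filter annotations drawn from comfortably passing ranges; with
# probability `rate` a record instead receives one failing value in a
# randomly chosen criterion.
synthetic_annotations <- function(n, rate = 0) {
  ann <- tibble::tibble(
    qd = runif(n, 5, 30), fs = runif(n, 0, 20), mq = runif(n, 40, 60),
    haplotype_score = runif(n, 0, 5), mq_rank_sum = runif(n, -4, 4),
    read_pos_rank_sum = runif(n, -4, 4)
  )
  if (rate > 0 && n > 0) {
    hit <- which(runif(n) < rate)
    which_crit <- sample.int(6, length(hit), replace = TRUE)
    fail_vals <- list(
      function(k) ann$qd[k] <<- runif(length(k), 0, 1.9),
      function(k) ann$fs[k] <<- runif(length(k), 61, 120),
      function(k) ann$mq[k] <<- runif(length(k), 0, 34),
      function(k) ann$haplotype_score[k] <<- runif(length(k), 13.5, 30),
      function(k) ann$mq_rank_sum[k] <<- runif(length(k), -20, -13),
      function(k) ann$read_pos_rank_sum[k] <<- runif(length(k), -15, -8.5)
    )
    for (c_ in 1:6) {
      k <- hit[which_crit == c_]
      if (length(k) > 0) fail_vals[[c_]](k)
    }
  }
  ann
}

#' Sample observed per-tissue callsets from a truth set
#'
#' Emulates exome sequencing of every tissue: for each (variant, tissue)
#' pair inside the variant's lineage scope, total depth is drawn
#' Poisson(`coverage_mean`) and alt reads Binomial(depth,
#' `cell_fraction * mutant_copies / ploidy`). A variant is called in a
#' tissue iff `alt_depth >= min_alt_reads` and `alt_depth/dp >= min_vaf`.
#' Called records receive synthetic filter annotations from passing ranges
#' (unless fail injection is enabled) and `func_class = "exonic"`. Tissues
#' outside a variant's scope never observe it: there are no false-positive
#' calls in the base model.
#'
#' @param truth A `truth_set` from [simulate_truth()].
#' @param config The same [sim_config()].
#' @param tree The [build_lineage_tree()] tree.
#' @param seed Optional seed for the observation stage (independent of the
#'   truth seed).
#' @return Named list of [tissue_callset()] objects, one per tissue of the
#'   tree (empty callsets included).
#' @export
sample_observed_callsets <- function(truth, config, tree, seed = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"),
            inherits(tree, "lineage_tree"))
  if (!is.null(seed)) set.seed(seed)
  tissues <- tree$tissues

  n_scope <- lengths(truth$scope)
  idx <- rep(seq_len(nrow(truth)), n_scope)
  tissue <- unlist(truth$scope)
  n <- length(idx)

  dp <- rpois(n, config$coverage_mean)
  p_read <- pmin(1, truth$cell_fraction[idx] * config$mutant_copies /
                   config$ploidy)
  alt <- rbinom(n, dp, p_read)
  vaf <- ifelse(dp > 0, alt / dp, 0)
  called <- dp > 0 & alt >= config$min_alt_reads & vaf >= config$min_vaf

  obs <- tibble::tibble(
    tissue = tissue[called], idx = idx[called],
    dp = dp[called], alt_depth = alt[called]
  )
  ann <- synthetic_annotations(nrow(obs), config$fail_inject_rate)

  groups <- split(seq_len(nrow(obs)),
                  factor(obs$tissue, levels = tissues$tissue))
  out <- vector("list", nrow(tissues))
  names(out) <- tissues$tissue
  for (i in seq_len(nrow(tissues))) {
    sel <- groups[[i]]
    ridx <- obs$idx[sel]
    rec <- tibble::tibble(
      chrom = truth$chrom[ridx], pos = truth$pos[ridx],
      ref = truth$ref[ridx], alt = truth$alt[ridx],
      key = truth$key[ridx], dp = obs$dp[sel], alt_depth = obs$alt_depth[sel],
      func_class = rep("exonic", length(sel)),
      db_id = rep(NA_character_, length(sel))
    )
    rec <- cbind(rec, ann[sel, ])
    out[[i]] <- tissue_callset(rec, tissue = tissues$tissue[i],
                               abbrev = tissues$abbrev[i],
                               layer = tissues$layer[i])
  }
  out
}

#' Run a full simulation
#'
#' Convenience wrapper: builds the lineage tree, simulates the truth set,
#' and samples observed callsets. The truth stage uses `config$seed` and
#' the observation stage `config$seed + 1` (when a seed is set), so the
#' whole run is reproducible from one integer.
#'
#' @param config A [sim_config()].
#' @param layer_map Tibble from [load_layer_map()].
#' @param table A [load_chrom_table()] feature table.
#' @return A list with `truth`, `callsets`, `tree`, `config`.
#' @export
simulate_mosaicism <- function(config = sim_config(),
                               layer_map = load_layer_map(),
                               table = load_chrom_table()) {
  tree <- build_lineage_tree(layer_map)
  truth <- simulate_truth(config, tree, table)
  obs_seed <- if (!is.null(config$seed)) config$seed + 1L else NULL
  callsets <- sample_observed_callsets(truth, config, tree, seed = obs_seed)
  list(truth = truth, callsets = callsets, tree = tree, config = config)
}

#' Write a simulation to disk
#'
#' Writes one VCF per tissue, a `truth.tsv` (key, stage, scope,
#' cell_fraction) and a `manifest.json` recording the configuration and
#' seed. Re-running with the same seed reproduces `truth.tsv` byte for
#' byte.
#'
#' @param callsets Named list of [tissue_callset()] objects.
#' @param truth A `truth_set` tibble.
#' @param out_dir Output directory.
#' @param config Optional [sim_config()] recorded in the manifest.
#' @param force Overwrite a non-empty directory (default `FALSE`).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(callsets, truth, out_dir, config = NULL,
                             force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    stop("output directory '", out_dir,
         "' is non-empty; use force = TRUE to overwrite", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in callsets) {
    write_callset(cs, file.path(out_dir, paste0(cs$abbrev, ".vcf")))
  }
  truth_flat <- tibble::tibble(
    key = truth$key, stage = truth$stage,
    scope = vapply(truth$scope, paste, character(1), collapse = ","),
    cell_fraction = truth$cell_fraction
  )
  readr::write_tsv(truth_flat, file.path(out_dir, "truth.tsv"),
                   progress = FALSE)
  manifest <- list(
    n_tissues = length(callsets),
    n_truth_variants = nrow(truth),
    seed = if (!is.null(config)) config$seed else NULL,
    config = if (!is.null(config)) {
      config[!vapply(config, is.function, logical(1))]
    } else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
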