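tab <- load_chrom_table()

test_that("the lineage tree mirrors the tissue-to-layer map", {
  tree <- build_lineage_tree(load_layer_map())
  expect_length(tree$layers, 3)
  expect_equal(nrow(tree$tissues), 16)
  expect_setequal(tree$layers$endoderm,
                  c("Liver", "Pancreas", "Small Intestine", "Thyroid"))

  single <- tibble::tibble(tissue = "Skin", abbrev = "Sk",
                           layer = "ectoderm")
  chain <- build_lineage_tree(single)
  expect_equal(chain$root, "zygote")
  expect_equal(unname(unlist(chain$layers)), "Skin")

  bad <- tibble::tibble(tissue = "Gland", abbrev = "Gl", layer = "unknown")
  expect_error(build_lineage_tree(bad), "unknown")
})

test_that("truth simulation is seed-reproducible and respects zero rates", {
  tree <- build_lineage_tree(small_layer_map())
  zero <- sim_config(n_germline = 0, n_per_layer = 0,
                     n_founder_per_tissue = 0, n_late_per_tissue = 0,
                     seed = 1)
  expect_equal(nrow(simulate_truth(zero, tree, tab)), 0)

  cfg <- sim_config(n_germline = 500, seed = 123)
  t1 <- simulate_truth(cfg, tree, tab)
  t2 <- simulate_truth(cfg, tree, tab)
  expect_identical(t1$key, t2$key)
  expect_identical(t1$stage, t2$stage)
})

test_that("truth scopes and fractions follow the five-stage model", {
  tree <- build_lineage_tree(small_layer_map())
  cfg <- sim_config(n_germline = 300, n_per_layer = 60,
                    n_founder_per_tissue = 20, n_late_per_tissue = 30,
                    seed = 5)
  truth <- simulate_truth(cfg, tree, tab)
  expect_false(anyDuplicated(truth$key) > 0)
  n_tissues <- nrow(tree$tissues)
  gz <- truth$stage %in% c("germline", "zygotic")
  expect_true(all(lengths(truth$scope[gz]) == n_tissues))
  expect_true(all(truth$cell_fraction[gz] == 1))
  lay <- truth$stage == "layer"
  expect_true(all(lengths(truth$scope[lay]) %in%
                    lengths(tree$layers)))
  expect_true(all(truth$cell_fraction[lay] == 1))
  expect_true(all(lengths(truth$scope[truth$stage %in%
                                        c("founder", "late")]) == 1))
  late_cf <- truth$cell_fraction[truth$stage == "late"]
  expect_true(all(late_cf > 0 & late_cf < 1))
  expect_true(all(truth$cell_fraction[truth$stage == "founder"] == 1))
})

test_that("chromosome placement follows the multinomial weights", {
  tree <- build_lineage_tree(small_layer_map())
  cfg <- sim_config(n_germline = 10000, n_per_layer = 0,
                    n_founder_per_tissue = 0, n_late_per_tissue = 0,
                    seed = 9)
  truth <- simulate_truth(cfg, tree, tab)
  w <- tab$coding_gene_count / sum(tab$coding_gene_count)
  obs <- as.integer(table(factor(truth$chrom, levels = tab$chrom)))
  n <- nrow(truth)
  # within 3 standard binomial errors of the expectation, per chromosome
  se <- sqrt(n * w * (1 - w))
  expect_true(all(abs(obs - n * w) <= pmax(3 * se, 3)))
})

test_that("observed VAF matches the binomial read-sampling model", {
  tree <- build_lineage_tree(small_layer_map())
  cfg <- sim_config(n_germline = 1000, n_per_layer = 0,
                    n_founder_per_tissue = 0, n_late_per_tissue = 0,
                    seed = 15)
  truth <- simulate_truth(cfg, tree, tab)
  css <- sample_observed_callsets(truth, cfg, tree, seed = 16)
  vafs <- unlist(lapply(css, function(cs) {
    cs$records$alt_depth / cs$records$dp
  }))
  expect_gt(length(vafs), 1000)
  expect_equal(mean(vafs), 0.5, tolerance = 0.02)
})

test_that("zero coverage yields no calls; permissive thresholds call all", {
  tree <- build_lineage_tree(small_layer_map())
  cfg0 <- sim_config(n_germline = 200, coverage_mean = 0, seed = 21)
  truth0 <- simulate_truth(cfg0, tree, tab)
  css0 <- sample_observed_callsets(truth0, cfg0, tree, seed = 22)
  expect_true(all(vapply(css0, callset_size, integer(1)) == 0))

  cfg1 <- sim_config(n_germline = 100, n_per_layer = 0,
                     n_founder_per_tissue = 0, n_late_per_tissue = 0,
                     min_alt_reads = 1, min_vaf = 0, seed = 23)
  truth1 <- simulate_truth(cfg1, tree, tab)
  css1 <- sample_observed_callsets(truth1, cfg1, tree, seed = 24)
  # a germline variant is called in every tissue under permissive calling
  for (cs in css1) {
    expect_setequal(callset_keys(cs), truth1$key)
  }
})

test_that("no called variant escapes its truth scope", {
  tree <- build_lineage_tree(small_layer_map())
  cfg <- sim_config(n_germline = 100, n_per_layer = 50,
                    n_founder_per_tissue = 40, n_late_per_tissue = 40,
                    seed = 31)
  truth <- simulate_truth(cfg, tree, tab)
  css <- sample_observed_callsets(truth, cfg, tree, seed = 32)
  scope_of <- setNames(truth$scope, truth$key)
  for (cs in css) {
    in_scope <- vapply(callset_keys(cs), function(k) {
      cs$tissue %in% scope_of[[k]]
    }, logical(1))
    expect_true(all(in_scope))
  }
  # tissue-specific keys across layers contain every called founder/late
  # variant of the first tissue
  a <- css[[which(vapply(css, function(x) x$layer, "") == "ectoderm")[1]]]
  b <- css[[which(vapply(css, function(x) x$layer, "") == "endoderm")[1]]]
  uniq <- pairwise_unique(a, b)
  fl_a <- callset_keys(a)[callset_keys(a) %in%
                            truth$key[truth$stage %in% c("founder", "late")]]
  fl_a <- fl_a[vapply(fl_a, function(k) identical(scope_of[[k]], a$tissue),
                      logical(1))]
  expect_true(all(fl_a %in% uniq))
})

test_that("call probability is non-decreasing in cell fraction", {
  tree <- build_lineage_tree(tibble::tibble(
    tissue = "T", abbrev = "T", layer = "ectoderm"))
  rates <- vapply(c(0.1, 0.3, 0.6), function(cf) {
    cfg <- sim_config(n_germline = 0, n_per_layer = 0,
                      n_founder_per_tissue = 0, n_late_per_tissue = 3000,
                      late_fraction_dist = function(n) rep(cf, n),
                      seed = 41)
    truth <- simulate_truth(cfg, tree, tab)
    css <- sample_observed_callsets(truth, cfg, tree, seed = 42)
    callset_size(css$T) / nrow(truth)
  }, double(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("fail injection produces records the hard filter rejects", {
  tree <- build_lineage_tree(small_layer_map())
  cfg <- sim_config(n_germline = 2000, n_per_layer = 0,
                    n_founder_per_tissue = 0, n_late_per_tissue = 0,
                    fail_inject_rate = 0.3, seed = 51)
  truth <- simulate_truth(cfg, tree, tab)
  css <- sample_observed_callsets(truth, cfg, tree, seed = 52)
  out <- apply_hard_filters(css[[1]], filter_thresholds(min_dp = 10))
  frac_fail <- 1 - out$report$n_pass / out$report$n_input
  expect_lt(abs(frac_fail - 0.3), 0.05)
})

test_that("simulations round-trip through the on-disk layout", {
  out_dir <- file.path(tempfile(), "sim")
  cfg <- sim_config(n_germline = 150, n_per_layer = 30,
                    n_founder_per_tissue = 10, n_late_per_tissue = 10,
                    seed = 61)
  sim <- simulate_mosaicism(cfg, layer_map = small_layer_map())
  write_simulation(sim$callsets, sim$truth, out_dir, config = cfg)
  vcfs <- list.files(out_dir, pattern = "\\.vcf$")
  expect_length(vcfs, 6)
  expect_true(file.exists(file.path(out_dir, "truth.tsv")))
  expect_true(file.exists(file.path(out_dir, "manifest.json")))
  truth_tab <- readr::read_tsv(file.path(out_dir, "truth.tsv"),
                               show_col_types = FALSE)
  expect_equal(nrow(truth_tab), nrow(sim$truth))

  # reading a written tissue back reproduces its key set
  cs <- sim$callsets[[1]]
  back <- read_callset(file.path(out_dir, paste0(cs$abbrev, ".vcf")),
                       tissue = cs$tissue)
  expect_setequal(callset_keys(back), callset_keys(cs))

  # refusing to clobber a non-empty directory
  expect_error(write_simulation(sim$callsets, sim$truth, out_dir),
               "force")

  # byte-identical truth.tsv under the same seed
  sim2 <- simulate_mosaicism(cfg, layer_map = small_layer_map())
  out2 <- file.path(tempfile(), "sim2")
  write_simulation(sim2$callsets, sim2$truth, out2, config = cfg)
  expect_identical(readLines(file.path(out2, "truth.tsv")),
                   readLines(file.path(out_dir, "truth.tsv")))
})
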