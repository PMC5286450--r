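test_that("mask_low_depth masks below threshold, keeps the boundary", {
  g <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  dp <- matrix(c(9L, 10L, 11L, 0L), 2, 2)
  tbl <- make_table(g, depth = dp)
  out <- mask_low_depth(tbl, 10)
  expect_true(is.na(out$geno[1, 1]))       # DP = 9 masked
  expect_equal(out$geno[2, 1], g[2, 1])    # DP = 10 retained (inclusive)
  expect_equal(out$geno[1, 2], g[1, 2])    # DP = 11 retained
  expect_true(is.na(out$geno[2, 2]))

  all0 <- make_table(g, depth = matrix(0L, 2, 2))
  out0 <- mask_low_depth(all0, 10)
  expect_true(all(is.na(out0$geno)))
  expect_equal(dim(out0$geno), dim(g))     # same shape, no loci removed
  expect_error(mask_low_depth(make_table(g), 10), "depths")
})

test_that("filter_site_quality enforces strict MAF and missingness bounds", {
  # 10 samples; rows: maf 0.05; maf exactly 0.10; maf 0.3 with 30% missing;
  # clean keeper
  g <- rbind(c(1L, rep(0L, 9)),                        # maf 0.05
             c(2L, rep(0L, 9)),                        # maf 0.10 (boundary)
             c(1L, 1L, 2L, 2L, 0L, 0L, 0L, NA, NA, NA),# 30% missing
             c(1L, 1L, 2L, 0L, 0L, 0L, 1L, 1L, 0L, 0L))
  tbl <- make_table(g, pos = c(100L, 200L, 300L, 400L))
  res <- filter_site_quality(tbl, 0.10, 0.25)
  expect_equal(locus_ids(res$table), "c1:400")
  expect_setequal(res$removed, c("c1:100", "c1:200", "c1:300"))
})

test_that("filter_site_quality matches a brute-force keep-set", {
  tbl <- random_table(80, 12, seed = 9, miss = 0.25)
  res <- filter_site_quality(tbl, 0.10, 0.25)
  keep_brute <- vapply(seq_len(n_loci(tbl)), function(l) {
    x <- tbl$geno[l, ]
    nt <- sum(!is.na(x))
    if (nt == 0) return(FALSE)
    p <- sum(x, na.rm = TRUE) / (2 * nt)
    maf <- min(p, 1 - p)
    miss <- 1 - nt / length(x)
    maf > 0.10 && miss < 0.25
  }, logical(1))
  expect_setequal(locus_ids(res$table), locus_ids(tbl)[keep_brute])
})

test_that("filter_contig_density drops dense contigs wholesale", {
  g <- matrix(1L, 7, 4)
  tbl <- make_table(g,
    contig = c("a", "a", "a", "b", "b", "b", "c"),
    pos = c(1L, 5L, 9L, 1L, 101L, 201L, 50L))
  res <- filter_contig_density(tbl, 10)
  expect_equal(res$removed_contigs, "a")          # density (9-1)/2 = 4 < 10
  expect_setequal(unique(res$table$loci$contig), c("b", "c"))  # density 100; single-SNP kept
  # brute-force oracle on a random layout
  tbl2 <- random_table(50, 6, seed = 2, miss = 0, contigs = 8)
  res2 <- filter_contig_density(tbl2, 100)
  for (ct in unique(tbl2$loci$contig)) {
    pos <- tbl2$loci$pos[tbl2$loci$contig == ct]
    dens <- if (length(pos) < 2) Inf else (max(pos) - min(pos)) / (length(pos) - 1)
    expect_equal(ct %in% res2$removed_contigs, dens < 100)
  }
})

test_that("ld_prune removes duplicates within contigs only", {
  base <- sample(0:2, 10, replace = TRUE)
  other <- c(0L, 2L, 1L, 0L, 1L, 2L, 0L, 1L, 2L, 0L)
  # same contig: copy removed
  tbl <- make_table(rbind(base, base, other), pos = c(100L, 300L, 500L))
  res <- ld_prune(tbl, 0.5)
  expect_equal(res$removed, "c1:300")
  expect_setequal(locus_ids(res$table), c("c1:100", "c1:500"))
  # different contigs: both identical columns retained
  tbl2 <- make_table(rbind(base, base), contig = c("c1", "c2"),
                     pos = c(100L, 100L))
  expect_length(ld_prune(tbl2, 0.5)$removed, 0)
})

test_that("ld_prune leaves no retained within-contig pair above r2_max", {
  tbl <- random_table(60, 15, seed = 13, miss = 0.1, contigs = 3)
  res <- ld_prune(tbl, 0.5)
  kept <- res$table
  for (ct in unique(kept$loci$contig)) {
    idx <- which(kept$loci$contig == ct)
    if (length(idx) < 2) next
    r2 <- suppressWarnings(
      stats::cor(t(kept$geno[idx, , drop = FALSE]),
                 use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    diag(r2) <- 0
    expect_lte(max(r2), 0.5)
  }
  # idempotent
  expect_length(ld_prune(kept, 0.5)$removed, 0)
})

test_that("spacing_filter keeps the first of a too-close run", {
  tbl <- make_table(matrix(1L, 3, 4), pos = c(1L, 50L, 150L))
  res <- spacing_filter(tbl, 100)
  expect_setequal(locus_ids(res$table), c("c1:1", "c1:150"))
  # gap of exactly min_spacing satisfies the requirement
  tbl2 <- make_table(matrix(1L, 2, 4), pos = c(1L, 101L))
  expect_length(spacing_filter(tbl2, 100)$removed, 0)
  # postcondition scan on a random fixture + idempotence
  tbl3 <- random_table(70, 5, seed = 21, miss = 0, contigs = 2)
  out3 <- spacing_filter(tbl3, 200)$table
  for (ct in unique(out3$loci$contig)) {
    pos <- sort(out3$loci$pos[out3$loci$contig == ct])
    if (length(pos) > 1) expect_gte(min(diff(pos)), 200)
  }
  expect_length(spacing_filter(out3, 200)$removed, 0)
})

test_that("drop_loci removes exactly the requested loci", {
  tbl <- random_table(20, 4, seed = 1, miss = 0)
  ids <- locus_ids(tbl)[c(3, 7, 11)]
  res <- drop_loci(tbl, ids, "custom")
  expect_equal(n_loci(res$table), 17L)
  expect_setequal(res$removed, ids)
  expect_equal(res$stage_name, "custom")
  expect_equal(n_loci(drop_loci(tbl, character(0))$table), 20L)  # empty = identity
  expect_error(drop_loci(tbl, "nope:1"), "unknown locus")
})

test_that("run_cascade with disabled thresholds is the identity", {
  tbl <- random_table(100, 20, seed = 31, miss = 0)
  frame <- sample_frame(data.frame(
    sample_id = tbl$samples, site_id = rep(c("s1", "s2"), 10),
    longitude = 137, latitude = -31, stringsAsFactors = FALSE))
  cfg <- filter_config(min_depth = 0, min_maf = 0, max_missing = 1,
                       min_bp_per_snp = 0, ld_r2_max = 1, min_spacing = 0,
                       run_outlier_scan = FALSE, run_fis_filter = FALSE)
  out <- run_cascade(tbl, frame, cfg)
  expect_equal(locus_ids(out$table), locus_ids(tbl))
  expect_equal(out$table$geno, tbl$geno)
})

test_that("cascade report chains counts, is disjoint and reproducible", {
  sim <- simulate_dataset(sim_params(
    n_clusters = 2, sites_per_cluster = c(2, 2), n_per_site = 10,
    n_loci = 120, f_ct = 0.1, f_sc = 0.03, f_is = 0.05,
    missing_rate = 0.03, seed = 41))
  cfg <- filter_config(run_outlier_scan = FALSE, run_fis_filter = TRUE,
                       fis_n_perm = 200)
  out1 <- run_cascade(sim$table, sim$frame, cfg, seed = 2)
  out2 <- run_cascade(sim$table, sim$frame, cfg, seed = 2)
  st <- out1$report$stages
  expect_equal(st$n_in - st$n_removed, st$n_out)
  expect_equal(st$n_out[-nrow(st)], st$n_in[-1])    # counts chain stage to stage
  removed <- unlist(out1$report$removed, use.names = FALSE)
  expect_equal(anyDuplicated(removed), 0L)          # stages disjoint
  expect_identical(out1$report, out2$report)        # pure function of inputs
  expect_identical(out1$table, out2$table)
})

test_that("cascade recovers spiked LD copies and paralogs", {
  sim <- simulate_dataset(sim_params(
    n_loci = 250, n_paralog = 20, n_ld_copies = 15,
    missing_rate = 0.02, seed = 51))
  truth <- sim$truth$loci
  cfg <- filter_config(min_depth = 10, min_maf = 0, max_missing = 1,
                       min_bp_per_snp = 0,
                       run_outlier_scan = FALSE, run_fis_filter = TRUE,
                       fis_n_perm = 300)
  out <- run_cascade(sim$table, sim$frame, cfg, seed = 3)
  ld_ids <- truth$locus[truth$class == "ld_copy"]
  par_ids <- truth$locus[truth$class == "paralog"]
  # exact duplicates pruned with 100% recall
  expect_true(all(ld_ids %in% out$report$removed$ld_prune))
  # forced-heterozygote loci flagged by the negative-FIS screen (>= 90%)
  hit <- mean(par_ids %in% out$report$removed$negative_fis)
  expect_gte(hit, 0.9)
  # class bookkeeping: spiked counts equal construction
  expect_equal(sum(truth$class == "ld_copy"), 15L)
  expect_equal(sum(truth$class == "paralog"), 20L)
  expect_equal(sum(truth$class == "neutral"), 250L)
})
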