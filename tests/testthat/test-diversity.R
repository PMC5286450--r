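test_that("heterozygosities match the worked examples", {
  # genotypes {AA, Aa, aa}: H_O = 1/3; H_E = 0.5 * 6/5 = 0.6 (corrected)
  tbl <- make_table(matrix(c(2L, 1L, 0L), 1, 3))
  div <- heterozygosities(tbl, list(g = tbl$samples))
  expect_equal(div$h_obs[div$group == "g"], 1 / 3)
  expect_equal(div$h_exp[div$group == "g"], 0.6)
  div_u <- heterozygosities(tbl, list(g = tbl$samples), corrected = FALSE)
  expect_equal(div_u$h_exp[div_u$group == "g"], 0.5)
  # monomorphic locus: both zero
  mono <- make_table(matrix(0L, 1, 3))
  divm <- heterozygosities(mono, list(g = mono$samples))
  expect_equal(divm$h_obs[1], 0)
  expect_equal(divm$h_exp[1], 0)
})

test_that("heterozygosities invariant to group relabeling; H_E > H_O under inbreeding", {
  tbl <- random_table(50, 10, seed = 3, miss = 0.1)
  g1 <- list(a = tbl$samples[1:5], b = tbl$samples[6:10])
  g2 <- list(zzz = tbl$samples[1:5], yyy = tbl$samples[6:10])
  d1 <- heterozygosities(tbl, g1)
  d2 <- heterozygosities(tbl, g2)
  expect_equal(d1[c("n", "h_obs", "h_exp")], d2[c("n", "h_obs", "h_exp")])

  sim <- simulate_dataset(sim_params(
    n_clusters = 1, sites_per_cluster = 1, n_per_site = 60, n_loci = 400,
    f_ct = 0, f_sc = 0, f_is = 0.2, missing_rate = 0, seed = 5))
  d <- heterozygosities(sim$table, list(all = sim$table$samples))
  expect_gt(d$h_exp[1], d$h_obs[1])
})

test_that("the pairing null matches brute-force allele shuffling", {
  set.seed(9)
  n_ind <- 7L
  a_alt <- 5L
  exact <- popcurate:::sample_het_pairing(n_ind, a_alt, 20000)
  brute <- brute_het_draws(n_ind, a_alt, 20000)
  ks <- sort(unique(c(exact, brute)))
  pmf_e <- tabulate(match(exact, ks), length(ks)) / length(exact)
  pmf_b <- tabulate(match(brute, ks), length(ks)) / length(brute)
  expect_lt(max(abs(pmf_e - pmf_b)), 0.02)
  # degenerate pools
  expect_equal(popcurate:::sample_het_pairing(4L, 0L, 10), rep(0L, 10))
  expect_equal(popcurate:::sample_het_pairing(4L, 8L, 10), rep(0L, 10))
})

test_that("fis_test flags heterozygote excess, not deficit", {
  # every individual heterozygous, n = 20: strong excess, flagged
  all_het <- make_table(matrix(1L, 1, 20))
  ft <- fis_test(all_het, list(g = all_het$samples), n_perm = 2000, seed = 1)
  expect_lt(ft$fis, 0)
  expect_lte(ft$p_low, 0.05)
  expect_true(ft$flag_negative)
  # all-homozygous polymorphic group: F_IS = 1, never flagged as negative
  homo <- make_table(matrix(rep(c(0L, 2L), 5), 1, 10))
  fh <- fis_test(homo, list(g = homo$samples), n_perm = 500, seed = 1)
  expect_equal(fh$fis, 1)
  expect_false(fh$flag_negative)
  # monomorphic: undefined, NA, unflagged
  mono <- make_table(matrix(2L, 1, 10))
  fm <- fis_test(mono, list(g = mono$samples), n_perm = 500, seed = 1)
  expect_true(is.na(fm$fis))
  expect_false(fm$flag_negative)
})

test_that("fis_test is calibrated under Hardy-Weinberg", {
  sim <- simulate_dataset(sim_params(
    n_clusters = 1, sites_per_cluster = 1, n_per_site = 50, n_loci = 1000,
    f_ct = 0, f_sc = 0, f_is = 0, missing_rate = 0, seed = 11))
  ft <- fis_test(sim$table, list(all = sim$table$samples),
                 n_perm = 500, seed = 3)
  expect_lte(mean(ft$flag_negative), 0.07)
  # p_low super-uniform under the null
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(ft$p_low <= a, na.rm = TRUE), a + 0.03)
})

test_that("pairwise theta: fixed difference, panmixia, and the 1984 oracle", {
  # pop1 all AA, pop2 all aa -> theta = 1
  fixed <- make_table(matrix(rep(c(2L, 0L), each = 4), 1, 8))
  gr <- list(p1 = fixed$samples[1:4], p2 = fixed$samples[5:8])
  expect_equal(unname(pairwise_fst(fixed, gr)[1, 2]), 1)

  # two groups from one panmictic pool: |theta| < 0.01 at 1000 loci
  sim <- simulate_dataset(sim_params(
    n_clusters = 1, sites_per_cluster = 2, n_per_site = 30, n_loci = 1000,
    f_ct = 0, f_sc = 0, f_is = 0, missing_rate = 0, seed = 13))
  grp <- split(sim$frame$sample_id, sim$frame$site_id)
  expect_lt(abs(pairwise_fst(sim$table, grp)[1, 2]), 0.01)

  # single locus, pop1 {AA, Aa}, pop2 {Aa, aa}: hand-computed theta
  tbl <- make_table(matrix(c(2L, 1L, 1L, 0L), 1, 4))
  gr2 <- list(p1 = tbl$samples[1:2], p2 = tbl$samples[3:4])
  got <- unname(pairwise_fst(tbl, gr2)[1, 2])
  want <- wc_theta_brute(c(2, 2), c(0.75, 0.25), c(0.5, 0.5))
  expect_equal(got, want)
  # symmetry and zero diagonal
  m <- pairwise_fst(tbl, gr2)
  expect_equal(m[1, 2], m[2, 1])
  expect_equal(unname(diag(m)), c(0, 0))
})

test_that("global theta is a ratio of sums over loci", {
  tbl <- random_table(40, 12, seed = 15, miss = 0.1)
  gr <- list(a = tbl$samples[1:4], b = tbl$samples[5:8], c = tbl$samples[9:12])
  gc <- popcurate:::group_counts(tbl, gr)
  num <- den <- 0
  for (l in seq_len(n_loci(tbl))) {
    n <- gc$n[, l]
    act <- n > 0
    if (sum(act) < 2) next
    n <- n[act]
    p <- gc$alt[act, l] / (2 * n)
    h <- gc$het[act, l] / n
    nbar <- mean(n)
    if (nbar <= 1) next
    r <- length(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    if (nc <= 0) next
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / sum(n)
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  expect_equal(global_fst(tbl, gr), num / den)
})

test_that("nested AMOVA: fixed cluster difference gives F_CT = 1", {
  geno <- rbind(matrix(rep(c(0L, 2L), each = 6), 5, 12, byrow = TRUE))
  tbl <- make_table(geno)
  frame <- sample_frame(data.frame(
    sample_id = tbl$samples,
    site_id = rep(c("s1", "s2", "s3", "s4"), each = 3),
    longitude = 137, latitude = -31,
    cluster_id = rep(c("C1", "C2"), each = 6), stringsAsFactors = FALSE))
  am <- nested_amova(tbl, build_hierarchy(frame), n_perm = 0)
  f <- setNames(am$f$value, am$f$index)
  expect_equal(unname(f["F_CT"]), 1)
  pc <- setNames(am$components$percent, am$components$stratum)
  expect_equal(unname(pc["within_individual"]), 0)
  expect_equal(sum(am$components$percent), 100, tolerance = 1e-6)
})

test_that("nested AMOVA is null-calibrated and internally consistent", {
  sim <- simulate_dataset(sim_params(
    n_loci = 800, f_ct = 0, f_sc = 0, f_is = 0,
    missing_rate = 0, seed = 23))
  am <- nested_amova(sim$table, build_hierarchy(sim$frame), n_perm = 99,
                     seed = 1)
  f <- setNames(am$f$value, am$f$index)
  expect_true(all(abs(f) < 0.02))
  # F_IT has no permutation scheme of its own; its p is NA by design
  p <- am$f$p[am$f$index != "F_IT"]
  expect_true(all(p > 0 & p <= 1))
  expect_equal(sum(am$components$percent), 100, tolerance = 1e-6)

  # theta on two groups equals the F_SC-level AMOVA ratio, same two sites
  # nested in one cluster (internal consistency oracle)
  sim2 <- simulate_dataset(sim_params(
    n_clusters = 1, sites_per_cluster = 2, n_per_site = c(8, 12),
    n_loci = 60, f_ct = 0, f_sc = 0.08, f_is = 0.1, missing_rate = 0.05,
    seed = 4))
  gr <- split(sim2$frame$sample_id, sim2$frame$site_id)
  th <- pairwise_fst(sim2$table, gr)[1, 2]
  am2 <- suppressWarnings(
    nested_amova(sim2$table, build_hierarchy(sim2$frame), n_perm = 0))
  fsc <- am2$f$value[am2$f$index == "F_SC"]
  expect_equal(unname(th), fsc, tolerance = 1e-8)
})

test_that("nested AMOVA recovers the generating indices", {
  targets <- c(f_ct = 0.17, f_sc = 0.05, f_is = 0.12)
  for (s in 1:2) {
    sim <- simulate_dataset(sim_params(seed = 60 + s))
    am <- nested_amova(sim$table, build_hierarchy(sim$frame), n_perm = 0)
    f <- setNames(am$f$value, am$f$index)
    expect_lt(abs(f["F_CT"] - targets["f_ct"]), 0.03)
    expect_lt(abs(f["F_SC"] - targets["f_sc"]), 0.03)
    expect_lt(abs(f["F_IS"] - targets["f_is"]), 0.03)
  }
})

test_that("degenerate hierarchies warn", {
  tbl <- random_table(20, 6, seed = 7, miss = 0)
  frame <- sample_frame(data.frame(
    sample_id = tbl$samples, site_id = rep(c("s1", "s2"), each = 3),
    longitude = 137, latitude = -31, cluster_id = "C1",
    stringsAsFactors = FALSE))
  expect_warning(nested_amova(tbl, build_hierarchy(frame), n_perm = 0),
                 "single cluster")
})
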