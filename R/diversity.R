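#' @title Heterozygosity, FIS, FST and nested AMOVA
#' @description Per-locus and multi-locus diversity statistics on dosage
#'   genotypes: observed/expected heterozygosity with a small-sample
#'   correction, FIS with an allele-pairing permutation test (the paralog
#'   screen), multi-locus Weir & Cockerham theta, and the four-level nested
#'   analysis of molecular variance with stratified permutation tests.
#' @name diversity_stats
NULL

# per-group per-locus counts: genotyped individuals, alt alleles, heterozygotes
group_counts <- function(table, grouping) {
  grouping <- as_grouping(table, grouping)
  G <- length(grouping)
  L <- n_loci(table)
  n <- alt <- het <- matrix(0, G, L,
                            dimnames = list(names(grouping), locus_ids(table)))
  for (k in seq_along(grouping)) {
    sub <- table$geno[, match(grouping[[k]], table$samples), drop = FALSE]
    n[k, ] <- rowSums(!is.na(sub))
    alt[k, ] <- rowSums(sub, na.rm = TRUE)
    het[k, ] <- rowSums(sub == 1L, na.rm = TRUE)
  }
  list(n = n, alt = alt, het = het)
}

# sample-size-corrected expected heterozygosity: (2n/(2n-1)) * 2pq
expected_het <- function(n, p, corrected = TRUE) {
  he <- 2 * p * (1 - p)
  if (corrected) he <- he * ifelse(n > 0, 2 * n / pmax(2 * n - 1, 1), 0)
  he
}

#' Observed and expected heterozygosity per group
#'
#' Per locus, observed heterozygosity is the heterozygote fraction among
#' non-missing genotypes; expected heterozygosity is `2pq` with the
#' small-sample correction `2n/(2n-1)` (n = genotyped diploids). Group values
#' are means over loci with data in that group; an `overall` row pools all
#' samples.
#'
#' @param table a `variant_table`.
#' @param grouping named list group -> sample ids, or a per-sample label
#'   vector.
#' @param corrected apply the `2n/(2n-1)` correction (default TRUE).
#' @return A `diversity_summary`: data.frame with columns `group`, `n`,
#'   `h_obs`, `h_exp`.
#' @export
heterozygosities <- function(table, grouping, corrected = TRUE) {
  grouping <- as_grouping(table, grouping)
  gc <- group_counts(table, grouping)
  per_group <- function(n, alt, het) {
    ok <- n > 0
    p <- ifelse(ok, alt / (2 * n), NA_real_)
    ho <- ifelse(ok, het / n, NA_real_)
    he <- ifelse(ok, expected_het(n, p, corrected), NA_real_)
    c(h_obs = mean(ho[ok]), h_exp = mean(he[ok]))
  }
  rows <- t(vapply(seq_along(grouping), function(k)
    per_group(gc$n[k, ], gc$alt[k, ], gc$het[k, ]), numeric(2)))
  pooled <- group_counts(table, list(overall = table$samples))
  ov <- per_group(pooled$n[1, ], pooled$alt[1, ], pooled$het[1, ])
  out <- data.frame(
    group = c(names(grouping), "overall"),
    n = c(vapply(grouping, length, integer(1)), n_samples(table)),
    h_obs = c(rows[, "h_obs"], ov["h_obs"]),
    h_exp = c(rows[, "h_exp"], ov["h_exp"]),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("diversity_summary", "data.frame")
  out
}

# exact distribution of the heterozygote count when 2n alleles (a of them
# alt) are paired at random into n diploids; returns B draws
sample_het_pairing <- function(n_ind, a_alt, B) {
  if (n_ind == 0) return(rep(0L, B))
  two_n <- 2L * n_ind
  kmax <- min(a_alt, two_n - a_alt)
  if (kmax <= 0) return(rep(0L, B))
  ks <- seq.int(a_alt %% 2L, kmax, by = 2L)
  logp <- ks * log(2) - lfactorial((a_alt - ks) / 2) - lfactorial(ks) -
    lfactorial((two_n - a_alt - ks) / 2)
  logp <- logp - max(logp)
  if (length(ks) == 1L) return(rep(ks, B))
  sample(ks, B, replace = TRUE, prob = exp(logp))
}

#' FIS with an allele-pairing permutation test
#'
#' Per-locus inbreeding coefficient `F_IS = 1 - H_O/H_E`, pooled over groups
#' by sample-size-weighted averages of the within-group heterozygosities.
#' The null distribution is that of shuffling alleles among individuals
#' within each group (equivalently, re-pairing the fixed allele pool at
#' random into diploids), sampled exactly from the conditional pairing
#' distribution. One-sided p-values are reported for heterozygote excess
#' (`p_low`: permuted FIS <= observed) and deficit (`p_high`), with `(b+1) /
#' (m+1)` smoothing. Loci with `p_low <= alpha` and negative FIS are flagged
#' — the paralog-collapse signature.
#'
#' @param table a `variant_table`.
#' @param grouping named list group -> sample ids, or per-sample labels.
#' @param n_perm number of permutations (>= 100).
#' @param alpha significance level for the negative-FIS flag.
#' @param seed integer seed.
#' @return A `fis_test_result` data.frame: `locus`, `fis`, `p_low`,
#'   `p_high`, `flag_negative`. Loci with undefined FIS (pooled H_E = 0)
#'   have `NA` statistics and are never flagged.
#' @export
fis_test <- function(table, grouping, n_perm = 10000, alpha = 0.05, seed = 1) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  grouping <- as_grouping(table, grouping)
  gc <- group_counts(table, grouping)
  G <- nrow(gc$n)
  L <- ncol(gc$n)
  n_tot <- colSums(gc$n)
  p_mat <- ifelse(gc$n > 0, gc$alt / (2 * gc$n), 0)
  he_mat <- expected_het(gc$n, p_mat)
  he_pool <- colSums(gc$n * he_mat) / pmax(n_tot, 1)
  ho_pool <- colSums(gc$het) / pmax(n_tot, 1)
  fis <- ifelse(he_pool > 0, 1 - ho_pool / he_pool, NA_real_)

  het_obs <- colSums(gc$het)
  p_low <- p_high <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    if (is.na(fis[l])) next
    h_perm <- rep(0L, n_perm)
    for (k in seq_len(G)) {
      if (gc$n[k, l] > 0)
        h_perm <- h_perm + sample_het_pairing(gc$n[k, l], gc$alt[k, l], n_perm)
    }
    # FIS decreases in the het count: low tail of FIS = high tail of hets
    p_low[l] <- (1 + sum(h_perm >= het_obs[l])) / (n_perm + 1)
    p_high[l] <- (1 + sum(h_perm <= het_obs[l])) / (n_perm + 1)
  }
  out <- data.frame(
    locus = locus_ids(table), fis = fis, p_low = p_low, p_high = p_high,
    flag_negative = !is.na(fis) & fis < 0 & !is.na(p_low) & p_low <= alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("fis_test_result", "data.frame")
  out
}

# Weir & Cockerham (1984) per-locus variance components a, b, c.
# n, p, h: groups x loci matrices of sample sizes (diploids), alt-allele
# frequencies and heterozygote fractions. Groups with n = 0 at a locus are
# dropped from that locus.
wc_components <- function(n, p, h) {
  active <- n > 0
  r <- colSums(active)
  p[!active] <- 0
  h[!active] <- 0
  nsum <- colSums(n)
  nbar <- nsum / pmax(r, 1)
  pbar <- colSums(n * p) / pmax(nsum, 1)
  pbar_m <- matrix(pbar, nrow(n), ncol(n), byrow = TRUE)
  s2 <- colSums(n * (p - pbar_m)^2) / pmax((r - 1) * nbar, 1)
  hbar <- colSums(n * h) / pmax(nsum, 1)
  nc <- (nsum - colSums(n^2) / pmax(nsum, 1)) / pmax(r - 1, 1)
  valid <- r >= 2 & nbar > 1 & nc > 0
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!valid] <- b[!valid] <- cc[!valid] <- NA_real_
  list(a = a, b = b, c = cc, valid = valid)
}

# multi-locus theta: ratio of sums over valid loci
wc_theta <- function(comp) {
  ok <- comp$valid & !is.na(comp$a)
  denom <- sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
  if (!any(ok) || denom == 0) return(NA_real_)
  sum(comp$a[ok]) / denom
}

#' Pairwise Weir-Cockerham FST between groups
#'
#' Multi-locus theta of Weir & Cockerham (1984): per-locus variance
#' components among populations (a), among individuals within populations
#' (b), and within individuals (c), combined over loci as ratio of sums,
#' `sum(a) / sum(a + b + c)`.
#'
#' @param table a `variant_table`.
#' @param grouping named list group -> sample ids, or per-sample labels.
#' @return An `fst_matrix`: symmetric group x group matrix of theta, zero
#'   diagonal; `NA` where a pair shares no informative locus.
#' @export
pairwise_fst <- function(table, grouping) {
  grouping <- as_grouping(table, grouping)
  if (length(grouping) < 2) stop("need at least two groups")
  gc <- group_counts(table, grouping)
  p <- ifelse(gc$n > 0, gc$alt / (2 * gc$n), 0)
  h <- ifelse(gc$n > 0, gc$het / gc$n, 0)
  G <- length(grouping)
  m <- matrix(0, G, G, dimnames = list(names(grouping), names(grouping)))
  for (i in seq_len(G - 1)) {
    for (j in seq.int(i + 1, G)) {
      idx <- c(i, j)
      comp <- wc_components(gc$n[idx, , drop = FALSE],
                            p[idx, , drop = FALSE], h[idx, , drop = FALSE])
      m[i, j] <- m[j, i] <- wc_theta(comp)
    }
  }
  structure(m, class = c("fst_matrix", class(m)))
}

#' Overall multi-locus Weir-Cockerham FST across all groups
#'
#' @inheritParams pairwise_fst
#' @return A single theta value.
#' @export
global_fst <- function(table, grouping) {
  grouping <- as_grouping(table, grouping)
  gc <- group_counts(table, grouping)
  p <- ifelse(gc$n > 0, gc$alt / (2 * gc$n), 0)
  h <- ifelse(gc$n > 0, gc$het / gc$n, 0)
  wc_theta(wc_components(gc$n, p, h))
}

# --- nested AMOVA -----------------------------------------------------------

# per-locus four-level variance components from site-level summaries.
# site_n/site_alt/site_het: sites x loci; cl: cluster factor over sites.
amova_from_sites <- function(site_n, site_alt, site_het, cl) {
  L <- ncol(site_n)
  N_p <- 2 * site_n                      # alleles per site
  sumg2 <- 2 * site_alt - site_het       # sum of squared dosages per site
  ratio_p <- ifelse(N_p > 0, site_alt^2 / N_p, 0)

  cl <- as.factor(cl)
  clu_n <- rowsum(site_n, cl)            # clusters x loci (individuals)
  clu_alt <- rowsum(site_alt, cl)
  clu_ratio <- ifelse(clu_n > 0, clu_alt^2 / (2 * clu_n), 0)
  # per-cluster sum of site ratios, for SS among pops within clusters
  site_ratio_by_clu <- rowsum(ratio_p, cl)

  m_tot <- colSums(site_n)
  N <- 2 * m_tot
  S <- colSums(site_alt)
  tot_ratio <- ifelse(N > 0, S^2 / N, 0)

  ss_wi <- colSums(site_het) / 2
  ss_ind <- colSums(ifelse(N_p > 0, sumg2 / 2 - ratio_p, 0))
  ss_pop <- colSums(site_ratio_by_clu - clu_ratio)
  ss_clu <- colSums(clu_ratio) - tot_ratio

  P_l <- colSums(site_n > 0)
  G_l <- colSums(clu_n > 0)
  df_wi <- m_tot
  df_ind <- m_tot - P_l
  df_pop <- P_l - G_l
  df_clu <- G_l - 1

  # unequal-size coefficients (allele units)
  sum_Np2_over_Nc <- colSums(
    N_p^2 / pmax(2 * clu_n[as.integer(cl), , drop = FALSE], 1))
  sum_Np2_over_N <- colSums(N_p^2) / pmax(N, 1)
  sum_Nc2_over_N <- colSums((2 * clu_n)^2) / pmax(N, 1)
  n1 <- (N - sum_Np2_over_Nc) / pmax(df_pop, 1)
  n2 <- (sum_Np2_over_Nc - sum_Np2_over_N) / pmax(df_clu, 1)
  n3 <- (N - sum_Nc2_over_N) / pmax(df_clu, 1)

  ms_wi <- ifelse(df_wi > 0, ss_wi / df_wi, 0)
  ms_ind <- ifelse(df_ind > 0, ss_ind / df_ind, 0)
  ms_pop <- ifelse(df_pop > 0, ss_pop / df_pop, 0)
  ms_clu <- ifelse(df_clu > 0, ss_clu / df_clu, 0)

  s2_w <- ms_wi
  s2_ind <- ifelse(df_ind > 0, (ms_ind - ms_wi) / 2, 0)
  s2_pop <- ifelse(df_pop > 0 & n1 > 0, (ms_pop - ms_ind) / n1, 0)
  s2_clu <- ifelse(df_clu > 0 & n3 > 0,
                   (ms_clu - ms_ind - n2 * s2_pop) / n3, 0)
  list(s2_w = sum(s2_w), s2_ind = sum(s2_ind),
       s2_pop = sum(s2_pop), s2_clu = sum(s2_clu),
       df_wi = df_wi, df_ind = df_ind,
       ss_ind_const = colSums(ifelse(N_p > 0, site_alt - ratio_p, 0)))
}

amova_f <- function(cm) {
  tot <- cm$s2_w + cm$s2_ind + cm$s2_pop + cm$s2_clu
  c(f_it = 1 - cm$s2_w / tot,
    f_is = cm$s2_ind / (cm$s2_ind + cm$s2_w),
    f_sc = cm$s2_pop / (tot - cm$s2_clu),
    f_ct = cm$s2_clu / tot)
}

#' Nested analysis of molecular variance
#'
#' Four-level hierarchical variance decomposition of allele dosages —
#' alleles within individuals, individuals within populations (sites),
#' populations within genetic clusters, and among clusters — with the
#' fixation indices `F_IT`, `F_IS`, `F_SC`, `F_CT` and stratified
#' permutation p-values: alleles re-paired among individuals within
#' populations (F_IS), individuals permuted among populations within
#' clusters (F_SC), and whole populations permuted among clusters (F_CT).
#'
#' @param table a `variant_table`.
#' @param hierarchy a [build_hierarchy()] object.
#' @param n_perm permutations per test (0 skips the tests).
#' @param seed integer seed.
#' @return An `amova_result` with `components` (per-stratum variance and
#'   percent of total) and `f` (index values with p-values).
#' @export
nested_amova <- function(table, hierarchy, n_perm = 999, seed = 1) {
  set.seed(seed)
  sites <- names(hierarchy$sites)
  gc <- group_counts(table, hierarchy$sites)
  cl_of_site <- vapply(sites, function(s) {
    hit <- vapply(hierarchy$clusters, function(ss) s %in% ss, logical(1))
    names(hierarchy$clusters)[hit][1]
  }, character(1))
  if (length(hierarchy$clusters) < 2)
    warning("single cluster: among-cluster component fixed at 0")
  if (all(lengths(hierarchy$clusters) < 2))
    warning("no cluster holds >1 population: among-population component degenerate")

  obs <- amova_from_sites(gc$n, gc$alt, gc$het, cl_of_site)
  f_obs <- amova_f(obs)

  p <- c(f_it = NA_real_, f_is = NA_real_, f_sc = NA_real_, f_ct = NA_real_)
  if (n_perm > 0) {
    # F_CT: permute whole populations among clusters
    b_ct <- vapply(seq_len(n_perm), function(b) {
      amova_f(amova_from_sites(gc$n, gc$alt, gc$het, sample(cl_of_site)))["f_ct"]
    }, numeric(1))
    p["f_ct"] <- (1 + sum(b_ct >= f_obs["f_ct"])) / (n_perm + 1)

    # F_SC: permute individuals among populations within clusters
    cl_of_sample <- hierarchy$cluster[table$samples]
    site_of_sample <- hierarchy$site[table$samples]
    tg <- t(table$geno)
    t_na <- !is.na(tg)
    t_g <- ifelse(t_na, tg, 0L)
    t_h <- t_na & tg == 1L
    b_sc <- vapply(seq_len(n_perm), function(b) {
      perm_site <- site_of_sample
      for (cl in unique(cl_of_sample)) {
        idx <- which(cl_of_sample == cl)
        perm_site[idx] <- perm_site[sample(idx)]
      }
      f <- factor(perm_site, levels = sites)
      amova_f(amova_from_sites(rowsum(t_na + 0L, f), rowsum(t_g, f),
                               rowsum(t_h + 0L, f), cl_of_site))["f_sc"]
    }, numeric(1))
    p["f_sc"] <- (1 + sum(b_sc >= f_obs["f_sc"])) / (n_perm + 1)

    # F_IS: re-pair alleles among individuals within populations; only the
    # heterozygote counts change, so draw them from the pairing distribution
    s2w_b <- s2i_b <- rep(0, n_perm)
    for (l in seq_len(n_loci(table))) {
      h_l <- rep(0L, n_perm)
      for (k in seq_len(nrow(gc$n))) {
        if (gc$n[k, l] > 0)
          h_l <- h_l + sample_het_pairing(gc$n[k, l], gc$alt[k, l], n_perm)
      }
      df_wi <- obs$df_wi[l]
      df_ind <- obs$df_ind[l]
      ms_wi <- if (df_wi > 0) (h_l / 2) / df_wi else 0
      # SS_ind = const - het/2, with const = sum_p (S_p - S_p^2/N_p)
      ms_ind <- if (df_ind > 0) (obs$ss_ind_const[l] - h_l / 2) / df_ind else 0
      s2w_b <- s2w_b + ms_wi
      if (df_ind > 0) s2i_b <- s2i_b + (ms_ind - ms_wi) / 2
    }
    f_is_b <- s2i_b / (s2i_b + s2w_b)
    p["f_is"] <- (1 + sum(f_is_b >= f_obs["f_is"])) / (n_perm + 1)
  }

  comps <- c(within_individual = obs$s2_w, among_individual = obs$s2_ind,
             among_population = obs$s2_pop, among_cluster = obs$s2_clu)
  out <- structure(list(
    components = data.frame(
      stratum = names(comps), sigma2 = unname(comps),
      percent = 100 * unname(comps) / sum(comps),
      stringsAsFactors = FALSE),
    f = data.frame(index = c("F_IT", "F_IS", "F_SC", "F_CT"),
                   value = unname(f_obs), p = unname(p),
                   stringsAsFactors = FALSE),
    n_perm = n_perm, seed = seed), class = "amova_result")
  out
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Nested AMOVA (allele dosages)\n")
  print(x$components, row.names = FALSE)
  cat("\nFixation indices:\n")
  print(x$f, row.names = FALSE)
  invisible(x)
}
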