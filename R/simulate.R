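#' Simulation parameters for hierarchical genotype datasets
#'
#' Defaults emulate the study design the package targets: 3 genetic
#' clusters holding 17 sampling sites (10/5/2 per cluster) of 5-8 diploids
#' each (89 individuals in total), 2,000 neutral biallelic loci on short
#' contigs, hierarchical differentiation near `F_CT = 0.17`, `F_SC = 0.05`
#' and within-population inbreeding `F_IS = 0.12`, negative-binomial read
#' depths (mean 40, dispersion 5, so a realistic few percent of calls fall
#' under a 10-read mask), 2% missing calls, and optional spiked locus
#' classes: high-differentiation outliers, forced-heterozygote paralog
#' artefacts, and exact within-contig LD copies.
#'
#' @param n_clusters number of genetic clusters.
#' @param sites_per_cluster integer vector, sites in each cluster.
#' @param n_per_site individuals per site (recycled across sites in order);
#'   the default reproduces the 89-sample design.
#' @param n_loci neutral loci.
#' @param f_ct,f_sc,f_is target fixation indices, each in `[0, 1)`.
#' @param missing_rate per-call missing probability.
#' @param depth_mean,depth_size negative-binomial depth parameters.
#' @param n_outlier spiked high-differentiation loci.
#' @param outlier_f_ct cluster-level differentiation of the spiked outliers.
#' @param n_paralog spiked paralog-like loci.
#' @param paralog_het_rate forced-heterozygote rate at paralog loci.
#' @param n_ld_copies exact duplicate loci placed next to their template on
#'   the same contig.
#' @param loci_per_contig SNPs per contig.
#' @param snp_spacing bp between consecutive SNPs on a contig.
#' @param spatial_coherent place sites around distinct cluster centres
#'   (TRUE) or uniformly across the region (FALSE).
#' @param seed integer seed (mandatory).
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_clusters = 3,
                       sites_per_cluster = c(10, 5, 2),
                       n_per_site = c(5, 5, 5, 5, 5, 5, 5, 5, 5, 6,
                                      5, 5, 8, 5, 5,
                                      5, 5),
                       n_loci = 2000,
                       f_ct = 0.17, f_sc = 0.05, f_is = 0.12,
                       missing_rate = 0.02,
                       depth_mean = 40, depth_size = 5,
                       n_outlier = 0, outlier_f_ct = 0.4,
                       n_paralog = 0, paralog_het_rate = 0.9,
                       n_ld_copies = 0,
                       loci_per_contig = 5, snp_spacing = 150,
                       spatial_coherent = TRUE,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(length(sites_per_cluster) == n_clusters,
            f_ct >= 0, f_ct < 1, f_sc >= 0, f_sc < 1, f_is >= 0, f_is < 1,
            n_loci > 0, all(n_per_site > 0))
  n_sites <- sum(sites_per_cluster)
  n_per_site <- rep_len(n_per_site, n_sites)
  structure(c(as.list(environment())), class = "sim_params")
}

# Balding-Nichols draw: child frequencies around p with dispersion F
bn_draw <- function(p, f) {
  if (f <= 0) return(p)
  theta <- (1 - f) / f
  stats::rbeta(length(p), p * theta, (1 - p) * theta)
}

#' Simulate a hierarchical genotype dataset with known truth
#'
#' Two-level Balding-Nichols hierarchy: ancestral frequencies
#' `p ~ U(0.1, 0.9)`, cluster frequencies Beta-distributed around `p` with
#' dispersion `f_ct`, site frequencies Beta around the cluster frequency
#' with dispersion `f_sc`. Genotypes are drawn with inbreeding `f_is`
#' (`P(het) = 2pq(1 - f_is)`). Spiked outlier loci redraw their cluster
#' frequencies at `outlier_f_ct`; paralog loci force heterozygotes at the
#' configured rate; LD-copy loci duplicate a template locus' genotypes on
#' the same contig. Depths are negative binomial and missingness uniform.
#'
#' @param params a [sim_params()] object.
#' @return list with `table` (a `variant_table`), `frame` (a
#'   `sample_frame` with `cluster_id`), and `truth` (a `truth_record`:
#'   per-locus class and the realized ancestral/cluster/site frequencies).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n_sites <- params$n_sites
  cluster_of_site <- rep(paste0("C", seq_len(params$n_clusters)),
                         params$sites_per_cluster)
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  n_ind <- sum(params$n_per_site)
  site_of_sample <- rep(site_ids, params$n_per_site)
  cluster_of_sample <- cluster_of_site[match(site_of_sample, site_ids)]
  sample_ids <- sprintf("I%03d", seq_len(n_ind))

  classes <- c(rep("neutral", params$n_loci),
               rep("outlier", params$n_outlier),
               rep("paralog", params$n_paralog))
  L0 <- length(classes)
  p_anc <- stats::runif(L0, 0.1, 0.9)
  f_clu <- ifelse(classes == "outlier", params$outlier_f_ct, params$f_ct)

  # cluster and site frequencies (loci x clusters / loci x sites)
  p_clu <- matrix(0, L0, params$n_clusters)
  for (k in seq_len(params$n_clusters)) {
    th <- (1 - f_clu) / pmax(f_clu, 1e-12)
    p_clu[, k] <- ifelse(f_clu > 0,
                         stats::rbeta(L0, p_anc * th, (1 - p_anc) * th),
                         p_anc)
  }
  p_site <- matrix(0, L0, n_sites)
  for (s in seq_len(n_sites)) {
    base <- p_clu[, match(cluster_of_site[s], paste0("C", seq_len(params$n_clusters)))]
    p_site[, s] <- bn_draw(base, params$f_sc)
  }
  p_site <- pmin(pmax(p_site, 0), 1)

  # genotypes with inbreeding
  geno <- matrix(NA_integer_, L0, n_ind)
  for (i in seq_len(n_ind)) {
    ps <- p_site[, match(site_of_sample[i], site_ids)]
    pq <- ps * (1 - ps)
    p_het <- 2 * pq * (1 - params$f_is)
    p_hom_alt <- ps^2 + pq * params$f_is
    u <- stats::runif(L0)
    geno[, i] <- ifelse(u < p_hom_alt, 2L, ifelse(u < p_hom_alt + p_het, 1L, 0L))
  }
  # paralog loci: collapse signature, forced heterozygotes
  par_idx <- which(classes == "paralog")
  for (l in par_idx) {
    forced <- stats::runif(n_ind) < params$paralog_het_rate
    geno[l, forced] <- 1L
  }

  # contig layout, LD copies appended right after their template
  n_copy <- params$n_ld_copies
  if (n_copy > 0) {
    templates <- sample(which(classes == "neutral"), n_copy)
    order_new <- integer(0)
    for (l in seq_len(L0)) {
      order_new <- c(order_new, l)
      if (l %in% templates) order_new <- c(order_new, -l)  # -l marks a copy
    }
    src <- abs(order_new)
    classes_full <- ifelse(order_new < 0, "ld_copy", classes[src])
    geno_full <- geno[src, , drop = FALSE]
    truth_src <- src
  } else {
    classes_full <- classes
    geno_full <- geno
    truth_src <- seq_len(L0)
  }
  L <- length(classes_full)

  # sequential contig fill; an LD copy never starts a new contig, so it
  # always shares a contig with its template
  contig_idx <- slot <- integer(L)
  ci <- 1L; s <- 0L
  for (l in seq_len(L)) {
    if (s >= params$loci_per_contig && classes_full[l] != "ld_copy") {
      ci <- ci + 1L; s <- 0L
    }
    s <- s + 1L
    contig_idx[l] <- ci; slot[l] <- s
  }
  contig <- sprintf("contig%05d", contig_idx)
  pos <- slot * params$snp_spacing
  loci <- data.frame(contig = contig, pos = pos, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)

  depth <- matrix(stats::rnbinom(L * n_ind, mu = params$depth_mean,
                                 size = params$depth_size), L, n_ind)
  geno_full[matrix(stats::runif(L * n_ind) < params$missing_rate, L, n_ind)] <- NA_integer_

  # coordinates: cluster centres spanning roughly 8 degrees of latitude
  centre_lat <- seq(-30.5, -35.8, length.out = params$n_clusters)
  centre_lon <- 137.0 + (seq_len(params$n_clusters) %% 3)
  if (params$spatial_coherent) {
    site_lat <- centre_lat[match(cluster_of_site, paste0("C", seq_len(params$n_clusters)))] +
      stats::rnorm(n_sites, 0, 0.5)
    site_lon <- centre_lon[match(cluster_of_site, paste0("C", seq_len(params$n_clusters)))] +
      stats::rnorm(n_sites, 0, 0.5)
  } else {
    site_lat <- stats::runif(n_sites, -36, -30)
    site_lon <- stats::runif(n_sites, 136.5, 140.5)
  }

  frame <- sample_frame(data.frame(
    sample_id = sample_ids, site_id = site_of_sample,
    longitude = site_lon[match(site_of_sample, site_ids)],
    latitude = site_lat[match(site_of_sample, site_ids)],
    cluster_id = cluster_of_sample, stringsAsFactors = FALSE))

  table <- variant_table(loci, geno_full, sample_ids, depth)
  # variant_table sorts by contig/pos; contigs are zero-padded so the
  # generated order is already canonical
  ids <- locus_ids(table)
  truth <- structure(list(
    loci = data.frame(locus = ids, class = classes_full,
                      p_ancestral = p_anc[truth_src],
                      stringsAsFactors = FALSE),
    p_cluster = p_clu[truth_src, , drop = FALSE],
    p_site = p_site[truth_src, , drop = FALSE],
    params = params), class = "truth_record")
  rownames(truth$p_cluster) <- rownames(truth$p_site) <- ids
  colnames(truth$p_cluster) <- paste0("C", seq_len(params$n_clusters))
  colnames(truth$p_site) <- site_ids
  list(table = table, frame = frame, truth = truth)
}

#' Closed-form fixation-index expectations of the simulation hierarchy
#'
#' The two Beta stages compose multiplicatively: the site-level total
#' differentiation is `1 - (1 - F_CT)(1 - F_SC)`, and with inbreeding the
#' total individual-level index is `1 - (1 - F_CT)(1 - F_SC)(1 - F_IS)`.
#'
#' @param params a [sim_params()] object.
#' @return list with `f_ct`, `f_sc`, `f_is`, `f_st_sites` (site-level
#'   total), `f_it`.
#' @export
expected_fst <- function(params) {
  single_cluster <- params$n_clusters < 2
  f_ct <- if (single_cluster) 0 else params$f_ct
  f_st_sites <- 1 - (1 - f_ct) * (1 - params$f_sc)
  list(f_ct = f_ct, f_sc = params$f_sc, f_is = params$f_is,
       f_st_sites = f_st_sites,
       f_it = 1 - (1 - f_st_sites) * (1 - params$f_is))
}
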