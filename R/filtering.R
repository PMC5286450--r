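#' Filter cascade configuration
#'
#' Thresholds for the ordered SNP curation cascade. Defaults follow the
#' curation protocol the package implements: genotype calls need at least 10
#' supporting reads, loci need a minor allele frequency above 10% and less
#' than 25% missing data, contigs need an average of at least 10 bp per SNP,
#' linked loci (r-squared > 0.5 within a contig) are pruned, retained SNPs
#' must be at least 100 bp apart, FST outliers are removed at a q-value FDR
#' of 0.05, and loci with significantly negative FIS (permutation test,
#' heterozygote excess — the paralog-collapse signature) are dropped.
#'
#' @param min_depth minimum reads per genotype call (calls below are masked).
#' @param min_maf minor allele frequency must be strictly greater than this.
#' @param max_missing per-SNP missing fraction must be strictly below this.
#' @param min_bp_per_snp minimum mean inter-SNP gap per contig (bp).
#' @param ld_r2_max maximum tolerated genotype r-squared within a contig.
#' @param min_spacing minimum bp between retained SNPs.
#' @param outlier_fdr q-value threshold for the FST-outlier removal stage.
#' @param fis_alpha significance level for the negative-FIS permutation screen.
#' @param run_outlier_scan,run_fis_filter logical toggles for the two
#'   model-based stages (useful when benchmarking the deterministic filters).
#' @param outlier_prior_odds,outlier_burn_in,outlier_n_iter,outlier_thin
#'   settings forwarded to [fit_outlier_model()].
#' @param fis_n_perm permutations for [fis_test()] inside the cascade.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 10, min_maf = 0.10, max_missing = 0.25,
                          min_bp_per_snp = 10, ld_r2_max = 0.5,
                          min_spacing = 100, outlier_fdr = 0.05,
                          fis_alpha = 0.05,
                          run_outlier_scan = TRUE, run_fis_filter = TRUE,
                          outlier_prior_odds = 10, outlier_burn_in = 2000,
                          outlier_n_iter = 8000, outlier_thin = 5,
                          fis_n_perm = 1000) {
  stopifnot(min_depth >= 0, min_maf >= 0, min_maf <= 1,
            max_missing >= 0, max_missing <= 1,
            min_spacing >= 0, outlier_fdr >= 0, outlier_fdr <= 1,
            fis_alpha >= 0, fis_alpha <= 1)
  structure(as.list(environment()), class = "filter_config")
}

new_filter_report <- function() {
  structure(list(stages = data.frame(stage = character(), n_in = integer(),
                                     n_removed = integer(), n_out = integer(),
                                     stringsAsFactors = FALSE),
                 removed = list()),
            class = "filter_report")
}

add_stage <- function(report, stage, n_in, removed_ids) {
  report$stages <- rbind(report$stages, data.frame(
    stage = stage, n_in = n_in, n_removed = length(removed_ids),
    n_out = n_in - length(removed_ids), stringsAsFactors = FALSE))
  report$removed[[stage]] <- removed_ids
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("SNP filter cascade:\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Mask genotype calls with insufficient read depth
#'
#' Sets genotypes to missing wherever the per-call depth is below
#' `min_depth`; a call with exactly `min_depth` reads is retained. No loci
#' are removed at this stage — downstream missingness filtering handles loci
#' left with too few calls.
#'
#' @param table a `variant_table` with depths.
#' @param min_depth minimum reads per call.
#' @return A `variant_table` with low-depth calls masked.
#' @export
mask_low_depth <- function(table, min_depth) {
  if (is.null(table$depth))
    stop("depth filtering requires per-genotype depths")
  mask <- !is.na(table$depth) & table$depth < min_depth
  table$geno[mask] <- NA_integer_
  table
}

#' Filter loci on minor allele frequency and missingness
#'
#' Removes loci whose minor allele frequency (computed over non-missing
#' genotypes) is not strictly above `min_maf`, or whose missing-call fraction
#' is not strictly below `max_missing`.
#'
#' @param table a `variant_table`.
#' @param min_maf MAF threshold (exclusive).
#' @param max_missing missing-fraction threshold (exclusive).
#' @return list with elements `table` (filtered) and `removed` (locus ids).
#' @export
filter_site_quality <- function(table, min_maf, max_missing) {
  g <- table$geno
  n_typed <- rowSums(!is.na(g))
  p <- ifelse(n_typed > 0, rowSums(g, na.rm = TRUE) / (2 * n_typed), NA_real_)
  maf <- pmin(p, 1 - p)
  miss_frac <- 1 - n_typed / n_samples(table)
  drop <- is.na(maf) | maf <= min_maf | miss_frac >= max_missing
  list(table = subset_loci(table, !drop), removed = locus_ids(table)[drop])
}

#' Remove contigs with excessive SNP density
#'
#' For each contig carrying two or more SNPs the density statistic is the
#' mean inter-SNP gap, `(max_pos - min_pos) / (n_snps - 1)`. Contigs whose
#' gap falls below `min_bp_per_snp` are removed wholesale (a mapping-error
#' signature); single-SNP contigs are always retained.
#'
#' @param table a `variant_table`.
#' @param min_bp_per_snp minimum mean gap in bp.
#' @return list with `table`, `removed` (locus ids) and `removed_contigs`.
#' @export
filter_contig_density <- function(table, min_bp_per_snp) {
  pos_by <- split(table$loci$pos, table$loci$contig)
  dens <- vapply(pos_by, function(p) {
    if (length(p) < 2) Inf else (max(p) - min(p)) / (length(p) - 1)
  }, numeric(1))
  bad_contigs <- names(dens)[dens < min_bp_per_snp]
  drop <- table$loci$contig %in% bad_contigs
  list(table = subset_loci(table, !drop),
       removed = locus_ids(table)[drop],
       removed_contigs = bad_contigs)
}

#' Prune loci in linkage disequilibrium
#'
#' Computes genotype-dosage r-squared for all within-contig pairs over
#' jointly non-missing samples, then makes a greedy pass in locus order: a
#' locus is removed when its r-squared with any earlier retained locus on the
#' same contig exceeds `r2_max`. Deterministic given input order. A pair
#' involving a zero-variance dosage vector carries no signal and is treated
#' as r-squared 0.
#'
#' @param table a `variant_table`.
#' @param r2_max maximum tolerated squared correlation (exclusive bound).
#' @return list with `table` and `removed` (locus ids).
#' @export
ld_prune <- function(table, r2_max) {
  keep <- rep(TRUE, n_loci(table))
  idx_by <- split(seq_len(n_loci(table)), table$loci$contig)
  for (idx in idx_by) {
    if (length(idx) < 2) next
    sub <- t(table$geno[idx, , drop = FALSE])
    r2 <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))^2
    r2[is.na(r2)] <- 0
    kept_local <- integer(0)
    for (j in seq_along(idx)) {
      if (length(kept_local) && any(r2[j, kept_local] > r2_max)) {
        keep[idx[j]] <- FALSE
      } else {
        kept_local <- c(kept_local, j)
      }
    }
  }
  list(table = subset_loci(table, keep), removed = locus_ids(table)[!keep])
}

#' Enforce a minimum spacing between retained SNPs
#'
#' Left-to-right sweep within each contig: a locus closer than `min_spacing`
#' bp to the last retained locus is removed; a gap of exactly `min_spacing`
#' satisfies the requirement. The first SNP of a too-close run is the one
#' kept (deterministic, order-stable).
#'
#' @param table a `variant_table`.
#' @param min_spacing minimum bp between consecutive retained SNPs.
#' @return list with `table` and `removed` (locus ids).
#' @export
spacing_filter <- function(table, min_spacing) {
  keep <- rep(TRUE, n_loci(table))
  idx_by <- split(seq_len(n_loci(table)), table$loci$contig)
  for (idx in idx_by) {
    pos <- table$loci$pos[idx]
    last <- -Inf
    for (j in seq_along(idx)) {
      if (pos[j] - last < min_spacing) {
        keep[idx[j]] <- FALSE
      } else {
        last <- pos[j]
      }
    }
  }
  list(table = subset_loci(table, keep), removed = locus_ids(table)[!keep])
}

#' Drop an explicit set of loci
#'
#' Used by the model-based stages (FST-outlier and negative-FIS removal) and
#' for replaying a recorded cascade.
#'
#' @param table a `variant_table`.
#' @param ids locus ids ("contig:pos") to remove; must all exist.
#' @param stage_name label recorded for the stage.
#' @return list with `table`, `removed` and `stage_name`.
#' @export
drop_loci <- function(table, ids, stage_name = "drop") {
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, locus_ids(table))
  if (length(unknown))
    stop("unknown locus id(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  keep <- !(locus_ids(table) %in% ids)
  list(table = subset_loci(table, keep), removed = ids, stage_name = stage_name)
}

#' Run the full SNP curation cascade
#'
#' Applies the stages in their canonical order: per-genotype depth masking,
#' MAF/missingness filtering, contig SNP-density control, LD pruning,
#' inter-SNP spacing, FST-outlier removal (Bayesian scan over sampling
#' sites), and the negative-FIS paralog screen. Returns the curated table
#' and a per-stage audit report whose counts chain consistently.
#'
#' @param table a `variant_table`.
#' @param frame a `sample_frame` covering the table's samples (defines the
#'   site grouping used by the two model-based stages).
#' @param config a [filter_config()].
#' @param seed integer seed driving the outlier-scan MCMC and the FIS
#'   permutations.
#' @return list with `table` (curated) and `report` (a `filter_report`).
#' @export
run_cascade <- function(table, frame, config = filter_config(), seed = 1) {
  frame <- check_samples(table, frame)
  report <- new_filter_report()
  cur <- table

  if (!is.null(cur$depth) && config$min_depth > 0) {
    cur <- mask_low_depth(cur, config$min_depth)
    report <- add_stage(report, "depth_mask", n_loci(cur), character(0))
  }

  st <- filter_site_quality(cur, config$min_maf, config$max_missing)
  report <- add_stage(report, "site_quality", n_loci(cur), st$removed)
  cur <- st$table

  st <- filter_contig_density(cur, config$min_bp_per_snp)
  report <- add_stage(report, "contig_density", n_loci(cur), st$removed)
  cur <- st$table

  st <- ld_prune(cur, config$ld_r2_max)
  report <- add_stage(report, "ld_prune", n_loci(cur), st$removed)
  cur <- st$table

  st <- spacing_filter(cur, config$min_spacing)
  report <- add_stage(report, "spacing", n_loci(cur), st$removed)
  cur <- st$table

  site_grouping <- split(frame$sample_id, frame$site_id)

  if (isTRUE(config$run_outlier_scan) && n_loci(cur) > 0) {
    af <- allele_frequencies(cur, site_grouping)
    scan <- fit_outlier_model(af, prior_odds = config$outlier_prior_odds,
                              n_iter = config$outlier_n_iter,
                              burn_in = config$outlier_burn_in,
                              thin = config$outlier_thin,
                              fdr = config$outlier_fdr, seed = seed)
    flagged <- scan$loci$locus[which(scan$loci$outlier)]
    st <- drop_loci(cur, flagged, "outlier_scan")
    report <- add_stage(report, "outlier_scan", n_loci(cur), st$removed)
    cur <- st$table
  }

  if (isTRUE(config$run_fis_filter) && n_loci(cur) > 0) {
    ft <- fis_test(cur, site_grouping, n_perm = config$fis_n_perm,
                   alpha = config$fis_alpha, seed = seed + 1L)
    flagged <- ft$locus[which(ft$flag_negative)]
    st <- drop_loci(cur, flagged, "negative_fis")
    report <- add_stage(report, "negative_fis", n_loci(cur), st$removed)
    cur <- st$table
  }

  list(table = cur, report = report)
}
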