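#' Pipeline configuration
#'
#' Bundles the inputs and per-stage parameters for [run_pipeline()]. Either
#' `vcf`/`metadata` paths or a [sim_params()] object must be given. All
#' seeds are explicit and echoed into the report, so a rerun with the same
#' configuration reproduces the report exactly.
#'
#' @param vcf,metadata input file paths (ignored when `sim` is given).
#' @param sim optional [sim_params()]: simulate the input instead of reading
#'   it.
#' @param filter a [filter_config()].
#' @param k_range candidate K values for the cluster scan.
#' @param n_pcs principal components retained by DAPC.
#' @param run_admixture run the admixture sampler K scan (slow stage;
#'   default FALSE — DAPC alone fixes the cluster assignment).
#' @param admixture list of sampler settings (`burn_in`, `n_iter`,
#'   `n_reps`).
#' @param n_perm permutations for AMOVA and RDA tests.
#' @param rda_degree spatial polynomial degree.
#' @param seed master seed; stage seeds are derived as small fixed offsets.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf = NULL, metadata = NULL, sim = NULL,
                            filter = filter_config(), k_range = 1:6,
                            n_pcs = 40, run_admixture = FALSE,
                            admixture = list(burn_in = 200, n_iter = 600,
                                             n_reps = 3),
                            n_perm = 199, rda_degree = 3, seed = 1) {
  if (is.null(sim) && (is.null(vcf) || is.null(metadata)))
    stop("give either vcf + metadata paths or a sim_params object")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — load or simulate the input, run the SNP
#' curation cascade, heterozygosity summaries, DAPC cluster inference (the
#' inferred or provided clusters define the hierarchy), optionally the
#' admixture sampler with delta-K, nested AMOVA, pairwise and overall FST,
#' and the spatial RDA with forward selection — and assembles a plain-list
#' report (JSON-serializable) with every stage's parameters and seed echoed.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list with elements `input`, `filter`,
#'   `diversity`, `clustering`, `amova`, `fst`, `rda`, and `config_echo`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (!is.null(config$sim)) {
    sim <- simulate_dataset(config$sim)
    table <- sim$table
    frame <- sim$frame
    truth_classes <- table(sim$truth$loci$class)
  } else {
    table <- read_vcf(config$vcf)
    frame <- read_metadata(config$metadata)
    truth_classes <- NULL
  }
  frame <- check_samples(table, frame)

  casc <- run_cascade(table, frame, config$filter, seed = seed)
  cur <- casc$table

  site_grouping <- split(frame$sample_id, frame$site_id)
  div <- heterozygosities(cur, site_grouping)

  scan <- dapc_find_clusters(cur, config$k_range, config$n_pcs,
                             seed = seed + 10L)
  k_best <- max(scan$best_k, 2L)
  dapc <- dapc_fit(cur, k_best, config$n_pcs, seed = seed + 11L)

  admix <- NULL
  if (isTRUE(config$run_admixture)) {
    ll <- t(vapply(config$k_range, function(k) {
      admixture_fit(cur, k, burn_in = config$admixture$burn_in,
                    n_iter = config$admixture$n_iter,
                    n_reps = config$admixture$n_reps,
                    seed = seed + 20L + k)$loglik
    }, numeric(config$admixture$n_reps)))
    rownames(ll) <- config$k_range
    dk <- tryCatch(evanno_delta_k(ll), error = function(e) NULL)
    admix <- list(loglik = ll, delta_k = dk)
  }

  if (is.null(frame$cluster_id)) {
    frame$cluster_id <- paste0("C", as.integer(dapc$assignment))
  }
  hier <- build_hierarchy(frame)
  amova <- nested_amova(cur, hier, n_perm = config$n_perm, seed = seed + 30L)
  cluster_grouping <- split(frame$sample_id, frame$cluster_id)
  fst_pair <- pairwise_fst(cur, cluster_grouping)
  fst_overall <- global_fst(cur, site_grouping)

  site_coords <- unique(frame[c("site_id", "longitude", "latitude")])
  site_coords <- site_coords[match(names(site_grouping), site_coords$site_id), ]
  af <- allele_frequencies(cur, site_grouping)
  terms <- spatial_polynomials(site_coords[c("longitude", "latitude")],
                               config$rda_degree)
  sel <- forward_select(af, terms, n_perm = config$n_perm, seed = seed + 40L)
  rda <- if (length(sel)) {
    rda_fit(af, attr(sel, "terms"), n_perm = config$n_perm, seed = seed + 41L)
  } else NULL

  report <- list(
    input = list(n_loci = n_loci(table), n_samples = n_samples(table),
                 n_sites = length(site_grouping),
                 truth_classes = as.list(truth_classes)),
    filter = list(stages = casc$report$stages,
                  n_final = n_loci(cur)),
    diversity = div,
    clustering = list(bic = scan$bic, best_k = scan$best_k,
                      cluster_sizes = as.list(table(dapc$assignment)),
                      var_explained = dapc$var_explained,
                      admixture = if (!is.null(admix))
                        list(delta_k = admix$delta_k) else NULL),
    amova = list(components = amova$components, f = amova$f),
    fst = list(pairwise = as.data.frame(unclass(fst_pair)),
               overall = fst_overall),
    rda = if (!is.null(rda)) list(
      selected_terms = as.character(sel),
      prop_constrained = rda$prop_constrained,
      pseudo_f = rda$pseudo_f, p_value = rda$p_value,
      explained_fst = explained_fst(rda$prop_constrained,
                                    max(min(fst_overall, 1), 0))
    ) else list(selected_terms = character(0)),
    config_echo = list(seed = seed, n_perm = config$n_perm,
                       k_range = config$k_range, n_pcs = config$n_pcs,
                       rda_degree = config$rda_degree,
                       filter = unclass(config$filter))
  )
  class(report) <- "pipeline_report"
  report
}

#' Serialize a pipeline report to JSON
#'
#' @param report a `pipeline_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
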