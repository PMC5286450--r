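#' @title Genetic-cluster inference
#' @description Discriminant analysis of principal components (PCA, k-means
#'   cluster scan scored by BIC, then linear discriminant analysis) and an
#'   admixture-model Gibbs sampler with Evanno delta-K model choice and
#'   CLUMPP-style replicate alignment.
#' @name clustering
NULL

# samples x PCs score matrix: dosages mean-imputed, centered, then PCA
pca_scores <- function(table, n_pcs) {
  X <- t(table$geno)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  n_pcs <- min(n_pcs, nrow(X) - 1, ncol(X))
  pr <- stats::prcomp(X, center = FALSE)
  pr$x[, seq_len(min(n_pcs, ncol(pr$x))), drop = FALSE]
}

#' Scan the number of genetic clusters with k-means and BIC
#'
#' Genotypes are mean-imputed and centered, reduced by PCA, and k-means
#' (multiple restarts) is run on the retained principal components for each
#' candidate K. The score is `BIC(K) = n ln(W_K / n) + K ln(n)` with `W_K`
#' the total within-cluster sum of squares (floored to keep the degenerate
#' one-sample-per-cluster case finite). The K with the lowest BIC is the
#' supported number of clusters.
#'
#' @param table a `variant_table`.
#' @param k_range candidate cluster counts (K > n samples are skipped with a
#'   warning).
#' @param n_pcs principal components retained (capped at n samples - 1).
#' @param seed integer seed shared by the k-means restarts.
#' @param n_start k-means restarts per K.
#' @return A `cluster_scan`: list with `bic` (data.frame `k`, `bic`, `W`),
#'   `best_k`, the per-K assignments, and the PC `scores`.
#' @export
dapc_find_clusters <- function(table, k_range = 1:10, n_pcs = 40, seed = 1,
                               n_start = 20) {
  set.seed(seed)
  scores <- pca_scores(table, n_pcs)
  n <- nrow(scores)
  if (any(k_range > n)) {
    warning("skipping K greater than the number of samples")
    k_range <- k_range[k_range <= n]
  }
  tot_ss <- sum(sweep(scores, 2, colMeans(scores))^2)
  assignments <- list()
  bic <- vapply(k_range, function(k) {
    if (k == 1) {
      W <- tot_ss
      assignments[[as.character(k)]] <<- rep(1L, n)
    } else if (k == n) {
      # one sample per cluster: stats::kmeans refuses centers == nrow(x)
      W <- 0
      assignments[[as.character(k)]] <<- seq_len(n)
    } else {
      km <- stats::kmeans(scores, centers = k, nstart = n_start,
                          iter.max = 50)
      W <- km$tot.withinss
      assignments[[as.character(k)]] <<- km$cluster
    }
    W <- max(W, .Machine$double.eps)
    n * log(W / n) + k * log(n)
  }, numeric(1))
  structure(list(
    bic = data.frame(k = k_range, bic = bic),
    best_k = k_range[which.min(bic)],
    assignments = assignments, scores = scores, n_pcs = ncol(scores),
    seed = seed), class = "cluster_scan")
}

#' Fit a DAPC model
#'
#' Linear discriminant analysis of cluster labels (from k-means on the
#' retained principal components, or supplied) in PC space, yielding at most
#' K-1 discriminant functions, per-sample membership probabilities from the
#' discriminant-space Gaussian model, and the percent of discriminable
#' variance carried by each function. When the within-class scatter is
#' (near-)singular, trailing PCs are dropped until the discriminant solve
#' succeeds, with a message.
#'
#' @param table a `variant_table`.
#' @param k number of clusters (>= 2).
#' @param n_pcs principal components retained.
#' @param seed integer seed for the k-means step.
#' @param groups optional per-sample cluster labels; when given, the k-means
#'   step is skipped.
#' @return A `dapc_result`: list with `assignment` (factor), `membership`
#'   (samples x K probabilities), `var_explained` (per discriminant
#'   function), `scores` (discriminant coordinates), `n_pcs` used.
#' @export
dapc_fit <- function(table, k, n_pcs = 40, seed = 1, groups = NULL) {
  stopifnot(k >= 2)
  set.seed(seed)
  scores <- pca_scores(table, n_pcs)
  if (is.null(groups)) {
    groups <- stats::kmeans(scores, centers = k, nstart = 20,
                            iter.max = 50)$cluster
  }
  groups <- factor(groups)
  fit <- NULL
  use <- ncol(scores)
  while (is.null(fit) && use >= 1) {
    fit <- tryCatch(
      suppressWarnings(MASS::lda(scores[, seq_len(use), drop = FALSE],
                                 grouping = groups)),
      error = function(e) NULL)
    if (is.null(fit)) use <- use - 1
  }
  if (is.null(fit)) stop("discriminant analysis failed on all PC subsets")
  if (use < ncol(scores))
    message(sprintf("dapc_fit: retained %d of %d PCs to keep the within-class scatter non-singular",
                    use, ncol(scores)))
  pred <- stats::predict(fit, scores[, seq_len(use), drop = FALSE])
  structure(list(
    assignment = pred$class,
    membership = pred$posterior,
    var_explained = 100 * fit$svd^2 / sum(fit$svd^2),
    scores = pred$x, n_pcs = use, groups = groups,
    seed = seed), class = "dapc_result")
}

# greedy label permutation aligning Q against a reference (CLUMPP-style):
# repeatedly match the most correlated (reference, replicate) column pair
align_q <- function(q, q_ref) {
  K <- ncol(q)
  if (K == 1) return(q)
  cm <- suppressWarnings(stats::cor(q_ref, q))
  cm[is.na(cm)] <- 0
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(cm), dim(cm))
    perm[idx[1]] <- idx[2]
    cm[idx[1], ] <- -Inf
    cm[, idx[2]] <- -Inf
  }
  q[, perm, drop = FALSE]
}

#' Admixture-model Gibbs sampler
#'
#' Bayesian clustering in which each individual's genome is a mixture over K
#' cluster-specific allele-frequency profiles. A Gibbs sampler alternates
#' over allele origins Z (categorical given Q and P), cluster allele
#' frequencies P (Beta posterior updates), and admixture proportions Q
#' (Dirichlet(alpha + origin counts), with a fixed uniform alpha). The mean
#' data log-likelihood over post-burn-in sweeps is recorded per replicate
#' (the quantity Evanno's delta-K consumes) and replicate Q matrices are
#' aligned by greedy label permutation before averaging.
#'
#' @param table a `variant_table`.
#' @param k number of clusters (k = 1 is allowed: Q is degenerate but the
#'   likelihood is still computed, as the delta-K scan needs it).
#' @param burn_in,n_iter burn-in and retained sweeps per replicate.
#' @param n_reps independent replicates.
#' @param seed integer seed (replicate r uses `seed + r`).
#' @param alpha symmetric Dirichlet hyperparameter for Q.
#' @return An `admixture_result`: list with `loglik` (replicate means),
#'   `q_reps` (aligned per-replicate mean Q), `q` (consensus Q), `k`.
#' @export
admixture_fit <- function(table, k, burn_in = 2000, n_iter = 10000,
                          n_reps = 3, seed = 1, alpha = 1) {
  stopifnot(k >= 1)
  G <- t(table$geno)            # samples x loci dosages
  G[is.na(G)] <- NA
  n <- nrow(G)
  L <- ncol(G)
  obs <- !is.na(G)
  g0 <- ifelse(obs, G, 0)

  g_int <- G
  storage.mode(g_int) <- "integer"

  run_chain <- function(rep_seed) {
    set.seed(rep_seed)
    if (k == 1) {
      # no admixture: conjugate Beta draws for the single frequency vector
      alt_tot <- colSums(g0)
      n_tot <- 2 * colSums(obs)
      ll <- numeric(n_iter)
      for (s in seq_len(n_iter)) {
        pvec <- stats::rbeta(L, 1 + alt_tot, 1 + n_tot - alt_tot)
        pvec <- pmin(pmax(pvec, 1e-9), 1 - 1e-9)
        f <- matrix(pvec, n, L, byrow = TRUE)
        ll[s] <- sum((g0 * log(f) + (2 - G) * log(1 - f) +
                        log(ifelse(G == 1L, 2, 1)))[obs])
      }
      return(list(loglik = mean(ll), q = matrix(1, n, 1)))
    }
    admixture_chain_cpp(g_int, k, burn_in, n_iter, alpha)
  }

  chains <- lapply(seq_len(n_reps), function(r) run_chain(seed + r))
  q_reps <- lapply(chains, `[[`, "q")
  ref <- q_reps[[1]]
  q_reps <- lapply(q_reps, align_q, q_ref = ref)
  q_cons <- Reduce(`+`, q_reps) / n_reps
  rownames(q_cons) <- table$samples
  structure(list(
    loglik = vapply(chains, `[[`, numeric(1), "loglik"),
    q_reps = q_reps, q = q_cons, k = k,
    settings = list(burn_in = burn_in, n_iter = n_iter, n_reps = n_reps,
                    seed = seed, alpha = alpha)),
    class = "admixture_result")
}

#' Evanno delta-K statistic
#'
#' The second difference of the replicate-mean data log-likelihood across K,
#' normalized by the replicate standard deviation:
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`.
#' Defined only for interior K of a consecutive scan; identical replicates
#' (zero sd) make it undefined and raise an error.
#'
#' @param loglik matrix of replicate mean log-likelihoods, one row per K
#'   (rownames or the `k` argument give the K values), columns = replicates.
#' @param k integer vector of K values, defaults to `rownames(loglik)`.
#' @return data.frame with `k` and `delta_k` for the interior K values.
#' @export
evanno_delta_k <- function(loglik, k = NULL) {
  loglik <- as.matrix(loglik)
  if (is.null(k)) k <- as.integer(rownames(loglik))
  stopifnot(length(k) == nrow(loglik), !anyNA(k))
  ord <- order(k)
  k <- k[ord]
  loglik <- loglik[ord, , drop = FALSE]
  if (nrow(loglik) < 3) stop("delta-K needs at least three consecutive K values")
  if (ncol(loglik) < 2) stop("delta-K needs at least two replicates per K")
  if (any(diff(k) != 1)) stop("K values must be consecutive")
  m <- rowMeans(loglik)
  s <- apply(loglik, 1, stats::sd)
  interior <- seq(2, length(k) - 1)
  if (any(s[interior] == 0))
    stop("replicates identical at some K: delta-K undefined (zero sd)")
  dk <- abs(m[interior + 1] - 2 * m[interior] + m[interior - 1]) / s[interior]
  data.frame(k = k[interior], delta_k = unname(dk))
}
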