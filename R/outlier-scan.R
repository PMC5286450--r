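#' Bayesian FST-outlier scan
#'
#' Island-model selection scan on per-population allele counts. Population
#' allele frequencies are Balding-Nichols distributed around an ancestral
#' frequency `p_i` with locus-by-population differentiation
#' `logit(F_ij) = alpha_i + beta_j`: `beta_j` is a population effect shared
#' by all loci and `alpha_i` a locus-specific (selection) effect whose
#' inclusion is toggled by reversible-jump MCMC with prior inclusion odds
#' `1:prior_odds`. Marginalizing the frequency gives a beta-binomial
#' likelihood for the observed alt-allele counts. Loci with high posterior
#' inclusion probability of `alpha_i` are differentiation outliers; q-values
#' convert posteriors to a false-discovery-rate scale.
#'
#' Priors: `p_i ~ U(0,1)`, `alpha_i ~ N(0,1)` when included,
#' `beta_j ~ N(-1,1)`. Proposal widths are tuned during burn-in by short
#' pilot blocks targeting a 25-45% acceptance rate.
#'
#' @param counts an [allele_frequencies()] result (integer allele counts per
#'   population), or a list with matrices `alt` and `total` (loci x pops).
#' @param prior_odds prior odds for neutrality (10 = one locus in eleven
#'   carries a selection effect a priori).
#' @param n_iter post-burn-in sweeps.
#' @param burn_in burn-in sweeps.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param fdr q-value threshold for the outlier flag.
#' @param seed integer seed.
#' @return An `outlier_result`: list with `loci` (data.frame: `locus`,
#'   `posterior_prob`, `alpha`, `qvalue`, `outlier`), `beta` and `pop_fst`
#'   (per-population posterior means), and the settings used. Loci
#'   monomorphic across all populations are excluded from the fit (warning)
#'   and reported with `NA` statistics.
#' @export
fit_outlier_model <- function(counts, prior_odds = 10, n_iter = 8000,
                              burn_in = 2000, thin = 5, fdr = 0.05,
                              seed = 1) {
  set.seed(seed)
  if (inherits(counts, "allele_freq_table")) {
    A_all <- t(round(counts$freq * counts$count))
    N_all <- t(counts$count)
    A_all[is.na(A_all)] <- 0
  } else {
    A_all <- as.matrix(counts$alt)
    N_all <- as.matrix(counts$total)
  }
  if (max(abs(A_all - round(A_all)), na.rm = TRUE) > 1e-8)
    stop("allele counts must be integers")
  if (ncol(N_all) < 2) stop("need at least two populations")
  loci_names <- rownames(A_all)
  if (is.null(loci_names)) loci_names <- as.character(seq_len(nrow(A_all)))

  tot_alt <- rowSums(A_all)
  tot_n <- rowSums(N_all)
  mono <- tot_alt == 0 | tot_alt == tot_n
  if (any(mono))
    warning(sprintf("%d locus/loci monomorphic across populations excluded from the scan",
                    sum(mono)))
  A <- A_all[!mono, , drop = FALSE]
  N <- N_all[!mono, , drop = FALSE]
  L <- nrow(A)
  J <- ncol(A)
  if (L == 0) stop("no polymorphic loci to scan")
  lconst <- lchoose(N, A)  # constant in all ratios; added for reported loglik

  # beta-binomial log-likelihood split so that terms depending only on the
  # dispersion theta (i.e. on alpha, beta) are cached across p updates
  make_theta <- function(aeff, beta) {
    eta <- matrix(aeff, L, J) + matrix(beta, L, J, byrow = TRUE)
    Fm <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-6)
    theta <- (1 - Fm) / Fm
    list(theta = theta, lgt = lgamma(theta), lgNt = lgamma(N + theta))
  }
  ll_from_theta <- function(p, th) {
    u <- p * th$theta
    v <- th$theta - u
    lgamma(A + u) + lgamma(N - A + v) - th$lgNt - lgamma(u) - lgamma(v) + th$lgt
  }

  # initial state
  p <- (tot_alt[!mono] + 1) / (tot_n[!mono] + 2)
  alpha <- rep(0, L)
  delta <- rep(FALSE, L)
  beta <- rep(-1, J)
  th <- make_theta(alpha * delta, beta)
  cur <- ll_from_theta(p, th)
  cur_row <- rowSums(cur)
  log_pi_ratio <- -log(prior_odds)   # log P(delta=1)/P(delta=0)

  sd_p <- 0.5; sd_a <- 0.5; sd_b <- 0.3
  acc_p <- acc_a <- acc_b <- n_p <- n_a <- n_b <- 0

  total_sweeps <- burn_in + n_iter
  sum_delta <- sum_alpha <- rep(0, L)
  sum_beta <- sum_fst <- rep(0, J)
  n_keep <- 0

  for (s in seq_len(total_sweeps)) {
    # ancestral frequencies, logit random walk (uniform prior + Jacobian)
    lp <- stats::qlogis(p)
    p_new <- stats::plogis(lp + stats::rnorm(L, 0, sd_p))
    prop <- ll_from_theta(p_new, th)
    prop_row <- rowSums(prop)
    lr <- prop_row - cur_row +
      log(p_new * (1 - p_new)) - log(p * (1 - p))
    acc <- log(stats::runif(L)) < lr
    p[acc] <- p_new[acc]
    cur[acc, ] <- prop[acc, , drop = FALSE]
    cur_row[acc] <- prop_row[acc]
    acc_p <- acc_p + sum(acc); n_p <- n_p + L

    # locus effects for included loci
    inc <- which(delta)
    if (length(inc)) {
      a_new <- alpha
      a_new[inc] <- alpha[inc] + stats::rnorm(length(inc), 0, sd_a)
      th_new <- make_theta(a_new * delta, beta)
      prop <- ll_from_theta(p, th_new)
      prop_row <- rowSums(prop)
      lr <- prop_row - cur_row +
        stats::dnorm(a_new, 0, 1, log = TRUE) -
        stats::dnorm(alpha, 0, 1, log = TRUE)
      acc <- rep(FALSE, L)
      acc[inc] <- log(stats::runif(length(inc))) < lr[inc]
      if (any(acc)) {
        alpha[acc] <- a_new[acc]
        cur[acc, ] <- prop[acc, , drop = FALSE]
        cur_row[acc] <- prop_row[acc]
        th$theta[acc, ] <- th_new$theta[acc, , drop = FALSE]
        th$lgt[acc, ] <- th_new$lgt[acc, , drop = FALSE]
        th$lgNt[acc, ] <- th_new$lgNt[acc, , drop = FALSE]
      }
      acc_a <- acc_a + sum(acc); n_a <- n_a + length(inc)
    }

    # reversible jump: toggle inclusion, proposing alpha from its prior
    a_star <- stats::rnorm(L, 0, 1)
    delta_new <- !delta
    a_eff_new <- ifelse(delta_new, a_star, 0)
    th_new <- make_theta(a_eff_new, beta)
    prop <- ll_from_theta(p, th_new)
    prop_row <- rowSums(prop)
    lr <- prop_row - cur_row + ifelse(delta_new, log_pi_ratio, -log_pi_ratio)
    acc <- log(stats::runif(L)) < lr
    if (any(acc)) {
      born <- acc & delta_new
      alpha[born] <- a_star[born]
      alpha[acc & !delta_new] <- 0
      delta[acc] <- delta_new[acc]
      cur[acc, ] <- prop[acc, , drop = FALSE]
      cur_row[acc] <- prop_row[acc]
      th$theta[acc, ] <- th_new$theta[acc, , drop = FALSE]
      th$lgt[acc, ] <- th_new$lgt[acc, , drop = FALSE]
      th$lgNt[acc, ] <- th_new$lgNt[acc, , drop = FALSE]
    }

    # population effects, one at a time (single-column evaluation)
    aeff <- alpha * delta
    for (j in seq_len(J)) {
      bj_new <- beta[j] + stats::rnorm(1, 0, sd_b)
      eta <- aeff + bj_new
      Fm <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-6)
      tcol <- (1 - Fm) / Fm
      u <- p * tcol
      v <- tcol - u
      prop_col <- lgamma(A[, j] + u) + lgamma(N[, j] - A[, j] + v) -
        lgamma(N[, j] + tcol) - lgamma(u) - lgamma(v) + lgamma(tcol)
      lr <- sum(prop_col - cur[, j]) +
        stats::dnorm(bj_new, -1, 1, log = TRUE) -
        stats::dnorm(beta[j], -1, 1, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        beta[j] <- bj_new
        cur_row <- cur_row + prop_col - cur[, j]
        cur[, j] <- prop_col
        th$theta[, j] <- tcol
        th$lgt[, j] <- lgamma(tcol)
        th$lgNt[, j] <- lgamma(N[, j] + tcol)
        acc_b <- acc_b + 1
      }
      n_b <- n_b + 1
    }

    # pilot adaptation during burn-in
    if (s <= burn_in && s %% 100 == 0) {
      tune <- function(sd, acc, n) {
        if (n == 0) return(sd)
        rate <- acc / n
        if (rate < 0.25) sd / 1.3 else if (rate > 0.45) sd * 1.3 else sd
      }
      sd_p <- tune(sd_p, acc_p, n_p)
      sd_a <- tune(sd_a, acc_a, n_a)
      sd_b <- tune(sd_b, acc_b, n_b)
      acc_p <- acc_a <- acc_b <- n_p <- n_a <- n_b <- 0
    }

    if (s > burn_in && (s - burn_in) %% thin == 0) {
      n_keep <- n_keep + 1
      sum_delta <- sum_delta + delta
      sum_alpha <- sum_alpha + alpha * delta
      sum_beta <- sum_beta + beta
      sum_fst <- sum_fst + stats::plogis(beta)
    }
  }

  post <- sum_delta / n_keep
  q_fit <- qvalues(post)
  res <- data.frame(
    locus = loci_names,
    posterior_prob = NA_real_, alpha = NA_real_, qvalue = NA_real_,
    outlier = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  res$posterior_prob[!mono] <- post
  res$alpha[!mono] <- sum_alpha / n_keep
  res$qvalue[!mono] <- q_fit
  res$outlier[!mono] <- !is.na(q_fit) & q_fit <= fdr
  structure(list(
    loci = res,
    beta = sum_beta / n_keep,
    pop_fst = sum_fst / n_keep,
    settings = list(prior_odds = prior_odds, n_iter = n_iter,
                    burn_in = burn_in, thin = thin, fdr = fdr, seed = seed),
    n_excluded = sum(mono)), class = "outlier_result")
}

#' q-values from posterior inclusion probabilities
#'
#' Ranking loci by descending posterior probability, the q-value of the
#' locus at rank k is the minimum over j >= k of the mean posterior error
#' `1 - posterior` among the top-j loci — the minimum FDR at which the locus
#' would be declared an outlier.
#'
#' @param posterior_probs per-locus posterior inclusion probabilities.
#' @return q-values aligned with the input.
#' @export
qvalues <- function(posterior_probs) {
  stopifnot(all(posterior_probs >= 0 & posterior_probs <= 1, na.rm = TRUE))
  n <- length(posterior_probs)
  out <- rep(NA_real_, n)
  ok <- which(!is.na(posterior_probs))
  if (!length(ok)) return(out)
  ord <- ok[order(posterior_probs[ok], decreasing = TRUE)]
  cm <- cumsum(1 - posterior_probs[ord]) / seq_along(ord)
  out[ord] <- rev(cummin(rev(cm)))
  out
}

#' @export
print.outlier_result <- function(x, ...) {
  cat(sprintf("outlier_result: %d loci scanned, %d flagged at q <= %.3g (%d excluded)\n",
              nrow(x$loci), sum(x$loci$outlier), x$settings$fdr, x$n_excluded))
  invisible(x)
}
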