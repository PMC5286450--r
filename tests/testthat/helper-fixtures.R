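# Small fixture builders and brute-force oracles shared across the suite.

make_table <- function(geno, contig = NULL, pos = NULL, samples = NULL,
                       depth = NULL) {
  geno <- as.matrix(geno)
  L <- nrow(geno)
  if (is.null(contig)) contig <- rep("c1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(geno)))
  variant_table(
    data.frame(contig = contig, pos = pos, ref = "A", alt = "T",
               stringsAsFactors = FALSE),
    geno, samples, depth)
}

random_table <- function(L, n, seed, miss = 0.1, contigs = 4, depth = FALSE) {
  set.seed(seed)
  geno <- matrix(sample(0:2, L * n, replace = TRUE), L, n)
  if (miss > 0) geno[matrix(stats::runif(L * n) < miss, L, n)] <- NA_integer_
  contig <- sprintf("c%02d", sort(rep_len(seq_len(contigs), L)))
  pos <- unlist(lapply(split(seq_len(L), contig),
                       function(i) seq_along(i) * 137L), use.names = FALSE)
  dp <- if (depth) matrix(stats::rpois(L * n, 30), L, n) else NULL
  make_table(geno, contig = contig, pos = pos, depth = dp)
}

# Weir & Cockerham (1984) single-locus theta written out independently from
# the printed component formulas: the brute-force oracle.
wc_theta_brute <- function(n_vec, p_vec, h_vec) {
  r <- length(n_vec)
  nbar <- mean(n_vec)
  nc <- (sum(n_vec) - sum(n_vec^2) / sum(n_vec)) / (r - 1)
  pbar <- sum(n_vec * p_vec) / sum(n_vec)
  s2 <- sum(n_vec * (p_vec - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_vec * h_vec) / sum(n_vec)
  inner <- pbar * (1 - pbar) - (r - 1) / r * s2
  a <- nbar / nc * (s2 - (inner - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# brute-force null heterozygote-count draws: shuffle the allele pool of one
# group and re-pair consecutive alleles into diploids
brute_het_draws <- function(n_ind, a_alt, B) {
  vapply(seq_len(B), function(b) {
    al <- sample(c(rep(1L, a_alt), rep(0L, 2L * n_ind - a_alt)))
    sum(al[seq(1L, 2L * n_ind, 2L)] != al[seq(2L, 2L * n_ind, 2L)])
  }, integer(1))
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# assignment accuracy maximized over cluster-label permutations
best_accuracy <- function(assign, truth) {
  truth <- as.integer(factor(truth))
  assign <- as.integer(factor(assign, levels = sort(unique(assign))))
  k <- max(truth, assign)
  max(vapply(all_perms(seq_len(k)),
             function(p) mean(p[assign] == truth), numeric(1)))
}

# beta-binomial allele counts at a common ancestral frequency per locus,
# with per-locus FST; the direct input format of fit_outlier_model
sim_outlier_counts <- function(L_neutral, L_spiked, n_pops, n_dip,
                               fst_neutral, fst_spiked, seed) {
  set.seed(seed)
  L <- L_neutral + L_spiked
  p <- stats::runif(L, 0.15, 0.85)
  f <- rep(c(fst_neutral, fst_spiked), c(L_neutral, L_spiked))
  th <- (1 - f) / f
  pj <- matrix(stats::rbeta(L * n_pops, p * th, (1 - p) * th), L, n_pops)
  A <- matrix(stats::rbinom(L * n_pops, 2L * n_dip, pj), L, n_pops)
  list(alt = A, total = matrix(2L * n_dip, L, n_pops),
       spiked = rep(c(FALSE, TRUE), c(L_neutral, L_spiked)))
}
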