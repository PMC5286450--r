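#' Orthogonal spatial polynomial terms
#'
#' Builds monomials of the (longitude, latitude) coordinates up to the given
#' total degree, in fixed order (x, y, x2, xy, y2, x3, x2y, xy2, y3 at
#' degree 3), then orthogonalizes them sequentially against the constant and
#' all prior terms (Gram-Schmidt via QR) and scales each surviving column to
#' unit norm. Terms that fall inside the span of earlier ones (up to the
#' rank, n - 1) are dropped with a warning. When one coordinate is constant
#' the basis reduces to the univariate polynomial in the other.
#'
#' @param coords two-column matrix or data.frame of population longitude and
#'   latitude (decimal degrees).
#' @param degree maximum total degree (default 3).
#' @return A `spatial_terms` matrix (populations x terms) with a `labels`
#'   attribute; columns are mutually orthogonal, orthogonal to the constant,
#'   and unit norm.
#' @export
spatial_polynomials <- function(coords, degree = 3) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, degree >= 1)
  if (nrow(unique(coords)) < 2) stop("all coordinates identical")
  x <- coords[, 1]
  y <- coords[, 2]
  labels <- character(0)
  raw <- NULL
  for (d in seq_len(degree)) {
    for (i in d:0) {
      j <- d - i
      col <- x^i * y^j
      lab <- paste0(if (i > 0) paste0("x", if (i > 1) i) else "",
                    if (j > 0) paste0("y", if (j > 1) j) else "")
      raw <- cbind(raw, col)
      labels <- c(labels, lab)
    }
  }
  # drop monomials that are constant (a degenerate coordinate)
  keep0 <- apply(raw, 2, function(v) stats::sd(v) > 0)
  raw <- raw[, keep0, drop = FALSE]
  labels <- labels[keep0]

  n <- nrow(raw)
  basis <- matrix(1 / sqrt(n), n, 1)  # constant, unit norm
  out <- NULL
  out_labels <- character(0)
  for (j in seq_len(ncol(raw))) {
    v <- raw[, j]
    resid <- v - basis %*% crossprod(basis, v)
    # second projection pass: the raw monomials are nearly collinear over
    # narrow coordinate ranges, and one classical Gram-Schmidt pass leaves
    # visible non-orthogonality
    resid <- resid - basis %*% crossprod(basis, resid)
    nr <- sqrt(sum(resid^2))
    if (nr < 1e-8 * sqrt(sum(v^2))) next   # inside the current span
    u <- resid / nr
    basis <- cbind(basis, u)
    out <- cbind(out, u)
    out_labels <- c(out_labels, labels[j])
  }
  if (is.null(out)) stop("no spatial term survives orthogonalization")
  if (ncol(out) < ncol(raw))
    warning(sprintf("dropped %d rank-deficient spatial term(s)",
                    ncol(raw) - ncol(out)))
  colnames(out) <- out_labels
  structure(out, labels = out_labels, degree = degree,
            class = c("spatial_terms", "matrix", "array"))
}

# response matrix from an allele_freq_table or plain matrix: rows =
# populations, columns = loci, centered per column; missing frequencies
# replaced by the column mean before centering
rda_response <- function(Y) {
  if (inherits(Y, "allele_freq_table")) Y <- Y$freq
  Y <- as.matrix(Y)
  for (j in which(colSums(is.na(Y)) > 0)) {
    mu <- mean(Y[, j], na.rm = TRUE)
    Y[is.na(Y[, j]), j] <- if (is.nan(mu)) 0 else mu
  }
  sweep(Y, 2, colMeans(Y))
}

rda_stats <- function(Yc, X) {
  qrX <- qr(cbind(1, X))
  fitted <- qr.fitted(qrX, Yc)
  tot <- sum(Yc^2)
  # the ratio is a proportion; rounding can push it epsilon above 1, which
  # would flip the sign of the pseudo-F denominator
  list(constrained = min(1, sum(fitted^2) / tot), fitted = fitted, tot = tot,
       q = qrX$rank - 1)
}

#' Forward selection of spatial terms
#'
#' Stepwise addition: at each step the candidate term with the largest
#' partial pseudo-F — the F for the variance it adds beyond the terms
#' already selected — is tested by permuting the residuals of the
#' reduced (already-selected) model; it enters if the permutation p-value
#' is below `alpha_enter`, and selection stops otherwise. Guards the
#' constrained ordination against overfitting.
#'
#' @param Y populations x loci response — an [allele_frequencies()] result
#'   or a plain matrix; centered internally.
#' @param terms a [spatial_polynomials()] matrix.
#' @param alpha_enter entry significance level.
#' @param n_perm permutations per entry test.
#' @param seed integer seed.
#' @return Character vector of selected term labels (possibly empty), with
#'   the selected columns as the `terms` attribute.
#' @export
forward_select <- function(Y, terms, alpha_enter = 0.05, n_perm = 999,
                           seed = 1) {
  set.seed(seed)
  Yc <- rda_response(Y)
  n <- nrow(Yc)
  stopifnot(nrow(terms) == n)
  candidates <- seq_len(ncol(terms))
  selected <- integer(0)

  # partial F of the candidate given the selected terms:
  # ((R2_joint - R2_sel) / 1) / ((1 - R2_joint) / (n - q_joint - 1))
  partial_f <- function(Ymat, r2_sel, cand) {
    st <- rda_stats(Ymat, terms[, c(selected, cand), drop = FALSE])
    (st$constrained - r2_sel) / ((1 - st$constrained) / (n - st$q - 1))
  }
  repeat {
    if (!length(candidates) || length(selected) >= n - 2) break
    if (length(selected)) {
      st_sel <- rda_stats(Yc, terms[, selected, drop = FALSE])
      fitted_sel <- st_sel$fitted
      r2_sel <- st_sel$constrained
    } else {
      fitted_sel <- matrix(0, n, ncol(Yc))
      r2_sel <- 0
    }
    if (1 - r2_sel < 1e-10) break   # reduced model already saturates Y
    resid_sel <- Yc - fitted_sel
    f_val <- vapply(candidates, function(cc)
      partial_f(Yc, r2_sel, cc), numeric(1))
    best <- candidates[which.max(f_val)]
    f_obs <- max(f_val)
    # permute the reduced-model residuals, keeping the fitted part in place
    f_perm <- vapply(seq_len(n_perm), function(b) {
      Yb <- fitted_sel + resid_sel[sample(n), , drop = FALSE]
      st_b <- if (length(selected))
        rda_stats(Yb, terms[, selected, drop = FALSE])$constrained else 0
      partial_f(Yb, st_b, best)
    }, numeric(1))
    p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
    if (p >= alpha_enter) break
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  labs <- colnames(terms)[selected]
  structure(labs, terms = terms[, selected, drop = FALSE])
}

#' Redundancy analysis of allele frequencies on spatial terms
#'
#' Classical RDA: the centered response is projected onto the span of the
#' explanatory terms by least squares; the constrained proportion is
#' `trace(fitted' fitted) / trace(Y'Y)`, the constrained axes come from the
#' singular decomposition of the fitted matrix, and significance is assessed
#' by an ANOVA-like pseudo-F with row permutation of the response.
#'
#' @param Y populations x loci response — an [allele_frequencies()] result
#'   or a plain matrix; centered internally.
#' @param X explanatory matrix (e.g. selected [spatial_polynomials()]
#'   columns); must have full column rank with fewer columns than n - 1.
#' @param n_perm permutations for the significance test.
#' @param seed integer seed.
#' @return An `rda_result`: `prop_constrained`, `axis_props` (per
#'   constrained axis, summing to the constrained proportion), `pseudo_f`,
#'   `p_value`, `terms`.
#' @export
rda_fit <- function(Y, X, n_perm = 999, seed = 1) {
  set.seed(seed)
  Yc <- rda_response(Y)
  X <- as.matrix(X)
  n <- nrow(Yc)
  stopifnot(nrow(X) == n)
  q <- qr(cbind(1, X))$rank - 1
  if (q < ncol(X)) stop("X is rank deficient")
  if (q >= n - 1) stop("saturated model: as many terms as residual dimensions")
  st <- rda_stats(Yc, X)
  sv <- svd(st$fitted, nu = 0, nv = 0)$d
  axis_props <- (sv^2 / st$tot)[sv^2 / st$tot > 1e-12]
  f_obs <- (st$constrained / q) / ((1 - st$constrained) / (n - q - 1))
  p <- NA_real_
  if (n_perm > 0) {
    f_perm <- vapply(seq_len(n_perm), function(b) {
      stb <- rda_stats(Yc[sample(n), , drop = FALSE], X)
      (stb$constrained / q) / ((1 - stb$constrained) / (n - q - 1))
    }, numeric(1))
    p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }
  structure(list(prop_constrained = st$constrained, axis_props = axis_props,
                 pseudo_f = f_obs, p_value = p,
                 terms = colnames(X), n = n, q = q, seed = seed),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("RDA: %.1f%% of total variance constrained by %d term(s); F = %.3f, P = %s\n",
              100 * x$prop_constrained, x$q, x$pseudo_f,
              format.pval(x$p_value)))
  invisible(x)
}

#' Spatially explained FST
#'
#' The share of total differentiation attributable to spatial structure: the
#' constrained proportion from the RDA multiplied by the overall
#' multi-locus FST, reported to three decimals.
#'
#' @param constrained_prop constrained proportion of variance, in `[0, 1]`.
#' @param overall_fst overall multi-locus FST, in `[0, 1]`.
#' @return The product, rounded to 3 decimals.
#' @export
explained_fst <- function(constrained_prop, overall_fst) {
  stopifnot(constrained_prop >= 0, constrained_prop <= 1,
            overall_fst >= 0, overall_fst <= 1)
  round(constrained_prop * overall_fst, 3)
}
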