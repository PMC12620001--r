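#' Minor allele frequency per marker
#'
#' Frequency of the rarer allele across all 2N haplotype entries at each
#' marker; soft populations use mean soft dosage.  Values are clamped from
#' below at `floor_eps` so that the inverse-square-root weighting of the
#' weighted breeding value stays finite at (nearly) monomorphic markers.
#'
#' @param pop a `population` (or a bare N x 2m matrix).
#' @param floor_eps lower clamp, default 0.01.
#' @return numeric vector of length m with entries in [floor_eps, 0.5].
#' @export
minor_allele_freq <- function(pop, floor_eps = 0.01) {
  w <- if (inherits(pop, "population")) pop$w else as.matrix(pop)
  m <- ncol(w) %/% 2L
  cm <- colMeans(w)
  f <- (cm[seq_len(m)] + cm[m + seq_len(m)]) / 2
  pmax(pmin(f, 1 - f), floor_eps)
}

#' Weighted breeding value of every individual
#'
#' WBV_i = sum_j alpha_j p_j^(-1/2) w_ij over all 2m entries, with p the
#' per-marker minor allele frequency (duplicated over both haplotypes).
#' Rare alleles are up-weighted, favoring long-term gain.
#'
#' @param pop a `population` (or matrix).
#' @param trait a `trait_arch`.
#' @param p minor allele frequencies (length m, all > 0); defaults to
#'   [minor_allele_freq()] of `pop`.
#' @return numeric vector of length N.
#' @export
wbv_individual <- function(pop, trait, p = NULL) {
  w <- if (inherits(pop, "population")) pop$w else as.matrix(pop)
  m <- ncol(w) %/% 2L
  if (is.null(p)) p <- minor_allele_freq(w)
  if (length(p) != m) stop("p must have length m")
  if (any(p <= 0)) stop("p must be strictly positive (apply the floor first)")
  a <- trait$alpha * rep(p, 2L)^(-0.5)
  as.vector(w %*% a)
}

#' Mean-parent WBV per mating pair
#'
#' @param wbv numeric vector of parent WBVs.
#' @param pairs a two-column matrix (kM, kP) of parent indices, kM <= kP.
#' @return numeric vector of length nrow(pairs); equals the parent's WBV
#'   for selfing pairs.
#' @export
wbv_pair_feature <- function(wbv, pairs) {
  if (max(pairs) > length(wbv) || min(pairs) < 1L) stop("pair index out of range")
  0.5 * (wbv[pairs[, 1L]] + wbv[pairs[, 2L]])
}

#' Diallel mating pairs with selfing
#'
#' All n(n+1)/2 unordered pairs (kM <= kP) of n parents, selfing included.
#'
#' @param n number of parents.
#' @return integer matrix with columns kM, kP, ordered by kM then kP.
#' @export
diallel_pairs <- function(n) {
  idx <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  m <- cbind(kM = idx[, "row"], kP = idx[, "col"])
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

# GVP quadratic-form kernel: C[j,j'] = (1 - 2 r_jj') beta_j beta_j'.
# Cross-chromosome pairs vanish (r = 0.5).
gvp_kernel <- function(trait, map) {
  (1 - 2 * recomb_matrix(map)) * outer(trait$beta, trait$beta)
}

#' Expected genetic variance of progeny (GVP) of one cross
#'
#' Theoretical variance of progeny genotypic values caused by Mendelian
#' segregation, from the parents' phase and the pairwise recombination
#' rates:
#'   gvp = sum_jj' sigma_jj' beta_j beta_j',
#'   sigma_jj' = 1/4 (1 - 2 r_jj') * sum over the two parents of
#'               (w_j - w_{j+m})(w_j' - w_{j'+m}).
#' Only markers heterozygous in a parent contribute; fully homozygous
#' parents give 0.
#'
#' @param w_kM,w_kP phased parental allele-score vectors (length 2m).
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @return non-negative scalar (up to numerical tolerance).
#' @export
gvp <- function(w_kM, w_kP, trait, map) {
  m <- map$m
  if (length(w_kM) != 2L * m || length(w_kP) != 2L * m)
    stop("parent vectors must have length 2m")
  C <- gvp_kernel(trait, map)
  dM <- w_kM[seq_len(m)] - w_kM[m + seq_len(m)]
  dP <- w_kP[seq_len(m)] - w_kP[m + seq_len(m)]
  0.25 * (as.numeric(dM %*% C %*% dM) + as.numeric(dP %*% C %*% dP))
}

# per-individual GVP quadratic form q_i = d_i' C d_i for a parent matrix;
# gvp of pair (kM,kP) is then (q_kM + q_kP)/4
gvp_quadform <- function(W, C) {
  m <- ncol(W) %/% 2L
  D <- W[, seq_len(m), drop = FALSE] - W[, m + seq_len(m), drop = FALSE]
  rowSums((D %*% C) * D)
}

#' Assemble the pair-goodness feature matrix
#'
#' Builds the full diallel (with selfing) over the selected parents and
#' computes, per pair, the mean-parent weighted breeding value and the
#' expected genetic variance of progeny.  With `standardize = TRUE`
#' (default) each feature column is z-scored across pairs so the two
#' metrics share a scale before entering the allocation softmax;
#' zero-variance columns map to 0.
#'
#' @param pop a `population` (or matrix) holding the *selected parents*.
#' @param selected indices of the parents within `pop`; defaults to all rows.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param p minor allele frequencies of the population being allocated
#'   (length m); defaults to [minor_allele_freq()] of `pop`.
#' @param standardize z-score the feature columns (default TRUE).
#' @param features character subset of c("wbv", "gvp") to compute.
#' @return object of class `pair_features`: `omega` (P x d matrix),
#'   `omega_raw`, `pairs`, `p`, `standardized`.
#' @export
assemble_features <- function(pop, selected = NULL, trait, map, p = NULL,
                              standardize = TRUE,
                              features = c("wbv", "gvp")) {
  w <- if (inherits(pop, "population")) pop$w else as.matrix(pop)
  if (is.null(selected)) selected <- seq_len(nrow(w))
  if (length(selected) < 1L) stop("selected must be non-empty")
  if (is.null(p)) p <- minor_allele_freq(w)
  Wsel <- w[selected, , drop = FALSE]
  n <- nrow(Wsel)
  pairs <- diallel_pairs(n)
  cols <- list()
  if ("wbv" %in% features) {
    wbv <- wbv_individual(Wsel, trait, p)
    cols$wbv <- wbv_pair_feature(wbv, pairs)
  }
  if ("gvp" %in% features) {
    q <- gvp_quadform(Wsel, gvp_kernel(trait, map))
    cols$gvp <- 0.25 * (q[pairs[, 1L]] + q[pairs[, 2L]])
  }
  omega_raw <- do.call(cbind, cols)
  omega <- if (standardize) apply(omega_raw, 2L, zscore_col) else omega_raw
  if (!is.matrix(omega)) omega <- matrix(omega, ncol = length(cols))
  colnames(omega) <- names(cols)
  structure(list(omega = omega, omega_raw = omega_raw, pairs = pairs,
                 p = p, standardized = standardize),
            class = "pair_features")
}

zscore_col <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}
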