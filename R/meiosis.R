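#' Sample Mendelian segregation indicators
#'
#' Draws the crossover indicators eta for every (progeny slot, mating pair,
#' marker).  Within a chromosome, eta[.,.,j] ~ Bernoulli(r_adj[j]), the
#' recombination rate to the previous marker; the first marker of every
#' chromosome uses the virtual rate 0.5, so each chromosome independently
#' starts from either parental haplotype with equal probability.
#'
#' @param map a `marker_map`.
#' @param n_slots number of progeny slots (>= 1).
#' @param n_pairs number of mating pairs (>= 1).
#' @param seed integer seed.
#' @return object of class `segregation_draws`: integer matrix `eta` of
#'   dimension (n_slots * n_pairs) x m, row index slot + n_slots*(pair-1),
#'   plus `n_slots`, `n_pairs`, `seed`.
#' @export
sample_segregation <- function(map, n_slots, n_pairs, seed) {
  stopifnot(inherits(map, "marker_map"), n_slots >= 1, n_pairs >= 1)
  set.seed(as.integer(seed))
  rates <- ifelse(map$chrom_first, 0.5, map$r_adj)
  nr <- n_slots * n_pairs
  eta <- matrix(0L, nr, map$m)
  for (j in seq_len(map$m)) eta[, j] <- rbinom(nr, 1L, rates[j])
  structure(list(eta = eta, n_slots = as.integer(n_slots),
                 n_pairs = as.integer(n_pairs), seed = as.integer(seed)),
            class = "segregation_draws")
}

# cumulative crossover parity per gamete: parity[., j] = sum(eta[., 1..j])
# mod 2, restarting at each chromosome (chromosomes segregate
# independently).  0 = first homologue, 1 = second.
eta_to_parity <- function(eta, map) {
  eta <- if (is.matrix(eta)) eta else matrix(eta, nrow = 1L)
  H <- eta
  for (j in seq_len(map$m)) {
    if (!map$chrom_first[j]) H[, j] <- (H[, j - 1L] + eta[, j]) %% 2L
  }
  H
}

# draw parity indicators directly (distributionally identical to
# eta_to_parity(sample_segregation(...))); fast path used by the simulators
sample_parity <- function(map, n_rows) {
  cpp_sample_parity(as.integer(n_rows), map$r_adj, map$chrom_first)
}

#' Generate one gamete from a phased parent
#'
#' The allele at marker j is read from the parent's first homologue
#' (columns 1..m) when the cumulative number of crossovers up to j is even,
#' and from the second homologue (columns m+1..2m) when odd.
#'
#' @param parent_w binary vector of length 2m (one parent's phased allele
#'   scores).
#' @param eta_row binary vector of length m of crossover indicators.
#' @param map a `marker_map`.
#' @return object of class `gamete_trace` with fields `l` (the source
#'   column per marker, j or j+m) and `gamete` (binary, length m).
#' @export
gamete_from_parent <- function(parent_w, eta_row, map) {
  m <- map$m
  if (length(parent_w) != 2L * m) stop("parent_w must have length 2m")
  if (length(eta_row) != m) stop("eta_row must have length m")
  parity <- drop(eta_to_parity(matrix(as.integer(eta_row), 1L), map))
  l <- seq_len(m) + m * parity
  structure(list(l = l, gamete = as.vector(parent_w[l])),
            class = "gamete_trace")
}

#' Generate one progeny from a mating pair
#'
#' Gametes are produced independently from the two parents and
#' concatenated: the first m entries of the progeny come from parent kM,
#' the last m from parent kP.
#'
#' @param w_kM,w_kP phased parental allele-score vectors (length 2m).
#' @param eta_M,eta_P crossover indicator vectors (length m), one per
#'   parental gamete.
#' @param map a `marker_map`.
#' @return binary vector of length 2m.
#' @export
progeny_from_pair <- function(w_kM, w_kP, eta_M, eta_P, map) {
  c(gamete_from_parent(w_kM, eta_M, map)$gamete,
    gamete_from_parent(w_kP, eta_P, map)$gamete)
}

# vectorized hard gametes: one gamete per row of the parity matrix H
# (n x m), all from the same parent
gametes_from_parity <- function(parent_w, H, m) {
  n <- nrow(H)
  l <- matrix(rep(seq_len(m), each = n), n, m) + m * H
  matrix(parent_w[l], n, m)
}

# batch of hard progeny from one pair: `count` offspring, fresh parity draws
hard_progeny_batch <- function(w_kM, w_kP, count, map) {
  m <- map$m
  HM <- sample_parity(map, count)
  HP <- sample_parity(map, count)
  cbind(gametes_from_parity(w_kM, HM, m), gametes_from_parity(w_kP, HP, m))
}
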