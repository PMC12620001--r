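#' Build a marker map with recombination rates
#'
#' Lays out `m` markers on `length(chrom_sizes)` chromosomes and converts
#' genetic distances (centimorgan) into recombination rates with the Haldane
#' map function, r = 0.5 * (1 - exp(-2 d / 100)).  Markers on different
#' chromosomes always recombine at rate 0.5.  The adjacent-rate vector
#' `r_adj` carries, for each marker, the recombination rate with the previous
#' marker on the same chromosome; the first marker of every chromosome gets
#' the virtual rate 0.5 so that a gamete starts from either parental
#' haplotype with equal probability.
#'
#' @param chrom_sizes integer vector, number of markers per chromosome
#'   (all entries >= 1).
#' @param spacing_cM positive scalar, uniform gap between adjacent markers.
#'   Ignored when `pos_cM` is given.
#' @param pos_cM optional numeric vector of explicit positions (length
#'   `sum(chrom_sizes)`), non-decreasing within each chromosome.
#' @param marker_id optional character vector of marker names; defaults to
#'   `M1..Mm`.
#' @return an object of class `marker_map` with fields `marker_id`, `chrom`,
#'   `pos_cM`, `r_adj`, `chrom_first` (logical, TRUE at each chromosome
#'   start), `m` and `n_chrom`.
#' @examples
#' map <- build_marker_map(c(2, 2), spacing_cM = 10)
#' recomb_rate(map, 1, 3)  # different chromosomes -> 0.5
#' @export
build_marker_map <- function(chrom_sizes, spacing_cM = 1,
                             pos_cM = NULL, marker_id = NULL) {
  chrom_sizes <- as.integer(chrom_sizes)
  if (length(chrom_sizes) < 1L || any(chrom_sizes < 1L))
    stop("every chromosome must carry at least one marker")
  m <- sum(chrom_sizes)
  chrom <- rep.int(seq_along(chrom_sizes), chrom_sizes)
  chrom_first <- !duplicated(chrom)
  if (is.null(pos_cM)) {
    if (!is.numeric(spacing_cM) || length(spacing_cM) != 1L || spacing_cM <= 0)
      stop("spacing_cM must be a positive scalar")
    within_idx <- sequence(chrom_sizes) - 1L
    pos_cM <- within_idx * spacing_cM
  } else {
    if (length(pos_cM) != m) stop("pos_cM length must equal sum(chrom_sizes)")
    for (ch in seq_along(chrom_sizes)) {
      p <- pos_cM[chrom == ch]
      if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", ch)
    }
  }
  if (is.null(marker_id)) marker_id <- paste0("M", seq_len(m))
  if (length(marker_id) != m) stop("marker_id length mismatch")
  gap <- c(0, diff(pos_cM))
  r_adj <- haldane(gap)
  r_adj[chrom_first] <- 0.5
  structure(
    list(marker_id = as.character(marker_id), chrom = chrom,
         pos_cM = as.numeric(pos_cM), r_adj = r_adj,
         chrom_first = chrom_first, m = m,
         n_chrom = length(chrom_sizes)),
    class = "marker_map")
}

#' Haldane map function
#'
#' @param d_cM genetic distance in centimorgan (non-negative).
#' @return recombination rate in [0, 0.5).
#' @export
haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Pairwise recombination rate between two markers
#'
#' Haldane rate from the position difference for markers on the same
#' chromosome, 0.5 across chromosomes.  Vectorized over `j` and `jp`.
#'
#' @param map a `marker_map`.
#' @param j,jp marker indices (1-based).
#' @return recombination rate(s) in [0, 0.5].
#' @export
recomb_rate <- function(map, j, jp) {
  r <- haldane(abs(map$pos_cM[j] - map$pos_cM[jp]))
  r[map$chrom[j] != map$chrom[jp]] <- 0.5
  r
}

#' Full m x m pairwise recombination-rate matrix
#'
#' @param map a `marker_map`.
#' @return symmetric matrix with zeros on the diagonal and 0.5 for
#'   cross-chromosome pairs.
#' @export
recomb_matrix <- function(map) {
  m <- map$m
  R <- haldane(abs(outer(map$pos_cM, map$pos_cM, "-")))
  R[outer(map$chrom, map$chrom, "!=")] <- 0.5
  R
}

#' @export
print.marker_map <- function(x, ...) {
  cat(sprintf("marker_map: %d markers on %d chromosome(s), %.1f cM total\n",
              x$m, x$n_chrom,
              sum(tapply(x$pos_cM, x$chrom, function(p) diff(range(p))))))
  invisible(x)
}

#' Construct a population of phased genotypes
#'
#' A population stores the allele-score matrix `w` (N rows, one per
#' individual; 2m columns: maternal haplotype first, then paternal), in
#' which each entry marks the presence of the alternative allele.  Hard
#' populations are strictly binary; soft populations (produced inside the
#' differentiable graph) have entries in [0, 1].
#'
#' @param w numeric matrix N x 2m.
#' @param generation non-negative integer generation index.
#' @param soft logical; when FALSE entries must be exactly 0/1.
#' @return object of class `population` with fields `w`, `m`, `N`,
#'   `generation`, `soft`.
#' @export
new_population <- function(w, generation = 0L, soft = FALSE) {
  w <- as.matrix(w)
  if (ncol(w) %% 2L != 0L) stop("w must have an even number of columns (2m)")
  if (nrow(w) < 1L) stop("population must contain at least one individual")
  if (anyNA(w)) stop("w contains missing values")
  if (!soft && !all(w == 0 | w == 1)) stop("hard population must be binary 0/1")
  if (soft && (min(w) < 0 || max(w) > 1)) stop("soft allele scores must lie in [0,1]")
  structure(list(w = w, m = ncol(w) %/% 2L, N = nrow(w),
                 generation = as.integer(generation), soft = soft),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("population: N=%d, m=%d markers, generation %d (%s)\n",
              x$N, x$m, x$generation, if (x$soft) "soft" else "hard"))
  invisible(x)
}

#' Per-marker allele dosage (0/1/2)
#'
#' @param pop a `population`.
#' @return N x m matrix of maternal + paternal allele scores.
#' @export
dosage <- function(pop) {
  m <- pop$m
  pop$w[, seq_len(m), drop = FALSE] + pop$w[, m + seq_len(m), drop = FALSE]
}

#' Simulate founder haplotypes
#'
#' Draws 2N binary haplotypes marker by marker.  Each marker j has a target
#' alternative-allele frequency f_j ~ Uniform(maf_lo, maf_hi).  Within a
#' chromosome, linkage disequilibrium is induced by a Markov copy process:
#' with probability exp(-ld_decay * d) (d the gap to the previous marker in
#' cM) a haplotype copies its previous allele, otherwise it draws fresh from
#' Bernoulli(f_j).  Chromosome starts always draw fresh.
#'
#' @param map a `marker_map`.
#' @param N number of diploid individuals (>= 2).
#' @param seed integer seed; the same (seed, parameters) reproduce the
#'   matrix bit for bit.
#' @param maf_range length-2 numeric, 0 < lo <= hi <= 0.5.
#' @param ld_decay non-negative decay rate per cM of the copy persistence.
#' @return a hard `population` at generation 0.
#' @export
simulate_founders <- function(map, N, seed, maf_range = c(0.05, 0.5),
                              ld_decay = 0.1) {
  stopifnot(inherits(map, "marker_map"))
  if (N < 2) stop("N must be >= 2")
  if (length(maf_range) != 2L || maf_range[1] <= 0 ||
      maf_range[1] > maf_range[2] || maf_range[2] > 0.5)
    stop("maf_range must satisfy 0 < lo <= hi <= 0.5")
  if (ld_decay < 0) stop("ld_decay must be >= 0")
  set.seed(as.integer(seed))
  m <- map$m
  H <- matrix(0L, nrow = 2L * N, ncol = m)
  freq <- runif(m, maf_range[1], maf_range[2])
  gap <- c(0, diff(map$pos_cM))
  for (j in seq_len(m)) {
    fresh <- rbinom(2L * N, 1L, freq[j])
    if (map$chrom_first[j]) {
      H[, j] <- fresh
    } else {
      keep <- runif(2L * N) < exp(-ld_decay * gap[j])
      H[, j] <- ifelse(keep, H[, j - 1L], fresh)
    }
  }
  # rows 2i-1 / 2i are the two haplotypes of individual i
  w <- cbind(H[seq(1L, 2L * N, by = 2L), , drop = FALSE],
             H[seq(2L, 2L * N, by = 2L), , drop = FALSE])
  colnames(w) <- c(map$marker_id, map$marker_id)
  new_population(w, generation = 0L)
}

#' Sample an additive trait architecture
#'
#' Marker effects are drawn i.i.d. Normal(0, effect_sd); every marker is a
#' QTL.  The duplicated effect vector `alpha` (length 2m) applies the same
#' effect to both haplotypes.
#'
#' @param map a `marker_map`.
#' @param seed integer seed.
#' @param effect_sd positive standard deviation of marker effects.
#' @return object of class `trait_arch` with fields `beta` (length m) and
#'   `alpha` (length 2m).
#' @export
sample_trait <- function(map, seed, effect_sd = 1) {
  stopifnot(inherits(map, "marker_map"))
  if (effect_sd <= 0) stop("effect_sd must be > 0")
  set.seed(as.integer(seed))
  beta <- rnorm(map$m, 0, effect_sd)
  new_trait(beta, map)
}

#' Construct a trait architecture from explicit marker effects
#'
#' @param beta numeric vector of per-marker effects (length m).
#' @param map optional `marker_map` used for a length check.
#' @return a `trait_arch`.
#' @export
new_trait <- function(beta, map = NULL) {
  beta <- as.numeric(beta)
  if (!is.null(map) && length(beta) != map$m)
    stop("beta length must equal the number of markers")
  structure(list(beta = beta, alpha = c(beta, beta)), class = "trait_arch")
}

#' Genotypic values of a population
#'
#' The additive genotypic value of individual i is the dot product of the
#' duplicated effect vector with its allele scores.  Works identically for
#' hard and soft populations.
#'
#' @param pop a `population` (or a bare N x 2m matrix).
#' @param trait a `trait_arch`.
#' @return numeric vector of length N.
#' @export
genotypic_values <- function(pop, trait) {
  w <- if (inherits(pop, "population")) pop$w else as.matrix(pop)
  if (ncol(w) != length(trait$alpha))
    stop("dimension mismatch between population and trait")
  as.vector(w %*% trait$alpha)
}

#' Deterministic child seed for a named component
#'
#' Expands one master seed into per-component seeds by hashing the
#' component tag, so that independent pipeline stages (founders, trait,
#' optimization, evaluation, ...) get decoupled but fully reproducible
#' random streams.  Results always fit in a 31-bit integer, as
#' [set.seed()] requires.
#'
#' @param seed integer master seed.
#' @param tag character component name.
#' @return integer seed.
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}
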