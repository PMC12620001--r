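# shared fixtures and independent oracles, all built in code

# small two-chromosome map
toy_map <- function(sizes = c(3, 3), spacing = 10) {
  build_marker_map(sizes, spacing_cM = spacing)
}

# population from explicit haplotype pairs: hap list of (maternal, paternal)
pop_from_haps <- function(haps) {
  w <- do.call(rbind, lapply(haps, function(h) c(h[[1]], h[[2]])))
  new_population(w, soft = !all(w %in% c(0, 1)))
}

# brute-force genotypic values: explicit double loop, no linear algebra
oracle_genotypic <- function(w, alpha) {
  out <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    s <- 0
    for (j in seq_len(ncol(w))) s <- s + alpha[j] * w[i, j]
    out[i] <- s
  }
  out
}

# brute-force WBV: triple loop over individuals, markers, haplotypes
oracle_wbv <- function(w, beta, p) {
  m <- length(beta)
  out <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    s <- 0
    for (j in seq_len(m)) {
      s <- s + beta[j] * p[j]^(-0.5) * w[i, j]
      s <- s + beta[j] * p[j]^(-0.5) * w[i, j + m]
    }
    out[i] <- s
  }
  out
}

# exhaustive gamete distribution for a single parent on an arbitrary map:
# enumerates every crossover-indicator pattern eta in {0,1}^m with its
# Bernoulli probability (rate 0.5 at chromosome starts, r_adj within), and
# accumulates the probability of each distinct gamete.  Independent of the
# package's parity short-cut: uses the cumulative mod-2 definition directly.
oracle_gamete_distribution <- function(parent_w, map) {
  m <- map$m
  rates <- ifelse(map$chrom_first, 0.5, map$r_adj)
  patterns <- as.matrix(expand.grid(rep(list(0:1), m)))
  dist <- new.env()
  for (r in seq_len(nrow(patterns))) {
    eta <- patterns[r, ]
    prob <- prod(ifelse(eta == 1, rates, 1 - rates))
    if (prob == 0) next
    # parity = cumulative sum of eta mod 2, restarting at chromosome starts
    parity <- integer(m)
    for (j in seq_len(m)) {
      parity[j] <- if (map$chrom_first[j]) eta[j]
                   else (parity[j - 1] + eta[j]) %% 2
    }
    gam <- parent_w[seq_len(m) + m * parity]
    key <- paste(gam, collapse = "")
    dist[[key]] <- (dist[[key]] %||% 0) + prob
  }
  probs <- unlist(as.list(dist))
  probs / sum(probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empirical gamete distribution over n draws
empirical_gamete_distribution <- function(parent_w, map, n, seed) {
  set.seed(seed)
  H <- breedgrad:::sample_parity(map, n)
  G <- breedgrad:::gametes_from_parity(parent_w, H, map$m)
  keys <- apply(G, 1, paste, collapse = "")
  table(keys) / n
}

# total-variation distance between two named discrete distributions
tv_distance <- function(p, q) {
  keys <- union(names(p), names(q))
  sum(abs(ifelse(keys %in% names(p), p[keys], 0) -
          ifelse(keys %in% names(q), q[keys], 0))) / 2
}
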