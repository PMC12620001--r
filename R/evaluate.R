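#' Integer progeny allocation by largest remainder
#'
#' Rounds N * pi to integer progeny counts per mating pair: floors first,
#' then hands the remaining slots to the largest fractional remainders,
#' ties broken by the lower pair index.  Counts always sum to N.
#'
#' @param pi probability vector over pairs (sums to 1).
#' @param N total number of progeny.
#' @return integer vector of counts, same length as `pi`.
#' @export
discrete_allocate <- function(pi, N) {
  if (N < 1L) stop("N must be >= 1")
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) stop("pi must be a probability vector")
  x <- N * pi
  counts <- floor(x)
  need <- N - sum(counts)
  if (need > 0L) {
    ord <- order(-(x - counts), seq_along(pi))
    counts[ord[seq_len(need)]] <- counts[ord[seq_len(need)]] + 1
  }
  as.integer(counts)
}

#' Discrete multi-generation breeding simulation
#'
#' The evaluation-side simulator: fully discrete, no Gumbel relaxation.
#' Each generation selects parents, scores all diallel pairs, converts the
#' allocation softmax into integer progeny counts (largest remainder) and
#' generates exactly that many hard progeny per pair by meiosis, keeping
#' the population size constant.
#'
#' @param founders a hard `population`.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param params an `allocation_params`; the "EQ" policy gives uniform
#'   allocation probabilities every generation.
#' @param cfg a `scheme_config`.
#' @param seed integer seed for the meiosis draws.
#' @return list of T + 1 `population`s (generations 0..T).
#' @export
simulate_scheme_hard <- function(founders, trait, map, params, cfg, seed) {
  stopifnot(inherits(founders, "population"), !founders$soft,
            inherits(params, "allocation_params"))
  set.seed(as.integer(seed))
  N <- founders$N
  pops <- vector("list", cfg$generations + 1L)
  pops[[1L]] <- founders
  w <- founders$w
  for (tau in seq_len(cfg$generations)) {
    p <- minor_allele_freq(w, cfg$maf_floor)
    sel <- select_parents(w, trait, p, cfg)$indices
    feats <- assemble_features(w, sel, trait, map, p,
                               standardize = cfg$standardize,
                               features = cfg$features)
    pi <- allocation_probs(feats, params$theta[tau, ])
    counts <- discrete_allocate(pi, N)
    Wsel <- w[sel, , drop = FALSE]
    blocks <- vector("list", sum(counts > 0L))
    bi <- 0L
    for (k in which(counts > 0L)) {
      bi <- bi + 1L
      blocks[[bi]] <- hard_progeny_batch(Wsel[feats$pairs[k, 1L], ],
                                         Wsel[feats$pairs[k, 2L], ],
                                         counts[k], map)
    }
    w <- do.call(rbind, blocks)
    pops[[tau + 1L]] <- new_population(w, generation = tau)
  }
  pops
}

#' Genetic gain per generation
#'
#' gain(t) = merit_topk(t) - merit_topk(0): the difference in top-K mean
#' genotypic value between generation t and the founders.
#'
#' @param populations list of `population`s (generations 0..T).
#' @param trait a `trait_arch`.
#' @param K top-K size.
#' @return numeric vector of length T + 1 (first entry 0).
#' @export
genetic_gain <- function(populations, trait, K) {
  merits <- vapply(populations, function(p)
    merit_topk(genotypic_values(p, trait), K), numeric(1L))
  merits - merits[1L]
}

#' Genetic variance of a population
#'
#' Population variance (divisor N) of the true genotypic values; the
#' diversity measure tracked across generations.
#'
#' @param pop a `population`.
#' @param trait a `trait_arch`.
#' @return non-negative scalar.
#' @export
genetic_variance <- function(pop, trait) {
  if (pop$N < 2L) stop("N must be >= 2")
  v <- genotypic_values(pop, trait)
  mean((v - mean(v))^2)
}

#' Replicated strategy comparison
#'
#' Runs the hard simulator `n_reps` times per strategy with common
#' (paired) meiosis seeds across strategies within each replicate, and
#' summarizes final-generation gains: means, 1st/50th/99th percentiles of
#' the empirical CDF, and the percent improvement of every strategy over
#' the "EQ" entry (when present), computed on paired replicate means.
#'
#' @param founders a hard `population`.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param strategies named list of `allocation_params` (names label the
#'   strategies; include "EQ" for improvement rates).
#' @param cfg a `scheme_config`.
#' @param n_reps number of replicates (>= 1).
#' @param seed integer master seed.
#' @return object of class `experiment_result`: `records` (data.frame:
#'   replicate, strategy, generation, gain, variance) and `summary`
#'   (data.frame: strategy, mean_final_gain, q01, q50, q99,
#'   improvement_vs_eq_pct).
#' @export
run_experiment <- function(founders, trait, map, strategies, cfg,
                           n_reps, seed) {
  stopifnot(n_reps >= 1L, length(strategies) >= 1L,
            !is.null(names(strategies)))
  recs <- vector("list", n_reps * length(strategies))
  ri <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- child_seed(seed, paste0("rep", r))
    for (sname in names(strategies)) {
      pops <- simulate_scheme_hard(founders, trait, map,
                                   strategies[[sname]], cfg, rep_seed)
      gains <- genetic_gain(pops, trait, cfg$K)
      vars <- vapply(pops, genetic_variance, numeric(1L), trait = trait)
      ri <- ri + 1L
      recs[[ri]] <- data.frame(replicate = r, strategy = sname,
                               generation = 0:cfg$generations,
                               gain = gains, variance = vars)
    }
  }
  records <- do.call(rbind, recs)
  final <- records[records$generation == cfg$generations, ]
  strat_names <- names(strategies)
  mean_gain <- vapply(strat_names, function(s)
    mean(final$gain[final$strategy == s]), numeric(1L))
  qs <- t(vapply(strat_names, function(s)
    stats::quantile(final$gain[final$strategy == s],
                    c(0.01, 0.5, 0.99), names = FALSE), numeric(3L)))
  imp <- rep(NA_real_, length(strat_names))
  if ("EQ" %in% strat_names) {
    eq_mean <- mean_gain[["EQ"]]
    imp <- 100 * (mean_gain - eq_mean) / eq_mean
  }
  summary <- data.frame(strategy = strat_names,
                        mean_final_gain = unname(mean_gain),
                        q01 = qs[, 1L], q50 = qs[, 2L], q99 = qs[, 3L],
                        improvement_vs_eq_pct = unname(imp),
                        row.names = NULL)
  structure(list(records = records, summary = summary, seed = seed,
                 n_reps = n_reps),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment: %d replicates\n", x$n_reps))
  print(x$summary, digits = 4)
  invisible(x)
}
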