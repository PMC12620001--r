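#' Scheme configuration
#'
#' Bundles the constants of a multi-generation recurrent-selection scheme.
#'
#' @param generations number of breeding cycles T (>= 1).
#' @param K top-K size defining genetic merit.
#' @param selection one of "SI1", "SI2", "SI3".
#' @param n_parents parents selected by SI1/SI3 (defaults 15 / 50).
#' @param n_clusters clusters for SI2 (default 25).
#' @param temperature Gumbel-Softmax temperature c > 0 (default 0.5);
#'   smaller values are closer to discrete pair sampling but give noisier
#'   gradients.
#' @param standardize z-score the pair features before the allocation
#'   softmax (default TRUE).
#' @param maf_floor lower clamp on minor allele frequencies (default 0.01).
#' @param features which pair-goodness metrics drive allocation, a subset
#'   of c("wbv", "gvp"); their number is the parameter dimension d.
#' @return object of class `scheme_config`.
#' @export
scheme_config <- function(generations = 4L, K = 5L, selection = "SI2",
                          n_parents = NULL, n_clusters = NULL,
                          temperature = 0.5, standardize = TRUE,
                          maf_floor = 0.01, features = c("wbv", "gvp")) {
  stopifnot(generations >= 1L, K >= 1L, temperature > 0,
            all(features %in% c("wbv", "gvp")), length(features) >= 1L)
  selection <- match.arg(selection, c("SI1", "SI2", "SI3"))
  structure(list(generations = as.integer(generations), K = as.integer(K),
                 selection = selection, n_parents = n_parents,
                 n_clusters = n_clusters, temperature = temperature,
                 standardize = standardize, maf_floor = maf_floor,
                 features = features, d = length(features)),
            class = "scheme_config")
}

#' Per-generation allocation parameters
#'
#' The optimized object is the unconstrained pre-image nu (one row per
#' generation, one column per feature); the softmax weights are its image
#' theta = lo + (hi - lo) * logistic(nu), strictly inside (lo, hi) =
#' (0.5, 3.5) by default.  The equal-allocation policy (`eq_params`) fixes
#' theta = 0, bypassing the transform, and is never optimized.
#'
#' @param nu numeric T x d matrix (or vector for T = 1).
#' @param bounds length-2 numeric, lo < hi.
#' @return object of class `allocation_params` with fields `nu`, `theta`,
#'   `bounds`, `policy`.
#' @export
allocation_params <- function(nu, bounds = c(0.5, 3.5)) {
  if (!is.matrix(nu)) nu <- matrix(nu, nrow = 1L)
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  structure(list(nu = nu, theta = bounded_transform(nu, bounds),
                 bounds = bounds, policy = "GORA"),
            class = "allocation_params")
}

#' @rdname allocation_params
#' @param generations,d dimensions of the fixed theta = 0 policy.
#' @export
eq_params <- function(generations, d = 2L) {
  structure(list(nu = NULL, theta = matrix(0, generations, d),
                 bounds = c(0.5, 3.5), policy = "EQ"),
            class = "allocation_params")
}

#' Allocation probabilities over mating pairs
#'
#' Softmax of the linear pair scores omega %*% theta, computed with
#' max-subtraction.  theta = 0 gives the uniform (equal-allocation)
#' distribution.
#'
#' @param features a `pair_features` object or a bare P x d matrix.
#' @param theta_row numeric weight vector of length d.
#' @return probability vector over the P pairs (sums to 1).
#' @export
allocation_probs <- function(features, theta_row) {
  omega <- if (inherits(features, "pair_features")) features$omega else as.matrix(features)
  if (anyNA(omega)) stop("NaN/NA in pair features")
  if (ncol(omega) != length(theta_row)) stop("theta dimension mismatch")
  s <- as.vector(omega %*% theta_row)
  e <- exp(s - max(s))
  e / sum(e)
}

#' Gumbel-Softmax relaxation of a categorical draw
#'
#' y_j = softmax_j((log pi_j + g_j) / c): a point on the simplex that
#' concentrates on the Gumbel-argmax category as the temperature c -> 0,
#' while remaining differentiable in pi for c > 0.
#'
#' @param pi probability vector (floored at 1e-12 before the log).
#' @param g_row standard Gumbel(0,1) draws, same length as `pi`.
#' @param c temperature > 0.
#' @return weight vector summing to 1.
#' @export
gumbel_softmax_sample <- function(pi, g_row, c) {
  if (c <= 0) stop("temperature must be > 0")
  s <- (log(pmax(pi, 1e-12)) + g_row) / c
  e <- exp(s - max(s))
  e / sum(e)
}

#' Soft progeny as a pair-weighted convex combination
#'
#' @param y_i weight vector over the P pairs (a simplex point).
#' @param candidates P x 2m matrix, row k the offspring generated from
#'   pair k for this progeny slot.
#' @return soft allele-score vector of length 2m, entries in [0, 1].
#' @export
soft_progeny <- function(y_i, candidates) {
  candidates <- as.matrix(candidates)
  if (length(y_i) != nrow(candidates)) stop("dimension mismatch")
  as.vector(crossprod(candidates, y_i))
}

#' Mean genotypic value of the top K individuals
#'
#' @param values numeric vector of genotypic values.
#' @param K number of top individuals, 1 <= K <= length(values).
#' @return scalar merit.
#' @export
merit_topk <- function(values, K) {
  if (K < 1L || K > length(values)) stop("K must satisfy 1 <= K <= N")
  mean(values[order(-values, seq_along(values))[seq_len(K)]])
}

# standard Gumbel(0,1) draws
rgumbel <- function(n) -log(-log(runif(n)))

#' Draw the per-generation noise of the differentiable scheme
#'
#' One Monte-Carlo replicate needs, per generation, a Gumbel matrix g
#' (N slots x P pairs) and two parity-indicator matrices (maternal- and
#' paternal-side segregation for every slot-pair candidate).  Freezing a
#' bank of such draws gives common random numbers across parameter values,
#' which finite-difference validation and the grid diagnostics rely on.
#'
#' @param map a `marker_map`.
#' @param N progeny slots per generation.
#' @param P number of mating pairs.
#' @param generations number of generations T.
#' @param n_mc number of Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list of `n_mc` replicates, each a list of T generations with
#'   elements `g`, `Hm`, `Hp`.
#' @export
draw_noise_bank <- function(map, N, P, generations, n_mc, seed) {
  set.seed(as.integer(seed))
  lapply(seq_len(n_mc), function(r)
    lapply(seq_len(generations), function(tau)
      list(g = matrix(rgumbel(N * P), N, P),
           Hm = sample_parity(map, N * P),
           Hp = sample_parity(map, N * P))))
}

# --- the differentiable forward pass -----------------------------------------

# Build one generation of the soft graph: select parents, score pairs,
# allocate softly, and convexly combine per-pair candidate offspring.
# Returns the next population node.  Discrete decisions (parent ranking,
# clustering, clamp branches) are frozen constants of the graph.
soft_generation <- function(tape, w_node, theta_node, trait, map, cfg, noise) {
  m <- map$m
  # minor allele frequencies of the population being allocated (in-graph)
  cm <- ad_colmeans(tape, w_node)
  f <- ad_scale(tape, ad_add(tape, ad_gather(tape, cm, seq_len(m)),
                             ad_gather(tape, cm, m + seq_len(m))), 0.5)
  p_node <- ad_clamp_min(tape, ad_minor(tape, f), cfg$maf_floor)
  # WBV of everyone, using the inverse-sqrt-MAF weighting
  pd <- ad_gather(tape, p_node, rep(seq_len(m), 2L))
  a_node <- ad_mul(tape, trait$alpha, ad_pow_const(tape, pd, -0.5))
  wbv_node <- ad_matvec(tape, w_node, a_node)
  # parent selection on detached values (ranking is not differentiated)
  sel <- select_parents_soft(ad_val(w_node), ad_val(wbv_node), cfg)
  n <- length(sel)
  pairs <- diallel_pairs(n)
  Wsel <- ad_gather_rows(tape, w_node, sel)
  wbv_sel <- ad_gather(tape, wbv_node, sel)
  # pair features
  feats <- list()
  if ("wbv" %in% cfg$features)
    feats$wbv <- ad_scale(tape, ad_add(tape,
                                       ad_gather(tape, wbv_sel, pairs[, 1L]),
                                       ad_gather(tape, wbv_sel, pairs[, 2L])), 0.5)
  if ("gvp" %in% cfg$features) {
    C <- gvp_kernel(trait, map)
    D <- ad_halves_diff(tape, Wsel)
    q <- ad_rowsums(tape, ad_mul(tape, ad_matmul_const(tape, D, C), D))
    feats$gvp <- ad_scale(tape, ad_add(tape,
                                       ad_gather(tape, q, pairs[, 1L]),
                                       ad_gather(tape, q, pairs[, 2L])), 0.25)
  }
  if (cfg$standardize) feats <- lapply(feats, function(x) ad_zscore(tape, x))
  # allocation softmax over pairs
  s <- NULL
  for (fidx in seq_along(feats)) {
    term <- ad_mul_scalar(tape, feats[[fidx]],
                          ad_gather(tape, theta_node, fidx))
    s <- if (is.null(s)) term else ad_add(tape, s, term)
  }
  pi_node <- ad_softmax_vec(tape, s)
  logpi <- ad_log(tape, ad_clamp_min(tape, pi_node, 1e-12))
  y <- ad_rows_softmax_affine(tape, logpi, noise$g, cfg$temperature)
  ad_soft_progeny(tape, Wsel, y, noise$Hm, noise$Hp,
                  pairs[, 1L], pairs[, 2L])
}

# z-score with the ranking-free zero-variance guard; sd uses divisor P-1
ad_zscore <- function(tape, x) {
  v <- ad_val(x)
  n <- length(v)
  if (n < 2L || stats::sd(v) < 1e-12) return(rep(0, n))
  mu <- ad_mean(tape, x)
  xc <- ad_sub(tape, x, mu)
  ss <- ad_scale(tape, ad_sum(tape, ad_mul(tape, xc, xc)), 1 / (n - 1))
  ad_div(tape, xc, ad_sqrt(tape, ss))
}

# selection on a (possibly soft) population with precomputed WBV values;
# SI2 clusters soft dosages, ranking ties broken by lower index
select_parents_soft <- function(w_val, wbv_val, cfg) {
  n_sel <- selection_size(cfg)
  if (n_sel > nrow(w_val)) stop("selection larger than population")
  if (cfg$selection == "SI2") {
    m <- ncol(w_val) %/% 2L
    dos <- w_val[, seq_len(m), drop = FALSE] + w_val[, m + seq_len(m), drop = FALSE]
    cl <- stats::cutree(stats::hclust(stats::dist(dos), method = "ward.D2"),
                        k = n_sel)
    sort(vapply(seq_len(n_sel), function(k) {
      members <- which(cl == k)
      members[order(-wbv_val[members], members)[1L]]
    }, integer(1L)))
  } else {
    top_by_wbv(wbv_val, n_sel)
  }
}

#' One differentiable forward pass of the breeding scheme
#'
#' Runs T soft generations from the founders under fixed noise draws and
#' returns the top-K merit of the final soft population together with its
#' gradients with respect to the allocation parameters, obtained by
#' reverse-mode automatic differentiation through the entire graph.  Given
#' fixed Gumbel and segregation draws (and frozen selection/ranking index
#' sets), every map from theta to F is smooth.
#'
#' @param founders a hard `population`.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param params an `allocation_params` (policy "GORA" or "EQ").
#' @param noise one replicate from [draw_noise_bank()] (list of T
#'   generations with `g`, `Hm`, `Hp`).
#' @param cfg a `scheme_config`.
#' @param want_grad compute gradients (ignored for the EQ policy).
#' @return list with `F` (scalar merit), `grad_nu` and `grad_theta`
#'   (T x d matrices, NULL for EQ or when `want_grad = FALSE`), `theta`
#'   (T x d) and `final_w` (the soft final population matrix).
#' @export
forward_scheme <- function(founders, trait, map, params, noise, cfg,
                           want_grad = TRUE) {
  stopifnot(inherits(params, "allocation_params"),
            inherits(cfg, "scheme_config"))
  T_ <- cfg$generations
  if (length(noise) != T_) stop("noise must hold one draw set per generation")
  d <- cfg$d
  tape <- ad_tape()
  lo <- params$bounds[1]; span <- diff(params$bounds)
  is_eq <- params$policy == "EQ"
  nu_nodes <- theta_nodes <- vector("list", T_)
  for (tau in seq_len(T_)) {
    if (is_eq) {
      theta_nodes[[tau]] <- rep(0, d) # constant, outside the transform
    } else {
      nu_nodes[[tau]] <- ad_input(tape, params$nu[tau, ])
      theta_nodes[[tau]] <- ad_add(tape, lo,
                                   ad_scale(tape, ad_sigmoid(tape, nu_nodes[[tau]]), span))
    }
  }
  w_node <- founders$w # constant leaf
  for (tau in seq_len(T_)) {
    w_node <- soft_generation(tape, w_node, theta_nodes[[tau]],
                              trait, map, cfg, noise[[tau]])
    if (anyNA(ad_val(w_node)) || any(!is.finite(ad_val(w_node))))
      stop("non-finite soft population at generation ", tau)
  }
  values <- ad_matvec(tape, w_node, trait$alpha)
  v <- ad_val(values)
  topk <- order(-v, seq_along(v))[seq_len(cfg$K)]
  F_node <- ad_mean(tape, ad_gather(tape, values, topk))
  grad_nu <- grad_theta <- NULL
  if (want_grad && !is_eq) {
    ad_backward(tape, F_node)
    grad_nu <- matrix(unlist(lapply(nu_nodes, function(nd)
      nd$grad %||% rep(0, d))), T_, d, byrow = TRUE)
    grad_theta <- matrix(unlist(lapply(theta_nodes, function(nd)
      nd$grad %||% rep(0, d))), T_, d, byrow = TRUE)
  }
  list(F = ad_val(F_node), grad_nu = grad_nu, grad_theta = grad_theta,
       theta = params$theta, final_w = ad_val(w_node))
}

#' Monte-Carlo expected merit and gradient
#'
#' Averages the differentiable merit and its parameter gradients over
#' `n_mc` independent noise replicates (or over a frozen bank when one is
#' supplied, giving common random numbers).
#'
#' @inheritParams forward_scheme
#' @param n_mc number of Monte-Carlo replicates (>= 1).
#' @param seed integer seed used to draw the bank when `noise_bank` is NULL.
#' @param noise_bank optional pre-drawn bank from [draw_noise_bank()].
#' @return list with `F_mean`, `grad_nu`, `grad_theta` (averaged), `n_mc`.
#' @export
expected_merit <- function(founders, trait, map, params, n_mc, seed, cfg,
                           noise_bank = NULL, want_grad = TRUE) {
  stopifnot(n_mc >= 1L)
  if (is.null(noise_bank)) {
    P <- selection_size(cfg) * (selection_size(cfg) + 1L) / 2L
    noise_bank <- draw_noise_bank(map, founders$N, P, cfg$generations,
                                  n_mc, seed)
  }
  if (length(noise_bank) < n_mc) stop("noise bank smaller than n_mc")
  Fs <- numeric(n_mc)
  gnu <- gth <- NULL
  for (r in seq_len(n_mc)) {
    res <- forward_scheme(founders, trait, map, params, noise_bank[[r]],
                          cfg, want_grad)
    Fs[r] <- res$F
    if (!is.null(res$grad_nu)) {
      gnu <- if (is.null(gnu)) res$grad_nu else gnu + res$grad_nu
      gth <- if (is.null(gth)) res$grad_theta else gth + res$grad_theta
    }
  }
  list(F_mean = mean(Fs), F_all = Fs,
       grad_nu = if (!is.null(gnu)) gnu / n_mc,
       grad_theta = if (!is.null(gth)) gth / n_mc,
       n_mc = n_mc)
}
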