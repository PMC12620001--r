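#' Bounded transform of allocation weights
#'
#' Maps the unconstrained pre-image nu to the weight domain via
#' theta = lo + (hi - lo) * logistic(nu); the default domain is
#' [0.5, 3.5].  Strictly monotone and smooth, so stochastic gradient
#' ascent can run unconstrained in nu.
#'
#' @param nu numeric (any shape).
#' @param bounds length-2 numeric, lo < hi.
#' @return theta, same shape as `nu`, strictly inside (lo, hi) for finite
#'   input.
#' @export
bounded_transform <- function(nu, bounds = c(0.5, 3.5)) {
  bounds[1] + diff(bounds) * stats::plogis(nu)
}

#' Initial-parameter presets for the allocation strategies
#'
#' GORA1 and GORA2 differ only in the initial weight on the
#' progeny-variance feature (GVP): GORA1 starts with the larger GVP
#' weight (nu_gvp = +1), GORA2 with the smaller (nu_gvp = -2); both start
#' the WBV weight at nu = 0 (theta = 2, the domain midpoint).  EQ is the
#' non-optimized equal-allocation baseline, fixing theta = 0 outside the
#' transform.
#'
#' @param name one of "GORA1", "GORA2", "EQ".
#' @param generations number of generations T.
#' @param d parameter dimension (number of features; GVP is the last).
#' @return an `allocation_params` object (initial values; EQ is final).
#' @export
strategy_preset <- function(name, generations = 4L, d = 2L) {
  switch(name,
         GORA1 = allocation_params(
           matrix(rep(c(rep(0, d - 1L), 1), each = generations),
                  generations, d)),
         GORA2 = allocation_params(
           matrix(rep(c(rep(0, d - 1L), -2), each = generations),
                  generations, d)),
         EQ = eq_params(generations, d),
         stop("unknown strategy preset: ", name))
}

#' Stochastic gradient ascent on the expected merit
#'
#' Optimizes the per-generation pre-image nu by plain SGD ascent,
#' nu <- nu + lr * dF/dnu, with fresh Monte-Carlo noise every epoch and a
#' step-decay learning-rate schedule (x `lr_decay` every
#' `lr_decay_every` epochs).  The recorded trace holds epochs + 1
#' entries: the mean merit measured at the parameters of each epoch
#' before its update, plus a final evaluation at the returned parameters.
#'
#' @param founders a hard `population`.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param init an `allocation_params` (e.g. from [strategy_preset()]);
#'   must have policy "GORA".
#' @param epochs number of SGD epochs (>= 1).
#' @param n_mc Monte-Carlo replicates per epoch.
#' @param lr initial learning rate.
#' @param lr_decay_every,lr_decay step-decay schedule (default halve every
#'   50 epochs).
#' @param seed integer seed; epoch noise is derived deterministically.
#' @param cfg a `scheme_config`.
#' @return list with `params` (optimized `allocation_params`) and `trace`
#'   (class `sgd_trace`: data.frame epoch/F_mean/lr plus `nu_history`,
#'   `theta_history` arrays of dim (epochs+1) x T x d).
#' @export
sgd_optimize <- function(founders, trait, map, init, epochs, n_mc, lr = 0.1,
                         lr_decay_every = 50L, lr_decay = 0.5, seed = 1L,
                         cfg = scheme_config()) {
  stopifnot(inherits(init, "allocation_params"), epochs >= 1L, n_mc >= 1L)
  if (init$policy != "GORA") stop("only GORA policies are optimized")
  nu <- init$nu
  T_ <- nrow(nu); d <- ncol(nu)
  F_trace <- numeric(epochs + 1L)
  lr_trace <- numeric(epochs + 1L)
  nu_hist <- array(NA_real_, c(epochs + 1L, T_, d))
  th_hist <- array(NA_real_, c(epochs + 1L, T_, d))
  cur_lr <- lr
  for (e in seq_len(epochs)) {
    if (e > 1L && (e - 1L) %% lr_decay_every == 0L) cur_lr <- cur_lr * lr_decay
    params <- allocation_params(nu, init$bounds)
    em <- expected_merit(founders, trait, map, params, n_mc,
                         child_seed(seed, paste0("epoch", e)), cfg)
    if (anyNA(em$grad_nu) || any(!is.finite(em$grad_nu)))
      stop("non-finite gradient at epoch ", e)
    F_trace[e] <- em$F_mean
    lr_trace[e] <- cur_lr
    nu_hist[e, , ] <- nu
    th_hist[e, , ] <- params$theta
    nu <- nu + cur_lr * em$grad_nu
  }
  params <- allocation_params(nu, init$bounds)
  em <- expected_merit(founders, trait, map, params, n_mc,
                       child_seed(seed, "final"), cfg, want_grad = FALSE)
  F_trace[epochs + 1L] <- em$F_mean
  lr_trace[epochs + 1L] <- cur_lr
  nu_hist[epochs + 1L, , ] <- nu
  th_hist[epochs + 1L, , ] <- params$theta
  trace <- structure(list(
    epoch = 0:epochs, F_mean = F_trace, lr = lr_trace,
    nu_history = nu_hist, theta_history = th_hist, seed = seed),
    class = "sgd_trace")
  list(params = params, trace = trace)
}

#' @export
print.sgd_trace <- function(x, ...) {
  cat(sprintf("SGD trace: %d epochs, F_mean %.4f -> %.4f\n",
              length(x$epoch) - 1L, x$F_mean[1L],
              x$F_mean[length(x$F_mean)]))
  invisible(x)
}
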