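#' Finite-difference validation of the reverse-mode gradients
#'
#' Compares the automatic-differentiation gradient of the Monte-Carlo mean
#' merit with central finite differences in the pre-image nu, component by
#' component, under common random numbers (one frozen noise bank is reused
#' for the base point and every perturbed evaluation, so the compared
#' quantity is the same deterministic function).
#'
#' @param founders a hard `population`.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param params an `allocation_params` with policy "GORA".
#' @param h central-difference step (>= 1e-7; smaller steps drown in
#'   floating-point cancellation).
#' @param n_mc Monte-Carlo replicates.
#' @param seed integer seed for the frozen bank.
#' @param cfg a `scheme_config`.
#' @return list with `max_rel_error` (over components with |FD| > 1e-8),
#'   `grad_ad`, `grad_fd` (T x d matrices) and `F_mean`.
#' @export
finite_difference_check <- function(founders, trait, map, params, h = 1e-3,
                                    n_mc = 20L, seed = 1L,
                                    cfg = scheme_config()) {
  if (h < 1e-7) stop("h too small for double precision (must be >= 1e-7)")
  if (params$policy != "GORA") stop("gradients exist only for GORA policies")
  P <- selection_size(cfg) * (selection_size(cfg) + 1L) / 2L
  bank <- draw_noise_bank(map, founders$N, P, cfg$generations, n_mc, seed)
  base <- expected_merit(founders, trait, map, params, n_mc, seed, cfg,
                         noise_bank = bank)
  nu <- params$nu
  grad_fd <- matrix(NA_real_, nrow(nu), ncol(nu))
  for (tau in seq_len(nrow(nu))) {
    for (j in seq_len(ncol(nu))) {
      nup <- num <- nu
      nup[tau, j] <- nu[tau, j] + h
      num[tau, j] <- nu[tau, j] - h
      Fp <- expected_merit(founders, trait, map,
                           allocation_params(nup, params$bounds),
                           n_mc, seed, cfg, noise_bank = bank,
                           want_grad = FALSE)$F_mean
      Fm <- expected_merit(founders, trait, map,
                           allocation_params(num, params$bounds),
                           n_mc, seed, cfg, noise_bank = bank,
                           want_grad = FALSE)$F_mean
      grad_fd[tau, j] <- (Fp - Fm) / (2 * h)
    }
  }
  keep <- abs(grad_fd) > 1e-8
  rel <- abs(base$grad_nu - grad_fd) / pmax(abs(grad_fd), 1e-12)
  list(max_rel_error = if (any(keep)) max(rel[keep]) else 0,
       grad_ad = base$grad_nu, grad_fd = grad_fd, F_mean = base$F_mean)
}

#' Grid field of merit values and gradients over two parameters
#'
#' Evaluates the Monte-Carlo mean merit and its nu-gradients on a regular
#' lattice spanned by two free parameter axes (a generation index plus a
#' feature), all other parameters held fixed.  `divisions` intervals per
#' axis give (divisions + 1)^2 nodes.  One frozen noise bank is reused at
#' every node, so the field is a deterministic surface suitable for
#' quiver/heat-map rendering of the gradient flow.
#'
#' @param founders a hard `population`.
#' @param trait a `trait_arch`.
#' @param map a `marker_map`.
#' @param axes list of two axis specs, each
#'   `list(generation = <1-based tau>, feature = <1-based column>,
#'   range = c(lo, hi))` in the nu domain.
#' @param base_nu T x d matrix of fixed nu values for the non-free
#'   parameters.
#' @param divisions intervals per axis (default 50, i.e. 2601 nodes).
#' @param n_mc Monte-Carlo replicates per node.
#' @param seed integer seed for the frozen bank.
#' @param cfg a `scheme_config`.
#' @return object of class `grad_field`: data.frame `grid` with columns
#'   nu1, nu2, F, dF_dnu1, dF_dnu2, plus `axes` and `divisions`.
#' @export
grid_gradient_field <- function(founders, trait, map, axes, base_nu,
                                divisions = 50L, n_mc = 20L, seed = 1L,
                                cfg = scheme_config()) {
  stopifnot(length(axes) == 2L, divisions >= 1L)
  for (ax in axes)
    if (ax$range[1] >= ax$range[2]) stop("axis domain must be non-empty")
  P <- selection_size(cfg) * (selection_size(cfg) + 1L) / 2L
  bank <- draw_noise_bank(map, founders$N, P, cfg$generations, n_mc, seed)
  grid1 <- seq(axes[[1L]]$range[1], axes[[1L]]$range[2], length.out = divisions + 1L)
  grid2 <- seq(axes[[2L]]$range[1], axes[[2L]]$range[2], length.out = divisions + 1L)
  nodes <- expand.grid(nu1 = grid1, nu2 = grid2, KEEP.OUT.ATTRS = FALSE)
  out <- matrix(NA_real_, nrow(nodes), 3L)
  for (i in seq_len(nrow(nodes))) {
    nu <- base_nu
    nu[axes[[1L]]$generation, axes[[1L]]$feature] <- nodes$nu1[i]
    nu[axes[[2L]]$generation, axes[[2L]]$feature] <- nodes$nu2[i]
    em <- expected_merit(founders, trait, map, allocation_params(nu),
                         n_mc, seed, cfg, noise_bank = bank)
    out[i, ] <- c(em$F_mean,
                  em$grad_nu[axes[[1L]]$generation, axes[[1L]]$feature],
                  em$grad_nu[axes[[2L]]$generation, axes[[2L]]$feature])
  }
  grid <- cbind(nodes, F = out[, 1L], dF_dnu1 = out[, 2L], dF_dnu2 = out[, 3L])
  structure(list(grid = grid, axes = axes, divisions = divisions,
                 n_mc = n_mc, seed = seed),
            class = "grad_field")
}

#' @export
print.grad_field <- function(x, ...) {
  cat(sprintf("grad_field: %d nodes (%d divisions per axis), F in [%.3f, %.3f]\n",
              nrow(x$grid), x$divisions, min(x$grid$F), max(x$grid$F)))
  invisible(x)
}
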