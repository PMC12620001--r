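# Minimal reverse-mode automatic differentiation on a tape.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; the tape records creation order, which is a valid
# topological order for the reverse sweep.  Operands may be nodes or plain
# numerics (treated as constants).  Elementwise ops broadcast length-1
# scalars; all other shapes must match exactly.  Discrete decisions
# (rankings, clamping branches, argmax) are frozen at forward time, so the
# graph is smooth in its parameters given fixed noise.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

is_node <- function(x) is.environment(x) && !is.null(x[["ad_value"]])

ad_val <- function(x) if (is_node(x)) x$ad_value else x

ad_node <- function(tape, value, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$ad_value <- value
  nd$grad <- NULL
  nd$backfn <- backfn
  n <- tape$n + 1L
  if (n > length(tape$nodes)) # grow geometrically
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# leaf with gradient tracking (an optimization parameter)
ad_input <- function(tape, value) ad_node(tape, value)

ad_accum <- function(nd, g) {
  if (!is_node(nd)) return(invisible())
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible()
}

# reverse sweep from a scalar output node
ad_backward <- function(tape, out) {
  stopifnot(length(ad_val(out)) == 1L)
  for (i in seq_len(tape$n)) tape$nodes[[i]]$grad <- NULL
  out$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backfn)) nd$backfn(nd$grad)
  }
  invisible()
}

# --- elementwise arithmetic (scalar broadcast) -------------------------------

# reduce a broadcast gradient back to the operand's shape
ad_reduce_to <- function(g, v) {
  if (length(v) == 1L && length(g) > 1L) sum(g) else g
}

ad_add <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va + vb, function(g) {
    ad_accum(a, ad_reduce_to(g, va))
    ad_accum(b, ad_reduce_to(g, vb))
  })
}

ad_sub <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va - vb, function(g) {
    ad_accum(a, ad_reduce_to(g, va))
    ad_accum(b, ad_reduce_to(-g, vb))
  })
}

ad_mul <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va * vb, function(g) {
    ad_accum(a, ad_reduce_to(g * vb, va))
    ad_accum(b, ad_reduce_to(g * va, vb))
  })
}

ad_div <- function(tape, a, b) {
  va <- ad_val(a); vb <- ad_val(b)
  ad_node(tape, va / vb, function(g) {
    ad_accum(a, ad_reduce_to(g / vb, va))
    ad_accum(b, ad_reduce_to(-g * va / (vb * vb), vb))
  })
}

ad_scale <- function(tape, a, s) { # s plain numeric scalar
  va <- ad_val(a)
  ad_node(tape, va * s, function(g) ad_accum(a, g * s))
}

ad_exp <- function(tape, a) {
  v <- exp(ad_val(a))
  ad_node(tape, v, function(g) ad_accum(a, g * v))
}

ad_log <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, log(va), function(g) ad_accum(a, g / va))
}

ad_sqrt <- function(tape, a) {
  v <- sqrt(ad_val(a))
  ad_node(tape, v, function(g) ad_accum(a, g / (2 * v)))
}

ad_pow_const <- function(tape, a, p) {
  va <- ad_val(a)
  ad_node(tape, va^p, function(g) ad_accum(a, g * p * va^(p - 1)))
}

ad_sigmoid <- function(tape, a) {
  v <- stats::plogis(ad_val(a))
  ad_node(tape, v, function(g) ad_accum(a, g * v * (1 - v)))
}

# max(x, eps); gradient passes only where x > eps (branch fixed forward)
ad_clamp_min <- function(tape, a, eps) {
  va <- ad_val(a)
  open <- va > eps
  ad_node(tape, pmax(va, eps), function(g) ad_accum(a, g * open))
}

# minor frequency min(f, 1 - f); branch fixed at forward time
ad_minor <- function(tape, a) {
  va <- ad_val(a)
  lower <- va <= 0.5
  ad_node(tape, pmin(va, 1 - va),
          function(g) ad_accum(a, ifelse(lower, g, -g)))
}

# --- reductions and linear algebra -------------------------------------------

ad_full_like <- function(v, g) {
  if (is.matrix(v)) matrix(g, nrow(v), ncol(v)) else rep(g, length(v))
}

ad_sum <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, sum(va), function(g) ad_accum(a, ad_full_like(va, g)))
}

ad_mean <- function(tape, a) {
  va <- ad_val(a); n <- length(va)
  ad_node(tape, mean(va), function(g) ad_accum(a, ad_full_like(va, g / n)))
}

ad_rowsums <- function(tape, a) {
  va <- ad_val(a)
  ad_node(tape, rowSums(va), function(g)
    ad_accum(a, matrix(g, nrow(va), ncol(va))))
}

ad_colmeans <- function(tape, a) {
  va <- ad_val(a); n <- nrow(va)
  ad_node(tape, colMeans(va), function(g)
    ad_accum(a, matrix(g / n, n, ncol(va), byrow = TRUE)))
}

# W %*% v with either operand differentiable
ad_matvec <- function(tape, W, v) {
  vW <- ad_val(W); vv <- ad_val(v)
  ad_node(tape, as.vector(vW %*% vv), function(g) {
    if (is_node(W)) ad_accum(W, outer(g, vv))
    if (is_node(v)) ad_accum(v, as.vector(crossprod(vW, g)))
  })
}

# A %*% B with constant B
ad_matmul_const <- function(tape, A, B) {
  vA <- ad_val(A)
  ad_node(tape, vA %*% B, function(g) ad_accum(A, g %*% t(B)))
}

# scalar-node times vector
ad_mul_scalar <- function(tape, v, s) {
  vv <- ad_val(v); vs <- ad_val(s)
  stopifnot(length(vs) == 1L)
  ad_node(tape, vv * vs, function(g) {
    ad_accum(v, g * vs)
    ad_accum(s, sum(g * vv))
  })
}

# --- gathers -----------------------------------------------------------------

ad_gather <- function(tape, v, idx) {
  vv <- ad_val(v)
  ad_node(tape, vv[idx], function(g) {
    acc <- numeric(length(vv))
    # accumulate duplicates (idx may repeat)
    tab <- rowsum(as.numeric(g), group = idx)
    acc[as.integer(rownames(tab))] <- tab[, 1L]
    ad_accum(v, acc)
  })
}

ad_gather_rows <- function(tape, M, idx) {
  vM <- ad_val(M)
  ad_node(tape, vM[idx, , drop = FALSE], function(g) {
    acc <- matrix(0, nrow(vM), ncol(vM))
    tab <- rowsum(g, group = idx)
    acc[as.integer(rownames(tab)), ] <- tab
    ad_accum(M, acc)
  })
}

# first-half minus second-half columns of an N x 2m matrix
ad_halves_diff <- function(tape, M) {
  vM <- ad_val(M); m <- ncol(vM) %/% 2L
  ad_node(tape, vM[, seq_len(m), drop = FALSE] - vM[, m + seq_len(m), drop = FALSE],
          function(g) ad_accum(M, cbind(g, -g)))
}

# --- softmax family ----------------------------------------------------------

ad_softmax_vec <- function(tape, s) {
  vs <- ad_val(s)
  e <- exp(vs - max(vs))
  p <- e / sum(e)
  ad_node(tape, p, function(g) ad_accum(s, p * (g - sum(g * p))))
}

# row-wise softmax of (G + logpi[col]) / c with constant Gumbel matrix G;
# this is the Gumbel-Softmax relaxation applied to every progeny slot at once
ad_rows_softmax_affine <- function(tape, logpi, G, c) {
  vl <- ad_val(logpi)
  S <- sweep(G, 2L, vl, "+") / c
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  Y <- E / rowSums(E)
  ad_node(tape, Y, function(g) {
    dS <- Y * (g - rowSums(g * Y))
    ad_accum(logpi, colSums(dS) / c)
  })
}

# --- soft progeny (C++ kernels) ----------------------------------------------

# One candidate offspring per (slot, pair) with fixed parity draws, convexly
# combined by the Gumbel-Softmax weights.  W: n x 2m parents (node), y: N x P
# weights (node); Hm/Hp: (N*P) x m parity constants; kM/kP: 1-based pair
# parent indices.
ad_soft_progeny <- function(tape, W, y, Hm, Hp, kM, kP) {
  vW <- ad_val(W); vy <- ad_val(y)
  fw <- cpp_soft_progeny_forward(vW, vy, Hm, Hp, kM - 1L, kP - 1L)
  ad_node(tape, fw$wsoft, function(g) {
    bw <- cpp_soft_progeny_backward(g, vW, vy, Hm, Hp, fw$gamM, fw$gamP,
                                    kM - 1L, kP - 1L)
    ad_accum(W, bw$dW)
    ad_accum(y, bw$dy)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
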