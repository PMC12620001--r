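test_that("gradient check is null on a flat landscape and guards its step", {
  map <- build_marker_map(c(3, 3), spacing_cM = 10)
  f <- new_population(matrix(1, 10, 12)) # monomorphic: constant merit
  tr <- sample_trait(map, 5)
  cfg <- scheme_config(generations = 1, K = 2, selection = "SI1", n_parents = 3)
  init <- strategy_preset("GORA2", 1)
  res <- finite_difference_check(f, tr, map, init, h = 1e-3, n_mc = 3,
                                 seed = 6, cfg = cfg)
  expect_equal(max(abs(res$grad_ad)), 0)
  expect_equal(max(abs(res$grad_fd)), 0)
  expect_equal(res$max_rel_error, 0)
  expect_error(finite_difference_check(f, tr, map, init, h = 1e-8,
                                       n_mc = 2, seed = 6, cfg = cfg),
               "1e-7")
  expect_error(finite_difference_check(f, tr, map, eq_params(1), h = 1e-3,
                                       n_mc = 2, seed = 6, cfg = cfg),
               "GORA")
})

test_that("common random numbers are what make the comparison tight", {
  map <- build_marker_map(c(4, 4), spacing_cM = 12)
  f <- simulate_founders(map, 12, seed = 11)
  tr <- sample_trait(map, 12)
  cfg <- scheme_config(generations = 1, K = 3, selection = "SI1", n_parents = 4)
  init <- allocation_params(matrix(c(0.5, -0.5), 1, 2))
  crn <- finite_difference_check(f, tr, map, init, h = 1e-3, n_mc = 10,
                                 seed = 13, cfg = cfg)
  # recompute the finite differences with independent noise per evaluation:
  # the difference of two noisy means at step 2h is dominated by MC error
  h <- 1e-3
  grad_fd_free <- matrix(NA_real_, 1, 2)
  for (j in 1:2) {
    nup <- num <- init$nu
    nup[1, j] <- nup[1, j] + h
    num[1, j] <- num[1, j] - h
    Fp <- expected_merit(f, tr, map, allocation_params(nup), 10, 1000 + j,
                         cfg, want_grad = FALSE)$F_mean
    Fm <- expected_merit(f, tr, map, allocation_params(num), 10, 2000 + j,
                         cfg, want_grad = FALSE)$F_mean
    grad_fd_free[1, j] <- (Fp - Fm) / (2 * h)
  }
  err_crn <- max(abs(crn$grad_ad - crn$grad_fd))
  err_free <- max(abs(crn$grad_ad - grad_fd_free))
  expect_lt(err_crn, err_free)
})

test_that("grid field covers the requested lattice exactly", {
  map <- build_marker_map(c(3, 3), spacing_cM = 10)
  f <- simulate_founders(map, 8, seed = 21)
  tr <- sample_trait(map, 22)
  cfg <- scheme_config(generations = 1, K = 2, selection = "SI1", n_parents = 3)
  axes <- list(list(generation = 1, feature = 1, range = c(-3, 2)),
               list(generation = 1, feature = 2, range = c(-5, 0)))
  field <- grid_gradient_field(f, tr, map, axes, matrix(0, 1, 2),
                               divisions = 1, n_mc = 2, seed = 23, cfg = cfg)
  expect_equal(nrow(field$grid), 4)
  expect_setequal(field$grid$nu1, c(-3, 2))
  expect_setequal(field$grid$nu2, c(-5, 0))
  expect_true(all(is.finite(field$grid$F)))
  expect_error(grid_gradient_field(f, tr, map,
                                   list(axes[[1]],
                                        list(generation = 1, feature = 2,
                                             range = c(0, 0))),
                                   matrix(0, 1, 2), divisions = 1,
                                   n_mc = 2, seed = 23, cfg = cfg),
               "non-empty")
})

test_that("grid gradients are consistent with the field's own differences", {
  # deterministic surface under a frozen noise bank: the stored gradients
  # must predict the sign of adjacent-node value differences wherever the
  # difference is appreciable
  map <- build_marker_map(c(4, 4), spacing_cM = 10)
  f <- simulate_founders(map, 14, seed = 31)
  tr <- sample_trait(map, 32)
  cfg <- scheme_config(generations = 1, K = 3, selection = "SI1", n_parents = 4)
  divisions <- 6
  axes <- list(list(generation = 1, feature = 1, range = c(-3, 2)),
               list(generation = 1, feature = 2, range = c(-5, 0)))
  field <- grid_gradient_field(f, tr, map, axes, matrix(0, 1, 2),
                               divisions = divisions, n_mc = 10, seed = 33,
                               cfg = cfg)
  g <- field$grid
  n1 <- divisions + 1
  idx <- function(i, j) (j - 1) * n1 + i # nu1 varies fastest
  checked <- agreed <- 0
  scale <- stats::sd(g$F)
  for (j in seq_len(n1)) {
    for (i in seq_len(n1 - 1)) {
      dF <- g$F[idx(i + 1, j)] - g$F[idx(i, j)]
      if (abs(dF) > 0.05 * scale) {
        checked <- checked + 1
        mean_grad <- (g$dF_dnu1[idx(i + 1, j)] + g$dF_dnu1[idx(i, j)]) / 2
        agreed <- agreed + (sign(mean_grad) == sign(dF))
      }
    }
  }
  expect_gt(checked, 10)
  expect_gt(agreed / checked, 0.7)
})

test_that("gradient arrows point toward a smoothed local maximum", {
  # two-generation scheme allocating on WBV only: moderate early weight and
  # high late weight can dominate both extremes, which puts the (smoothed)
  # optimum in the interior of the grid for this instance
  map <- build_marker_map(c(4, 4), spacing_cM = 10)
  f <- simulate_founders(map, 20, seed = 31)
  tr <- sample_trait(map, 32)
  cfg <- scheme_config(generations = 2, K = 3, selection = "SI1",
                       n_parents = 5, features = "wbv")
  divisions <- 6
  axes <- list(list(generation = 1, feature = 1, range = c(-3, 2)),
               list(generation = 2, feature = 1, range = c(-3, 2)))
  field <- grid_gradient_field(f, tr, map, axes, matrix(0, 2, 1),
                               divisions = divisions, n_mc = 20, seed = 33,
                               cfg = cfg)
  g <- field$grid
  n1 <- divisions + 1
  Fm <- matrix(g$F, n1, n1) # nu1 along rows
  # 3x3 box smoothing of the interior
  S <- matrix(NA_real_, n1, n1)
  for (i in 2:(n1 - 1)) for (j in 2:(n1 - 1))
    S[i, j] <- mean(Fm[(i - 1):(i + 1), (j - 1):(j + 1)])
  peak <- which(S == max(S, na.rm = TRUE), arr.ind = TRUE)[1, ]
  ok <- tot <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    i <- peak[1] + di; j <- peak[2] + dj
    node <- (j - 1) * n1 + i
    dir <- c(-di, -dj) # toward the peak
    dp <- g$dF_dnu1[node] * dir[1] + g$dF_dnu2[node] * dir[2]
    tot <- tot + 1
    ok <- ok + (dp >= 0)
  }
  expect_gte(ok / tot, 0.8)
})
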