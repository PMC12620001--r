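test_that("allocation softmax reduces to known closed forms", {
  omega <- matrix(rnorm(10), 5, 2)
  # theta = 0: uniform over pairs (the equal-allocation policy)
  expect_equal(allocation_probs(omega, c(0, 0)), rep(0.2, 5))

  # scores (ln 2, 0) -> (2/3, 1/3)
  omega2 <- matrix(c(log(2), 0), 2, 1)
  expect_equal(allocation_probs(omega2, 1), c(2/3, 1/3))

  # shift invariance: adding a constant to every score changes nothing
  om <- matrix(rnorm(8), 4, 2)
  th <- c(1.3, -0.7)
  expect_equal(allocation_probs(om, th),
               allocation_probs(om + 5, th) , tolerance = 1e-12)
  expect_error(allocation_probs(matrix(NA_real_, 2, 1), 1), "NaN")
})

test_that("Gumbel-Softmax weights are simplex points that sharpen", {
  set.seed(15)
  for (i in 1:20) {
    pi <- as.vector(allocation_probs(matrix(rnorm(12), 6, 2), rnorm(2)))
    y <- gumbel_softmax_sample(pi, breedgrad:::rgumbel(6), c = 0.7)
    expect_equal(sum(y), 1, tolerance = 1e-9)
    expect_true(all(y >= 0))
  }
  # near-zero temperature: one-hot at the Gumbel argmax
  y0 <- gumbel_softmax_sample(c(0.5, 0.5), c(0.1, -0.2), c = 1e-6)
  expect_equal(y0, c(1, 0), tolerance = 1e-9)
  # symmetric ties at c = 1 stay uniform
  expect_equal(gumbel_softmax_sample(c(0.5, 0.5), c(0, 0), c = 1),
               c(0.5, 0.5))
  expect_error(gumbel_softmax_sample(c(0.5, 0.5), c(0, 0), c = 0), "temperature")
})

test_that("soft progeny is the pair-weighted convex combination", {
  cand <- rbind(c(1, 0, 1, 1), c(0, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(soft_progeny(c(0, 1, 0), cand), c(0, 1, 0, 0))
  expect_equal(soft_progeny(c(0.5, 0.5), cand[1:2, ]),
               c(0.5, 0.5, 0.5, 0.5))
  same <- rbind(c(1, 0), c(1, 0))
  expect_equal(soft_progeny(c(0.3, 0.7), same), c(1, 0))
})

test_that("top-K merit matches the sort oracle", {
  expect_equal(merit_topk(c(3, 1, 2), 2), 2.5)
  v <- rnorm(30)
  expect_equal(merit_topk(v, 30), mean(v))
  set.seed(25)
  for (i in 1:10) {
    v <- rnorm(40)
    expect_equal(merit_topk(v, 5), mean(sort(v, decreasing = TRUE)[1:5]))
  }
  expect_error(merit_topk(v, 0), "K")
  expect_error(merit_topk(v, 41), "K")
})

test_that("soft populations stay inside [0,1] and merit dominates the mean", {
  map <- build_marker_map(c(5, 5), spacing_cM = 8)
  f <- simulate_founders(map, 16, seed = 55)
  tr <- sample_trait(map, 56)
  cfg <- scheme_config(generations = 2, K = 4, selection = "SI1", n_parents = 5)
  P <- 15
  bank <- draw_noise_bank(map, f$N, P, 2, 1, seed = 57)
  res <- forward_scheme(f, tr, map, strategy_preset("GORA2", 2), bank[[1]], cfg)
  expect_true(all(res$final_w >= 0 & res$final_w <= 1))
  vals <- genotypic_values(res$final_w, tr)
  expect_gte(res$F, mean(vals))
  expect_equal(res$F, merit_topk(vals, 4))
})

test_that("near-zero temperature recovers the hard argmax-pair progeny", {
  map <- build_marker_map(c(4, 4), spacing_cM = 10)
  f <- simulate_founders(map, 10, seed = 61)
  tr <- sample_trait(map, 62)
  cfg <- scheme_config(generations = 1, K = 3, selection = "SI1",
                       n_parents = 4, temperature = 1e-6)
  n <- 4; P <- 10
  bank <- draw_noise_bank(map, f$N, P, 1, 1, seed = 63)
  params <- strategy_preset("GORA2", 1)
  res <- forward_scheme(f, tr, map, params, bank[[1]], cfg)
  # reconstruct the hard candidates from the same frozen noise
  p <- minor_allele_freq(f$w, 0.01)
  sel <- select_si1(f$w, tr, p, n = n)$indices
  feats <- assemble_features(f$w, sel, tr, map, p)
  pi <- allocation_probs(feats, bounded_transform(params$nu[1, ]))
  noise <- bank[[1]][[1]]
  for (i in seq_len(f$N)) {
    k_star <- which.max((log(pi) + noise$g[i, ]) / 1e-6)
    kM <- feats$pairs[k_star, 1]; kP <- feats$pairs[k_star, 2]
    rowk <- i + f$N * (k_star - 1)
    gm <- breedgrad:::gametes_from_parity(f$w[sel[kM], ],
                                          noise$Hm[rowk, , drop = FALSE], map$m)
    gp <- breedgrad:::gametes_from_parity(f$w[sel[kP], ],
                                          noise$Hp[rowk, , drop = FALSE], map$m)
    expect_equal(res$final_w[i, ], unname(c(gm, gp)), tolerance = 1e-6)
  }
})

test_that("reverse-mode gradients match central finite differences", {
  map <- build_marker_map(c(4, 4), spacing_cM = 12)
  f <- simulate_founders(map, 12, seed = 71)
  tr <- sample_trait(map, 72)
  cfg <- scheme_config(generations = 2, K = 3, selection = "SI1", n_parents = 4)
  set.seed(73)
  init <- allocation_params(matrix(rnorm(4, sd = 0.5), 2, 2))
  res <- finite_difference_check(f, tr, map, init, h = 1e-3, n_mc = 5,
                                 seed = 74, cfg = cfg)
  expect_lt(res$max_rel_error, 1e-3)
  # gradients are non-trivial on this instance
  expect_gt(max(abs(res$grad_ad)), 1e-4)
})

test_that("theta = 0 soft simulation agrees with the hard equal allocation", {
  map <- build_marker_map(c(5, 5), spacing_cM = 10)
  f <- simulate_founders(map, 20, seed = 81)
  tr <- sample_trait(map, 82)
  cfg_soft <- scheme_config(generations = 2, K = 5, selection = "SI1",
                            n_parents = 5, temperature = 1e-4)
  cfg_hard <- scheme_config(generations = 2, K = 5, selection = "SI1",
                            n_parents = 5)
  eq <- eq_params(2)
  n_rep <- 300
  P <- 15
  bank <- draw_noise_bank(map, f$N, P, 2, n_rep, seed = 83)
  F_soft <- vapply(seq_len(n_rep), function(r)
    forward_scheme(f, tr, map, eq, bank[[r]], cfg_soft, want_grad = FALSE)$F,
    numeric(1))
  F_hard <- vapply(seq_len(n_rep), function(r) {
    pops <- simulate_scheme_hard(f, tr, map, eq, cfg_hard,
                                 seed = child_seed(84, paste0("r", r)))
    merit_topk(genotypic_values(pops[[3]], tr), 5)
  }, numeric(1))
  se <- sqrt(var(F_soft) / n_rep + var(F_hard) / n_rep)
  expect_lt(abs(mean(F_soft) - mean(F_hard)), 4 * se)
})

test_that("Monte-Carlo expected merit is reproducible and concentrates", {
  map <- build_marker_map(c(4, 4), spacing_cM = 10)
  f <- simulate_founders(map, 12, seed = 91)
  tr <- sample_trait(map, 92)
  cfg <- scheme_config(generations = 1, K = 3, selection = "SI1", n_parents = 4)
  params <- strategy_preset("GORA1", 1)
  em1 <- expected_merit(f, tr, map, params, n_mc = 3, seed = 93, cfg)
  em2 <- expected_merit(f, tr, map, params, n_mc = 3, seed = 93, cfg)
  expect_identical(em1$F_mean, em2$F_mean)
  expect_identical(em1$grad_nu, em2$grad_nu)

  # n_mc = 1 reduces to a single forward pass on the same bank
  P <- 10
  bank <- draw_noise_bank(map, f$N, P, 1, 1, seed = 94)
  em3 <- expected_merit(f, tr, map, params, 1, 94, cfg, noise_bank = bank)
  fw <- forward_scheme(f, tr, map, params, bank[[1]], cfg)
  expect_equal(em3$F_mean, fw$F)

  # variance of the n_mc-mean shrinks roughly like 1/n_mc
  big <- expected_merit(f, tr, map, params, n_mc = 400, seed = 95, cfg,
                        want_grad = FALSE)
  v10 <- var(colMeans(matrix(big$F_all, 10)))
  v40 <- var(colMeans(matrix(big$F_all, 40)))
  expect_gt(v10 / v40, 2) # theoretical ratio 4, generous band
})
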