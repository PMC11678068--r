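test_that("nearest-neighbour smoothing hits its boundary cases", {
  set.seed(3)
  x <- rnorm(50); z <- rnorm(50)
  expect_equal(rank_nearest_smooth(x, z, m = 50), rep(mean(x), 50))
  expect_equal(rank_nearest_smooth(x, z, m = 1), x)  # self is nearest
  expect_equal(rank_nearest_smooth(c(1, 2, 3, 10), c(1, 2, 3, 10), m = 3)[1],
               mean(c(1, 2, 3)))
  expect_error(rank_nearest_smooth(x, z, m = 51), "at least m")
})

test_that("smoothing is permutation-equivariant", {
  set.seed(4)
  x <- rnorm(120); z <- rnorm(120)
  xs <- rank_nearest_smooth(x, z, m = 10)
  perm <- sample.int(120)
  xs_perm <- rank_nearest_smooth(x[perm], z[perm], m = 10)
  expect_equal(xs_perm, xs[perm])
})

test_that("correlation matrices show attenuation before and recovery after smoothing", {
  d <- simulate_xyz(3, 0, seed = 1)
  cm0 <- correlation_matrices(d$x, d$y, d$z, m = 2)
  expect_equal(unname(cm0$old_cor), matrix(1, 3, 3))  # x = y = z

  set.seed(6)
  indep <- list(x = rnorm(10000), y = rnorm(10000), z = rnorm(10000))
  raw <- cor(cbind(indep$x, indep$y, indep$z))
  expect_true(all(abs(raw[upper.tri(raw)]) < 0.05))

  d2 <- simulate_xyz(5000, noise_sd = 3, seed = 11)
  cm <- correlation_matrices(d2$x, d2$y, d2$z, m = 100)
  expect_lt(abs(cm$old_cor["x", "y"]), 0.3)
  expect_gt(cm$new_cor["xs", "ys"], 0.8)
})

test_that("the simulation model matches its closed-form correlation", {
  d <- simulate_xyz(6, 0, seed = 2)
  expect_equal(d$x, d$z)
  expect_equal(d$y, d$z)
  expect_identical(simulate_xyz(100, 1, seed = 9), simulate_xyz(100, 1, seed = 9))

  n <- 20000; s <- 1.5
  d2 <- simulate_xyz(n, s, seed = 13)
  rho <- 1 / (1 + s^2)          # population cor(x, y) for f = g = identity
  se <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(cor(d2$x, d2$y) - rho), 3 * se)
})

test_that("the exhaustive permutation test reproduces hand-enumerated cases", {
  r <- perm_cor_diff_test(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3))
  expect_equal(r$diff, 2)
  expect_equal(r$p, 0.25)     # 2 of the 8 assignments reach diff = 2
  expect_true(r$exhaustive)
  expect_equal(r$n_perm, 8L)

  set.seed(14)
  z <- rnorm(6); x <- rnorm(6)
  same <- perm_cor_diff_test(x, x, z)
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  expect_true(all(same$perm_diffs == 0))
})

test_that("the exhaustive permutation distribution is antisymmetric with 2^-n p-values", {
  set.seed(15)
  x <- rnorm(8); y <- rnorm(8); z <- rnorm(8)
  r <- perm_cor_diff_test(x, y, z)
  expect_equal(r$n_perm, 256L)
  expect_equal(mean(r$perm_diffs), 0, tolerance = 1e-12)
  expect_equal(sort(r$perm_diffs), sort(-r$perm_diffs), tolerance = 1e-12)
  expect_equal(r$p * 2^8, round(r$p * 2^8), tolerance = 1e-9)
  # the sampled path engages beyond the cap and is seed-reproducible
  s1 <- perm_cor_diff_test(x, y, z, cap = 100, seed = 5)
  s2 <- perm_cor_diff_test(x, y, z, cap = 100, seed = 5)
  expect_false(s1$exhaustive)
  expect_equal(s1$n_perm, 100L)
  expect_identical(s1$perm_diffs, s2$perm_diffs)
})

test_that("literal mode reproduces the concatenation construction", {
  x <- c(1, 2, 3); y <- c(2, 1, 4); z <- c(3, 1, 2)
  r <- perm_cor_diff_test(x, y, z, mode = "literal")
  # independent re-derivation of the 8 concatenated differences
  combs <- expand.grid(rep(list(c(TRUE, FALSE)), 3))
  want <- apply(combs, 1, function(s) {
    cor(c(x[s], y[!s]), z) - cor(c(x[!s], y[s]), z)
  })
  expect_equal(sort(r$perm_diffs), sort(want), tolerance = 1e-12)
  expect_error(perm_cor_diff_test(c(1, 1, 1), y, z), "variance")
  expect_error(perm_cor_diff_test(1:2, 1:2, 1:2), "at least 3")
})

test_that("the sign-adaptive p-value doubles the one-sided rejection rate", {
  # under pairwise exchangeability the adaptive rule rejects at ~2 * alpha,
  # while a fixed a-priori direction holds the nominal level
  set.seed(16)
  n_rep <- 400
  p_auto <- p_fixed <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    r_auto <- perm_cor_diff_test(x, y, z)
    r_fixed <- perm_cor_diff_test(x, y, z, alternative = "greater")
    p_auto[i] <- r_auto$p
    p_fixed[i] <- r_fixed$p
  }
  expect_gt(mean(p_auto <= 0.05), 0.06)   # anti-conservative
  expect_lt(mean(p_auto <= 0.05), 0.16)
  expect_gt(mean(p_fixed <= 0.05), 0.02)  # calibrated
  expect_lt(mean(p_fixed <= 0.05), 0.08)
})
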