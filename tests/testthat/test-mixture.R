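test_that("mode counting distinguishes one from two well-separated Gaussians", {
  one_ok <- 0L; two_ok <- 0L
  for (s in 1:20) {
    set.seed(s)
    x1 <- rnorm(5000)
    if (count_modes(x1)$n_modes == 1L) one_ok <- one_ok + 1L
    set.seed(s + 1000)
    x2 <- c(rnorm(2500), rnorm(2500, mean = 8))  # 8 pooled SDs apart
    if (count_modes(x2)$n_modes == 2L) two_ok <- two_ok + 1L
  }
  expect_gte(one_ok, 18L)
  expect_gte(two_ok, 18L)
})

test_that("mode counting handles degenerate and small inputs", {
  expect_error(count_modes(rnorm(20)), "fewer than 50")
  expect_warning(cm <- count_modes(rep(3.7, 120)), "unreliable")
  expect_identical(cm$n_modes, 1L)
  expect_equal(cm$centroids, 3.7)
})

test_that("single-component Gaussian warm start equals the sample moments", {
  set.seed(2)
  x <- rnorm(4000, 5, 2)
  g <- gmm_warm_start(x, 1, mean(x))
  expect_equal(g$means, mean(x), tolerance = 1e-6)
  expect_equal(g$sds, sqrt(mean((x - mean(x))^2)), tolerance = 1e-6)
  expect_identical(g$weights, 1)
})

test_that("Gaussian warm start recovers separated components and ignores order", {
  set.seed(3)
  x <- c(rnorm(3000, 0, 1), rnorm(2000, 6, 1.2))
  g <- gmm_warm_start(x, 2, c(-0.2, 6.3))
  expect_equal(sum(g$weights), 1, tolerance = 1e-12)
  expect_lt(abs(g$means[1] - 0), 0.5)
  expect_lt(abs(g$means[2] - 6), 0.5 * 1.2)
  gp <- gmm_warm_start(sample(x), 2, c(-0.2, 6.3))
  expect_equal(gp$means, g$means, tolerance = 1e-8)
  expect_equal(gp$weights, g$weights, tolerance = 1e-8)
})

test_that("mixture fit with one mode reduces to the single-SIGD fit", {
  b <- rsigd(3000, 3.96, 149.25, 14.01, seed = 4)
  single <- fit_sigd(b)
  mixed <- fit_sigd_mixture(b, s_max = 1 / 1.99)
  expect_identical(mixed$mixture$n_modes, 1L)
  cc <- mixed$mixture$components[[1]]
  expect_equal(cc$alpha, single$alpha, tolerance = 0.05)
  expect_equal(cc$beta, single$beta, tolerance = 0.05)
  expect_equal(cc$b0, single$b0, tolerance = 0.5)
})

test_that("mixture fit recovers a bimodal ground truth", {
  mx <- bimodal_mixture()
  sim <- sample_mixture(mx, 3000, seed = 9)
  fit <- fit_sigd_mixture(sim$b, s_max = 1 / 2.40)
  expect_identical(fit$mixture$n_modes, 2L)
  expect_lt(abs(fit$mixture$weights[1] - 0.79), 0.07)
  means_true <- c(72.34, 174.3)
  means_fit <- vapply(fit$mixture$components,
                      function(cc) sigd_mean(cc$alpha, cc$beta, cc$b0),
                      numeric(1))
  expect_lt(max(abs(means_fit - means_true) / means_true), 0.07)
  # hard labels agree with the generating component for most atoms
  expect_gt(mean(fit$assignment$hard_labels == sim$labels), 0.9)
})

test_that("EM log-likelihood is non-decreasing and responsibilities are proper", {
  mx <- bimodal_mixture()
  sim <- sample_mixture(mx, 2000, seed = 11)
  fit <- fit_sigd_mixture(sim$b, s_max = 1 / 2.40)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  g <- fit$assignment$responsibilities
  expect_equal(rowSums(g), rep(1, nrow(g)), tolerance = 1e-9)
})

test_that("posterior assignment is deterministic at the support boundary", {
  mx <- bimodal_mixture()
  # B far below the second component's shift (99.82): zero density there
  asn <- assign_modes(mx, c(50, 60, 175))
  expect_equal(asn$responsibilities[1:2, 1], c(1, 1), tolerance = 1e-12)
  expect_identical(asn$hard_labels[1:2], c(1L, 1L))
  # near the second component's mean the posterior favours it
  expect_gt(asn$responsibilities[3, 2], 0.5)
})

test_that("component reporting order is ascending mean regardless of input order", {
  mx1 <- sigd_mixture(c(0.3, 0.7), alpha = c(10, 4), beta = c(700, 100),
                      b0 = c(100, 20))
  means <- vapply(mx1$components,
                  function(cc) sigd_mean(cc$alpha, cc$beta, cc$b0),
                  numeric(1))
  expect_true(!is.unsorted(means))
  # relabeling leaves the mixture density unchanged
  mx2 <- sigd_mixture(c(0.7, 0.3), alpha = c(4, 10), beta = c(100, 700),
                      b0 = c(20, 100))
  g <- seq(21, 400, length.out = 50)
  expect_equal(dsigd_mixture(g, mx1), dsigd_mixture(g, mx2),
               tolerance = 1e-12)
})
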