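test_that("mu + k sigma threshold uses the sample SD", {
  tm <- compute_threshold(c(10, 12, 14), k = 3)
  expect_equal(tm$mu0, 12)
  expect_equal(tm$sigma0, 2)
  expect_equal(tm$threshold, 18)
  expect_equal(compute_threshold(c(10, 12, 14), k = 0)$threshold, 12)
  expect_equal(compute_threshold(rep(7, 5))$threshold, 7)
  expect_error(compute_threshold(3), "at least 2")
})

test_that("fraction above threshold is a strict exceedance fraction", {
  expect_equal(fraction_above(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(fraction_above(c(1, 2), 10), 0)
  expect_equal(fraction_above(c(1, 2), compute_threshold(c(0, 0.1), k = 0)), 1)
  expect_error(fraction_above(numeric(0), 1), "empty")
  # invariance under a strictly increasing transform of both sides
  set.seed(5)
  x <- rlnorm(200)
  thr <- quantile(x, 0.8)
  f <- function(z) 3 * z + 10
  expect_equal(fraction_above(x, thr), fraction_above(f(x), f(thr)))
  expect_equal(fraction_above(x, thr), fraction_above(log(x), log(thr)))
})

test_that("the 3-sigma tail of the negative control itself is ~0.00135", {
  set.seed(99)
  x <- rnorm(1e5, 100, 10)
  tm <- compute_threshold(x, k = 3)
  fa <- fraction_above(x, tm)
  p <- pnorm(3, lower.tail = FALSE)        # 0.001349898
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(fa - p), 3 * se)
})

test_that("SEM curves follow s/sqrt(n) exactly", {
  set.seed(1)
  x <- rnorm(80, 100, 27)
  sc <- sem_curve(x, c(1, 3, 4, 16, 80))
  s <- sd(x)
  expect_equal(sc$sem, s / sqrt(c(1, 3, 4, 16, 80)))
  expect_equal(sc$sem[sc$n == 4], sc$sem[sc$n == 1] / 2)
  expect_equal(sc$sem[sc$n == 16], sc$sem[sc$n == 4] / 2)
  expect_equal(sc$sem[sc$n == 3] / sc$sem[sc$n == 80], sqrt(80 / 3))
  expect_equal(sc$relative_sem, s / (mean(x) * sqrt(sc$n)))
  expect_true(all(sem_curve(rep(5, 10), 1:5)$sem == 0))
})

test_that("one-tailed Welch test behaves at its fixed points and swaps to 1 - p", {
  x <- c(1, 2, 3, 4)
  expect_equal(one_tailed_t_test(x, x), 0.5)
  set.seed(7)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 5, 1)
  expect_lt(one_tailed_t_test(a, b), 1e-10)
  expect_equal(one_tailed_t_test(a, b) + one_tailed_t_test(b, a), 1)
  expect_error(one_tailed_t_test(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(one_tailed_t_test(1, c(1, 2)), "n >= 2")
})

test_that("sample classification follows the count and fraction rules", {
  tm <- compute_threshold(rnorm(50, 100, 5), k = 3)
  below <- rnorm(20, 100, 1)
  expect_equal(classify_sample(below, tm), "negative")
  expect_equal(classify_sample(c(below, tm$threshold + 1), tm), "positive")
  expect_equal(classify_sample(c(1, 1, 1, 1, 10), 5, min_fraction = 0.5),
               "negative")
  expect_equal(classify_sample(c(1, 10, 10, 1), 5, min_fraction = 0.5),
               "positive")
})

test_that("Monte Carlo subsampling is deterministic, exhausts at n = N and tracks closed forms", {
  neg <- sample_intensity_population(0, 30, seed = 3)
  pos <- sample_intensity_population(0.1, 30, seed = 4)
  tm <- compute_threshold(neg)
  cfg <- monte_carlo_config(n_values = c(2, 5, 10, 30), reps = 2000, seed = 8)
  r1 <- monte_carlo_subsample(neg, pos, tm, cfg)
  r2 <- monte_carlo_subsample(neg, pos, tm, cfg)
  expect_identical(r1$per_n, r2$per_n)

  # n = N: sampling without replacement exhausts the population
  at_n <- r1$per_n[r1$per_n$n == 30, ]
  expect_equal(at_n$mean_intensity_sd, 0)
  expect_equal(at_n$fraction_above_sd, 0)
  expect_equal(at_n$mean_intensity_mean, mean(pos))

  # finite-population SD of the subset mean
  S <- sd(pos); N <- 30
  for (n in c(2, 5, 10)) {
    closed <- S / sqrt(n) * sqrt((N - n) / N)
    got <- r1$per_n$mean_intensity_sd[r1$per_n$n == n]
    expect_lt(abs(got - closed) / closed, 0.1)
  }

  # disjoint populations at 3 sigma: no false negatives at any n
  neg2 <- rnorm(60, 100, 5); pos2 <- rnorm(60, 200, 5)
  set.seed(1)
  r3 <- monte_carlo_subsample(neg2, pos2, compute_threshold(neg2),
                              monte_carlo_config(n_values = c(1, 5, 20),
                                                 reps = 500, seed = 2))
  expect_true(all(r3$per_n$false_negative_rate == 0))

  expect_error(monte_carlo_subsample(neg, pos, tm,
                                     monte_carlo_config(n_values = 31)),
               "exceeds")
})

test_that("false-negative rates match the hypergeometric oracle on a small population", {
  # population of N = 10 with K = 4 above threshold; brute-force enumeration
  pop <- c(1, 2, 3, 4, 5, 6, 11, 12, 13, 14)
  thr_val <- 10
  tm <- structure(list(mu0 = 5, sigma0 = 5 / 3, k = 3, threshold = thr_val),
                  class = "threshold_model")
  N <- 10; K <- 4
  for (n in c(1, 2, 3, 5)) {
    combs <- utils::combn(N, n)
    brute <- mean(apply(combs, 2, function(ix) all(pop[ix] <= thr_val)))
    expect_equal(brute, choose(N - K, n) / choose(N, n))
  }
  res <- monte_carlo_subsample(rep(c(4, 5), 5), pop, tm,
                               monte_carlo_config(n_values = c(1, 2, 3, 5),
                                                  reps = 4000, seed = 12))
  for (i in seq_len(nrow(res$per_n))) {
    n <- res$per_n$n[i]
    p_exact <- choose(N - K, n) / choose(N, n)
    se <- sqrt(p_exact * (1 - p_exact) / 4000)
    expect_lt(abs(res$per_n$false_negative_rate[i] - p_exact), 3 * se + 1e-9)
  }
  expect_true(all(diff(res$per_n$false_negative_rate) <= 1e-9))
})

test_that("paired-threshold comparison favours the fraction metric under shared drift", {
  set.seed(21)
  neg <- list(); pos <- list()
  for (r in 1:3) {
    b <- rnorm(1, 0, 50)
    neg[[r]] <- rnorm(80, 100, 25) + b
    pos[[r]] <- rnorm(80, 250, 25) + b
  }
  cm <- compare_methods(neg, pos)
  expect_lt(cm$p_fraction, cm$p_mean)
  expect_true(is.finite(cm$p_fraction) && is.finite(cm$p_mean))

  # identical repeats in both arms: both tests are uninformative (p = 0.5)
  same <- list(c(1, 2, 3), c(1, 2, 3))
  cm0 <- compare_methods(same, same)
  expect_equal(cm0$p_fraction, 0.5)
  expect_equal(cm0$p_mean, 0.5)
})

test_that("dose-response fitting recovers linear parameters and the operational LOD", {
  # exactly linear means
  tab <- data.frame(condition = rep(c(0, 0.2, 0.5, 1, 2), each = 3),
                    mean_intensity = 100 + 400 * rep(c(0, 0.2, 0.5, 1, 2),
                                                     each = 3))
  fit <- fit_dose_response(tab, k = 3)
  expect_equal(fit$slope, 400, tolerance = 1e-9)
  expect_equal(fit$intercept, 100, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  # zero-dose replicates are identical, so the threshold collapses to mu0
  # and the first non-zero dose is the operational LOD
  expect_true(fit$detected)
  expect_equal(fit$lod_estimate, 0.2)

  # generator-built design where 0.05 ng/mL is the first exceedance
  doses <- c(0, 0.05, 0.1, 1)
  tab2 <- do.call(rbind, lapply(doses, function(d) {
    data.frame(condition = d,
               mean_intensity = sample_intensity_population(
                 d, 80, cv = 0.25, seed = 100 + round(1000 * d)))
  }))
  fit2 <- fit_dose_response(tab2, linear_range = c(0, 1), k = 3)
  expect_true(fit2$detected)
  expect_equal(fit2$lod_estimate, 0.05)
  expect_gt(fit2$slope, 0)

  # zero-slope data: flagged not-detected
  tab3 <- data.frame(condition = rep(c(0, 0.5, 1), each = 5),
                     mean_intensity = rnorm(15, 100, 1))
  fit3 <- fit_dose_response(tab3, k = 3)
  expect_false(fit3$detected)
  expect_true(is.na(fit3$lod_estimate))
  expect_error(fit_dose_response(tab3[tab3$condition < 0.6, ]),
               "at least 3")
})
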