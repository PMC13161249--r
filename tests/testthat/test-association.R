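test_that("two-group R-squared matches hand computation and the linear model", {
  expect_equal(rsq_two_group(c(1, 2, 3, 4), factor(c("A", "A", "B", "B"))), 0.8,
               ignore_attr = TRUE)
  # within-group constant, groups differ -> 1
  expect_equal(rsq_two_group(c(2, 2, 9, 9), factor(c("A", "A", "B", "B"))), 1,
               ignore_attr = TRUE)
  # constant values are degenerate, scored 0
  r0 <- rsq_two_group(rep(3, 6), factor(rep(c("A", "B"), 3)))
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))

  set.seed(14)
  for (i in 1:60) {
    n <- sample(6:40, 1)
    f <- factor(c(rep("A", ceiling(n / 2)), rep("B", floor(n / 2))))
    y <- rnorm(n) + 2 * (f == "B") * runif(1)
    expect_equal(rsq_two_group(y, f),
                 summary(lm(y ~ f))$r.squared,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("null R-squared has expectation 1/(n-1) over permutations", {
  set.seed(5)
  n <- 20
  y <- rnorm(n)
  r <- replicate(4000, rsq_two_group(y, sample(rep(c("A", "B"), n / 2))))
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 1 / (n - 1)), 4 * se)
})

test_that("covariate R-squared equals squared correlation and the regression R2", {
  z <- seq(1, 10)
  expect_equal(rsq_covariate(2 * z + 1, z), 1, ignore_attr = TRUE)
  set.seed(33)
  y <- rnorm(500); z2 <- rnorm(500)
  expect_lt(rsq_covariate(y, z2), 0.03)
  for (i in 1:25) {
    y <- rnorm(30) + rnorm(1) * (z3 <- rnorm(30))
    expect_equal(rsq_covariate(y, z3), summary(lm(y ~ z3))$r.squared,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(rsq_covariate(rnorm(5), rep(1, 5)), "constant")
  r0 <- rsq_covariate(rep(2, 5), 1:5)
  expect_true(attr(r0, "degenerate"))
})

test_that("top selection takes ceil((1-r2tol) M) with deterministic ties", {
  set.seed(2)
  s465 <- setNames(runif(465), sprintf("i%03d", 1:465))
  expect_length(select_top(s465, 0.98), 10L)
  expect_length(select_top(setNames(runif(100), paste0("i", 1:100)), 0.98), 2L)
  expect_length(select_top(setNames(runif(10), paste0("i", 1:10)), 0.5), 5L)
  # the selected really are the k largest
  top <- select_top(s465, 0.98)
  expect_true(min(s465[top]) >= max(s465[-top]))
  # ties broken by name, reproducibly
  tied <- setNames(c(1, 1, 1, 0.2), c("c", "a", "b", "d"))
  expect_identical(names(tied)[select_top(tied, 0.6)], c("a", "b"))
  # |top set| non-increasing in r2tol
  ks <- vapply(c(0.5, 0.8, 0.9, 0.98), function(t) length(select_top(s465, t)), 0L)
  expect_true(all(diff(ks) <= 0))
})

test_that("bootstrap support bookkeeping uses denominator wg_rounds + 1", {
  sim <- generate_planted_dataset(n_per_group = 25, d = 2.2, seed = 91)
  ild <- compute_ilds(sim$data, map = sim$map)
  res <- ildsr2(ild, sim$factor, wg_rounds = 99, seed = 17)
  expect_true(all(res$top$support * 100 == round(res$top$support * 100)))
  expect_true(all(res$top$support >= 1 / 100))
  expect_identical(res$top$support, (1 + res$top$hits) / 100)

  # identical runs are bit-identical; different seeds differ
  res2 <- ildsr2(ild, sim$factor, wg_rounds = 99, seed = 17)
  expect_identical(res$top, res2$top)
  expect_identical(res$all_r2, res2$all_r2)

  expect_warning(r0 <- ildsr2(ild, sim$factor, wg_rounds = 0), "wg_rounds")
  expect_true(all(r0$top$support == 1))
})

test_that("within-group-constant data give every top ILD full support", {
  ts <- tiny_symmetric()
  arr <- array(NA_real_, c(6, 6, 3))
  for (i in 1:3) arr[i, , ] <- ts$cfg
  for (i in 4:6) arr[i, , ] <- ts$cfg * 1.1
  a <- landmark_array(arr, landmark_names = rownames(ts$cfg))
  res <- ildsr2(a, factor(rep(c("F", "M"), each = 3)), r2tol = 0.9,
                wg_rounds = 49, seed = 3, map = ts$map)
  expect_true(all(res$top$support == 1))
  expect_true(all(res$top$rsq == 1))
})

test_that("a strongly planted ILD is always selected with high support", {
  # population R2 ~ 0.6 against a null background, n = 50 + 50
  ok <- vapply(1:20, function(s) {
    sim <- generate_planted_dataset(n_per_group = 50, d = 2.45, seed = 1000 + s)
    res <- ildsr2(compute_ilds(sim$data, map = sim$map), sim$factor,
                  wg_rounds = 99, seed = s)
    all(sim$planted %in% res$top$name[res$top$support > 0.5])
  }, TRUE)
  expect_true(all(ok))
})

test_that("group-contrast diagnostics reproduce the worked ratio arithmetic", {
  # one ILD engineered to have group means 127.4 and 137.5 mm
  arr <- array(NA_real_, c(4, 3, 3))
  f_cfg <- rbind(c(0, 0, 0), c(127.4, 0, 0), c(0, 50, 0))
  m_cfg <- rbind(c(0, 0, 0), c(137.5, 0, 0), c(0, 50, 0))
  arr[1, , ] <- f_cfg; arr[2, , ] <- f_cfg
  arr[3, , ] <- m_cfg; arr[4, , ] <- m_cfg
  a <- landmark_array(arr, landmark_names = c("p1", "p2", "p3"))
  d <- ild_diagnostics(compute_ilds(a), factor(c("F", "F", "M", "M")))
  row <- d[d$name == "p1-p2", ]
  expect_equal(row$ratio_of_means, 137.5 / 127.4, tolerance = 1e-12)
  expect_equal(round(row$ratio_of_means, 2), 1.08)
  expect_lt(abs(row$grand_mean - 132.45), 1e-9)
  expect_equal(row$r2, 1)
})

test_that("identical group distributions give mean ratios of exactly 1", {
  s <- tiny_sample(n = 6, noise = 0, seed = 2)
  d <- ild_diagnostics(compute_ilds(s$data, map = s$map),
                       factor(rep(c("F", "M"), 3)))
  expect_true(all(abs(d$ratio_of_means - 1) < 1e-12))
})

test_that("direct and form-consensus means coincide on noise-free data", {
  sim <- generate_dataset(n_per_group = 3, noise_sd = 0, seed = 6,
                          effects = list(mid01 = c(0, 0, 8)))
  g <- gpa(sim$data)
  d_direct <- ild_diagnostics(compute_ilds(g, map = sim$map), sim$factor)
  d_form <- ild_diagnostics(g, sim$factor, mean_source = "form_consensus",
                            map = sim$map)
  expect_equal(d_form$ratio_of_means, d_direct$ratio_of_means, tolerance = 1e-9)
  expect_equal(d_form$grand_mean, d_direct$grand_mean, tolerance = 1e-9)
  # form-consensus means are refused on raw coordinates
  expect_error(ild_diagnostics(sim$data, sim$factor,
                               mean_source = "form_consensus"),
               "raw coordinates")
})

test_that("expected sample R-squared matches theory and Monte Carlo", {
  expect_equal(expected_rsq(0, 1, 50, 50), 1 / 99, tolerance = 1e-8)
  expect_equal(expected_rsq(0, 2, 10, 14), 1 / 23, tolerance = 1e-8)
  expect_gt(expected_rsq(5, 0.01, 20, 20), 0.999)
  # large-ncp regime: E[R2] ~ 1 - nu/ncp
  expect_equal(expected_rsq(5, 0.1, 20, 20), 1 - 38 / (10 * 2500),
               tolerance = 1e-3)
  # monotone in the effect
  es <- vapply(c(0, 0.5, 1, 2, 4), expected_rsq, 0, sd = 1, n1 = 15, n2 = 15)
  expect_true(all(diff(es) > 0))

  # brute-force Monte-Carlo validation of the finite-n expectation
  set.seed(44)
  n1 <- 15; n2 <- 15; delta <- 1; sdv <- 1
  R <- 40000
  y <- matrix(rnorm((n1 + n2) * R, sd = sdv), n1 + n2)
  y[(n1 + 1):(n1 + n2), ] <- y[(n1 + 1):(n1 + n2), ] + delta
  cm <- colMeans(y)
  sst <- colSums(y^2) - (n1 + n2) * cm^2
  m1 <- colMeans(y[1:n1, ]); m2 <- colMeans(y[(n1 + 1):(n1 + n2), ])
  ssb <- n1 * (m1 - cm)^2 + n2 * (m2 - cm)^2
  r2 <- ssb / sst
  se <- sd(r2) / sqrt(R)
  expect_lt(abs(mean(r2) - expected_rsq(delta, sdv, n1, n2)), 3 * se)
})
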