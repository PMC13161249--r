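test_that("base configurations are symmetric, distinct and reproducible", {
  b1 <- generate_base_config(7, 12, seed = 1)
  b2 <- generate_base_config(7, 12, seed = 1)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 31L)
  # exact reflect-and-relabel invariance by construction
  map <- ildsel:::base_config_map(7, 12, rownames(b1))
  sigma <- ildsel:::mirror_permutation(map)
  mir <- b1[sigma, ]; mir[, 1] <- -mir[, 1]
  expect_identical(unname(mir), unname(b1))
  expect_gt(centroid_size(b1), 0)
  # canonical distances all distinct (mirror twins are equal by symmetry)
  ild <- compute_ilds(landmark_array(array(b1, c(1, 31, 3)),
                                     landmark_names = rownames(b1)),
                      map = map)
  d <- sort(ild$values[1, ild$canonical])
  expect_gt(min(diff(d)), 1e-6)
})

test_that("generated datasets are reproducible with noise-free degeneracy", {
  s1 <- generate_dataset(n_per_group = 4, seed = 13)
  s2 <- generate_dataset(n_per_group = 4, seed = 13)
  expect_identical(s1$data$coords, s2$data$coords)

  # no noise, no effect: every ILD is constant, scored 0 and degenerate
  s0 <- generate_dataset(n_per_group = 3, noise_sd = 0, seed = 2)
  expect_identical(nrow(s0$truth), 0L)
  ild <- compute_ilds(s0$data, map = s0$map)
  r <- rsq_two_group(ild$values[, 1], s0$factor)
  expect_true(attr(r, "degenerate"))
})

test_that("a noise-free displacement moves exactly the incident distances", {
  s <- generate_dataset(n_per_group = 2, noise_sd = 0, seed = 5,
                        effects = list(mid01 = c(0, 0, 10)))
  # all changed canonical ILDs involve the displaced landmark
  expect_gt(nrow(s$truth), 0)
  expect_true(all(grepl("mid01", s$truth$name)))
  # and they separate the groups perfectly
  ild <- compute_ilds(s$data, map = s$map)
  for (nm in s$truth$name) {
    col <- which(ild$names == nm)[1]
    expect_equal(rsq_two_group(ild$values[, col], s$factor), 1,
                 ignore_attr = TRUE)
  }
  # untouched distances are exactly constant
  quiet <- setdiff(ild$names[ild$canonical], s$truth$name)
  qcols <- match(quiet, ild$names)
  expect_lt(max(apply(ild$values[, qcols], 2, sd)), 1e-12)
})

test_that("bilateral effects are applied mirror-symmetrically", {
  s <- generate_dataset(n_per_group = 2, noise_sd = 0, seed = 6,
                        effects = list(lat01 = c(3, -2, 5)))
  sigma <- ildsel:::mirror_permutation(s$map)
  mir <- s$target_mean[sigma, ]; mir[, 1] <- -mir[, 1]
  expect_equal(unname(mir), unname(s$target_mean), tolerance = 1e-12)
  expect_error(generate_dataset(n_per_group = 2, seed = 1,
                                effects = list(mid01 = c(1, 0, 0))),
               "zero first coordinate")
  expect_error(generate_dataset(n_per_group = 2, seed = 1,
                                effects = list(nothere = c(0, 0, 1))),
               "nothere")
})

test_that("without asymmetric jitter, symmetrization is a near no-op", {
  s <- generate_dataset(n_per_group = 3, noise_sd = 0, seed = 7,
                        effects = list(mid02 = c(0, 4, 0)))
  g <- gpa(s$data)
  sym <- symmetrize(g, s$map)
  expect_lt(max(abs(sym$coords - g$coords)), 1e-8)
})

test_that("the planted benchmark has the advertised effect size and truth", {
  sim <- generate_planted_dataset(n_per_group = 100, d = 2.2, seed = 17)
  expect_identical(sort(sim$planted), sort(utils::head(sim$truth$name, 2)))
  ild <- compute_ilds(sim$data, map = sim$map)
  for (nm in sim$planted) {
    v <- ild$values[, which(ild$names == nm)[1]]
    m1 <- mean(v[sim$factor == "F"]); m2 <- mean(v[sim$factor == "M"])
    sp <- sqrt((var(v[sim$factor == "F"]) + var(v[sim$factor == "M"])) / 2)
    d_hat <- (m2 - m1) / sp
    expect_lt(abs(d_hat - 2.2), 0.45)  # ~3 se at n = 100 + 100
  }
  # collateral (non-planted) effects are negligible against the noise
  other <- setdiff(sim$truth$name, sim$planted)
  if (length(other))
    expect_lt(max(abs(sim$truth$mean_diff_mm[match(other, sim$truth$name)])),
              0.2 * min(abs(sim$truth$mean_diff_mm[match(sim$planted, sim$truth$name)])))
  expect_true(sim$analytic$bayes_accuracy > 0.5 &&
                sim$analytic$bayes_accuracy < 1)
})

test_that("strong planted effects pass the full pipeline in every seed", {
  ok <- vapply(1:10, function(s) {
    sim <- generate_planted_dataset(n_per_group = 30, d = 4, seed = 400 + s)
    sym <- symmetrize(gpa(sim$data), sim$map)
    sub <- run_subsample_experiment(compute_ilds(sym, map = sim$map),
                                    sim$factor, n_per_group = 15,
                                    n_reps = 6, wg_rounds = 33, seed = s)
    identical(sort(final_ild_selection(sub)), sort(sim$planted))
  }, TRUE)
  expect_true(all(ok))
})
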