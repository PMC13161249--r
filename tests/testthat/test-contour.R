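scatter_2d <- function(n = 30, seed = 1) {
  set.seed(seed)
  cbind(runif(n, 100, 160), runif(n, 80, 140))
}

test_that("a constant field fits with zero weights and a flat surface", {
  pts <- scatter_2d(20, seed = 2)
  m <- fit_tps(pts, rep(0.42, 20), lambda = 0)
  expect_lt(max(abs(m$w)), 1e-10)
  expect_equal(m$a, c(0.42, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
  g <- evaluate_surface(m, n_grid = 25)
  expect_lt(max(abs(g$raw - 0.42)), 1e-8)
})

test_that("affine functions are reproduced exactly at lambda = 0", {
  pts <- scatter_2d(25, seed = 3)
  vals <- 2 + 0.5 * pts[, 1] - 0.3 * pts[, 2]
  m <- fit_tps(pts, vals, lambda = 0)
  probe <- scatter_2d(40, seed = 4)
  expect_equal(predict(m, probe, clamp = FALSE),
               2 + 0.5 * probe[, 1] - 0.3 * probe[, 2], tolerance = 1e-8)
})

test_that("lambda = 0 interpolates training values; side conditions hold", {
  pts <- scatter_2d(40, seed = 5)
  vals <- runif(40)
  m <- fit_tps(pts, vals, lambda = 0)
  expect_equal(predict(m, pts, clamp = FALSE), vals, tolerance = 1e-8)
  # orthogonality of kernel weights to the affine space
  expect_lt(abs(sum(m$w)), 1e-10)
  expect_lt(max(abs(crossprod(pts, m$w))), 1e-7)
})

test_that("grid evaluation equals a pointwise loop", {
  pts <- scatter_2d(15, seed = 6)
  m <- fit_tps(pts, runif(15), lambda = 1e-4)
  g <- evaluate_surface(m, n_grid = 11)
  for (i in c(1, 5, 11)) for (j in c(1, 6, 11))
    expect_equal(g$raw[i, j],
                 predict(m, cbind(g$x[i], g$y[j]), clamp = FALSE),
                 tolerance = 1e-12)
})

test_that("degenerate inputs are refused with actionable messages", {
  pts <- scatter_2d(10, seed = 7)
  expect_error(fit_tps(pts[1:3, ], runif(3)), "at least 4")
  expect_error(fit_tps(cbind(pts, 1), runif(10)), "two predictors")
  dup <- rbind(pts, pts[1, ])
  expect_error(fit_tps(dup, runif(11), lambda = 0), "lambda > 0")
  # but the ridge handles duplicates
  expect_s3_class(fit_tps(dup, runif(11), lambda = 1e-3), "tps_contour")
})

test_that("GCV smoothing selection is deterministic", {
  pts <- scatter_2d(30, seed = 8)
  vals <- plogis((pts[, 1] - 130) / 10) + rnorm(30, 0, 0.05)
  m1 <- fit_tps(pts, vals, lambda = "gcv")
  m2 <- fit_tps(pts, vals, lambda = "gcv")
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$gcv, m2$gcv)
  expect_gt(m1$lambda, 0)
})

test_that("new cases are classified with bands, clamping and hull flags", {
  # constant 0.5 surface: everything is indeterminate
  pts <- scatter_2d(12, seed = 9)
  m05 <- fit_tps(pts, rep(0.5, 12), lambda = 0)
  out <- classify_new(m05, pts[1:3, ], labels = c("F", "M"))
  expect_true(all(out$label == "indeterminate"))

  # a separated 0/1 training set: training points classify like their values
  pts2 <- rbind(scatter_2d(10, seed = 10) - 40, scatter_2d(10, seed = 11) + 40)
  vals2 <- rep(c(0, 1), each = 10)
  m <- fit_tps(pts2, vals2, lambda = 0, groups = rep(c("F", "M"), each = 10))
  res <- classify_new(m, pts2[c(1, 20), ])
  expect_identical(res$label, c("F", "M"))
  expect_identical(res$band, c("0.0-0.1", "0.9-1.0"))
  expect_false(any(res$low_confidence))
  expect_true(all(res$pp >= 0 & res$pp <= 1))

  # far outside the data: flagged as extrapolated, still classified
  far <- classify_new(m, cbind(500, 500))
  expect_true(far$extrapolated)
})

test_that("the 0.5 contour separates well-separated group centroids", {
  sim <- generate_planted_dataset(n_per_group = 60, d = 2.2, seed = 21)
  ild <- compute_ilds(sim$data, map = sim$map)
  X <- ild$values[, match(sim$planted, ild$names)]
  colnames(X) <- sim$planted
  mod <- fit_lda(X, sim$factor)
  tc <- fit_tps(X, posterior(mod, X), groups = sim$factor)
  c1 <- colMeans(X[sim$factor == "F", ])
  c2 <- colMeans(X[sim$factor == "M", ])
  ts <- seq(0, 1, length.out = 101)
  seg <- cbind(c1[1] + ts * (c2[1] - c1[1]), c1[2] + ts * (c2[2] - c1[2]))
  v <- predict(tc, seg, clamp = FALSE) - 0.5
  expect_lt(v[1], 0); expect_gt(v[101], 0)
  expect_true(any(diff(sign(v)) != 0))
})

test_that("surface and direct-posterior classifications agree on hold-outs", {
  train <- generate_planted_dataset(n_per_group = 50, d = 2.2, seed = 31)
  test <- generate_planted_dataset(n_per_group = 30, d = 2.2, seed = 32)
  get_X <- function(sim) {
    ild <- compute_ilds(sim$data, map = sim$map)
    X <- ild$values[, match(sim$planted, ild$names)]
    colnames(X) <- sim$planted
    X
  }
  Xtr <- get_X(train); Xte <- get_X(test)
  mod <- fit_lda(Xtr, train$factor)
  tc <- fit_tps(Xtr, posterior(mod, Xtr), lambda = "gcv", groups = train$factor)
  lab_surface <- classify_new(tc, Xte)$label
  lab_direct <- ifelse(posterior(mod, Xte) > 0.5, "M", "F")
  expect_gte(mean(lab_surface == lab_direct), 0.95)
})

test_that("the contour figure renders all 0.1-step levels deterministically", {
  pts2 <- rbind(scatter_2d(10, seed = 12) - 30, scatter_2d(10, seed = 13) + 30)
  vals2 <- rep(c(0.1, 0.9), each = 10)
  m <- fit_tps(pts2, vals2, lambda = 1e-2, groups = rep(c("F", "M"), each = 10))
  render <- function(file) {
    png(file, width = 400, height = 400)
    out <- plot(m, new_points = cbind(0, 0), n_grid = 60)
    dev.off()
    out
  }
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  out <- render(f1); render(f2)
  expect_equal(out$levels, seq(0, 1, by = 0.1))
  expect_true(0.5 %in% out$levels && 0.2 %in% out$levels && 0.8 %in% out$levels)
  expect_gt(file.size(f1), 0)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
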