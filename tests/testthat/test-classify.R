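make_overlap_data <- function(n = 60, p = 2, sep = 1.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  f <- factor(rep(c("F", "M"), each = n / 2))
  X[f == "M", ] <- X[f == "M", ] + sep / sqrt(p)
  colnames(X) <- paste0("ild", seq_len(p))
  list(X = X, f = f)
}

test_that("fitted parameters match direct mean/pooled-covariance computation", {
  d <- make_overlap_data(seed = 11)
  m <- fit_lda(d$X, d$f)
  i1 <- d$f == "F"
  expect_equal(m$means[1, ], colMeans(d$X[i1, ]), tolerance = 1e-12)
  expect_equal(m$means[2, ], colMeans(d$X[!i1, ]), tolerance = 1e-12)
  Sw <- (cov(d$X[i1, ]) * (sum(i1) - 1) + cov(d$X[!i1, ]) * (sum(!i1) - 1)) /
    (nrow(d$X) - 2)
  expect_equal(m$pooled_cov, Sw, tolerance = 1e-12)
  expect_equal(m$priors, c(0.5, 0.5))

  expect_error(fit_lda(cbind(d$X, d$X[, 1]), d$f), "singular")
})

test_that("posteriors are symmetric at the midpoint, normalized, monotone", {
  d <- make_overlap_data(seed = 21)
  m <- fit_lda(d$X, d$f)
  mid <- colMeans(m$means)
  expect_equal(posterior(m, mid), 0.5, tolerance = 1e-9)
  # at the target mean with wide separation, PP -> 1
  far <- make_overlap_data(sep = 20, seed = 3)
  mf <- fit_lda(far$X, far$f)
  expect_gt(posterior(mf, mf$means[2, ]), 1 - 1e-6)
  # two group posteriors sum to one
  pr <- predict(m, d$X)
  expect_equal(rowSums(pr$posterior), rep(1, nrow(d$X)), tolerance = 1e-12)
  # monotone in the linear discriminant score
  w <- solve(m$pooled_cov, m$means[2, ] - m$means[1, ])
  sc <- as.vector(d$X %*% w)
  expect_false(is.unsorted(pr$pp_target[order(sc)]))
})

test_that("leave-one-out matches the MASS oracle and ignores row order", {
  skip_if_not_installed("MASS")
  d <- make_overlap_data(n = 60, seed = 31)
  rep1 <- loo_cv(d$X, d$f)
  or <- MASS::lda(d$X, d$f, prior = c(0.5, 0.5), CV = TRUE)
  expect_equal(rep1$per_individual$pp_target, unname(or$posterior[, "M"]),
               tolerance = 1e-8)
  agree <- rep1$per_individual$predicted == as.character(or$class)
  expect_true(all(agree[rep1$per_individual$predicted != "indeterminate"]))

  # permuting individuals permutes, but does not change, the predictions
  set.seed(5)
  perm <- sample(nrow(d$X))
  rep2 <- loo_cv(d$X[perm, ], d$f[perm], ids = rownames(d$X)[perm])
  expect_equal(rep2$per_individual$pp_target[order(perm)],
               rep1$per_individual$pp_target, tolerance = 1e-12)
  expect_identical(rep2$confusion, rep1$confusion)
})

test_that("widely separated groups classify perfectly with zero bias", {
  d <- make_overlap_data(n = 40, sep = 25, seed = 41)
  rep <- loo_cv(d$X, d$f)
  expect_equal(unname(rep$per_group_accuracy), c(100, 100))
  expect_equal(rep$average_accuracy, 100)
  expect_equal(rep$bias, 0)
})

test_that("report arithmetic reproduces the published accuracy/bias layout", {
  # confusion 92/8 over 13/87 in percent: bias = 92 - 87 = +5
  truth <- rep(c("F", "M"), each = 100)
  pred <- c(rep("F", 92), rep("M", 8), rep("F", 13), rep("M", 87))
  rep <- ildsel:::build_report(truth, pred, c("F", "M"),
                               pp_target = rep(0.5, 200),
                               typ = rep(1, 200), ids = seq_len(200))
  expect_identical(unname(rep$confusion), rbind(c(92L, 8L), c(13L, 87L)))
  expect_equal(unname(rep$per_group_accuracy), c(92, 87))
  expect_equal(rep$average_accuracy, 89.5)  # prints as 90
  expect_equal(rep$bias, 5)
  expect_equal(rowSums(rep$confusion), c(F = 100, M = 100))
})

test_that("ties at posterior 0.5 are indeterminate and counted as errors", {
  d <- make_overlap_data(seed = 51)
  m <- fit_lda(d$X, d$f)
  mid <- colMeans(m$means)
  pr <- predict(m, rbind(mid))
  expect_identical(pr$class, "indeterminate")
  rep <- ildsel:::build_report(c("F", "M"), c("indeterminate", "indeterminate"),
                               c("F", "M"), c(0.5, 0.5), c(1, 1), 1:2)
  expect_equal(unname(diag(rep$confusion)), c(0L, 0L))
})

test_that("typicality is a chi-squared tail with uniform coverage", {
  d <- make_overlap_data(seed = 61)
  m <- fit_lda(d$X, d$f)
  expect_equal(typicality(m, m$means[1, ], "F"), 1)
  # a case at Mahalanobis D2 = chi-squared 99th percentile has typicality 0.01
  ev <- eigen(m$pooled_cov)
  x99 <- m$means[2, ] + ev$vectors[, 1] * sqrt(qchisq(0.99, df = 2) * ev$values[1])
  expect_equal(mahalanobis(rbind(x99), m$means[2, ], m$pooled_cov),
               qchisq(0.99, df = 2), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(typicality(m, x99, "M"), 0.01, tolerance = 1e-9)

  # probability integral transform: samples from the model's own Gaussian
  # have uniform typicality
  skip_if_not_installed("MASS")
  set.seed(9)
  model <- structure(list(means = rbind(F = c(0, 0), M = c(3, 1)),
                          pooled_cov = diag(c(2, 0.5)),
                          priors = c(0.5, 0.5), labels = c("F", "M"),
                          predictors = c("a", "b"), n = c(50L, 50L)),
                     class = "ild_lda")
  xs <- MASS::mvrnorm(10000, c(0, 0), diag(c(2, 0.5)))
  u <- typicality(model, xs, "F")
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("fitted models survive a JSON round-trip to full precision", {
  d <- make_overlap_data(seed = 71)
  m <- fit_lda(d$X, d$f)
  path <- withr::local_tempfile(fileext = ".json")
  write_lda_model(m, path)
  m2 <- read_lda_model(path)
  expect_equal(posterior(m2, d$X), posterior(m, d$X), tolerance = 1e-12)
  expect_identical(m2$labels, m$labels)
  expect_identical(m2$predictors, m$predictors)
})
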