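# thin-plate spline machinery for the posterior-probability contour plot

# 2D TPS kernel U(r) = r^2 log(r), with U(0) = 0; the usual 1/(8*pi) constant
# is absorbed into the weights and does not affect the fitted surface
tps_kernel <- function(r) {
  out <- r * r * log(r)
  out[r == 0] <- 0
  out
}

tps_K <- function(A, B) {
  dx <- outer(A[, 1L], B[, 1L], `-`)
  dy <- outer(A[, 2L], B[, 2L], `-`)
  tps_kernel(sqrt(dx * dx + dy * dy))
}

# solve the bordered TPS system for one ridge value; returns weights, affine
# part and the hat matrix diagonal ingredients needed for GCV
tps_solve <- function(K, P, y, ridge) {
  n <- nrow(K)
  M <- rbind(cbind(K + diag(ridge, n), P),
             cbind(t(P), matrix(0, 3L, 3L)))
  sol <- solve(M, c(y, rep(0, 3L)))
  list(w = sol[seq_len(n)], a = sol[n + 1:3])
}

tps_hat <- function(K, P, ridge) {
  n <- nrow(K)
  M <- rbind(cbind(K + diag(ridge, n), P),
             cbind(t(P), matrix(0, 3L, 3L)))
  Minv_cols <- solve(M, rbind(diag(n), matrix(0, 3L, n)))
  cbind(K, P) %*% Minv_cols
}

#' Fit a thin-plate-spline surface over a two-ILD data space
#'
#' Solves the standard 2D thin-plate system with kernel `U(r) = r^2 log(r)`,
#' an affine part, and a ridge term `lambda` on the kernel block.  With
#' `lambda = 0` the surface interpolates the training values exactly; with
#' `lambda = "gcv"` (the default) the smoothing parameter minimizing
#' generalized cross-validation over a log-spaced grid is chosen —
#' deterministic, and the usual default behaviour of thin-plate smoothers.
#'
#' Used here to interpolate discriminant posterior probabilities over the
#' plane of two selected interlandmark distances, so that the 0.1-step
#' contour lines of the fitted surface classify plotted cases graphically.
#'
#' @param points `n x 2` matrix of predictor coordinates (mm), `n >= 4`.
#'   Exactly two columns: with more predictors a posterior-probability
#'   contour plot over the observed measurements is not possible.
#' @param values `n` surface values (posterior probabilities of the target
#'   group, in `[0, 1]`).
#' @param lambda non-negative ridge, or `"gcv"`.
#' @param groups optional factor of training group labels (kept for
#'   plotting).
#' @param padding bounding-box padding fraction used for evaluation grids.
#' @return Object of class `tps_contour`: kernel weights `w`, affine
#'   coefficients `a` (constant + two slopes), `lambda`, the GCV trace (if
#'   searched), training data, bounding box and convex hull.
#' @export
fit_tps <- function(points, values, lambda = "gcv", groups = NULL,
                    padding = 0.05) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L)
    stop_("the contour surface needs exactly two predictors; ",
          "with more than two ILDs one cannot make a PP contour scatterplot")
  n <- nrow(points)
  if (n < 4L) stop_("need at least 4 points to fit a thin-plate spline")
  if (length(values) != n) stop_("'values' length must match rows of 'points'")
  if (any(duplicated(points)) && is.numeric(lambda) && lambda == 0)
    stop_("duplicate points cannot be interpolated exactly (values may conflict); ",
          "use lambda > 0 or \"gcv\"")
  K <- tps_K(points, points)
  P <- cbind(1, points)
  gcv <- NULL
  if (identical(lambda, "gcv")) {
    scale <- stats::median(abs(K[upper.tri(K)])) + .Machine$double.eps
    grid <- scale * 10^seq(-9, 2, by = 0.5)
    gcv <- vapply(grid, function(l) {
      A <- tps_hat(K, P, l)
      res <- values - as.vector(A %*% values)
      denom <- (n - sum(diag(A)))^2
      n * sum(res^2) / max(denom, .Machine$double.eps)
    }, 0)
    lambda <- grid[which.min(gcv)]
    gcv <- data.frame(lambda = grid, gcv = gcv)
  } else if (!is.numeric(lambda) || lambda < 0) {
    stop_("'lambda' must be a non-negative number or \"gcv\"")
  }
  sol <- tps_solve(K, P, values, lambda)
  bbox <- apply(points, 2L, range)
  pad <- padding * (bbox[2L, ] - bbox[1L, ])
  bbox <- rbind(bbox[1L, ] - pad, bbox[2L, ] + pad)
  hull <- grDevices::chull(points)
  structure(list(w = sol$w, a = sol$a, lambda = lambda, gcv = gcv,
                 train_points = points, train_pp = as.numeric(values),
                 groups = if (!is.null(groups)) droplevels(as.factor(groups)),
                 bbox = bbox, padding = padding,
                 hull = points[c(hull, hull[1L]), , drop = FALSE]),
            class = "tps_contour")
}

#' @export
print.tps_contour <- function(x, ...) {
  cat(sprintf("Thin-plate spline PP surface: %d training points, lambda = %.4g%s\n",
              nrow(x$train_points), x$lambda,
              if (!is.null(x$gcv)) " (GCV)" else ""))
  invisible(x)
}

# raw (unclamped) surface values at query points
tps_eval <- function(model, Q) {
  Q <- matrix(as.numeric(Q), ncol = 2L)
  as.vector(tps_K(Q, model$train_points) %*% model$w +
            cbind(1, Q) %*% model$a)
}

#' @export
predict.tps_contour <- function(object, newdata, clamp = TRUE, ...) {
  v <- tps_eval(object, newdata)
  if (clamp) pmin(pmax(v, 0), 1) else v
}

#' Evaluate a fitted surface at points or on a grid
#'
#' With `query` given, returns a data frame of raw and `[0, 1]`-clamped
#' values plus an `extrapolated` flag for points outside the padded data
#' bounding box.  Without `query`, evaluates on an `n_grid x n_grid` regular
#' grid over the padded bounding box and returns a `grid_field`: strictly
#' increasing axes and both the raw and clamped value grids (clamping
#' affects display and classification only; the raw surface is kept for
#' audit).
#'
#' @param model a `tps_contour` model.
#' @param query optional `k x 2` matrix of evaluation points.
#' @param n_grid grid resolution per axis (default 200).
#' @param padding bounding-box padding fraction (default: as fitted).
#' @return A data frame (point query) or a `grid_field` list
#'   (`x`, `y`, `raw`, `values`).
#' @export
evaluate_surface <- function(model, query = NULL, n_grid = 200L, padding = NULL) {
  if (!inherits(model, "tps_contour")) stop_("'model' must be a tps_contour")
  if (!is.null(query)) {
    Q <- matrix(as.numeric(as.matrix(query)), ncol = 2L)
    raw <- tps_eval(model, Q)
    outside <- Q[, 1L] < model$bbox[1L, 1L] | Q[, 1L] > model$bbox[2L, 1L] |
               Q[, 2L] < model$bbox[1L, 2L] | Q[, 2L] > model$bbox[2L, 2L]
    return(data.frame(pp_raw = raw, pp = pmin(pmax(raw, 0), 1),
                      extrapolated = outside))
  }
  bbox <- model$bbox
  if (!is.null(padding)) {
    b <- apply(model$train_points, 2L, range)
    pad <- padding * (b[2L, ] - b[1L, ])
    bbox <- rbind(b[1L, ] - pad, b[2L, ] + pad)
  }
  xs <- seq(bbox[1L, 1L], bbox[2L, 1L], length.out = n_grid)
  ys <- seq(bbox[1L, 2L], bbox[2L, 2L], length.out = n_grid)
  Q <- cbind(rep(xs, times = n_grid), rep(ys, each = n_grid))
  raw <- matrix(tps_eval(model, Q), n_grid, n_grid)
  structure(list(x = xs, y = ys, raw = raw,
                 values = pmin(pmax(raw, 0), 1)),
            class = "grid_field")
}

#' Classify new cases on a posterior-probability surface
#'
#' Reads each case's interpolated posterior probability off the fitted
#' surface (clamped to `[0, 1]`), labels it target (`pp > 0.5`), start
#' (`pp < 0.5`) or indeterminate (at 0.5, to floating-point tolerance),
#' reports which 0.1-wide probability band it falls in, flags low-confidence
#' cases (group-specific posterior below 0.8), and flags extrapolation
#' outside the convex hull of the training points — the regime in which the
#' surface is least trustworthy.
#'
#' @param model a `tps_contour` fitted to training posterior probabilities.
#' @param new_points `k x 2` matrix of new cases (same two ILDs, mm).
#' @param threshold classification threshold (default 0.5).
#' @param labels length-2 group labels (start, target); taken from the
#'   model's training groups when available.
#' @return Data frame: `pp_raw`, `pp`, `label`, `band` (e.g. `"0.6-0.7"`),
#'   `low_confidence`, `extrapolated`.
#' @export
classify_new <- function(model, new_points, threshold = 0.5, labels = NULL) {
  if (!inherits(model, "tps_contour")) stop_("'model' must be a tps_contour")
  labels <- labels %||% (if (!is.null(model$groups)) levels(model$groups)
                         else c("start", "target"))
  Q <- matrix(as.numeric(as.matrix(new_points)), ncol = 2L)
  raw <- tps_eval(model, Q)
  pp <- pmin(pmax(raw, 0), 1)
  lab <- label_from_pp(pp, labels, threshold)
  lo <- pmin(floor(pp * 10) / 10, 0.9)
  band <- sprintf("%.1f-%.1f", lo, lo + 0.1)
  inside <- mgcv::in.out(model$hull, Q)
  data.frame(pp_raw = raw, pp = pp, label = lab, band = band,
             low_confidence = pmax(pp, 1 - pp) < 0.8,
             extrapolated = !inside)
}

#' Posterior-probability contour scatterplot
#'
#' The graphical classifier: training individuals are plotted in the
#' two-ILD data space (circles for the start group, squares for the target
#' group), filled with a pink-to-blue gradient proportional to the target
#' posterior probability; thin-plate-spline contour lines of the surface are
#' drawn at 0.1 intervals, with the 0.5 classification boundary emphasized
#' in violet and the 0.2/0.8 80%-confidence levels highlighted in pink and
#' blue.  New cases can be overplotted (filled green circles / orange
#' squares by group, grey diamonds when unlabelled) and read off the
#' contours like elevations on a topographic map; an optional square grid
#' helps locate them precisely.
#'
#' @param x a `tps_contour` model.
#' @param new_points optional `k x 2` matrix of new cases.
#' @param new_groups optional factor of new-case labels (2 levels).
#' @param n_grid evaluation grid resolution (default 200).
#' @param levels contour levels (default `seq(0, 1, 0.1)`).
#' @param show_grid overlay a square reference grid?
#' @param xlab,ylab axis labels (default: training column names).
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, a list with the evaluated `grid_field` and the contour
#'   `levels` drawn.
#' @export
plot.tps_contour <- function(x, new_points = NULL, new_groups = NULL,
                             n_grid = 200L, levels = seq(0, 1, by = 0.1),
                             show_grid = FALSE, xlab = NULL, ylab = NULL, ...) {
  gf <- evaluate_surface(x, n_grid = n_grid)
  cn <- colnames(x$train_points) %||% c("ILD 1", "ILD 2")
  xlab <- xlab %||% paste(cn[1L], "(mm)")
  ylab <- ylab %||% paste(cn[2L], "(mm)")
  pal <- grDevices::colorRampPalette(c("deeppink", "lavenderblush3", "darkblue"))(101)
  graphics::plot(NA, xlim = range(gf$x), ylim = range(gf$y),
                 xlab = xlab, ylab = ylab, ...)
  if (show_grid) graphics::grid(col = "grey85", lty = 1)
  lcol <- ifelse(levels == 0.5, "mediumorchid4",
                 ifelse(levels == 0.2, "deeppink",
                        ifelse(levels == 0.8, "darkblue", "grey55")))
  lwd <- ifelse(levels == 0.5, 2.5, ifelse(levels %in% c(0.2, 0.8), 1.8, 1))
  for (i in seq_along(levels))
    graphics::contour(gf$x, gf$y, gf$raw, levels = levels[i], add = TRUE,
                      col = lcol[i], lwd = lwd[i], drawlabels = TRUE)
  pchs <- if (!is.null(x$groups)) ifelse(x$groups == levels(x$groups)[1L], 21, 22)
          else rep(21, nrow(x$train_points))
  cols <- pal[round(pmin(pmax(x$train_pp, 0), 1) * 100) + 1]
  graphics::points(x$train_points, pch = pchs, bg = cols, col = "grey25")
  if (!is.null(new_points)) {
    np <- as.matrix(new_points)
    if (!is.null(new_groups)) {
      ng <- droplevels(as.factor(new_groups))
      npch <- ifelse(ng == levels(ng)[1L], 21, 22)
      nbg <- ifelse(ng == levels(ng)[1L], "green3", "darkorange")
    } else { npch <- 23; nbg <- "grey50" }
    graphics::points(np, pch = npch, bg = nbg, col = "black", cex = 1.3)
  }
  invisible(list(grid = gf, levels = levels))
}

#' Export an evaluated grid field to CSV
#'
#' Long format: one row per grid node with raw and clamped surface values.
#'
#' @param gf a `grid_field` from [evaluate_surface()].
#' @param path output CSV.
#' @export
write_grid_field <- function(gf, path) {
  if (!inherits(gf, "grid_field")) stop_("'gf' must be a grid_field")
  df <- data.frame(x = rep(gf$x, times = length(gf$y)),
                   y = rep(gf$y, each = length(gf$x)),
                   pp_raw = as.vector(gf$raw),
                   pp_clamped = as.vector(gf$values))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}
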