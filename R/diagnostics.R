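#' Per-ILD group-contrast diagnostics
#'
#' For each canonical ILD, computes the ratio of the target-group mean to the
#' start-group mean, the grand mean of the two group means (mm), the
#' R-squared against the factor, and the within-group coefficients of
#' variation (sd/mean).  With `mean_source = "direct"` the group means are
#' averages of the per-individual ILDs; with `"form_consensus"` each group's
#' mean *configuration* is computed in form space first and the ILDs of the
#' two mean forms are used — a shortcut whose results are usually nearly
#' identical, but that is only meaningful on superimposed form data, never on
#' raw coordinates (group mean coordinates would then contain spurious
#' translational/rotational differences).
#'
#' @param x an `ild_matrix`, or (for `mean_source = "form_consensus"`) a
#'   `gpa_array` of unscaled form coordinates.
#' @param target two-level factor, or [factor_table].
#' @param mean_source `"direct"` or `"form_consensus"`.
#' @param map optional [symmetry_map] when `x` holds coordinates.
#' @return A data frame of class `ild_diagnostics` with one row per canonical
#'   ILD: `name`, `ratio_of_means`, `grand_mean`, `r2`, `cv_start`,
#'   `cv_target`; the mean source is kept as an attribute.
#' @export
ild_diagnostics <- function(x, target, mean_source = c("direct", "form_consensus"),
                            map = NULL) {
  mean_source <- match.arg(mean_source)
  if (mean_source == "form_consensus") {
    if (!inherits(x, "gpa_array"))
      stop_("form-consensus means need superimposed form data; ",
            "they cannot be used when the input contains raw coordinates")
    if (x$scaled)
      stop_("form-consensus means need unscaled (form-space) data")
    arr <- x
    ilds <- compute_ilds(arr, map = map)
  } else {
    ilds <- if (inherits(x, "ild_matrix")) x else compute_ilds(x, map = map)
    arr <- NULL
  }
  tgt <- resolve_target(target, ilds$ids)
  if (tgt$mode != "factor") stop_("diagnostics need a two-level factor")
  f <- tgt$f
  start <- f == levels(f)[1L]

  can <- which(ilds$canonical)
  V <- ilds$values[, can, drop = FALSE]
  r2 <- score_columns(V, tgt)

  if (mean_source == "direct") {
    m_start <- colMeans(V[start, , drop = FALSE])
    m_target <- colMeans(V[!start, , drop = FALSE])
  } else {
    q <- n_lmk(arr); d <- arr$dim
    mean_cfg <- function(idx) apply(arr$coords[idx, , , drop = FALSE], c(2L, 3L), mean)
    ild_of <- function(cfg) {
      p <- ilds$pairs[can, , drop = FALSE]
      sqrt(rowSums((cfg[p[, 1L], , drop = FALSE] - cfg[p[, 2L], , drop = FALSE])^2))
    }
    m_start <- ild_of(mean_cfg(which(start)))
    m_target <- ild_of(mean_cfg(which(!start)))
  }
  sd_start <- apply(V[start, , drop = FALSE], 2L, stats::sd)
  sd_target <- apply(V[!start, , drop = FALSE], 2L, stats::sd)

  out <- data.frame(name = ilds$names[can],
                    ratio_of_means = m_target / m_start,
                    grand_mean = (m_start + m_target) / 2,
                    r2 = r2,
                    cv_start = sd_start / colMeans(V[start, , drop = FALSE]),
                    cv_target = sd_target / colMeans(V[!start, , drop = FALSE]),
                    row.names = NULL)
  attr(out, "mean_source") <- mean_source
  attr(out, "levels") <- levels(f)
  class(out) <- c("ild_diagnostics", "data.frame")
  out
}

#' Four-panel diagnostic plot for ILD/group contrasts
#'
#' (a) ratio of target-group to start-group mean ILD against the grand mean;
#' (b) R-squared against the grand mean, with a grey line at the top-2%
#' R-squared cut; (c) histogram of the ratios; (d) histogram of the
#' R-squared values.  Panels (a)-(c) are only meaningful for form-space
#' input; the R-squared histogram is scale-free.
#'
#' @param x an `ild_diagnostics` data frame.
#' @param r2tol percentile marked in panel (b) (default 0.98).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ild_diagnostics <- function(x, r2tol = 0.98, ...) {
  op <- graphics::par(mfrow = c(2L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  lv <- attr(x, "levels") %||% c("start", "target")
  graphics::plot(x$grand_mean, x$ratio_of_means,
                 xlab = "ILD grand mean (mm)",
                 ylab = sprintf("mean %s / mean %s", lv[2L], lv[1L]),
                 pch = 16, cex = 0.6, col = "grey30", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::plot(x$grand_mean, x$r2,
                 xlab = "ILD grand mean (mm)", ylab = "Rsq",
                 pch = 16, cex = 0.6, col = "grey30")
  graphics::abline(h = stats::quantile(x$r2, r2tol), col = "grey60", lwd = 2)
  graphics::hist(x$ratio_of_means, main = "", xlab = "ratio of group means",
                 col = "grey80", border = "white")
  graphics::hist(x$r2, main = "", xlab = "Rsq", col = "grey80", border = "white")
  invisible(x)
}
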