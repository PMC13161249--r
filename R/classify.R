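#' Fit a two-group linear discriminant model
#'
#' Gaussian equal-covariance discriminant: per-group mean vectors and the
#' pooled within-group covariance with divisor `n - 2`.  Priors default to
#' equal — the forensic convention, and identical to proportional priors
#' when the groups are balanced.
#'
#' @param X `n x p` numeric predictor matrix (columns named).
#' @param grouping two-level factor; the second level is the "target" group
#'   whose posterior probability is reported.
#' @param priors `"equal"` or `"proportional"`.
#' @return Object of class `ild_lda`: `means` (2 x p), `pooled_cov`,
#'   `priors`, `labels`, `predictors`, `n` (per group).
#' @export
fit_lda <- function(X, grouping, priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  f <- droplevels(as.factor(grouping))
  if (nlevels(f) != 2L) stop_("'grouping' must have exactly two levels")
  if (length(f) != nrow(X)) stop_("'grouping' length must match rows of X")
  n <- table(f)
  if (any(n < 2L)) stop_("both groups need at least 2 individuals")
  p <- ncol(X)
  i1 <- f == levels(f)[1L]
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  S <- (stats::cov(X[i1, , drop = FALSE]) * (n[1L] - 1L) +
        stats::cov(X[!i1, , drop = FALSE]) * (n[2L] - 1L)) / (sum(n) - 2L)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop_("pooled covariance is singular; use fewer (or less collinear) predictors")
  pr <- if (priors == "equal") c(0.5, 0.5) else as.vector(n / sum(n))
  structure(list(means = rbind(m1, m2), pooled_cov = S, chol = ch,
                 priors = pr, labels = levels(f), predictors = colnames(X),
                 n = as.vector(n)),
            class = "ild_lda")
}

#' @export
print.ild_lda <- function(x, ...) {
  cat(sprintf("Two-group LDA: %s (n=%d) vs %s (n=%d), %d predictor(s)\n",
              x$labels[1L], x$n[1L], x$labels[2L], x$n[2L],
              length(x$predictors)))
  cat("Predictors:", paste(x$predictors, collapse = ", "), "\n")
  cat("Priors:", paste(sprintf("%.3g", x$priors), collapse = " / "), "\n")
  invisible(x)
}

# squared Mahalanobis distances of rows of X to both group means
maha2_both <- function(model, X) {
  X <- matrix(as.numeric(X), ncol = length(model$predictors))
  d2 <- sapply(1:2, function(g)
    stats::mahalanobis(X, model$means[g, ], model$pooled_cov))
  matrix(d2, ncol = 2L)
}

#' Posterior probability of the target group
#'
#' Gaussian equal-covariance posterior
#' `pp_target = pi_T exp(-D2_T/2) / sum_g pi_g exp(-D2_g/2)` with `D2_g` the
#' squared Mahalanobis distance to group `g` under the pooled covariance.
#' The two group posteriors sum to one.
#'
#' @param model an `ild_lda` model.
#' @param x predictor vector, or an `n x p` matrix of cases.
#' @return Numeric vector of posterior probabilities of the *second*
#'   ("target") group.
#' @export
posterior <- function(model, x) {
  if (!inherits(model, "ild_lda")) stop_("'model' must be an ild_lda")
  d2 <- maha2_both(model, x)
  # log-space for numerical stability at large separations
  lg <- sweep(-d2 / 2, 2L, log(model$priors), `+`)
  mx <- pmax(lg[, 1L], lg[, 2L])
  e1 <- exp(lg[, 1L] - mx); e2 <- exp(lg[, 2L] - mx)
  as.vector(e2 / (e1 + e2))
}

#' Typicality probability of a case in a group
#'
#' Upper-tail probability of the chi-squared distribution with `p` degrees of
#' freedom at the squared Mahalanobis distance of the case from the group
#' mean.  Small values flag cases atypical for the group even when the
#' posterior classifies them confidently.
#'
#' @param model an `ild_lda` model.
#' @param x predictor vector or matrix of cases.
#' @param group group label (one of `model$labels`).
#' @return Probabilities in `[0, 1]` (1 at the group mean).
#' @export
typicality <- function(model, x, group) {
  if (!inherits(model, "ild_lda")) stop_("'model' must be an ild_lda")
  g <- match(group, model$labels)
  if (is.na(g)) stop_(sprintf("unknown group '%s'", group))
  d2 <- maha2_both(model, x)[, g]
  stats::pchisq(d2, df = length(model$predictors), lower.tail = FALSE)
}

#' @export
predict.ild_lda <- function(object, newdata, ...) {
  pp <- posterior(object, newdata)
  lab <- label_from_pp(pp, object$labels)
  list(class = lab, pp_target = pp,
       posterior = cbind(`colnames<-`(cbind(1 - pp, pp), object$labels)))
}

# classification rule: > 0.5 target, < 0.5 start; ties at 0.5 (to sqrt(eps),
# since posteriors are floating point) are "indeterminate"
label_from_pp <- function(pp, labels, threshold = 0.5) {
  out <- ifelse(abs(pp - threshold) <= sqrt(.Machine$double.eps), "indeterminate",
                ifelse(pp > threshold, labels[2L], labels[1L]))
  out
}

#' Leave-one-out cross-validated discriminant classification
#'
#' For each individual the full model (group means and pooled covariance) is
#' refit on the remaining `n - 1` cases and the held-out case is classified
#' by its posterior (threshold 0.5; an exact tie is labelled
#' `"indeterminate"` and counted as misclassified).  Reports the confusion
#' table, per-group accuracies, their unweighted average, and the signed
#' bias (first-group accuracy minus second-group accuracy, e.g. 92 and 87
#' give a bias of +5), plus per-individual posteriors and typicality in the
#' predicted group.
#'
#' @param X `n x p` predictor matrix.
#' @param grouping two-level factor.
#' @param priors `"equal"` (default) or `"proportional"`.
#' @param ids optional individual identifiers.
#' @return Object of class `ild_loo`; see [print.ild_loo()].
#' @export
loo_cv <- function(X, grouping, priors = c("equal", "proportional"), ids = NULL) {
  priors <- match.arg(priors)
  X <- as.matrix(X)
  f <- droplevels(as.factor(grouping))
  n <- nrow(X)
  if (length(f) != n) stop_("'grouping' length must match rows of X")
  if (min(table(f)) < 3L) stop_("leave-one-out would empty or degenerate a group")
  ids <- ids %||% rownames(X) %||% paste0("ind", seq_len(n))
  pp <- numeric(n); typ <- numeric(n); pred <- character(n)
  for (i in seq_len(n)) {
    m <- fit_lda(X[-i, , drop = FALSE], f[-i], priors = priors)
    pp[i] <- posterior(m, X[i, ])
    pred[i] <- label_from_pp(pp[i], m$labels)
    typ[i] <- typicality(m, X[i, ],
                         if (pred[i] == "indeterminate") as.character(f[i]) else pred[i])
  }
  build_report(truth = as.character(f), predicted = pred, labels = levels(f),
               pp_target = pp, typ = typ, ids = ids)
}

# assembles a ClassificationReport from per-individual records; split out so
# the accuracy/bias arithmetic is testable on synthetic confusion layouts
build_report <- function(truth, predicted, labels, pp_target, typ, ids) {
  # indeterminate cases count against the true group
  eff <- ifelse(predicted == "indeterminate",
                ifelse(truth == labels[1L], labels[2L], labels[1L]), predicted)
  confusion <- table(factor(truth, levels = labels),
                     factor(eff, levels = labels))
  acc <- 100 * diag(confusion) / rowSums(confusion)
  structure(list(confusion = unclass(confusion),
                 per_group_accuracy = stats::setNames(as.vector(acc), labels),
                 average_accuracy = mean(acc),
                 bias = as.vector(acc[1L] - acc[2L]),
                 labels = labels,
                 per_individual = data.frame(id = ids, true = truth,
                                             predicted = predicted,
                                             pp_target = pp_target,
                                             typicality = typ)),
            class = "ild_loo")
}

#' @export
print.ild_loo <- function(x, ...) {
  l <- x$labels
  cf <- x$confusion
  pct <- round(100 * cf / rowSums(cf))
  cat("Leave-one-out cross-validated classification (%)\n")
  cat(sprintf("%-12s %-4s %5s %5s %9s %9s\n", "Validation", "Sex",
              l[1L], l[2L], "Average", paste0(l[1L], "-biased")))
  cat(sprintf("%-12s %-4s %5d %5d\n", "LOO-ILDs", l[1L], pct[1L, 1L], pct[1L, 2L]))
  cat(sprintf("%-12s %-4s %5d %5d %9.0f %9.0f\n", "", l[2L],
              pct[2L, 1L], pct[2L, 2L], x$average_accuracy, x$bias))
  lowtyp <- sum(x$per_individual$typicality < 0.01)
  if (lowtyp > 0)
    cat(sprintf("Note: %d case(s) with typicality probability < 0.01\n", lowtyp))
  invisible(x)
}

#' Export a classification report to CSV
#'
#' Writes the summary row (per-group accuracies, average, bias) and the
#' per-individual records.
#'
#' @param x an `ild_loo` report.
#' @param path output CSV for the per-individual table; the summary goes to
#'   `<stem>_summary.csv`.
#' @export
write_report <- function(x, path) {
  if (!inherits(x, "ild_loo")) stop_("'x' must be an ild_loo report")
  utils::write.csv(x$per_individual, path, row.names = FALSE)
  s <- data.frame(t(c(x$per_group_accuracy,
                      Average = x$average_accuracy, Bias = x$bias)))
  utils::write.csv(s, sub("\\.csv$", "_summary.csv", path), row.names = FALSE)
  invisible(NULL)
}

#' Save / load a fitted discriminant model as JSON
#'
#' A plain-text round-trippable export (means, pooled covariance, priors,
#' labels, predictor names) so a fitted model can seed the contour module or
#' be shared.
#'
#' @param model an `ild_lda`.
#' @param path JSON file.
#' @return `read_lda_model` returns the reconstructed `ild_lda`; posteriors
#'   computed from it match the original to full precision.
#' @export
write_lda_model <- function(model, path) {
  if (!inherits(model, "ild_lda")) stop_("'model' must be an ild_lda")
  obj <- list(means = model$means, pooled_cov = model$pooled_cov,
              priors = model$priors, labels = model$labels,
              predictors = model$predictors, n = model$n)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(NULL)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  S <- matrix(unlist(obj$pooled_cov), length(obj$predictors))
  dimnames(S) <- list(obj$predictors, obj$predictors)
  means <- matrix(unlist(obj$means), 2L)
  colnames(means) <- obj$predictors
  structure(list(means = means, pooled_cov = S, chol = chol(S),
                 priors = as.numeric(obj$priors), labels = obj$labels,
                 predictors = obj$predictors, n = as.integer(obj$n)),
            class = "ild_lda")
}
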