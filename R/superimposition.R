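#' Centroid size of a landmark configuration
#'
#' The square root of the summed squared deviations of all landmarks from the
#' configuration centroid — the standard morphometric size measure, in the
#' units of the coordinates (mm).
#'
#' @param config `q x d` numeric matrix of landmark coordinates.
#' @return Non-negative scalar; 0 for a single landmark.
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  if (nrow(config) < 1L) stop_("need at least one landmark")
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2L, ctr)^2))
}

# rotation R (det +1) minimizing ||A %*% R - B||_F
rotation_onto <- function(A, B) {
  s <- svd(crossprod(A, B))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]  # flip smallest singular direction
    R <- u %*% t(s$v)
  }
  R
}

#' Generalized Procrustes superimposition
#'
#' Iteratively centres each configuration, rotates it to the running consensus
#' by the rotation-only orthogonal Procrustes solution (reflections are never
#' allowed), and updates the consensus until its root-mean-square change falls
#' below `tol`.  With `scale = FALSE` (the default) configurations keep their
#' original centroid size, yielding *form space*: size, and hence every
#' interlandmark distance, is preserved exactly.  With `scale = TRUE` each
#' configuration is rescaled to unit centroid size before rotation (shape
#' space).
#'
#' The global orientation of the result is fixed, deterministically, by
#' rotating the whole aligned set so that the consensus matches the first
#' individual's centred configuration as closely as possible.
#'
#' @param data a [landmark_array].
#' @param scale logical; rescale configurations to unit centroid size?
#' @param tol convergence tolerance on the RMS consensus change (default
#'   `1e-10`).
#' @param max_iter maximum number of iterations (default 200); an error is
#'   raised if the algorithm has not converged by then.
#' @return An object of class `gpa_array` (also a `landmark_array`) with
#'   aligned `coords`, the `consensus` (`q x d`), per-individual
#'   `centroid_sizes` (pre-alignment, mm) and flags `scaled`, `symmetrized`.
#' @export
gpa <- function(data, scale = FALSE, tol = 1e-10, max_iter = 200L) {
  if (!inherits(data, "landmark_array")) stop_("'data' must be a landmark_array")
  co <- data$coords
  n <- dim(co)[1L]; q <- dim(co)[2L]; d <- dim(co)[3L]
  cs <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- matrix(co[i, , ], q, d)
    cfg <- sweep(cfg, 2L, colMeans(cfg))
    cs[i] <- sqrt(sum(cfg^2))
    if (cs[i] <= .Machine$double.eps)
      stop_(sprintf("degenerate configuration (all landmarks coincident) for individual '%s'",
                    data$ids[i]))
    X[[i]] <- if (scale) cfg / cs[i] else cfg
  }
  first <- X[[1L]]
  consensus <- X[[1L]]
  converged <- n == 1L
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) X[[i]] <- X[[i]] %*% rotation_onto(X[[i]], consensus)
    new_cons <- Reduce(`+`, X) / n
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) converged <- TRUE
  }
  if (!converged && n > 1L)
    stop_(sprintf("Procrustes superimposition did not converge in %d iterations", max_iter))
  # deterministic global orientation: align consensus to the first individual's
  # centred configuration
  R0 <- rotation_onto(consensus, first)
  consensus <- consensus %*% R0
  out <- array(NA_real_, dim(co), dimnames = dimnames(co))
  for (i in seq_len(n)) out[i, , ] <- X[[i]] %*% R0
  structure(list(coords = out, ids = data$ids, landmarks = data$landmarks,
                 dim = d, consensus = consensus, centroid_sizes = cs,
                 scaled = scale, symmetrized = isTRUE(data$symmetrized)),
            class = c("gpa_array", "landmark_array"))
}

# mirrored-and-relabelled copy of one configuration: negate the first axis and
# swap left/right labels
reflect_relabel <- function(cfg, sigma) {
  m <- cfg[sigma, , drop = FALSE]
  m[, 1L] <- -m[, 1L]
  m
}

#' Extract the symmetric component of bilaterally symmetric configurations
#'
#' For each aligned individual, a mirrored copy is built by negating the first
#' coordinate axis and swapping each left/right landmark pair; the mirrored
#' copy is rigidly aligned (rotation only) back onto the original and the two
#' are averaged landmark-wise.  The averaged configurations re-enter
#' [gpa()] without scaling.  The result is invariant under
#' reflect-and-relabel, so every mirror-redundant interlandmark distance pair
#' becomes numerically identical; small digitizing asymmetries are discarded.
#'
#' @param data a `gpa_array` from [gpa()].
#' @param map a [symmetry_map] partitioning the landmarks.
#' @return A `gpa_array` with `symmetrized = TRUE`.
#' @export
symmetrize <- function(data, map) {
  if (!inherits(data, "gpa_array")) stop_("'data' must come from gpa()")
  q <- n_lmk(data)
  check_map(map, q)
  sigma <- mirror_permutation(map)
  co <- data$coords
  n <- dim(co)[1L]; d <- dim(co)[3L]
  if (d != 3L && d != 2L) stop_("unsupported dimensionality")
  sym <- array(NA_real_, dim(co), dimnames = dimnames(co))
  for (i in seq_len(n)) {
    cfg <- matrix(co[i, , ], q, d)
    cfg <- sweep(cfg, 2L, colMeans(cfg))
    mir <- reflect_relabel(cfg, sigma)
    mir <- mir %*% rotation_onto(mir, cfg)
    sym[i, , ] <- (cfg + mir) / 2
  }
  arr <- landmark_array(sym, individual_ids = data$ids,
                        landmark_names = data$landmarks)
  out <- gpa(arr, scale = data$scaled)
  out$symmetrized <- TRUE
  out$centroid_sizes <- vapply(seq_len(n), function(i)
    centroid_size(matrix(sym[i, , ], q, d)), 0)
  out
}
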