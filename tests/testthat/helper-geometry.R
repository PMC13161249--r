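# shared test utilities: small configurations and rigid motions

# random proper rotation matrix
rand_rotation <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(rnorm(d * d), d))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# apply a random rigid motion (rotation + translation) to one configuration
rigid_motion <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(cfg)
  cfg %*% rand_rotation(d) + matrix(runif(d, -50, 50), nrow(cfg), d, byrow = TRUE)
}

# independent least-squares alignment used as an oracle: rotate A onto B
align_onto <- function(A, B) {
  s <- svd(t(A) %*% B)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { s$u[, ncol(s$u)] <- -s$u[, ncol(s$u)]; R <- s$u %*% t(s$v) }
  A %*% R
}

# tiny symmetric test configuration: 2 midplane + 2 bilateral pairs (q = 6)
tiny_symmetric <- function() {
  cfg <- rbind(glabella  = c(0, 80, 10),
               basion    = c(0, -40, -30),
               alare_L   = c(-20, 50, -10),
               alare_R   = c(20, 50, -10),
               zygion_L  = c(-60, 0, 0),
               zygion_R  = c(60, 0, 0))
  map <- symmetry_map(c("midplane", "midplane", "left", "right", "left", "right"),
                      landmarks = rownames(cfg))
  list(cfg = cfg, map = map)
}

# n noisy copies of a symmetric configuration as a landmark_array
tiny_sample <- function(n = 6, noise = 0.5, seed = 1) {
  set.seed(seed)
  ts <- tiny_symmetric()
  arr <- array(NA_real_, c(n, nrow(ts$cfg), 3L))
  for (i in seq_len(n))
    arr[i, , ] <- ts$cfg + matrix(rnorm(length(ts$cfg), 0, noise), nrow(ts$cfg))
  list(data = landmark_array(arr, landmark_names = rownames(ts$cfg)),
       map = ts$map, cfg = ts$cfg)
}
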