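# Shared internal helpers. Lengths nm, times ps throughout.

# Minimum-image correction of displacements along one periodic axis.
# `d` raw displacements, `box` matching box lengths (recycled).
min_image <- function(d, box) {
  d - box * round(d / box)
}

# Wrap coordinates into [0, box).
wrap_box <- function(x, box) {
  x - box * floor(x / box)
}

# Deterministic 1-D two-means split. Returns list(centers, cluster) with
# cluster 1 = lower-centre group. Initialised at the range extremes so the
# result does not depend on input order.
two_means_1d <- function(z, max_iter = 100L) {
  c_lo <- min(z)
  c_hi <- max(z)
  cl <- rep(1L, length(z))
  for (i in seq_len(max_iter)) {
    new_cl <- ifelse(abs(z - c_lo) <= abs(z - c_hi), 1L, 2L)
    if (all(new_cl == cl) && i > 1L) break
    cl <- new_cl
    if (any(cl == 1L)) c_lo <- mean(z[cl == 1L])
    if (any(cl == 2L)) c_hi <- mean(z[cl == 2L])
  }
  if (c_lo > c_hi) { # keep cluster 1 the lower group
    cl <- 3L - cl
    tmp <- c_lo; c_lo <- c_hi; c_hi <- tmp
  }
  list(centers = c(c_lo, c_hi), cluster = cl)
}

# Angle in degrees at vertex `v` subtended by points `a` and `b`.
# All arguments are n x 3 matrices; returns a length-n vector.
vertex_angle_deg <- function(a, v, b) {
  u1 <- a - v
  u2 <- b - v
  n1 <- sqrt(rowSums(u1^2))
  n2 <- sqrt(rowSums(u2^2))
  cosang <- rowSums(u1 * u2) / (n1 * n2)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

# Extract, for a set of atom row indices, an n_frames x n_atoms matrix of one
# coordinate axis (1 = x, 2 = y, 3 = z).
traj_axis_matrix <- function(traj, ids, axis = 3L) {
  out <- vapply(traj$coords, function(m) m[ids, axis], numeric(length(ids)))
  if (length(ids) == 1L) matrix(out, ncol = 1L) else t(out)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
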