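# Internal geometry helpers shared across modules.

# Reshape one row of an ensemble xyz matrix (x1,y1,z1,x2,...) into n x 3.
xyz_to_mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

mat_to_xyz <- function(m) as.numeric(t(m))

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

# Optimal rotation (no reflection) mapping mobile onto fixed, both n x 3,
# after centering. Returns list(R, t_fixed, t_mobile): apply as
# (x - t_mobile) %*% R + t_fixed.
kabsch <- function(fixed, mobile) {
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  A <- crossprod(sweep(mobile, 2, cm), sweep(fixed, 2, cf))
  s <- svd(A)
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  list(R = R, t_fixed = cf, t_mobile = cm)
}

apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$t_mobile) %*% fit$R, 2, fit$t_fixed, `+`)
}

rmsd_fit <- function(fixed, mobile) {
  ft <- kabsch(fixed, mobile)
  moved <- apply_fit(mobile, ft)
  sqrt(mean(rowSums((moved - fixed)^2)))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Dihedral angle (degrees, in (-180, 180]) defined by four points.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- vec_norm(b2)
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

angle_deg <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  cosang <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# Random rigid-body motion used by invariance tests and docs examples.
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (vec_norm(q) > 1e-8) break
  }
  q <- q / vec_norm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
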