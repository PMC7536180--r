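# Small 3D geometry utilities shared across modules. All angles in degrees
# unless noted; coordinates are plain numeric 3-vectors or n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg <- function(rad) rad * 180 / pi
rad <- function(deg) deg * pi / 180

#' Angle at vertex b of the triple a-b-c, in degrees
#' @param a,b,c numeric 3-vectors
#' @return angle in degrees in [0, 180]
#' @keywords internal
vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  deg(acos(max(-1, min(1, ct))))
}

#' Signed dihedral a-b-c-d, IUPAC convention, degrees in (-180, 180]
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D given positions of A, B, C, a bond length |C-D|, the angle
# B-C-D and the torsion A-B-C-D (NeRF construction).
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- rad(angle); tor <- rad(torsion)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  # minus sign on the out-of-plane term so the realized IUPAC dihedral
  # a-b-c-new equals `torsion`
  d2 <- length * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for angle degrees about unit axis (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  u <- unit(axis); th <- rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Rotation angle (degrees, [0,180]) of a rotation matrix.
rotation_angle_of <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  deg(acos(max(-1, min(1, ct))))
}

# Signed twist (degrees, (-180,180]) of rotation R about unit axis a:
# the rotation component about a in a swing-twist decomposition,
# computed via the quaternion projection onto the axis.
twist_about_axis <- function(R, axis) {
  a <- unit(axis)
  # quaternion from rotation matrix (w >= 0 branch)
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    w <- s / 4
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / s
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    v <- numeric(3)
    v[i] <- s / 4
    v[j] <- (R[j, i] + R[i, j]) / s
    v[k] <- (R[k, i] + R[i, k]) / s
    w <- (R[k, j] - R[j, k]) / s
  }
  p <- sum(v * a)
  ang <- deg(2 * atan2(p, w))
  if (ang > 180) ang <- ang - 360
  if (ang <= -180) ang <- ang + 360
  ang
}

# Principal axis (first PC direction) through an n x 3 coordinate matrix,
# oriented from the first point toward the last.
principal_axis <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  a <- sv$v[, 1]
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * a) < 0) a <- -a
  list(center = ctr, axis = unit(a))
}

# Helix axis by the curvature (second-difference) construction: the
# vectors h_k = p_k - 2 p_{k+1} + p_{k+2} are radial for an ideal helix,
# so successive cross products all point along the axis. Exact for ideal
# helices regardless of phase coverage, where a plain principal-component
# line can tilt by a few tenths of a degree; falls back to the principal
# axis for very short inputs. Oriented first point -> last point.
helix_axis <- function(xyz) {
  n <- nrow(xyz)
  if (n < 5) return(principal_axis(xyz))
  H <- xyz[1:(n - 2), ] - 2 * xyz[2:(n - 1), ] + xyz[3:n, ]
  acc <- c(0, 0, 0)
  for (k in seq_len(nrow(H) - 1)) {
    v <- cross3(H[k, ], H[k + 1, ])
    nv <- vnorm(v)
    if (nv < 1e-12) next
    v <- v / nv
    if (sum(v * acc) < 0) v <- -v
    acc <- acc + v
  }
  if (vnorm(acc) < 1e-9) return(principal_axis(xyz))
  a <- unit(acc)
  if (sum((xyz[n, ] - xyz[1, ]) * a) < 0) a <- -a
  list(center = colMeans(xyz), axis = a)
}
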