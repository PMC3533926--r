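# Internal vector/rotation helpers shared across modules. All coordinates are
# in Angstrom, angles in degrees unless a function says otherwise.

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-10) stop("cannot normalise a zero-length vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' @noRd
# Four-point torsion angle, IUPAC sign convention, in (-180, 180].
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- -rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle difference into (-180, 180].
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x == -180] <- 180
  x
}

# Place atom D from A-B-C using bond length r (C-D), bond angle theta
# (B-C-D, degrees) and torsion chi (A-B-C-D, degrees).  Natural extension
# reference frame construction.
nerf_place <- function(a, b, c, r, theta, chi) {
  theta <- deg2rad(theta)
  chi <- deg2rad(chi)
  b2 <- vunit(c - b)
  n <- vunit(vcross(b - a, b2))
  m <- vcross(n, b2)
  c + r * (-cos(theta) * b2 + sin(theta) * (cos(chi) * m + sin(chi) * n))
}

# Rotation matrix (column convention, y = R %*% x) about unit axis k, deg.
rotation_matrix <- function(axis, deg) {
  k <- vunit(axis)
  th <- deg2rad(deg)
  K <- matrix(c(0, k[3L], -k[2L],
                -k[3L], 0, k[1L],
                k[2L], -k[1L], 0), nrow = 3L)
  diag(3L) * cos(th) + sin(th) * K + (1 - cos(th)) * tcrossprod(k)
}

# Rotate rows of an n x 3 matrix about a point along an axis.
rotate_points <- function(xyz, origin, axis, deg) {
  R <- rotation_matrix(axis, deg)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, "+")
}

# Kabsch least-squares superposition of mobile onto reference (both n x 3).
# Returns rotation R (proper, det +1), translation t and the fitted rmsd,
# with the convention fitted = mobile %*% t(R) + t (rows are coordinates).
kabsch_fit <- function(mobile, reference) {
  if (nrow(mobile) != nrow(reference))
    stop("mobile and reference must have the same number of atoms")
  if (nrow(mobile) < 3L)
    stop("degenerate fit: need at least 3 atoms for superposition")
  mc <- colMeans(mobile)
  rc <- colMeans(reference)
  M <- sweep(mobile, 2L, mc)
  Rf <- sweep(reference, 2L, rc)
  # collinearity check: rank of the centred mobile cloud
  sv <- svd(M)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1))
    stop("degenerate fit: fit atoms are (near-)collinear")
  H <- crossprod(M, Rf)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  Rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # column convention
  tr <- rc - as.vector(Rot %*% mc)
  fitted <- M %*% t(Rot)
  rmsd <- sqrt(mean(rowSums((fitted - Rf)^2)))
  list(rotation = Rot, translation = tr, rmsd = rmsd)
}

apply_fit <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2L, fit$translation, "+")
}

# Principal axis of an n x 3 point cloud, oriented from the first toward the
# last point (N -> C for residue-ordered Calpha sets).
principal_axis <- function(xyz) {
  if (nrow(xyz) < 4L) stop("need at least 4 points to fit an axis")
  cen <- colMeans(xyz)
  p <- prcomp(xyz, center = TRUE)
  ax <- p$rotation[, 1L]
  ends <- xyz[nrow(xyz), ] - xyz[1L, ]
  if (sum(ax * ends) < 0) ax <- -ax
  vunit(ax)
}
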