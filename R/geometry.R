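# Small 3D geometry kernel used by the TS builder: vector helpers, rotation
# about an arbitrary axis (Rodrigues), and rigid superposition (Kabsch).

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix for angle theta (radians) about unit axis k.
rotation_matrix <- function(k, theta) {
  k <- unit(k)
  K <- matrix(c(0, -k[3], k[2],
                k[3], 0, -k[1],
                -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Rotate points (n x 3) about the axis through `origin` with direction `axis`.
rotate_about_axis <- function(points, origin, axis, theta) {
  R <- rotation_matrix(axis, theta)
  shifted <- sweep(points, 2, origin)
  sweep(shifted %*% t(R), 2, origin, `+`)
}

#' Minimal RMSD between two point sets after rigid superposition
#'
#' Kabsch alignment of `b` onto `a` (rows are corresponding points).
#'
#' @param a,b n x 3 coordinate matrices with rows in correspondence.
#' @return The root-mean-square deviation in the units of the input.
#' @export
rmsd_aligned <- function(a, b) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == 3, ncol(b) == 3)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  s <- svd(t(bc) %*% ac)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  br <- bc %*% t(R)
  sqrt(mean(rowSums((ac - br)^2)))
}

# All pairwise distances between two coordinate sets (n x 3, m x 3) -> n x m.
cross_distances <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  sqrt(d2)
}
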