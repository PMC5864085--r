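# Rigid-body and distance primitives shared by the structure and density code.
# Internal unit conventions: coordinates nm, energies kJ/mol, times ns.

# Kabsch least-squares superposition: returns the rotation R and translation t
# such that mobile %*% R + t best fits fixed (row-vector convention).
kabsch <- function(fixed, mobile) {
  stopifnot(is.matrix(fixed), is.matrix(mobile),
            nrow(fixed) == nrow(mobile), ncol(fixed) == 3L, ncol(mobile) == 3L,
            nrow(fixed) >= 3L)
  cf <- colMeans(fixed)
  cm <- colMeans(mobile)
  P <- sweep(fixed, 2, cf)
  Q <- sweep(mobile, 2, cm)
  H <- crossprod(Q, P)                 # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t <- cf - as.vector(cm %*% R)
  list(rotation = R, translation = t)
}

apply_rigid <- function(coords, fit) {
  sweep(coords %*% fit$rotation, 2, fit$translation, "+")
}

# Minimum-image displacement components for an orthorhombic box.
# x: n x 3 displacement matrix; box: length-3 box vector (nm). Zero or NA
# box entries disable wrapping along that axis.
min_image <- function(x, box) {
  for (k in seq_len(ncol(x))) {
    b <- box[k]
    if (!is.na(b) && b > 0) x[, k] <- x[, k] - b * round(x[, k] / b)
  }
  x
}

# All pairwise minimum-image distances between two coordinate sets.
# Returns an nrow(a) x nrow(b) matrix. Sizes here are CG-bead scale
# (hundreds), so the dense matrix is fine.
cross_dist <- function(a, b, box = NULL) {
  na <- nrow(a); nb <- nrow(b)
  if (is.null(box)) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    return(sqrt(d2))
  }
  d2 <- matrix(0, na, nb)
  for (k in seq_len(ncol(a))) {
    dk <- outer(a[, k], b[, k], "-")
    bk <- box[k]
    if (!is.na(bk) && bk > 0) dk <- dk - bk * round(dk / bk)
    d2 <- d2 + dk^2
  }
  sqrt(d2)
}

# Deterministic quasi-uniform points on the unit sphere (golden-spiral
# lattice), used by the Shrake-Rupley surface sampling.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# z-rotation matrix for row-vector convention: x %*% rot_z(theta) rotates
# points counterclockwise by theta degrees about +z.
rot_z <- function(theta_deg) {
  r <- theta_deg * pi / 180
  matrix(c(cos(r), sin(r), 0,
           -sin(r), cos(r), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
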