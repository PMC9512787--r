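#' Rigid transforms
#'
#' A rigid transform is a rotation `R` (3x3, det +1) plus a translation
#' `t`; applying it maps a coordinate row-vector `p` to `p %*% t(R) + t`.
#'
#' @param R 3x3 rotation matrix
#' @param t length-3 translation (Angstrom)
#' @return an object of class `rigid_transform`
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- unname(as.matrix(R)); t <- as.numeric(t)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(R %*% t(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("R is not a proper rotation", call. = FALSE)
  }
  structure(list(R = R, t = t), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_axis(x$R)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f)\n",
              ang$angle, x$t[1], x$t[2], x$t[3]))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param x an N x 3 coordinate matrix or an atom table
#' @param tf a [rigid_transform()]
#' @return same shape as `x`, transformed
#' @export
apply_transform <- function(x, tf) {
  if (inherits(x, "atom_tbl") || is.data.frame(x)) {
    return(set_coords(x, apply_transform(coords(x), tf)))
  }
  sweep(x %*% t(tf$R), 2, tf$t, "+")
}

#' Compose / invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b,tf rigid transforms
#' @return a rigid transform
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired point sets, via SVD of the covariance matrix with the usual
#' determinant correction so reflections are never returned. Degenerate
#' (rank-deficient) point sets are handled by the same correction.
#'
#' @param mobile,reference N x 3 matrices, rows paired by index (N >= 3)
#' @return a list: `transform` ([rigid_transform()] taking `mobile` onto
#'   `reference`) and `rmsd` (Angstrom, after superposition)
#' @export
kabsch <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3 ||
      ncol(reference) != 3) {
    stop("mobile and reference must be N x 3 with equal N", call. = FALSE)
  }
  if (nrow(mobile) < 3) stop("need at least 3 points", call. = FALSE)
  if (!all(is.finite(mobile)) || !all(is.finite(reference))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t <- as.numeric(cr - R %*% cm)
  tf <- rigid_transform(R, t)
  moved <- apply_transform(mobile, tf)
  list(transform = tf,
       rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

#' RMSD between paired coordinate sets
#'
#' @param a,b N x 3 matrices (no superposition is performed)
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}

# axis-angle decomposition of a rotation matrix; angle in [0, 180] deg,
# axis right-handed. Near 180 deg the skew part vanishes, so the axis is
# taken from the eigenvector of R for eigenvalue +1.
rotation_angle_axis <- function(R, tol = 1e-6) {
  tr <- sum(diag(R))
  cth <- (tr - 1) / 2
  if (cth > 1 + tol || cth < -1 - tol) {
    stop("rotation trace out of range: trace = ", format(tr), call. = FALSE)
  }
  cth <- min(1, max(-1, cth))
  sk <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  sth <- sqrt(sum(sk^2)) / 2
  # atan2 keeps full precision at both ends of the range, where acos of
  # the trace alone loses half the significant digits
  angle <- atan2(sth, cth)
  if (angle < 1e-9) {
    return(list(angle = 0, axis = c(0, 0, 1)))
  }
  if (pi - angle > 1e-4) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(angle))
  } else {
    ev <- eigen(R)
    k <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, k])
    ax <- ax / sqrt(sum(ax^2))
    # fix sign so that the skew part (if any) agrees
    sk <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sum(sk * ax) < 0) ax <- -ax
  }
  list(angle = angle * 180 / pi, axis = ax / sqrt(sum(ax^2)))
}

# rotation matrix about a unit axis by angle (degrees), right-handed
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
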