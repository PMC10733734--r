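#' Kabsch least-squares superposition
#'
#' Computes the proper rotation and translation minimising the RMSD of the
#' mobile point set onto the target, with the reflection branch of the SVD
#' corrected by the sign of the determinant so that the result is always a
#' pure rotation.
#'
#' @param mobile,target Numeric n x 3 matrices (n >= 3) of paired points.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3),
#'   and `rmsd` (Angstrom). A point x maps as `rotation %*% x + translation`.
#' @examples
#' p <- matrix(rnorm(30), 10, 3)
#' fit <- kabschSuperpose(p, p)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target))) {
    stop("mobile and target must have identical dimensions")
  }
  if (nrow(mobile) < 3L || ncol(mobile) != 3L) {
    stop("superposition needs at least 3 paired 3D points")
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  M <- sweep(mobile, 2, cm)
  T <- sweep(target, 2, ct)
  H <- t(M) %*% T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- M %*% t(R)
  rmsd <- sqrt(sum((moved - T)^2) / nrow(M))
  list(rotation = R, translation = as.numeric(ct - R %*% cm), rmsd = rmsd)
}

#' Apply a superposition result to coordinates
#' @param coords n x 3 matrix.
#' @param fit Result of [kabschSuperpose()].
#' @return Transformed n x 3 matrix.
#' @export
applySuperposition <- function(coords, fit) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}
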