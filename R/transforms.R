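#' Rigid-body transform
#'
#' A rotation plus translation acting on Nx3 coordinate matrices as
#' `x %*% t(R) + t`. Rotations must be proper orthonormal matrices.
#'
#' @param R 3x3 rotation matrix.
#' @param t length-3 translation (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stop("R must be a proper orthonormal rotation matrix")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz Nx3 coordinate matrix.
#' @param tr A [rigid_transform()].
#' @return Transformed Nx3 matrix.
#' @export
apply_transform <- function(xyz, tr) {
  stopifnot(inherits(tr, "rigid_transform"))
  sweep(xyz %*% t(tr$R), 2, -tr$t)
}

# rotation about a unit axis by angle (radians), Rodrigues form
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# uniform random rotation via a random unit quaternion (uses R's RNG)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# orthonormal frame (3x3, columns e1 e2 e3) with e1 along `v`
frame_from_direction <- function(v) {
  e1 <- v / sqrt(sum(v^2))
  ref <- if (abs(e1[1]) > 0.9) c(0, 1, 0) else c(1, 0, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  cbind(e1, e2, e3)
}
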