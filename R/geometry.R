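#' Rigid pose: axis-angle rotation plus translation
#'
#' A pose carries body Q from its reference placement to its current
#' placement while body P stays fixed; the reference pose is the identity.
#' Rotation is about an axis through the origin of the frame attached to P,
#' right-handed, with positive angles counterclockwise when viewed from the
#' +axis direction. Angles are in radians; length units are whatever the
#' particle coordinates use (no conversion is performed).
#'
#' @param axis unit 3-vector (checked to 1e-9 whenever `angle != 0`)
#' @param angle rotation angle in radians
#' @param translation 3-vector
#' @return an object of class `"rigid_pose"`
#' @examples
#' p <- pose(angle = pi / 2, translation = c(1, 0, 0))
#' apply_pose(p, c(1, 0, 0))
#' @export
pose <- function(axis = c(0, 0, 1), angle = 0, translation = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  translation <- as.numeric(translation)
  stopifnot(length(axis) == 3, length(translation) == 3, length(angle) == 1)
  if (!is.finite(angle)) stop("pose angle must be finite")
  if (!all(is.finite(translation))) stop("pose translation must be finite")
  if (angle != 0) {
    nrm <- sqrt(sum(axis^2))
    if (abs(nrm - 1) > 1e-9) {
      stop("rotation axis must have unit norm (got ", format(nrm), ")")
    }
  }
  structure(list(axis = axis, angle = angle, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("<rigid_pose> angle =", format(x$angle),
      " axis = (", paste(format(x$axis), collapse = ", "), ")",
      " translation = (", paste(format(x$translation), collapse = ", "), ")\n")
  invisible(x)
}

#' Rigid pose families
#'
#' A pose family fixes which of the six rigid-motion parameters vary:
#' \describe{
#'   \item{`translation_x1`}{one free parameter `x1`, translation along the
#'     first axis, no rotation.}
#'   \item{`rotation_x3`}{one free parameter `theta`, rotation about the
#'     third axis through the frame origin, no translation.}
#'   \item{`general_se3`}{six free parameters `(r1, r2, r3, x1, x2, x3)`:
#'     a rotation vector (axis times angle) followed by a translation.}
#' }
#'
#' @param kind one of `"translation_x1"`, `"rotation_x3"`, `"general_se3"`
#' @param fixed named list of frozen parameters (currently unused by the
#'   built-in families; kept for forward compatibility)
#' @return an object of class `"pose_family"`
#' @export
pose_family <- function(kind = c("translation_x1", "rotation_x3", "general_se3"),
                        fixed = list()) {
  kind <- match.arg(kind)
  vars <- switch(kind,
    translation_x1 = "x1",
    rotation_x3 = "theta",
    general_se3 = c("r1", "r2", "r3", "x1", "x2", "x3"))
  structure(list(kind = kind, variable_names = vars, fixed_values = fixed),
            class = "pose_family")
}

#' @export
print.pose_family <- function(x, ...) {
  cat("<pose_family>", x$kind, "- free:",
      paste(x$variable_names, collapse = ", "), "\n")
  invisible(x)
}

n_free <- function(family) length(family$variable_names)

#' Axis-angle (Rodrigues) rotation matrix
#'
#' Entry (1,1) is `cos(angle) + u1^2 (1 - cos(angle))` and so on for the
#' standard axis-angle form; the returned matrix is orthogonal with
#' determinant +1.
#'
#' @param axis unit 3-vector (norm checked to 1e-9)
#' @param angle radians
#' @return 3x3 rotation matrix
#' @examples
#' axis_angle_matrix(c(0, 0, 1), pi / 2) %*% c(1, 0, 0) # ~ (0, 1, 0)
#' @export
axis_angle_matrix <- function(axis, angle) {
  axis <- as.numeric(axis)
  stopifnot(length(axis) == 3, length(angle) == 1)
  if (!is.finite(angle)) stop("angle must be finite (got NaN or Inf)")
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || abs(nrm - 1) > 1e-9) {
    stop("axis must be a unit vector (norm = ", format(nrm),
         "); normalize it before calling")
  }
  u <- axis
  ct <- cos(angle)
  st <- sin(angle)
  vt <- 1 - ct
  matrix(c(
    ct + u[1]^2 * vt,        u[1] * u[2] * vt - u[3] * st, u[1] * u[3] * vt + u[2] * st,
    u[2] * u[1] * vt + u[3] * st, ct + u[2]^2 * vt,        u[2] * u[3] * vt - u[1] * st,
    u[3] * u[1] * vt - u[2] * st, u[3] * u[2] * vt + u[1] * st, ct + u[3]^2 * vt),
    nrow = 3, byrow = TRUE)
}

#' Apply a rigid pose to points
#'
#' Each point is mapped to `R p + x` where `R` is the pose's rotation matrix
#' and `x` its translation.
#'
#' @param pose a [pose()]
#' @param points a 3-vector or an n x 3 matrix of points
#' @return object of the same shape as `points`
#' @export
apply_pose <- function(pose, points) {
  stopifnot(inherits(pose, "rigid_pose"))
  vec <- is.null(dim(points))
  pts <- if (vec) matrix(as.numeric(points), nrow = 1) else as.matrix(points)
  if (ncol(pts) != 3) stop("points must be 3-vectors")
  if (!all(is.finite(pts))) stop("points must be finite")
  out <- if (pose$angle == 0) pts else pts %*% t(axis_angle_matrix(pose$axis, pose$angle))
  out <- out + matrix(pose$translation, nrow(pts), 3, byrow = TRUE)
  if (vec) drop(out) else out
}

#' Build a pose from a family and its free-parameter values
#'
#' @param family a [pose_family()]
#' @param values numeric vector with one entry per free parameter
#' @return a [pose()]
#' @examples
#' make_pose(pose_family("translation_x1"), 2.5)
#' make_pose(pose_family("rotation_x3"), -pi / 4)
#' @export
make_pose <- function(family, values) {
  stopifnot(inherits(family, "pose_family"))
  values <- as.numeric(values)
  if (length(values) != n_free(family)) {
    stop("pose family '", family$kind, "' needs ", n_free(family),
         " parameter(s), got ", length(values))
  }
  switch(family$kind,
    translation_x1 = pose(translation = c(values[1], 0, 0)),
    rotation_x3 = pose(axis = c(0, 0, 1), angle = values[1]),
    general_se3 = {
      r <- values[1:3]
      ang <- sqrt(sum(r^2))
      ax <- if (ang > 0) r / ang else c(0, 0, 1)
      pose(axis = ax, angle = ang, translation = values[4:6])
    })
}
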