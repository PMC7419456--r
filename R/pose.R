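#' @useDynLib fetopose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

# Frame conventions used throughout the package (single source of truth):
#  * camera frame {C}: x right, y down, z along the viewing direction into the
#    scene; the image origin coincides with the origin of {C};
#  * placenta frame {P}: -P_z is the surface normal pointing into the uterine
#    cavity (towards the camera), so P_z points into the tissue;
#  * positive rotate_label() angles are counter-clockwise in (x, y) label
#    coordinates.
# Poses are 4x4 homogeneous rigid transforms, positions in mm.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Elementary rotation matrices
#'
#' Right-handed rotations about the coordinate axes, angles in degrees.
#'
#' @param deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_x <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_y <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @export
rot_z <- function(deg) {
  a <- deg2rad(deg); c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Test a matrix for orthonormality
#'
#' @param R a 3x3 matrix.
#' @param tol maximum allowed deviation of crossprod(R) from the identity and
#'   of det(R) from +1.
#' @return TRUE if `R` is a proper rotation within `tol`.
#' @export
is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

#' Build a rigid transform
#'
#' @param rotation 3x3 rotation matrix.
#' @param position length-3 translation (mm).
#' @return 4x4 homogeneous transform.
#' @export
rigid_transform <- function(rotation = diag(3), position = c(0, 0, 0)) {
  stopifnot(length(position) == 3L)
  if (!is_rotation_matrix(rotation, tol = 1e-6)) {
    stop("rotation part is not orthonormal")
  }
  T <- diag(4)
  T[1:3, 1:3] <- rotation
  T[1:3, 4] <- position
  T
}

normalize_vec <- function(v) v / sqrt(sum(v^2))

assert_unit <- function(v, name, tol = 1e-3) {
  n <- sqrt(sum(v^2))
  if (abs(n - 1) > tol) {
    stop(sprintf("'%s' is not a unit vector (norm %.6f)", name, n))
  }
  if (abs(n - 1) > 1e-9) {
    warning(sprintf("'%s' re-normalized (norm deviated by %.2e)", name, abs(n - 1)))
    v <- v / n
  }
  v
}

#' Inclination label from a relative rotation
#'
#' The minimal 2-component orientation representation: the x and y components
#' of the placenta z-axis expressed in the camera frame, i.e. the first two
#' entries of the third column of the camera-to-placenta rotation. (0, 0)
#' means the camera views the surface perpendicularly; the twist of the
#' placenta frame about its own z-axis does not enter.
#'
#' @param R 3x3 rotation of frame {P} relative to {C} (columns are the
#'   placenta axes in camera coordinates).
#' @return Numeric length-2 label `c(x, y)` with `x^2 + y^2 <= 1`.
#' @export
components_from_rotation <- function(R) {
  if (!is.matrix(R) || !all(dim(R) == c(3L, 3L))) {
    stop("R must be a 3x3 matrix")
  }
  if (max(abs(sqrt(colSums(R^2)) - 1)) > 1e-6 ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
    stop("invalid rotation: columns are not orthonormal with determinant +1")
  }
  c(x = R[1, 3], y = R[2, 3])
}

#' Inclination label from scene geometry
#'
#' Expresses the placenta z-axis (the opposite of the into-cavity surface
#' normal) in camera coordinates and returns its x and y components. Requires
#' the camera to face the surface: the placenta z-axis must have a positive
#' component along the camera optical axis.
#'
#' @param camera_pose 4x4 world-to-camera placement `^W T_C`.
#' @param normal_into_cavity unit surface normal pointing into the cavity
#'   (towards the camera), world coordinates.
#' @return Numeric length-2 label `c(x, y)`.
#' @export
label_from_scene <- function(camera_pose, normal_into_cavity) {
  stopifnot(is.matrix(camera_pose), all(dim(camera_pose) == c(4L, 4L)))
  n <- assert_unit(normal_into_cavity, "normal_into_cavity")
  Rc <- camera_pose[1:3, 1:3]
  p_z <- -n                         # placenta z points into the tissue
  v <- drop(crossprod(Rc, p_z))     # ^C Z_P
  if (v[3] <= 0) {
    stop("orientation out of range: camera faces away from the surface")
  }
  c(x = v[1], y = v[2])
}

#' Rotate an inclination label in the image plane
#'
#' Label transform matching an in-plane rotation of the image about its
#' center (the augmentation used to enrich sparsely sampled orientation
#' data). Positive angles are counter-clockwise in (x, y) label coordinates;
#' the Euclidean norm of the label is preserved exactly.
#'
#' @param label numeric length-2 label.
#' @param theta_deg rotation angle in degrees.
#' @return The rotated label.
#' @export
rotate_label <- function(label, theta_deg) {
  stopifnot(length(label) == 2L, is.finite(theta_deg))
  a <- deg2rad(theta_deg); c <- cos(a); s <- sin(a)
  c(x = c * label[[1]] - s * label[[2]],
    y = s * label[[1]] + c * label[[2]])
}

#' Convert label components to per-axis inclination angles
#'
#' Per-axis arcsine of each component, in degrees. This inverts the
#' projection exactly for single-axis tilts. Components outside [-1, 1]
#' (possible for raw network output) are clamped with a warning.
#'
#' @param label numeric length-2 label.
#' @return `c(angle_x, angle_y)` in degrees, each in [-90, 90].
#' @export
components_to_angles <- function(label) {
  stopifnot(length(label) == 2L)
  l <- as.numeric(label)
  if (any(abs(l) > 1)) {
    warning("label components outside [-1, 1] clamped before angle conversion")
    l <- pmin(1, pmax(-1, l))
  }
  c(angle_x = rad2deg(asin(l[1])), angle_y = rad2deg(asin(l[2])))
}

#' Combined alignment error between two axes
#'
#' The angle between the camera optical axis and the placental z-axis, both
#' in world coordinates: `acos(z_c . z_p)` in degrees. Symmetric in its
#' arguments; zero iff the axes coincide.
#'
#' @param z_c,z_p unit 3-vectors (world frame).
#' @return Angle in degrees, in [0, 180].
#' @export
combined_error <- function(z_c, z_p) {
  z_c <- assert_unit(z_c, "z_c")
  z_p <- assert_unit(z_p, "z_p")
  rad2deg(acos(pmin(1, pmax(-1, sum(z_c * z_p)))))
}

#' Both-angles accuracy rule
#'
#' A prediction is deemed accurate when both per-axis inclination angles are
#' within `tol` degrees of the ground truth (boundary inclusive).
#'
#' @param pred,truth numeric length-2 labels.
#' @param tol acceptance half-width in degrees (default 5).
#' @return Logical.
#' @export
is_accurate <- function(pred, truth, tol = 5) {
  d <- abs(components_to_angles(pred) - components_to_angles(truth))
  all(d <= tol)
}

#' Embed a label as a unit vector
#'
#' Lifts a 2-component label back to the full placenta z-axis direction in
#' camera coordinates, `c(x, y, sqrt(1 - x^2 - y^2))`.
#'
#' @param label numeric length-2 label with `x^2 + y^2 <= 1`.
#' @return Unit 3-vector.
#' @export
label_to_axis <- function(label) {
  r2 <- sum(as.numeric(label)^2)
  if (r2 > 1 + 1e-12) stop("label lies outside the unit disc")
  c(label[[1]], label[[2]], sqrt(max(0, 1 - r2)))
}

#' Clamp a label to the closed unit disc
#'
#' @param label numeric length-2 label.
#' @return Label scaled radially onto the disc if its norm exceeds 1.
#' @export
clamp_label <- function(label) {
  r <- sqrt(sum(as.numeric(label)^2))
  if (r > 1) label <- label / r
  c(x = label[[1]], y = label[[2]])
}

# Rotation taking unit vector a onto unit vector b (Rodrigues). Used to
# construct camera orientations with a prescribed label.
rotation_between <- function(a, b) {
  a <- normalize_vec(a); b <- normalize_vec(b)
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {  # antipodal: rotate 180 deg about any orthogonal axis
    ax <- normalize_vec(if (abs(a[1]) < 0.9) c(1, 0, 0) - a[1] * a else c(0, 1, 0) - a[2] * a)
    K <- skew(ax)
    return(diag(3) + 2 * K %*% K)
  }
  K <- skew(v)
  diag(3) + K + K %*% K / (1 + cth)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Construct a camera pose with a prescribed label
#'
#' Places the camera so that its optical axis hits `target` on the surface at
#' distance `distance_mm`, oriented so that `label_from_scene()` returns
#' exactly `label`, with an additional roll about the optical axis.
#'
#' @param label desired inclination label (inside the open unit disc).
#' @param distance_mm camera-to-target distance along the optical axis.
#' @param normal_into_cavity surface normal pointing into the cavity (world).
#' @param target point on the surface the optical axis passes through (world
#'   mm, default origin).
#' @param roll_deg roll about the optical axis, degrees.
#' @return 4x4 pose `^W T_C`.
#' @export
camera_pose_for_label <- function(label, distance_mm,
                                  normal_into_cavity = c(0, 0, 1),
                                  target = c(0, 0, 0), roll_deg = 0) {
  n <- normalize_vec(normal_into_cavity)
  # roll is applied by post-multiplying Rz(roll); that maps a camera-frame
  # label l to Rz(-roll) l, so pre-compensate.
  l0 <- rotate_label(label, roll_deg)
  v <- label_to_axis(l0)            # desired ^C Z_P before roll
  p_z <- -n
  R <- rotation_between(v, p_z) %*% rot_z(roll_deg)
  z_c <- R[, 3]
  pos <- target - distance_mm * z_c
  rigid_transform(R, pos)
}
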