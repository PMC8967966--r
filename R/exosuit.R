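# Gravity-compensation assist law, cable geometry/tension mapping, and strap
# interaction forces.
#
# Frames: elbow at the origin, x anterior, y vertical up.  The upper arm is
# locked vertical; the forearm axis unit vector is d(theta) = (sin t, -cos t)
# and its perpendicular n(theta) = (cos t, sin t) (anterior side).  One anchor
# pair serves both cables: the flexor cable routes on the anterior side, the
# extensor cable mirrors it on the posterior side.

forearm_axis <- function(theta) c(sin(theta), -cos(theta))
forearm_perp <- function(theta) c(cos(theta), sin(theta))

cross2 <- function(p, v) p[1] * v[2] - p[2] * v[1]

#' Gravity-compensation assist moment
#'
#' The controller output \eqn{\tau_a = (m g l_c + M g l_l)\sin\theta}: the
#' flexion moment gravity demands at the measured elbow angle.  Uses only the
#' angle (no velocity or acceleration terms).
#'
#' @param model an [arm_model()].
#' @param theta measured elbow angle (rad).
#' @param enabled actuator ON/OFF; OFF returns 0.
#' @return assist moment (N m).
#' @export
gc_assist_moment <- function(model, theta, enabled = TRUE) {
  if (!enabled) return(0)
  gravity_moment(model, theta)
}

#' Cable geometry at a joint angle
#'
#' Each cable is the straight segment from its upper-arm anchor (fixed in the
#' vertical upper-arm frame) to its forearm anchor (rotating with the
#' forearm).  Moment arm = perpendicular distance from the elbow origin to the
#' cable line; unit vectors point from the forearm anchor toward the arm
#' anchor (the direction tension pulls the forearm).
#'
#' When the straight segment would pass within `wrap_radius` of the elbow
#' (as the posterior extensor routing does at flexed angles), the cable is
#' taken to wrap a cylinder of that radius around the joint: it leaves the
#' forearm anchor tangent to the cylinder, so its moment arm equals the wrap
#' radius and its pull direction is the tangent direction.
#'
#' @param geom exosuit anchor list (`arm_anchor`, `forearm_anchor`), each
#'   (offset, along-axis) in m, optionally `wrap_radius` (m, default 0.025).
#' @param theta elbow angle (rad).
#' @return list with flexor/extensor moment arms `r1`, `r2` (m, positive),
#'   unit vectors `u1`, `u2`, and forearm-anchor world positions `p1`, `p2`.
#' @export
cable_geometry <- function(geom, theta) {
  a <- geom$arm_anchor       # (anterior offset, height above elbow)
  f <- geom$forearm_anchor   # (perpendicular offset, distance along forearm)
  rw <- geom$wrap_radius %||% 0.025
  d <- forearm_axis(theta)
  n <- forearm_perp(theta)
  arm1 <- c(a[1], a[2])          # flexor routing, anterior
  arm2 <- c(-a[1], a[2])         # extensor routing, posterior
  p1 <- f[2] * d + f[1] * n
  p2 <- f[2] * d - f[1] * n
  v1 <- arm1 - p1
  v2 <- arm2 - p2
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  if (l1 < 1e-9 || l2 < 1e-9)
    stop("degenerate cable geometry: zero-length cable segment", call. = FALSE)
  u1 <- v1 / l1; u2 <- v2 / l2
  r1 <- cross2(p1, u1)
  r2 <- -cross2(p2, u2)
  if (r1 < rw) {
    u1 <- wrap_tangent(p1, rw, side = +1)
    r1 <- rw
  }
  if (r2 < rw) {
    u2 <- wrap_tangent(p2, rw, side = -1)
    r2 <- rw
  }
  list(r1 = r1, r2 = r2, u1 = u1, u2 = u2, p1 = p1, p2 = p2)
}

# Unit vector from anchor p tangent to the wrap cylinder (radius rw around the
# elbow origin); side +1 yields moment +rw (flexion), -1 yields -rw.
wrap_tangent <- function(p, rw, side) {
  rho <- sqrt(sum(p^2))
  if (rho <= rw)
    stop("degenerate cable geometry: anchor inside the wrap cylinder",
         call. = FALSE)
  alpha <- asin(rw / rho)
  ca <- cos(alpha); sa <- -side * sin(alpha)
  v <- -p / rho
  c(ca * v[1] - sa * v[2], sa * v[1] + ca * v[2])
}

#' Map an assist moment to cable tensions
#'
#' A positive (flexion) moment is carried entirely by the flexor cable,
#' a negative moment by the extensor cable; tensions are nonnegative and at
#' most one is nonzero.
#'
#' @param assist_moment desired actuator moment (N m).
#' @param r1,r2 flexor/extensor cable moment arms (m, must be positive).
#' @return c(T1, T2) tensions (N).
#' @export
cable_tensions <- function(assist_moment, r1, r2) {
  if (r1 <= 0 || r2 <= 0)
    stop("cable moment arms must be positive, got r1 = ", r1, ", r2 = ", r2,
         call. = FALSE)
  if (assist_moment > 0) c(assist_moment / r1, 0)
  else if (assist_moment < 0) c(0, -assist_moment / r2)
  else c(0, 0)
}

#' Strap interaction forces on the forearm
#'
#' Decomposes the total cable force at the forearm anchor into the component
#' along the forearm long axis (shear, which would slide the strap) and
#' perpendicular to it (normal, which presses the strap onto the limb).  Both
#' are reported as magnitudes.
#'
#' @param geom exosuit anchor list.
#' @param theta elbow angle (rad).
#' @param T1,T2 flexor/extensor cable tensions (N, nonnegative).
#' @return list with `normal` (N), `shear` (N), `force` (world-frame vector)
#'   and `at = "forearm_strap"`.
#' @export
interaction_forces <- function(geom, theta, T1, T2) {
  stopifnot(T1 >= 0, T2 >= 0)
  cg <- cable_geometry(geom, theta)
  fvec <- T1 * cg$u1 + T2 * cg$u2
  d <- forearm_axis(theta)
  n <- forearm_perp(theta)
  list(normal = abs(sum(fvec * n)), shear = abs(sum(fvec * d)),
       force = fvec, at = "forearm_strap")
}
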