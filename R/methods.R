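# S3 methods for simulation results.

#' @export
print.exosim_result <- function(x, ...) {
  s <- x$series
  cat(sprintf("<exosim_result> '%s': %.3g s task, load %.3g kg, assist %s\n",
              x$label, x$trajectory$duration, x$model$load$external_mass,
              if (x$assist) "ON" else "OFF"))
  cat(sprintf("  tracking: max |theta - theta_ref| = %.4g rad\n",
              max(abs(s$theta - s$theta_ref))))
  cat(sprintf("  joint moment RMS %.3f N m; metabolic rate RMS %.2f W\n",
              rms(s$tau), rms(s$metabolic_rate)))
  invisible(x)
}

#' @export
summary.exosim_result <- function(object, ...) {
  s <- object$series
  out <- list(
    label = object$label, assist = object$assist,
    duration = object$trajectory$duration,
    load = object$model$load$external_mass,
    tracking_max_error = max(abs(s$theta - s$theta_ref)),
    moment_rms = rms(s$tau),
    reaction_rms = rms(s$reaction),
    metabolic_rms = rms(s$metabolic_rate),
    activation_rms = apply(object$activations, 2, rms),
    peak_strap_normal = max(s$strap_normal),
    peak_strap_shear = max(s$strap_shear),
    diagnostics = object$diagnostics
  )
  class(out) <- "summary.exosim_result"
  out
}

#' @export
print.summary.exosim_result <- function(x, ...) {
  cat(sprintf("Run '%s' (%s, %.3g s, %.3g kg)\n", x$label,
              if (x$assist) "assisted" else "unassisted", x$duration, x$load))
  cat(sprintf("  max tracking error: %.4g rad\n", x$tracking_max_error))
  cat(sprintf("  RMS moment %.3f N m | reaction %.2f N | metabolic %.2f W\n",
              x$moment_rms, x$reaction_rms, x$metabolic_rms))
  cat("  activation RMS:\n")
  print(round(x$activation_rms, 4))
  cat(sprintf("  strap peaks: normal %.1f N, shear %.1f N\n",
              x$peak_strap_normal, x$peak_strap_shear))
  invisible(x)
}

#' Tracking residuals of a simulation
#'
#' @param object an `exosim_result`.
#' @param ... unused.
#' @return numeric vector `theta - theta_ref` on the sampling grid.
#' @export
residuals.exosim_result <- function(object, ...) {
  object$series$theta - object$series$theta_ref
}

#' Plot a simulation result
#'
#' Four panels: tracking, joint and assist moments, muscle activations, and
#' the metabolic rate.
#'
#' @param x an `exosim_result`.
#' @param ... passed to the first panel's plot call.
#' @export
plot.exosim_result <- function(x, ...) {
  s <- x$series
  oldpar <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  graphics::plot(s$time, s$theta_ref, type = "l", lty = 2, xlab = "time (s)",
                 ylab = "elbow angle (rad)", main = x$label, ...)
  graphics::lines(s$time, s$theta, col = 2)
  graphics::legend("bottomright", c("reference", "output"), lty = c(2, 1),
                   col = c(1, 2), bty = "n")
  graphics::plot(s$time, s$tau, type = "l", xlab = "time (s)",
                 ylab = "moment (N m)")
  graphics::lines(s$time, s$assist_moment, col = 4)
  graphics::legend("topright", c("muscle", "assist"), lty = 1, col = c(1, 4),
                   bty = "n")
  graphics::matplot(s$time, x$activations, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "activation")
  graphics::plot(s$time, s$metabolic_rate, type = "l", xlab = "time (s)",
                 ylab = "metabolic rate (W)")
  invisible(x)
}

#' Write the full time-series record to CSV
#'
#' Column dictionary: the scalar channels of the run (`time`, kinematics,
#' moments, tensions, reaction and strap forces, metabolic rate) followed by
#' per-muscle activation (`act_*`), excitation (`exc_*`) and force (`frc_*`)
#' columns.
#'
#' @param result an `exosim_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(result, path) {
  d <- result$series
  addm <- function(d, m, prefix) {
    colnames(m) <- paste0(prefix, colnames(m))
    cbind(d, m)
  }
  d <- addm(d, result$activations, "act_")
  d <- addm(d, result$excitations, "exc_")
  d <- addm(d, result$muscle_forces, "frc_")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
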