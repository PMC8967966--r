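#' @keywords internal
"_PACKAGE"

# ---- domain constructors & validation ---------------------------------------

MUSCLE_NAMES <- c("biceps_long", "biceps_short", "brachialis",
                  "triceps_long", "triceps_medial", "triceps_lateral")

#' Per-muscle Hill-model parameters
#'
#' Bundles the Hill-type parameters and angle-polynomial geometry of one elbow
#' muscle.  The moment-arm polynomial gives the signed elbow moment arm (m,
#' positive = flexion) as a function of elbow angle; the MTU-length polynomial
#' must be its exact negative antiderivative so that
#' \eqn{dL_{mtu}/d\theta = -\mathrm{sign}\,|d(\theta)|}.
#'
#' @param name one of the six model muscle names.
#' @param sign +1 for a flexor, -1 for an extensor.
#' @param max_isometric_force maximum isometric fiber force (N).
#' @param optimal_fiber_length optimal fiber length (m).
#' @param tendon_slack_length tendon slack length (m), rigid tendon.
#' @param max_contraction_velocity maximum shortening velocity (optimal fiber
#'   lengths per second).
#' @param pennation_at_optimal pennation angle at optimal fiber length (rad).
#' @param act_time_constant,deact_time_constant activation dynamics time
#'   constants (s); activation must be faster than deactivation.
#' @param moment_arm_coeffs,mtu_length_coeffs polynomial coefficients in the
#'   elbow angle, ascending powers (m).
#' @param origin_xy effective origin in the upper-arm frame (m), used only to
#'   orient muscle force vectors for the joint-reaction balance.
#' @param insertion_s,insertion_offset effective insertion along / perpendicular
#'   to the forearm axis (m).
#' @param fast_twitch_fraction fast-twitch fiber fraction, feeds the muscle
#'   energetics model.
#' @return an object of class `muscle_params`.
#' @export
muscle_params <- function(name, sign, max_isometric_force, optimal_fiber_length,
                          tendon_slack_length, max_contraction_velocity = 10,
                          pennation_at_optimal = 0,
                          act_time_constant = 0.010, deact_time_constant = 0.040,
                          moment_arm_coeffs, mtu_length_coeffs,
                          origin_xy = c(0, 0.2), insertion_s = 0.03,
                          insertion_offset = 0.01, fast_twitch_fraction = 0.5) {
  m <- structure(list(
    name = name, sign = sign,
    max_isometric_force = max_isometric_force,
    optimal_fiber_length = optimal_fiber_length,
    tendon_slack_length = tendon_slack_length,
    max_contraction_velocity = max_contraction_velocity,
    pennation_at_optimal = pennation_at_optimal,
    act_time_constant = act_time_constant,
    deact_time_constant = deact_time_constant,
    moment_arm_coeffs = as.numeric(moment_arm_coeffs),
    mtu_length_coeffs = as.numeric(mtu_length_coeffs),
    origin_xy = as.numeric(origin_xy),
    insertion_s = insertion_s, insertion_offset = insertion_offset,
    fast_twitch_fraction = fast_twitch_fraction
  ), class = "muscle_params")
  validate_muscle_params(m)
  m
}

validate_muscle_params <- function(m) {
  if (!m$name %in% MUSCLE_NAMES)
    stop("unknown muscle name '", m$name, "'", call. = FALSE)
  if (!m$sign %in% c(-1, 1))
    stop("muscle '", m$name, "': sign must be +1 or -1, got ", m$sign,
         call. = FALSE)
  for (f in c("max_isometric_force", "optimal_fiber_length",
              "tendon_slack_length", "max_contraction_velocity",
              "act_time_constant", "deact_time_constant")) {
    if (!is.finite(m[[f]]) || m[[f]] <= 0)
      stop("muscle '", m$name, "': ", f, " must be > 0, got ", m[[f]],
           call. = FALSE)
  }
  if (m$act_time_constant >= m$deact_time_constant)
    stop("muscle '", m$name, "': activation time constant (",
         m$act_time_constant, ") must be smaller than deactivation constant (",
         m$deact_time_constant, ")", call. = FALSE)
  if (m$pennation_at_optimal < 0 || m$pennation_at_optimal >= pi / 2)
    stop("muscle '", m$name, "': pennation must lie in [0, pi/2)", call. = FALSE)
  # moment arm keeps the sign declared by `sign` over the task range
  th <- seq(0, pi / 2, length.out = 50)
  d <- polyval(m$moment_arm_coeffs, th)
  if (any(sign(d) != m$sign))
    stop("muscle '", m$name, "': moment arm changes sign on [0, pi/2]",
         call. = FALSE)
  invisible(m)
}

#' Simulation settings
#'
#' @param sample_rate control-loop sampling rate (Hz).  The grid is inclusive
#'   of both endpoints: 121 samples for a 1 s task at 121 Hz.
#' @param integrator_max_step,integrator_min_step adaptive integrator step
#'   bounds (s); the defaults honor the robust range 0.004-0.02 s.
#' @param optimizer_tolerance moment-equality tolerance of the static
#'   optimization (N m).
#' @param rtol,atol integrator relative/absolute tolerances.
#' @param rng_seed reserved; the pipeline is deterministic and does not draw
#'   random numbers.
#' @return an object of class `sim_settings`.
#' @export
sim_settings <- function(sample_rate = 121, integrator_max_step = 0.02,
                         integrator_min_step = 0, optimizer_tolerance = 1e-6,
                         rtol = 1e-6, atol = 1e-8, rng_seed = NULL) {
  stopifnot(sample_rate > 0, integrator_max_step > 0,
            integrator_max_step <= 0.02 + 1e-12)
  structure(list(sample_rate = sample_rate,
                 integrator_max_step = integrator_max_step,
                 integrator_min_step = integrator_min_step,
                 optimizer_tolerance = optimizer_tolerance,
                 rtol = rtol, atol = atol, rng_seed = rng_seed),
            class = "sim_settings")
}

#' PD feedback gains of the acceleration command
#'
#' @param kp position-error gain (1/s^2), default 900.
#' @param kv velocity-error gain (1/s), default 60.
#' @return an object of class `pd_gains`.
#' @export
pd_gains <- function(kp = 900, kv = 60) {
  if (!is.finite(kp) || kp <= 0) stop("kp must be > 0, got ", kp, call. = FALSE)
  if (!is.finite(kv) || kv <= 0) stop("kv must be > 0, got ", kv, call. = FALSE)
  structure(list(kp = kp, kv = kv), class = "pd_gains")
}

#' Assemble a planar elbow + exosuit model
#'
#' The model world: elbow at the origin, upper arm locked vertical, the elbow
#' flexion angle theta measured from the downward vertical (theta = 0 arm
#' hanging, increasing toward flexion).
#'
#' @param segment list with `forearm_mass` (kg), `com_distance` (m),
#'   `inertia_about_elbow` (kg m^2) and `upper_arm_orientation` (rad).
#' @param load list with `external_mass` (kg) and `load_distance` (m).
#' @param muscles list of exactly six [muscle_params()] (three flexors, three
#'   extensors).
#' @param exosuit list with `arm_anchor` and `forearm_anchor`, each (offset,
#'   along-axis) coordinates in m w.r.t. the elbow.
#' @param gravity gravitational acceleration (m/s^2, downward).
#' @param inertia_frame `"elbow"` to use the tabulated forearm inertia as given
#'   (about the elbow), `"com"` to treat it as a COM value and add
#'   `m * lc^2`.
#' @return an object of class `arm_model`.
#' @export
arm_model <- function(segment, load, muscles = default_muscle_fixture(),
                      exosuit = list(arm_anchor = c(0.04, 0.14),
                                     forearm_anchor = c(0.02, 0.15)),
                      gravity = 9.81, inertia_frame = c("elbow", "com")) {
  inertia_frame <- match.arg(inertia_frame)
  model <- structure(list(segment = segment, load = load, muscles = muscles,
                          exosuit = exosuit, gravity = gravity,
                          inertia_frame = inertia_frame),
                     class = "arm_model")
  validate_arm_model(model)
  model
}

validate_arm_model <- function(model) {
  seg <- model$segment
  need <- c("forearm_mass", "com_distance", "inertia_about_elbow",
            "upper_arm_orientation")
  miss <- setdiff(need, names(seg))
  if (length(miss))
    stop("segment: missing field(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in c("forearm_mass", "com_distance", "inertia_about_elbow"))
    if (!is.finite(seg[[f]]) || seg[[f]] <= 0)
      stop("segment: ", f, " must be > 0, got ", seg[[f]], call. = FALSE)
  ld <- model$load
  miss <- setdiff(c("external_mass", "load_distance"), names(ld))
  if (length(miss))
    stop("load: missing field(s) ", paste(miss, collapse = ", "), call. = FALSE)
  if (!is.finite(ld$external_mass) || ld$external_mass < 0)
    stop("load: external_mass must be >= 0, got ", ld$external_mass,
         call. = FALSE)
  if (!is.finite(ld$load_distance) || ld$load_distance <= 0)
    stop("load: load_distance must be > 0, got ", ld$load_distance,
         call. = FALSE)
  if (length(model$muscles) != 6L)
    stop("expected 6 muscles, got ", length(model$muscles), call. = FALSE)
  for (m in model$muscles) validate_muscle_params(m)
  signs <- vapply(model$muscles, `[[`, numeric(1), "sign")
  if (sum(signs == 1) != 3L || sum(signs == -1) != 3L)
    stop("expected 3 flexors and 3 extensors, got ", sum(signs == 1),
         " flexors", call. = FALSE)
  nm <- vapply(model$muscles, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate muscle names in model", call. = FALSE)
  for (a in c("arm_anchor", "forearm_anchor")) {
    p <- model$exosuit[[a]]
    if (is.null(p) || length(p) != 2L || !all(is.finite(p)))
      stop("exosuit: ", a, " must be two finite coordinates", call. = FALSE)
    if (sqrt(sum(p^2)) < 1e-6)
      stop("exosuit: ", a, " coincides with the elbow origin", call. = FALSE)
  }
  # both routing sides must keep a positive moment arm over the task range
  th <- seq(0, pi / 2, length.out = 40)
  for (t in th) {
    cg <- cable_geometry(model$exosuit, t)
    if (cg$r1 <= 0 || cg$r2 <= 0)
      stop("exosuit: nonpositive cable moment arm at theta = ",
           signif(t, 3), call. = FALSE)
  }
  invisible(model)
}

# ---- fixture & config I/O ---------------------------------------------------

#' The packaged six-muscle elbow fixture
#'
#' Loads the parameter set shipped with the package: the three elbow flexors
#' (biceps long and short heads, brachialis) and three extensors (triceps long,
#' medial, lateral heads).  Architectural parameters follow the publicly
#' documented arm26 model; the angle-polynomial geometry is a reconstruction
#' documented in the fixture file itself.
#'
#' @return list of six [muscle_params()].
#' @export
default_muscle_fixture <- function() {
  path <- system.file("extdata", "arm26_muscles.yaml", package = "exoflex")
  raw <- yaml::read_yaml(path)
  lapply(raw$muscles, function(x) do.call(muscle_params, x))
}

MODEL_TOP_KEYS <- c("segment", "load", "exosuit", "gravity", "inertia_frame",
                    "muscles")

#' Read and validate a model configuration file
#'
#' @param config_path path to a YAML model configuration (see the packaged
#'   `default_model.yaml` for the schema).  Unknown keys are rejected.
#' @return a validated [arm_model()].
#' @export
load_model <- function(config_path) {
  if (!file.exists(config_path))
    stop("config file not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  unknown <- setdiff(names(cfg), MODEL_TOP_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(c("segment", "load"), names(cfg))
  if (length(miss))
    stop("configuration missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  muscles <- cfg$muscles
  if (is.null(muscles) || identical(muscles, "arm26")) {
    muscles <- default_muscle_fixture()
  } else {
    muscles <- lapply(muscles, function(x) do.call(muscle_params, x))
  }
  arm_model(
    segment = cfg$segment, load = cfg$load, muscles = muscles,
    exosuit = if (is.null(cfg$exosuit))
      list(arm_anchor = c(0.04, 0.14), forearm_anchor = c(0.02, 0.15))
    else lapply(cfg$exosuit, as.numeric),
    gravity = if (is.null(cfg$gravity)) 9.81 else cfg$gravity,
    inertia_frame = if (is.null(cfg$inertia_frame)) "elbow" else cfg$inertia_frame
  )
}

#' Write a model configuration file
#'
#' Serializes an [arm_model()] (including its full muscle list) so that
#' [load_model()] reproduces an equal model.
#'
#' @param model an [arm_model()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(model, path) {
  cfg <- list(
    segment = model$segment,
    load = model$load,
    exosuit = lapply(model$exosuit, as.numeric),
    gravity = model$gravity,
    inertia_frame = model$inertia_frame,
    muscles = lapply(model$muscles, function(m) unclass(m))
  )
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' Default model with a given hand load
#'
#' Convenience wrapper around the packaged configuration.
#'
#' @param external_mass hand-held mass (kg); the study sweep uses 0, 2, 5.
#' @param load_distance elbow-to-load distance (m).
#' @return an [arm_model()].
#' @export
default_model <- function(external_mass = 0, load_distance = 0.35) {
  model <- load_model(system.file("extdata", "default_model.yaml",
                                  package = "exoflex"))
  model$load$external_mass <- external_mass
  model$load$load_distance <- load_distance
  validate_arm_model(model)
  model
}

#' @export
print.arm_model <- function(x, ...) {
  cat("<arm_model> planar elbow, 6 muscles\n")
  cat(sprintf("  forearm: m = %.3g kg, lc = %.3g m, I = %.3g kg m^2 (%s frame)\n",
              x$segment$forearm_mass, x$segment$com_distance,
              x$segment$inertia_about_elbow, x$inertia_frame))
  cat(sprintf("  load:    M = %.3g kg at ll = %.3g m\n",
              x$load$external_mass, x$load$load_distance))
  cat(sprintf("  exosuit: arm anchor (%.3g, %.3g) m, forearm anchor (%.3g, %.3g) m\n",
              x$exosuit$arm_anchor[1], x$exosuit$arm_anchor[2],
              x$exosuit$forearm_anchor[1], x$exosuit$forearm_anchor[2]))
  invisible(x)
}

# ---- small shared numerics --------------------------------------------------

# Evaluate a polynomial with ascending coefficients at x (vectorized in x).
polyval <- function(coeffs, x) {
  y <- numeric(length(x)) + coeffs[length(coeffs)]
  if (length(coeffs) > 1)
    for (k in seq(length(coeffs) - 1, 1)) y <- y * x + coeffs[k]
  y
}

# Derivative coefficients of an ascending-coefficient polynomial.
polyder <- function(coeffs) {
  n <- length(coeffs)
  if (n == 1) return(0)
  coeffs[-1] * seq_len(n - 1)
}

rms <- function(x) sqrt(mean(x^2))
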