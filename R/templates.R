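# Analytic human-motion templates. Each activity is modeled as a handful of
# point scatterers (torso, head, limbs) with smooth analytic range
# trajectories; the template returns the scatterer list for one recording
# given per-subject kinematic parameters and a per-repetition RNG for small
# jitters. The trajectory building blocks keep closed-form radial
# velocities so the Doppler term never relies on finite differences.

# smooth ramp: 0 before t0, 1 after t0 + dur, cubic smoothstep in between
smoothstep <- function(t, t0, dur) {
  u <- pmin(pmax((t - t0) / dur, 0), 1)
  u * u * (3 - 2 * u)
}
smoothstep_deriv <- function(t, t0, dur) {
  u <- pmin(pmax((t - t0) / dur, 0), 1)
  6 * u * (1 - u) / dur
}

# scatterer moving r0 -> r0 + amp along a smoothstep, optional extra terms
ramp_scatterer <- function(r0, amp, t0, dur, amplitude = 1) {
  scatterer(
    range_fn = function(t) r0 + amp * smoothstep(t, t0, dur),
    velocity_fn = function(t) amp * smoothstep_deriv(t, t0, dur),
    amplitude = amplitude
  )
}

# translating scatterer with sinusoidal micro-motion (limb swing)
swing_scatterer <- function(r0, v, a, f, phi, amplitude = 1) {
  scatterer(
    range_fn = function(t) r0 - v * t + a * sin(2 * pi * f * t + phi),
    velocity_fn = function(t) -v + a * 2 * pi * f * cos(2 * pi * f * t + phi),
    amplitude = amplitude
  )
}

static_scatterer <- function(r0, amplitude = 1) {
  scatterer(range_fn = function(t) rep_len(r0, length(t)),
            velocity_fn = function(t) rep_len(0, length(t)),
            amplitude = amplitude)
}

#' The six activity classes
#'
#' @return character vector of the class labels, in canonical order.
#' @export
activity_classes <- function() {
  c("walking", "sitting_down", "standing_up", "bending", "drinking", "falling")
}

#' Analytic motion templates for the six activities
#'
#' Each template is a function `(subj, rng)` returning a list of
#' [scatterer()]s for one recording: `subj` carries per-subject kinematic
#' parameters (`speed`, `amp`, `r0` in meters, `t0` onset in seconds) and
#' `rng` is a function `(lo, hi)` drawing per-repetition jitters.
#'
#' Morphologies: walking is a continuous translation with sinusoidal limb
#' oscillations (periodic micro-Doppler straddling the torso line);
#' sitting/standing/bending/drinking are short transient ramps differing in
#' sign, duration and bandwidth; falling is a rapid large monotone range
#' change with staggered body parts, producing a broadband short-duration
#' "waterfall". A weak static reflector adds the zero-Doppler clutter line
#' seen in measured signatures.
#'
#' @param duration recording length in seconds (templates are parameterized
#'   for the default 2 s dwell).
#' @return named list of template functions, one per class in
#'   [activity_classes()] order.
#' @export
activity_templates <- function(duration = 2) {
  walking <- function(subj, rng) {
    v <- 1.1 * subj$speed
    f <- 1.7 * subj$speed + rng(-0.05, 0.05)
    r0 <- subj$r0 + 0.9            # start farther, walk toward the radar
    list(
      swing_scatterer(r0, v, 0.012 * subj$amp, f, rng(0, 2 * pi), 1.0),  # torso
      swing_scatterer(r0 + 0.05, v, 0.008 * subj$amp, f, rng(0, 2 * pi), 0.55), # head
      swing_scatterer(r0, v, 0.30 * subj$amp, f / 2, 0 + rng(-0.2, 0.2), 0.42),  # leg
      swing_scatterer(r0, v, 0.30 * subj$amp, f / 2, pi + rng(-0.2, 0.2), 0.42), # leg
      swing_scatterer(r0, v, 0.15 * subj$amp, f / 2, pi / 2 + rng(-0.3, 0.3), 0.3), # arm
      swing_scatterer(r0, v, 0.15 * subj$amp, f / 2, 3 * pi / 2 + rng(-0.3, 0.3), 0.3),
      static_scatterer(subj$r0 + 1.6, 0.25)
    )
  }
  transient <- function(sign, span, dur_s, arm_span, arm_dur) {
    function(subj, rng) {
      t0 <- subj$t0 + rng(-0.05, 0.05)
      d <- dur_s / subj$speed
      list(
        ramp_scatterer(subj$r0, sign * span * subj$amp, t0, d, 1.0),      # torso
        ramp_scatterer(subj$r0 - 0.05, sign * span * 1.25 * subj$amp,
                       t0 + 0.05, d * 0.9, 0.5),                          # head
        ramp_scatterer(subj$r0 + 0.02, sign * arm_span * subj$amp,
                       t0 + rng(0, 0.1), arm_dur / subj$speed, 0.4),      # arm
        static_scatterer(subj$r0 + 0.8, 0.25)
      )
    }
  }
  bending <- function(subj, rng) {
    t0 <- subj$t0 + rng(-0.05, 0.05)
    d <- 0.5 / subj$speed
    down_up <- function(r0, span, amp) scatterer(
      range_fn = function(t) r0 + span * (smoothstep(t, t0, d) -
                                            smoothstep(t, t0 + d + 0.25, d)),
      velocity_fn = function(t) span * (smoothstep_deriv(t, t0, d) -
                                          smoothstep_deriv(t, t0 + d + 0.25, d)),
      amplitude = amp
    )
    list(
      down_up(subj$r0, 0.35 * subj$amp, 1.0),          # torso leans in
      down_up(subj$r0 - 0.05, 0.6 * subj$amp, 0.55),   # head travels farther
      down_up(subj$r0 + 0.02, 0.45 * subj$amp, 0.4),   # reaching arm
      static_scatterer(subj$r0 + 0.8, 0.25)
    )
  }
  drinking <- function(subj, rng) {
    t0 <- subj$t0 + rng(-0.05, 0.05)
    d <- 0.35 / subj$speed
    arm <- scatterer(
      range_fn = function(t) subj$r0 - 0.3 * subj$amp *
        (smoothstep(t, t0, d) - smoothstep(t, t0 + d + 0.45, d)),
      velocity_fn = function(t) -0.3 * subj$amp *
        (smoothstep_deriv(t, t0, d) - smoothstep_deriv(t, t0 + d + 0.45, d)),
      amplitude = 0.55
    )
    list(static_scatterer(subj$r0, 1.0), static_scatterer(subj$r0 - 0.05, 0.5),
         arm, static_scatterer(subj$r0 + 0.8, 0.25))
  }
  falling <- function(subj, rng) {
    t0 <- subj$t0 + rng(-0.05, 0.05)
    d <- 0.5 / subj$speed
    list(
      ramp_scatterer(subj$r0, 1.1 * subj$amp, t0, d, 1.0),               # torso
      ramp_scatterer(subj$r0 - 0.05, 1.5 * subj$amp, t0, d * 0.85, 0.55), # head
      ramp_scatterer(subj$r0, 0.9 * subj$amp, t0 + 0.12, d * 1.2, 0.4),  # legs
      ramp_scatterer(subj$r0 + 0.02, 1.25 * subj$amp, t0 + 0.05, d * 0.8, 0.4),
      static_scatterer(subj$r0 + 0.8, 0.25)
    )
  }
  list(
    walking = walking,
    sitting_down = transient(+1, 0.45, 0.6, 0.3, 0.4),
    standing_up = transient(-1, 0.45, 0.65, 0.3, 0.4),
    bending = bending,
    drinking = drinking,
    falling = falling
  )
}
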