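#' Baseline anthropometry of the synthetic humanoid
#'
#' Reference geometry and mass fractions for the nine-body model at a
#' 1.75 m stature: pelvis root, thighs/shanks/feet, a trunk+head branch and
#' a lumped upper-limb branch. The numbers are generator configuration
#' shaped like standard adult anthropometry — inputs to the simulation, not
#' measured values. Lengths scale linearly with stature.
#'
#' @return List with `fractions` (named, sums to 1), `displacement` (named
#'   list, meters at reference stature), `local_com` (named list, meters),
#'   `segment_length` (named, meters), `ref_stature` (m).
#' @export
humanoid_baseline <- function() {
  list(
    fractions = c("1" = 0.142, "2" = 0.100, "3" = 0.0465, "4" = 0.0145,
                  "5" = 0.100, "6" = 0.0465, "7" = 0.0145,
                  "8" = 0.436, "9" = 0.100),
    displacement = list(
      "1" = c(0, 0, 0),
      "2" = c(0, -0.09, 0),     # right hip, ML-
      "3" = c(0, 0, -0.42),     # knee below hip
      "4" = c(0, 0, -0.43),     # ankle below knee
      "5" = c(0, 0.09, 0),      # left hip, ML+
      "6" = c(0, 0, -0.42),
      "7" = c(0, 0, -0.43),
      "8" = c(0, 0, 0.12),      # L5/S1 above pelvis origin
      "9" = c(0, 0, 0.40)),     # shoulder girdle above pelvis origin
    local_com = list(
      "1" = c(0.01, 0, 0.04),   # pelvis
      "2" = c(0, 0, -0.18),     # thigh
      "3" = c(0, 0, -0.19),     # shank
      "4" = c(0.06, 0, -0.03),  # foot, CoM anterior to ankle
      "5" = c(0, 0, -0.18),
      "6" = c(0, 0, -0.19),
      "7" = c(0.06, 0, -0.03),
      "8" = c(0.02, 0, 0.28),   # trunk+head, slightly anterior
      "9" = c(0.01, 0, -0.15)), # arms hang below the shoulder girdle
    segment_length = c("1" = 0.20, "2" = 0.42, "3" = 0.43, "4" = 0.12,
                       "5" = 0.42, "6" = 0.43, "7" = 0.12,
                       "8" = 0.55, "9" = 0.55),
    ref_stature = 1.75)
}

#' Generate a synthetic subject
#'
#' A subject is the default nine-body tree plus ground-truth segment
#' parameters drawn around [humanoid_baseline()]. The `"fit"` preset
#' jitters mass fractions by up to +/-5% (renormalized) and scales all
#' lengths by a random stature; the `"obese"` preset additionally
#' multiplies the mass fractions of the trunk branch (pelvis, trunk+head,
#' upper limbs) by `obese_factor` before renormalizing, emulating
#' trunk-dominant mass redistribution at unchanged geometry.
#'
#' @param preset `"fit"` or `"obese"`.
#' @param seed Integer seed; the same seed reproduces the same subject.
#' @param obese_factor Trunk-branch mass multiplier for the obese preset.
#' @param fraction_jitter Half-width of the uniform relative jitter applied
#'   to every mass fraction.
#' @return Object of class `synthetic_subject`: `tree`, `params`
#'   ([segment_parameters()]), `preset`, `stature` (m), `total_mass` (kg),
#'   `measurements` ([subject_measurements()]), `seed`.
#' @export
make_subject <- function(preset = c("fit", "obese"), seed = 1L,
                         obese_factor = 1.4, fraction_jitter = 0.05) {
  preset <- match.arg(preset)
  base <- humanoid_baseline()
  tree <- default_tree()
  with_seed(seed, {
    stature <- stats::runif(1, 1.60, 1.90)
    total_mass <- if (preset == "fit") stats::runif(1, 55, 85) else
      stats::runif(1, 90, 130)
    frac <- base$fractions *
      (1 + stats::runif(length(base$fractions), -fraction_jitter,
                        fraction_jitter))
    if (preset == "obese") {
      trunk <- c("1", "8", "9")
      frac[trunk] <- frac[trunk] * obese_factor
    }
    frac <- frac / sum(frac)
    scale <- stature / base$ref_stature
    params <- segment_parameters(
      mass = frac * total_mass,
      local_com = lapply(base$local_com, function(v) v * scale),
      displacement = lapply(base$displacement, function(v) v * scale))
    meas <- subject_measurements(total_mass, base$segment_length * scale)
    structure(list(tree = tree, params = params, preset = preset,
                   stature = stature, total_mass = total_mass,
                   measurements = meas, seed = seed),
              class = "synthetic_subject")
  })
}

#' The fit-calibrated anthropometric comparator table
#'
#' The table a practitioner would apply to any subject: baseline mass
#' fractions and geometry (no subject jitter, no trunk redistribution)
#' encoded exactly via [table_from_parameters()]. Applied to a fit subject
#' it is nearly correct; applied to an obese subject it mis-assigns the
#' trunk mass and biases the segmental estimate.
#'
#' @return An [anthropometric_table()].
#' @export
fit_reference_table <- function() {
  base <- humanoid_baseline()
  tree <- default_tree()
  params <- segment_parameters(mass = base$fractions * 70,
                               local_com = base$local_com,
                               displacement = base$displacement)
  meas <- subject_measurements(70, base$segment_length)
  table_from_parameters(tree, params, meas,
                        source_label = "synthetic fit baseline")
}

#' Sample random static postures
#'
#' Joint angles are drawn uniformly from physiological ranges (defaults:
#' +/-30 degrees per spherical Euler axis, 0-60 degrees knee flexion,
#' +/-20 degrees ankle) with the root held upright at a fixed position.
#'
#' @param subject A [make_subject()] result.
#' @param m Number of postures.
#' @param seed Integer seed.
#' @param spherical_range_deg Half-width of the spherical-joint Euler range.
#' @param knee_range_deg Length-2 vector, knee hinge range (degrees).
#' @param ankle_range_deg Half-width of the ankle hinge range (degrees).
#' @param root_range_deg Half-width of the root (pelvis) orientation range
#'   per Euler axis: subjects lean and rotate the pelvis while posing, which
#'   is also what makes every link component observable from the horizontal
#'   CoP. Set to 0 for a strictly upright root.
#' @param root_position Root position used for every posture (meters).
#' @return List of `m` [posture_frame()]s.
#' @export
sample_static_postures <- function(subject, m, seed = 1L,
                                   spherical_range_deg = 30,
                                   knee_range_deg = c(0, 60),
                                   ankle_range_deg = 20,
                                   root_range_deg = 15,
                                   root_position = c(0, 0, 0.95)) {
  tree <- subject$tree
  ch <- angle_channels(tree)
  knees <- c("3", "6")
  with_seed(seed, {
    lapply(seq_len(m), function(i) {
      a <- numeric(nrow(ch))
      for (k in seq_len(nrow(ch))) {
        a[k] <- if (ch$axis[k] != "hinge") {
          stats::runif(1, -spherical_range_deg, spherical_range_deg)
        } else if (ch$body[k] %in% knees) {
          stats::runif(1, knee_range_deg[1], knee_range_deg[2])
        } else {
          stats::runif(1, -ankle_range_deg, ankle_range_deg)
        }
      }
      re <- stats::runif(3, -root_range_deg, root_range_deg) * pi / 180
      posture_from_angles(tree, a,
                          root_rotation = rot_from_euler_zxy(re[1], re[2],
                                                             re[3]),
                          root_position = root_position)
    })
  })
}

#' Sensor noise model
#'
#' @param cop_sd_mm CoP additive Gaussian noise SD, millimeters.
#' @param angle_sd_deg Per-joint orientation noise SD, degrees (applied as a
#'   small random rotation composed with the true joint rotation; hinge
#'   joints are perturbed within their axis).
#' @param seed Integer seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(cop_sd_mm = 2.0, angle_sd_deg = 0.5, seed = 1L) {
  if (cop_sd_mm < 0 || angle_sd_deg < 0) stop("noise SDs must be >= 0")
  structure(list(cop_sd_mm = cop_sd_mm, angle_sd_deg = angle_sd_deg,
                 seed = seed),
            class = "noise_model")
}

perturb_posture <- function(tree, posture, angle_sd_rad) {
  if (angle_sd_rad == 0) return(posture)
  jr <- posture$joint_rotation
  for (b in names(jr)) {
    if (tree$joint[[b]] == "hinge") {
      ax <- tree$hinge_axis[[b]]
      ang <- hinge_angle(jr[[b]], ax) + stats::rnorm(1, 0, angle_sd_rad)
      jr[[b]] <- hinge_rotation(ax, ang)
    } else {
      w <- stats::rnorm(3, 0, angle_sd_rad)
      th <- vnorm(w)
      if (th > 0) jr[[b]] <- jr[[b]] %*% hinge_rotation(w / th, th)
    }
  }
  posture_frame(tree, posture$root_rotation, posture$root_position, jr)
}

#' Simulate a static-posture trial
#'
#' For each posture the true CoM is computed from the ground-truth
#' parameters; the CoP observation is its horizontal projection plus
#' Gaussian sensor noise, and the observed posture is the true posture with
#' small random joint-orientation perturbations. The truth is retained
#' separately for recovery tests.
#'
#' @param subject A [make_subject()] result.
#' @param postures List of true [posture_frame()]s.
#' @param noise A [noise_model()].
#' @return List with `observations` (list of [static_observation()]s using
#'   the observed postures), `true_com` (m x 3 matrix, meters),
#'   `true_postures`, `noise`.
#' @export
simulate_trial <- function(subject, postures, noise = noise_model()) {
  tree <- subject$tree
  with_seed(noise$seed, {
    true_com <- t(vapply(postures, function(p)
      brute_force_com(tree, subject$params, p), numeric(3)))
    colnames(true_com) <- c("ap", "ml", "vert")
    observations <- lapply(seq_along(postures), function(i) {
      obs_posture <- perturb_posture(tree, postures[[i]],
                                     noise$angle_sd_deg * pi / 180)
      cop <- true_com[i, 1:2] + stats::rnorm(2, 0, noise$cop_sd_mm / 1000)
      static_observation(obs_posture, cop)
    })
    list(observations = observations, true_com = true_com,
         true_postures = postures, noise = noise)
  })
}

#' Expand static observations into raw 60 Hz streams
#'
#' Each observation becomes a plateau of `hold_s` seconds with sub-threshold
#' jitter; consecutive plateaus are joined by `transition_s`-second
#' transitions carrying a large half-sine excursion on every angle channel
#' and on the CoP, so any window overlapping a transition violates the
#' stillness criteria. With the default 2 s hold and 1 s transition the
#' plateau/transition boundaries align with the non-overlapping 1 s window
#' grid, and the detector recovers exactly one static region per input
#' observation.
#'
#' @param tree A [kinematic_tree()].
#' @param observations List of [static_observation()]s.
#' @param criteria A [static_posture_criteria()].
#' @param hold_s Plateau duration (must be `>= criteria$window_s`).
#' @param transition_s Transition duration between consecutive plateaus.
#' @param seed Integer seed for the jitter.
#' @param angle_jitter_deg Plateau angle jitter SD (set 0 for noiseless
#'   round trips).
#' @param cop_jitter_mm Plateau CoP jitter SD.
#' @param transition_angle_deg Amplitude of the transition angle excursion.
#' @param transition_cop_mm Amplitude of the transition CoP excursion.
#' @return List with `angles` (frames x channels matrix, degrees), `cop`
#'   (frames x 2, mm), `time_s`, `criteria`.
#' @export
expand_to_time_series <- function(tree, observations,
                                  criteria = static_posture_criteria(),
                                  hold_s = 2.0, transition_s = 1.0,
                                  seed = 1L,
                                  angle_jitter_deg = 0.2,
                                  cop_jitter_mm = 0.5,
                                  transition_angle_deg = 25,
                                  transition_cop_mm = 50) {
  if (hold_s < criteria$window_s) {
    stop("hold_s must be at least one detection window")
  }
  rate <- criteria$sample_rate_hz
  nh <- as.integer(round(hold_s * rate))
  nt <- as.integer(round(transition_s * rate))
  # root orientation is tracked like any joint: three leading Euler channels
  ang <- t(vapply(observations, function(o)
    c(euler_zxy(o$posture$root_rotation) * 180 / pi,
      angles_from_posture(tree, o$posture)),
    numeric(3L + nrow(angle_channels(tree)))))
  cop <- t(vapply(observations, function(o) o$cop * 1000, numeric(2)))
  k <- length(observations)
  blocks_a <- list()
  blocks_c <- list()
  with_seed(seed, {
    for (i in seq_len(k)) {
      ja <- matrix(stats::rnorm(nh * ncol(ang), 0, angle_jitter_deg), nh)
      jc <- matrix(stats::rnorm(nh * 2, 0, cop_jitter_mm), nh)
      blocks_a[[length(blocks_a) + 1L]] <-
        matrix(ang[i, ], nh, ncol(ang), byrow = TRUE) + ja
      blocks_c[[length(blocks_c) + 1L]] <-
        matrix(cop[i, ], nh, 2, byrow = TRUE) + jc
      if (i < k) {
        s <- seq_len(nt) / (nt + 1)
        bump <- sin(pi * s)
        ramp_a <- outer(1 - s, ang[i, ]) + outer(s, ang[i + 1L, ]) +
          transition_angle_deg * bump
        ramp_c <- outer(1 - s, cop[i, ]) + outer(s, cop[i + 1L, ]) +
          transition_cop_mm * bump
        blocks_a[[length(blocks_a) + 1L]] <- ramp_a
        blocks_c[[length(blocks_c) + 1L]] <- ramp_c
      }
    }
  })
  angles <- do.call(rbind, blocks_a)
  colnames(angles) <- c("root_euler_z_deg", "root_euler_x_deg",
                        "root_euler_y_deg", angle_channels(tree)$channel)
  copm <- do.call(rbind, blocks_c)
  colnames(copm) <- c("cop_x_mm", "cop_y_mm")
  list(angles = angles, cop = copm,
       time_s = (seq_len(nrow(angles)) - 1) / rate,
       criteria = criteria)
}
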