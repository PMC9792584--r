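#' Stillness criteria for static-posture selection
#'
#' A window of the recording counts as static when, over `window_s` seconds,
#' the standard deviation of every joint-angle channel stays below
#' `angle_sd_max_deg` and the standard deviation of the CoP displacement
#' stays below `cop_sd_max_mm`. Defaults: 1 s window, 1.5 degrees, 6 mm, at
#' a 60 Hz sampling rate.
#'
#' @param window_s Window length, seconds.
#' @param angle_sd_max_deg Per-channel angle SD threshold, degrees.
#' @param cop_sd_max_mm CoP displacement SD threshold, millimeters.
#' @param sample_rate_hz Sampling rate, Hz.
#' @return Object of class `static_posture_criteria`.
#' @export
static_posture_criteria <- function(window_s = 1.0, angle_sd_max_deg = 1.5,
                                    cop_sd_max_mm = 6.0, sample_rate_hz = 60) {
  if (window_s <= 0 || angle_sd_max_deg <= 0 || cop_sd_max_mm <= 0 ||
      sample_rate_hz <= 0) {
    stop("all criteria must be > 0")
  }
  if (window_s * sample_rate_hz < 2) {
    stop("window must span at least 2 samples")
  }
  structure(list(window_s = window_s, angle_sd_max_deg = angle_sd_max_deg,
                 cop_sd_max_mm = cop_sd_max_mm,
                 sample_rate_hz = sample_rate_hz),
            class = "static_posture_criteria")
}

# SD of an angle channel (degrees) on wrapped differences, so a channel
# hovering around +/-180 deg is not flagged as moving.
wrapped_angle_sd <- function(x) {
  dev <- ((x - x[1] + 180) %% 360) - 180
  stats::sd(dev)
}

wrapped_angle_mean <- function(x) {
  dev <- ((x - x[1] + 180) %% 360) - 180
  r <- x[1] + mean(dev)
  ((r + 180) %% 360) - 180
}

#' Detect static postures in joint-angle and CoP streams
#'
#' Scans the synchronized streams in non-overlapping windows (default; a
#' sliding mode with greedy non-overlap resolution is available), marks each
#' window static when every angle channel and the CoP satisfy the
#' [static_posture_criteria()], and groups runs of consecutive static
#' windows into maximal static regions. One representative observation — the
#' per-channel mean — is reported per region.
#'
#' @param angles Numeric matrix (frames x channels), degrees.
#' @param cop Numeric matrix (frames x 2), millimeters, columns (AP, ML).
#' @param criteria A [static_posture_criteria()].
#' @param mode `"nonoverlap"` (default) or `"sliding"` (stride of one
#'   sample, overlapping candidates resolved greedily left to right).
#' @param cop_mode `"per_axis"` (default: both axis SDs must pass) or
#'   `"resultant"` (SD of the distance from the window-mean CoP).
#' @return Object of class `posture_detection`: `windows` (data frame with
#'   `start`, `end`, `static`, `max_angle_sd_deg`, `cop_sd_mm`), `regions`
#'   (data frame with `start`, `end`, `n_windows`), `angles` (region
#'   representatives, one row per region, degrees) and `cop` (region
#'   representatives, mm).
#' @export
detect_static_postures <- function(angles, cop, criteria = static_posture_criteria(),
                                   mode = c("nonoverlap", "sliding"),
                                   cop_mode = c("per_axis", "resultant")) {
  mode <- match.arg(mode)
  cop_mode <- match.arg(cop_mode)
  angles <- as.matrix(angles)
  cop <- as.matrix(cop)
  if (nrow(angles) != nrow(cop)) {
    stop("angle and CoP streams have different lengths (",
         nrow(angles), " vs ", nrow(cop), ")")
  }
  w <- as.integer(round(criteria$window_s * criteria$sample_rate_hz))
  n <- nrow(angles)
  if (n < w) stop("stream shorter than one window")
  starts <- if (mode == "nonoverlap") seq(1L, n - w + 1L, by = w) else
    seq_len(n - w + 1L)

  eval_window <- function(s) {
    idx <- s:(s + w - 1L)
    a_sd <- apply(angles[idx, , drop = FALSE], 2, wrapped_angle_sd)
    c_sd <- if (cop_mode == "per_axis") {
      apply(cop[idx, , drop = FALSE], 2, stats::sd)
    } else {
      mu <- colMeans(cop[idx, , drop = FALSE])
      stats::sd(sqrt((cop[idx, 1] - mu[1])^2 + (cop[idx, 2] - mu[2])^2))
    }
    c(max(a_sd), max(c_sd))
  }
  sds <- t(vapply(starts, eval_window, numeric(2)))
  static <- sds[, 1] < criteria$angle_sd_max_deg &
    sds[, 2] < criteria$cop_sd_max_mm

  if (mode == "sliding") {
    # greedy left-to-right resolution to non-overlapping static windows
    keep <- logical(length(starts))
    last_end <- 0L
    for (i in seq_along(starts)) {
      if (static[i] && starts[i] > last_end) {
        keep[i] <- TRUE
        last_end <- starts[i] + w - 1L
      }
    }
    starts <- starts[keep | !static]  # retain all failures for tallies
    sds <- sds[keep | !static, , drop = FALSE]
    static <- static[keep | !static]
  }

  windows <- data.frame(start = starts, end = starts + w - 1L,
                        static = static,
                        max_angle_sd_deg = sds[, 1], cop_sd_mm = sds[, 2])

  # maximal runs of temporally adjacent static windows
  sw <- windows[windows$static, , drop = FALSE]
  regions <- list()
  reps_a <- list()
  reps_c <- list()
  if (nrow(sw)) {
    run_start <- 1L
    for (i in seq_len(nrow(sw))) {
      last_in_run <- i == nrow(sw) || sw$start[i + 1L] > sw$end[i] + 1L
      if (last_in_run) {
        idx <- sw$start[run_start]:sw$end[i]
        regions[[length(regions) + 1L]] <-
          data.frame(start = sw$start[run_start], end = sw$end[i],
                     n_windows = i - run_start + 1L)
        reps_a[[length(reps_a) + 1L]] <-
          apply(angles[idx, , drop = FALSE], 2, wrapped_angle_mean)
        reps_c[[length(reps_c) + 1L]] <- colMeans(cop[idx, , drop = FALSE])
        run_start <- i + 1L
      }
    }
  }
  structure(list(
    windows = windows,
    regions = if (length(regions)) do.call(rbind, regions) else
      data.frame(start = integer(0), end = integer(0), n_windows = integer(0)),
    angles = if (length(reps_a)) do.call(rbind, reps_a) else
      matrix(numeric(0), 0, ncol(angles)),
    cop = if (length(reps_c)) do.call(rbind, reps_c) else
      matrix(numeric(0), 0, 2),
    criteria = criteria, mode = mode, cop_mode = cop_mode),
    class = "posture_detection")
}

#' Summarize a static-posture selection
#'
#' @param detected A [detect_static_postures()] result.
#' @param requested Number of postures the protocol asked for.
#' @return List with `n_detected` (static regions), `n_requested`,
#'   `yield_pct` and per-criterion window rejection tallies
#'   (`rejected_angle`, `rejected_cop`, `rejected_both`).
#' @export
summarize_selection <- function(detected, requested = NA_integer_) {
  w <- detected$windows
  fail_a <- w$max_angle_sd_deg >= detected$criteria$angle_sd_max_deg
  fail_c <- w$cop_sd_mm >= detected$criteria$cop_sd_max_mm
  n_det <- nrow(detected$regions)
  list(n_detected = n_det,
       n_requested = requested,
       yield_pct = if (is.na(requested) || requested == 0) NA_real_ else
         100 * n_det / requested,
       rejected_angle = sum(fail_a & !fail_c),
       rejected_cop = sum(fail_c & !fail_a),
       rejected_both = sum(fail_a & fail_c))
}

#' Convert detected postures to static observations
#'
#' Turns the per-region representative angle vectors and CoP means of a
#' detection result into [static_observation()]s for identification. The
#' root pose is taken as fixed (the streams carry joint angles only).
#'
#' @param tree A [kinematic_tree()].
#' @param detected A [detect_static_postures()] result whose angle columns
#'   follow the [angle_channels()] layout (degrees), optionally preceded by
#'   the three root channels `root_euler_z/x/y_deg` (as written by
#'   [expand_to_time_series()]).
#' @param root_rotation,root_position Root pose applied to every posture
#'   (`root_rotation` is ignored when the streams carry root channels).
#' @return List of [static_observation()]s (CoP converted from mm to m).
#' @export
observations_from_detection <- function(tree, detected,
                                        root_rotation = diag(3),
                                        root_position = c(0, 0, 0)) {
  a <- detected$angles
  has_root <- !is.null(colnames(a)) && "root_euler_z_deg" %in% colnames(a)
  joint_cols <- if (has_root) setdiff(colnames(a), c("root_euler_z_deg",
                                                     "root_euler_x_deg",
                                                     "root_euler_y_deg"))
    else seq_len(ncol(a))
  lapply(seq_len(nrow(detected$regions)), function(i) {
    rr <- if (has_root) {
      re <- a[i, c("root_euler_z_deg", "root_euler_x_deg",
                   "root_euler_y_deg")] * pi / 180
      rot_from_euler_zxy(re[1], re[2], re[3])
    } else root_rotation
    static_observation(
      posture_from_angles(tree, a[i, joint_cols],
                          root_rotation = rr,
                          root_position = root_position),
      detected$cop[i, ] / 1000)
  })
}
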