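#' Run the full identification/evaluation pipeline on one synthetic subject
#'
#' Samples `m` static postures, simulates noisy observations, splits them
#' 75/25 (by default) into identification and evaluation sets, identifies
#' the subject's serial-chain link vectors from the identification set, and
#' evaluates both the identified model and the table-driven segmental
#' comparator on the held-out set against the CoP readings.
#'
#' @param subject A [make_subject()] result.
#' @param m Number of static postures.
#' @param noise A [noise_model()].
#' @param fraction_identify Identification fraction of the split.
#' @param seed Integer seed (drives posture sampling and the split; the
#'   noise model carries its own seed).
#' @param comparator_table Optional [anthropometric_table()] for the
#'   segmental comparator (default [fit_reference_table()]).
#' @return List with `identification` ([identify_sesc()] result), `sesc`
#'   and `segmental` evaluation blocks (each with `estimates`, `rmse`
#'   ([rmse_per_axis()], mm), `bland_altman` per axis), `references`
#'   (held-out CoP, mm), `split`, `subject`.
#' @export
run_subject_pipeline <- function(subject, m = 100, noise = noise_model(),
                                 fraction_identify = 0.75, seed = 1L,
                                 comparator_table = fit_reference_table()) {
  tree <- subject$tree
  postures <- sample_static_postures(subject, m, seed = seed)
  trial <- simulate_trial(subject, postures, noise)
  split <- split_postures(trial$observations, fraction_identify,
                          seed = seed + 1L,
                          min_identify = minimum_postures(tree$n_bodies))
  # hinge chains make axis-aligned link components jointly observable only,
  # so the design is structurally rank-deficient; the rank is reported in
  # the result rather than warned about here
  ident <- suppressWarnings(identify_sesc(stack_system(tree, split$identify)))

  eval_postures <- lapply(split$evaluate, function(o) o$posture)
  cop_mm <- t(vapply(split$evaluate, function(o) o$cop * 1000, numeric(2)))
  colnames(cop_mm) <- c("ap", "ml")

  sesc_mm <- predict_com(tree, ident$V, eval_postures)[, 1:2] * 1000
  seg_mm <- t(vapply(eval_postures, function(p)
    segmental_com(tree, comparator_table, subject$measurements, p)[1:2],
    numeric(2))) * 1000

  eval_block <- function(est) {
    list(estimates = est,
         rmse = rmse_per_axis(est, cop_mm),
         bland_altman = list(
           ap = bland_altman(est[, 1], cop_mm[, 1]),
           ml = bland_altman(est[, 2], cop_mm[, 2]),
           pooled = bland_altman(c(est[, 1], est[, 2]),
                                 c(cop_mm[, 1], cop_mm[, 2]))))
  }
  list(identification = ident,
       sesc = eval_block(sesc_mm),
       segmental = eval_block(seg_mm),
       references = cop_mm,
       split = split,
       subject = subject)
}

#' End-to-end stream pipeline: simulate, expand, detect, identify, evaluate
#'
#' Exercises every stage on one subject: noisy (or noiseless) observations
#' are expanded into raw 60 Hz angle/CoP streams, the static-posture
#' detector recovers the postures, and the recovered observations feed the
#' identification/evaluation split. Returns held-out horizontal prediction
#' errors against the recovered CoP references.
#'
#' @inheritParams run_subject_pipeline
#' @param hold_s,transition_s,angle_jitter_deg,cop_jitter_mm Passed to
#'   [expand_to_time_series()].
#' @return List with `n_detected`, `identification`, `rmse_mm`
#'   ([rmse_per_axis()] of the held-out predictions, mm), `detection`.
#' @export
run_stream_pipeline <- function(subject, m = 60, noise = noise_model(0, 0),
                                fraction_identify = 0.75, seed = 1L,
                                hold_s = 2.0, transition_s = 1.0,
                                angle_jitter_deg = 0, cop_jitter_mm = 0) {
  tree <- subject$tree
  postures <- sample_static_postures(subject, m, seed = seed)
  trial <- simulate_trial(subject, postures, noise)
  criteria <- static_posture_criteria()
  streams <- expand_to_time_series(tree, trial$observations, criteria,
                                   hold_s = hold_s,
                                   transition_s = transition_s,
                                   seed = seed + 2L,
                                   angle_jitter_deg = angle_jitter_deg,
                                   cop_jitter_mm = cop_jitter_mm)
  det <- detect_static_postures(streams$angles, streams$cop, criteria)
  root_position <- trial$observations[[1]]$posture$root_position
  obs <- observations_from_detection(tree, det,
                                     root_position = root_position)
  split <- split_postures(obs, fraction_identify, seed = seed + 3L,
                          min_identify = minimum_postures(tree$n_bodies))
  ident <- suppressWarnings(identify_sesc(stack_system(tree, split$identify)))
  eval_postures <- lapply(split$evaluate, function(o) o$posture)
  cop_mm <- t(vapply(split$evaluate, function(o) o$cop * 1000, numeric(2)))
  est_mm <- predict_com(tree, ident$V, eval_postures)[, 1:2] * 1000
  list(n_detected = nrow(det$regions),
       identification = ident,
       rmse_mm = rmse_per_axis(est_mm, cop_mm),
       detection = det)
}
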