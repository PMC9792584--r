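test_that("the posture-count rule follows two equations per posture", {
  expect_identical(minimum_postures(1), 2L)
  expect_identical(minimum_postures(2), 3L)
  expect_identical(minimum_postures(9), 14L)
  expect_true(all(2 * sapply(1:20, minimum_postures) >= 3 * (1:20)))
  expect_true(all(2 * (sapply(1:20, minimum_postures) - 1) < 3 * (1:20)))
  expect_error(minimum_postures(0), ">= 1")
})

test_that("stacked systems have the declared shape and exact consistency", {
  tree <- default_tree()
  n_ch <- nrow(angle_channels(tree))
  idp <- posture_from_angles(tree, rep(0, n_ch), root_position = c(0.3, -0.2, 1))
  obs0 <- static_observation(idp, c(0.3, -0.2))
  sys1 <- stack_system(tree, list(obs0))
  expect_equal(dim(sys1$A), c(2, 27))
  expect_equal(sys1$b, c(0, 0))

  sub <- make_subject("fit", seed = 61)
  trial <- simulate_trial(sub, sample_static_postures(sub, 20, seed = 62),
                          noise_model(0, 0, seed = 63))
  sys <- stack_system(tree, trial$observations)
  expect_equal(dim(sys$A), c(40, 27))
  expect_equal(length(sys$b), 40)
  Vt <- sesc_vector_from_parameters(tree, sub$params)
  expect_lt(max(abs(sys$A %*% Vt$stacked - sys$b)), 1e-12)

  expect_error(stack_system(tree, list()), "at least one")
})

test_that("pseudoinverse solve matches direct inversion and minimum norm", {
  set.seed(67)
  # well-conditioned square system: exact solve
  A <- matrix(rnorm(36), 6, 6)
  x_true <- rnorm(6)
  sys <- structure(list(A = A, b = as.numeric(A %*% x_true),
                        body_order = c("1", "2"), n_obs = 3L),
                   class = "sesc_system")
  res <- identify_sesc(sys, min_m = 1)
  expect_equal(res$V$stacked, x_true, tolerance = 1e-8)
  expect_equal(res$rank, 6L)
  expect_lt(res$residual_rms, 1e-10)

  # rank-deficient stack: warns, agrees with the Moore-Penrose solution
  skip_if_not_installed("MASS")
  A2 <- A
  A2[, 6] <- A2[, 5]  # duplicated column
  b2 <- rnorm(6)
  sys2 <- structure(list(A = A2, b = b2, body_order = c("1", "2"),
                         n_obs = 3L), class = "sesc_system")
  expect_warning(res2 <- identify_sesc(sys2, min_m = 1), "rank-deficient")
  expect_equal(res2$rank, 5L)
  expect_equal(res2$V$stacked, as.numeric(MASS::ginv(A2) %*% b2),
               tolerance = 1e-8)
})

test_that("insufficient or degenerate designs are reported", {
  tree <- default_tree()
  sub <- make_subject("fit", seed = 71)
  trial <- simulate_trial(sub, sample_static_postures(sub, 10, seed = 72),
                          noise_model(0, 0, seed = 73))
  sys <- stack_system(tree, trial$observations)
  expect_error(identify_sesc(sys), "insufficient postures")

  # all postures identical: rank-deficient warning, solution still returned
  one <- sample_static_postures(sub, 1, seed = 74)
  rep_trial <- simulate_trial(sub, rep(one, 20), noise_model(0, 0, seed = 75))
  sys_rep <- stack_system(tree, rep_trial$observations)
  expect_warning(res <- identify_sesc(sys_rep), "rank-deficient")
  expect_equal(res$rank, 2L)
  expect_length(res$V$stacked, 27)
  expect_true(res$condition_number >= 1)
})

test_that("noiseless identification predicts held-out postures exactly", {
  tree <- default_tree()
  sub <- make_subject("fit", seed = 77)
  trial <- simulate_trial(sub, sample_static_postures(sub, 30, seed = 78),
                          noise_model(0, 0, seed = 79))
  sp <- split_postures(trial$observations, 0.75, seed = 80,
                       min_identify = minimum_postures(9))
  res <- suppressWarnings(identify_sesc(stack_system(tree, sp$identify)))
  est <- predict_com(tree, res$V, lapply(sp$evaluate, function(o) o$posture))
  ref <- t(sapply(sp$evaluate, function(o) o$cop))
  expect_lt(max(abs(est[, 1:2] - ref)), 1e-9)
})

test_that("posture splits have the documented sizes and determinism", {
  obs <- as.list(seq_len(120))
  sp <- split_postures(obs, 0.75, seed = 1)
  expect_length(sp$identify, 90)
  expect_length(sp$evaluate, 30)

  sp103 <- split_postures(as.list(seq_len(103)), 0.75, seed = 2)
  expect_length(sp103$identify, 77)
  expect_length(sp103$evaluate, 26)

  # disjoint and exhaustive
  expect_setequal(c(sp103$identify_idx, sp103$evaluate_idx), seq_len(103))
  expect_length(intersect(sp103$identify_idx, sp103$evaluate_idx), 0)

  sp_a <- split_postures(obs, 0.75, seed = 9)
  sp_b <- split_postures(obs, 0.75, seed = 9)
  expect_identical(sp_a$identify_idx, sp_b$identify_idx)

  sp_seq <- split_postures(obs, 0.75, seed = 1, method = "sequential")
  expect_identical(sp_seq$identify_idx, 1:90)

  expect_error(split_postures(as.list(1:10), 0.75, seed = 1,
                              min_identify = 14),
               "insufficient postures")
  expect_error(split_postures(list(), 0.75, seed = 1), "empty")
})

test_that("held-out error scales with noise and improves with postures", {
  tree <- default_tree()
  overall_rmse <- function(sub, m, seed) {
    r <- run_subject_pipeline(sub, m = m,
                              noise = noise_model(2, 0, seed = seed),
                              seed = seed + 1000L)
    sqrt(mean(c(r$sesc$rmse$rmse_ap, r$sesc$rmse$rmse_ml)^2))
  }
  sub <- make_subject("fit", seed = 83)
  meds <- sapply(c(14 * 4 / 3, 30, 60), function(m) {
    # m scaled so the identification set (75%) holds ~m postures
    stats::median(sapply(1:8, function(s)
      overall_rmse(sub, ceiling(m / 0.75) + 2, s)))
  })
  # monotone improvement in the median, allowing no more than one inversion
  expect_lt(sum(diff(meds) > 0), 2)
  expect_true(all(meds > 0.3 & meds < 6))
})

test_that("identified predictions are stable across split seeds", {
  tree <- default_tree()
  sub <- make_subject("fit", seed = 89)
  trial <- simulate_trial(sub, sample_static_postures(sub, 100, seed = 90),
                          noise_model(2, 0, seed = 91))
  probe <- sample_static_postures(sub, 20, seed = 92)
  pred <- function(split_seed) {
    sp <- split_postures(trial$observations, 0.75, seed = split_seed,
                         min_identify = 14)
    res <- suppressWarnings(identify_sesc(stack_system(tree, sp$identify)))
    predict_com(tree, res$V, probe)[, 1:2]
  }
  d <- pred(1) - pred(2)
  expect_lt(sqrt(mean(d^2)) * 1000, 2)  # < 2 mm RMS at 2 mm CoP noise
})
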