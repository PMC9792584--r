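test_that("weighted-sum CoM handles degenerate cases exactly", {
  t1 <- single_body_tree()
  params <- segment_parameters(c("1" = 3),
                               list("1" = c(0.1, 0.2, 0.3)),
                               list("1" = c(0, 0, 0)))
  p <- posture_frame(t1, diag(3), c(1, 2, 3))
  expect_equal(brute_force_com(t1, params, p), c(1.1, 2.2, 3.3))

  # two equal-mass bodies: CoM is the midpoint of the two global CoMs
  t2 <- two_link_tree()
  params2 <- segment_parameters(c("1" = 2, "2" = 2),
                                list("1" = c(0.2, 0, 0), "2" = c(0, 0.3, 0)),
                                list("1" = c(0, 0, 0), "2" = c(0, 0, 0.5)))
  set.seed(31)
  p2 <- rand_posture(t2)
  H <- oracle_global_transforms(t2, p2, params2$displacement)
  g1 <- (H[["1"]] %*% c(0.2, 0, 0, 1))[1:3]
  g2 <- (H[["2"]] %*% c(0, 0.3, 0, 1))[1:3]
  expect_equal(brute_force_com(t2, params2, p2), (g1 + g2) / 2,
               tolerance = 1e-12)

  expect_error(brute_force_com(t2, params, p2), "parameters missing")
})

test_that("weighted-sum CoM matches the literal nine-term expansion", {
  tree <- default_tree()
  set.seed(37)
  for (rep in 1:10) {
    params <- rand_params(tree)
    p <- rand_posture(tree)
    com <- brute_force_com(tree, params, p)
    expect_equal(com, oracle_com_ninebody(tree, params, p), tolerance = 1e-12)
    expect_equal(com, oracle_com(tree, params, p), tolerance = 1e-12)
  }
})

test_that("closed-form link vectors reproduce hand expansions", {
  # single body: v_1 = C_1
  t1 <- single_body_tree()
  params <- segment_parameters(c("1" = 5), list("1" = c(0.1, -0.2, 0.3)),
                               list("1" = c(0, 0, 0)))
  V <- sesc_vector_from_parameters(t1, params)
  expect_equal(V$links[["1"]], c(0.1, -0.2, 0.3))

  # two-link chain: v_1 = (m1 C1 + m2 d2)/M, v_2 = m2 C2 / M
  t2 <- two_link_tree()
  m1 <- 3; m2 <- 7
  C1 <- c(0.1, 0.2, -0.1); C2 <- c(-0.2, 0.05, 0.3); d2 <- c(0, 0.1, 0.6)
  params2 <- segment_parameters(c("1" = m1, "2" = m2),
                                list("1" = C1, "2" = C2),
                                list("1" = c(0, 0, 0), "2" = d2))
  V2 <- sesc_vector_from_parameters(t2, params2)
  M <- m1 + m2
  expect_equal(V2$links[["1"]], (m1 * C1 + m2 * d2) / M, tolerance = 1e-14)
  expect_equal(V2$links[["2"]], m2 * C2 / M, tolerance = 1e-14)
})

test_that("serial-chain form equals the weighted sum for random instances", {
  tree <- default_tree()
  set.seed(41)
  params <- rand_params(tree)
  V <- sesc_vector_from_parameters(tree, params)
  for (rep in 1:100) {
    p <- rand_posture(tree)
    row <- build_regressor_row(tree, p)
    expect_equal(estimate_com(row, p$root_position, V),
                 brute_force_com(tree, params, p), tolerance = 1e-12)
    # and through the [I | Rhat] [d1; V] product directly
    expect_equal(as.numeric(row$full %*% c(p$root_position, V$stacked)),
                 brute_force_com(tree, params, p), tolerance = 1e-12)
  }
})

test_that("regressor rows have the declared block structure", {
  tree <- default_tree()
  idp <- posture_from_angles(tree, rep(0, nrow(angle_channels(tree))))
  row <- build_regressor_row(tree, idp)
  expect_equal(dim(row$full), c(3, 3 + 3 * 9))
  expect_equal(row$full[, 1:3], diag(3))
  for (j in seq_len(9)) {
    expect_equal(row$full[, 3 * j + (1:3)], diag(3))
  }
  expect_equal(row$horizontal, row$full[1:2, -(1:3)])

  # single body rotated 90 deg about vertical maps AP to ML
  t1 <- single_body_tree()
  p90 <- posture_frame(t1, hinge_rotation(c(0, 0, 1), pi / 2), c(0, 0, 0))
  r90 <- build_regressor_row(t1, p90)
  expect_equal(as.numeric(r90$full[, 4:6] %*% c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
})

test_that("serial-chain prediction degenerates correctly", {
  tree <- default_tree()
  n_ch <- nrow(angle_channels(tree))
  idp <- posture_from_angles(tree, rep(0, n_ch), root_position = c(1, 2, 3))
  row <- build_regressor_row(tree, idp)
  V0 <- sesc_vector_from_stacked(rep(0, 27), tree$order)
  expect_equal(estimate_com(row, idp$root_position, V0), c(1, 2, 3))

  set.seed(43)
  V <- sesc_vector_from_stacked(rnorm(27), tree$order)
  tot <- Reduce(`+`, V$links)
  expect_equal(estimate_com(row, idp$root_position, V), c(1, 2, 3) + tot,
               tolerance = 1e-12)

  Vshort <- sesc_vector_from_stacked(rnorm(6), c("1", "2"))
  expect_error(estimate_com(row, c(0, 0, 0), Vshort), "body orders")
})

test_that("both CoM forms are covariant under rigid root motion", {
  tree <- default_tree()
  set.seed(47)
  params <- rand_params(tree)
  V <- sesc_vector_from_parameters(tree, params)
  p <- rand_posture(tree)
  Q <- rand_rotation(); shift <- rnorm(3)
  p2 <- posture_frame(tree, Q %*% p$root_rotation,
                      as.numeric(Q %*% p$root_position + shift),
                      p$joint_rotation)
  moved <- function(x) as.numeric(Q %*% x + shift)
  expect_equal(brute_force_com(tree, params, p2),
               moved(brute_force_com(tree, params, p)), tolerance = 1e-10)
  expect_equal(estimate_com(build_regressor_row(tree, p2), p2$root_position, V),
               moved(estimate_com(build_regressor_row(tree, p), p$root_position, V)),
               tolerance = 1e-10)
})

test_that("the CoM lies inside the convex hull of segment CoMs", {
  tree <- default_tree()
  set.seed(53)
  for (rep in 1:5) {
    params <- rand_params(tree)
    p <- rand_posture(tree)
    com <- brute_force_com(tree, params, p)
    H <- forward_body_transforms(tree, p, params$displacement)
    pts <- sapply(tree$ids, function(b)
      apply_transform(H[[b]], params$local_com[[b]]))
    # support-function check along random directions
    for (k in 1:20) {
      u <- rnorm(3)
      expect_lte(sum(com * u), max(colSums(pts * u)) + 1e-12)
      expect_gte(sum(com * u), min(colSums(pts * u)) - 1e-12)
    }
  }
})

test_that("SESC vectors serialize to JSON and back", {
  tree <- default_tree()
  set.seed(59)
  V <- sesc_vector_from_parameters(tree, rand_params(tree))
  tf <- tempfile(fileext = ".json")
  write_sesc_json(V, tf)
  V2 <- read_sesc_json(tf)
  expect_equal(V2$body_order, V$body_order)
  expect_equal(V2$stacked, V$stacked, tolerance = 1e-12)
})
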