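test_that("path rotation composes joint rotations along root-to-body paths", {
  tree <- default_tree()
  idp <- posture_from_angles(tree, rep(0, nrow(angle_channels(tree))))
  for (b in tree$ids) {
    expect_equal(path_rotation(tree, idp, b), diag(3), tolerance = 1e-14)
  }

  # two quarter turns about the vertical compose to a half turn
  t2 <- two_link_tree()
  qz <- hinge_rotation(c(0, 0, 1), pi / 2)
  p <- posture_frame(t2, root_rotation = qz, joint_rotation = list("2" = qz))
  expect_equal(path_rotation(t2, p, "2"),
               diag(c(-1, -1, 1)), tolerance = 1e-12)

  # random postures: agrees with the 4x4 transform-composition oracle and
  # with the rotation blocks of forward_body_transforms
  set.seed(11)
  d <- stats::setNames(lapply(tree$ids, function(b) rnorm(3)), tree$ids)
  for (rep in 1:5) {
    p <- rand_posture(tree)
    H <- forward_body_transforms(tree, p, d)
    Ho <- oracle_global_transforms(tree, p, d)
    for (b in tree$ids) {
      expect_equal(path_rotation(tree, p, b), Ho[[b]][1:3, 1:3],
                   tolerance = 1e-12)
      expect_equal(H[[b]]$rotation, path_rotation(tree, p, b),
                   tolerance = 1e-12)
      expect_equal(H[[b]]$translation, Ho[[b]][1:3, 4], tolerance = 1e-12)
    }
  }
  expect_error(path_rotation(tree, p, "42"), "unknown body")
})

test_that("hinge rotations satisfy closed-form identities", {
  expect_equal(hinge_rotation(c(1, 0, 0), 0), diag(3))
  expect_equal(hinge_rotation(c(0, 0, 1), pi), diag(c(-1, -1, 1)),
               tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, -pi, pi)
    R <- hinge_rotation(ax, th)
    expect_equal(sum(diag(R)), 1 + 2 * cos(th), tolerance = 1e-12)
    expect_true(is_rotation(R, 1e-12))
    expect_equal(hinge_angle(R, ax), th, tolerance = 1e-10)
  }
  expect_error(hinge_rotation(c(1, 1, 0), 0.3), "unit norm")
})

test_that("orthonormality survives long composition chains", {
  set.seed(7)
  R <- diag(3)
  for (i in 1:200) R <- R %*% rand_rotation()
  expect_true(is_rotation(R, 1e-9))
})

test_that("transform composition is associative and identity is neutral", {
  set.seed(13)
  a <- rigid_transform(rand_rotation(), rnorm(3))
  b <- rigid_transform(rand_rotation(), rnorm(3))
  cc <- rigid_transform(rand_rotation(), rnorm(3))
  lhs <- compose_transform(compose_transform(a, b), cc)
  rhs <- compose_transform(a, compose_transform(b, cc))
  expect_equal(lhs$rotation, rhs$rotation, tolerance = 1e-12)
  expect_equal(lhs$translation, rhs$translation, tolerance = 1e-12)
  p <- rnorm(3)
  expect_equal(apply_transform(rigid_transform(), p), p)
})

test_that("forward transforms handle identity, single-body and bad input", {
  tree <- default_tree()
  idp <- posture_from_angles(tree, rep(0, nrow(angle_channels(tree))))
  zero_d <- stats::setNames(lapply(tree$ids, function(b) c(0, 0, 0)), tree$ids)
  H <- forward_body_transforms(tree, idp, zero_d)
  for (b in tree$ids) {
    expect_equal(H[[b]]$rotation, diag(3))
    expect_equal(H[[b]]$translation, c(0, 0, 0))
  }
  expect_error(forward_body_transforms(tree, idp, zero_d[1:3]),
               "displacement missing")

  t1 <- single_body_tree()
  set.seed(3)
  R1 <- rand_rotation(); d1 <- rnorm(3)
  p1 <- posture_frame(t1, R1, d1)
  H1 <- forward_body_transforms(t1, p1, list())
  expect_equal(H1[["1"]]$rotation, R1)
  expect_equal(H1[["1"]]$translation, d1)
})

test_that("euler and quaternion constructors round-trip", {
  set.seed(17)
  for (rep in 1:20) {
    R <- rand_rotation()
    e <- euler_zxy(R)
    expect_equal(rot_from_euler_zxy(e[1], e[2], e[3]), R, tolerance = 1e-10)
  }
  q <- rnorm(4)
  expect_true(is_rotation(rot_from_quat(q[1], q[2], q[3], q[4]), 1e-12))
})

test_that("posture frames validate hinge-axis constraints and coverage", {
  tree <- default_tree()
  jr <- stats::setNames(lapply(2:9, function(i) diag(3)), as.character(2:9))
  expect_s3_class(posture_frame(tree, joint_rotation = jr), "posture_frame")
  jr3 <- jr
  jr3[["3"]] <- hinge_rotation(c(1, 0, 0), 0.4)  # knee is an ML hinge
  expect_error(posture_frame(tree, joint_rotation = jr3),
               "not about its declared axis")
  expect_error(posture_frame(tree, joint_rotation = jr[1:5]),
               "joint_rotation missing")
})

test_that("tree invariants are enforced", {
  expect_error(kinematic_tree(c("1" = NA, "2" = NA),
                              c("1" = "root", "2" = "root")),
               "exactly one root")
  expect_error(kinematic_tree(c("1" = 2, "2" = 1),
                              c("1" = "spherical", "2" = "spherical")),
               "exactly one root")
  expect_error(kinematic_tree(c("1" = NA, "2" = 7),
                              c("1" = "root", "2" = "spherical")),
               "unknown parent")
  expect_error(kinematic_tree(c("1" = NA, "2" = 1),
                              c("1" = "root", "2" = "hinge")),
               "hinge body")
})

test_that("tree JSON and posture CSV round-trip", {
  tree <- default_tree()
  tf <- tempfile(fileext = ".json")
  write_tree_json(tree, tf)
  tree2 <- read_tree_json(tf)
  expect_equal(tree2$parent, tree$parent)
  expect_equal(tree2$joint, tree$joint)
  expect_equal(tree2$hinge_axis, tree$hinge_axis)

  set.seed(23)
  sub <- make_subject("fit", seed = 1)
  postures <- sample_static_postures(sub, 4, seed = 2)
  pf <- tempfile(fileext = ".csv")
  write_posture_csv(postures, tree, pf)
  back <- read_posture_csv(pf, tree)
  for (i in seq_along(postures)) {
    expect_equal(back[[i]]$root_rotation, postures[[i]]$root_rotation,
                 tolerance = 1e-8)
    expect_equal(back[[i]]$root_position, postures[[i]]$root_position,
                 tolerance = 1e-10)
    for (b in names(postures[[i]]$joint_rotation)) {
      expect_equal(back[[i]]$joint_rotation[[b]],
                   postures[[i]]$joint_rotation[[b]], tolerance = 1e-8)
    }
  }
})
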