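# Independent oracles and random-instance generators for the test suite.
# The oracles deliberately use plain 4x4 homogeneous-matrix arithmetic, a
# different code path from the package's rigid_transform composition.

hom4 <- function(R, d) {
  m <- rbind(cbind(R, d), c(0, 0, 0, 1))
  dimnames(m) <- NULL
  m
}

# global 4x4 transform of every body by sequential products down the tree
oracle_global_transforms <- function(tree, posture, d) {
  H <- list()
  for (b in tree$order) {
    Hl <- if (b == tree$root) {
      hom4(posture$root_rotation, posture$root_position)
    } else {
      hom4(posture$joint_rotation[[b]], d[[b]])
    }
    H[[b]] <- if (b == tree$root) Hl else
      H[[as.character(tree$parent[[b]])]] %*% Hl
  }
  H
}

# mass-weighted CoM via the 4x4 oracle transforms
oracle_com <- function(tree, params, posture) {
  H <- oracle_global_transforms(tree, posture, params$displacement)
  s <- c(0, 0, 0)
  for (b in tree$ids) {
    s <- s + params$mass[[b]] *
      (H[[b]] %*% c(params$local_com[[b]], 1))[1:3]
  }
  s / params$total_mass
}

# literal nine-term expansion for the default tree: root, chains
# 1-2-3-4 and 1-5-6-7, branches 1-8 and 1-9
oracle_com_ninebody <- function(tree, params, posture) {
  R <- function(b) if (b == "1") posture$root_rotation else
    posture$joint_rotation[[b]]
  d <- function(b) if (b == "1") posture$root_position else
    params$displacement[[b]]
  Hc <- function(bodies) {
    M <- diag(4)
    for (b in bodies) M <- M %*% hom4(R(b), d(b))
    M
  }
  paths <- list("1" = "1", "2" = c("1", "2"), "3" = c("1", "2", "3"),
                "4" = c("1", "2", "3", "4"), "5" = c("1", "5"),
                "6" = c("1", "5", "6"), "7" = c("1", "5", "6", "7"),
                "8" = c("1", "8"), "9" = c("1", "9"))
  s <- c(0, 0, 0)
  for (b in names(paths)) {
    s <- s + params$mass[[b]] *
      (Hc(paths[[b]]) %*% c(params$local_com[[b]], 1))[1:3]
  }
  s / params$total_mass
}

rand_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  rot_from_quat(q[1], q[2], q[3], q[4])
}

rand_posture <- function(tree, root_position = stats::rnorm(3)) {
  jr <- list()
  for (b in setdiff(tree$ids, tree$root)) {
    jr[[b]] <- if (tree$joint[[b]] == "hinge") {
      hinge_rotation(tree$hinge_axis[[b]], stats::runif(1, -pi, pi))
    } else {
      rand_rotation()
    }
  }
  posture_frame(tree, rand_rotation(), root_position, jr)
}

rand_params <- function(tree) {
  ids <- tree$ids
  mass <- stats::setNames(stats::runif(length(ids), 0.5, 10), ids)
  local_com <- stats::setNames(
    lapply(ids, function(b) stats::runif(3, -0.3, 0.3)), ids)
  displacement <- stats::setNames(
    lapply(ids, function(b) stats::runif(3, -0.5, 0.5)), ids)
  segment_parameters(mass, local_com, displacement)
}

two_link_tree <- function() {
  kinematic_tree(parent = c("1" = NA, "2" = 1),
                 joint = c("1" = "root", "2" = "spherical"))
}

single_body_tree <- function() {
  kinematic_tree(parent = c("1" = NA), joint = c("1" = "root"))
}
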