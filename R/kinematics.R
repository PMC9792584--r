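#' Branched rigid-body kinematic tree
#'
#' A `kinematic_tree` describes the topology of a branched rigid-body model
#' of the human body: one root body carrying a free 6-DoF pose, and child
#' bodies attached to their parents by either spherical (3-DoF) or hinge
#' (1-DoF) joints. The default humanoid model ([default_tree()]) has nine
#' bodies: a pelvis root, two three-link leg chains (hip-knee-ankle) and two
#' single-link branches off the root for the trunk/head and the upper limbs.
#'
#' Global frame convention used throughout the package: x = anteroposterior
#' (AP, anterior positive), y = mediolateral (ML), z = vertical (up).
#'
#' @param parent Named integer vector mapping body id to parent body id; the
#'   root's entry is `NA`. Names are body ids ("1", "2", ...).
#' @param joint Named character vector mapping body id to joint type, one of
#'   `"root"`, `"spherical"`, `"hinge"`. The root body must be `"root"`.
#' @param hinge_axis Named list of unit 3-vectors (local/parent frame) for
#'   every hinge body.
#' @return An object of class `kinematic_tree` with elements `ids`,
#'   `n_bodies`, `parent`, `joint`, `hinge_axis`, `children` and `order`
#'   (depth-first body order used to stack SESC vectors).
#' @export
kinematic_tree <- function(parent, joint, hinge_axis = list()) {
  ids <- names(parent)
  if (is.null(ids) || any(ids == "")) {
    stop("`parent` must be a named vector (names are body ids)")
  }
  if (anyDuplicated(ids)) stop("duplicate body ids")
  if (is.null(names(joint)) || !setequal(names(joint), ids)) {
    stop("`joint` must cover exactly the bodies named in `parent`")
  }
  joint <- joint[ids]
  bad <- setdiff(unique(joint), c("root", "spherical", "hinge"))
  if (length(bad)) stop("unknown joint type(s): ", paste(bad, collapse = ", "))
  root <- ids[is.na(parent)]
  if (length(root) != 1L) stop("the tree must have exactly one root body")
  if (joint[[root]] != "root") stop("the root body must have joint type 'root'")
  if (any(joint[ids != root] == "root")) stop("only the root may have joint type 'root'")
  for (b in ids[ids != root]) {
    p <- as.character(parent[[b]])
    if (!p %in% ids) stop("body ", b, " has unknown parent ", p)
  }
  # acyclicity: every body must reach the root
  for (b in ids) {
    seen <- character(0)
    cur <- b
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("parent map contains a cycle through body ", b)
      seen <- c(seen, cur)
      cur <- as.character(parent[[cur]])
    }
  }
  hinge_ids <- ids[joint == "hinge"]
  for (b in hinge_ids) {
    ax <- hinge_axis[[b]]
    if (is.null(ax)) stop("hinge body ", b, " needs an entry in `hinge_axis`")
    check_unit_axis(ax)
    hinge_axis[[b]] <- as.numeric(ax)
  }
  children <- lapply(ids, function(b) ids[!is.na(parent) & as.character(parent) == b])
  names(children) <- ids
  tree <- structure(
    list(ids = ids, n_bodies = length(ids), root = root,
         parent = parent, joint = joint,
         hinge_axis = hinge_axis[intersect(names(hinge_axis), hinge_ids)],
         children = children),
    class = "kinematic_tree")
  tree$order <- dfs_order(tree)
  tree
}

dfs_order <- function(tree) {
  out <- character(0)
  visit <- function(b) {
    out <<- c(out, b)
    for (ch in tree$children[[b]]) visit(ch)
  }
  visit(tree$root)
  out
}

check_unit_axis <- function(ax, tol = 1e-8) {
  ax <- as.numeric(ax)
  if (length(ax) != 3L || !all(is.finite(ax))) stop("hinge axis must be a finite 3-vector")
  if (abs(sqrt(sum(ax^2)) - 1) > tol) stop("hinge axis must have unit norm (within 1e-8)")
  invisible(ax)
}

#' @export
print.kinematic_tree <- function(x, ...) {
  cat("Kinematic tree:", x$n_bodies, "bodies, root =", x$root, "\n")
  for (b in x$order) {
    p <- x$parent[[b]]
    cat(sprintf("  body %s  parent %s  joint %s\n", b,
                ifelse(is.na(p), "-", p), x$joint[[b]]))
  }
  invisible(x)
}

#' Default nine-body humanoid tree
#'
#' Pelvis root (body 1), right leg 1-2-3-4 and left leg 1-5-6-7
#' (hip spherical, knee and ankle hinges about the parent ML axis), and two
#' single-link spherical branches off the root: trunk/head (body 8) and
#' lumped upper limbs (body 9). 19 joint DoF in addition to the free root
#' pose.
#'
#' @return A [kinematic_tree()].
#' @export
default_tree <- function() {
  ml <- c(0, 1, 0)  # hinge flexion/extension axis: parent mediolateral
  kinematic_tree(
    parent = c("1" = NA, "2" = 1, "3" = 2, "4" = 3,
               "5" = 1, "6" = 5, "7" = 6, "8" = 1, "9" = 1),
    joint = c("1" = "root", "2" = "spherical", "3" = "hinge", "4" = "hinge",
              "5" = "spherical", "6" = "hinge", "7" = "hinge",
              "8" = "spherical", "9" = "spherical"),
    hinge_axis = list("3" = ml, "4" = ml, "6" = ml, "7" = ml))
}

#' Path from the root to a body
#' @param tree A [kinematic_tree()].
#' @param body Body id (coerced to character).
#' @return Character vector of body ids, root first, `body` last.
#' @export
path_from_root <- function(tree, body) {
  body <- as.character(body)
  if (!body %in% tree$ids) stop("unknown body id: ", body)
  path <- character(0)
  cur <- body
  repeat {
    path <- c(cur, path)
    p <- tree$parent[[cur]]
    if (is.na(p)) break
    cur <- as.character(p)
  }
  path
}

# ---- rotations ---------------------------------------------------------

#' Validate a rotation matrix
#' @param R 3x3 matrix.
#' @param tol Orthonormality/determinant tolerance.
#' @return `TRUE` or `FALSE`.
#' @export
is_rotation <- function(R, tol = 1e-10) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && abs(det(R) - 1) <= tol
}

assert_rotation <- function(R, what = "rotation", tol = 1e-8) {
  if (!is_rotation(R, tol)) stop(what, " is not a valid rotation matrix")
  invisible(R)
}

#' Rotation about an arbitrary unit axis (Rodrigues formula)
#'
#' @param axis Unit 3-vector (checked to 1e-8).
#' @param angle Rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
hinge_rotation <- function(axis, angle) {
  axis <- check_unit_axis(axis)
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Signed hinge angle of a rotation about a known axis
#' @param R 3x3 rotation about `axis`.
#' @param axis Unit 3-vector.
#' @return Angle in radians in (-pi, pi].
#' @export
hinge_angle <- function(R, axis) {
  axis <- check_unit_axis(axis)
  a <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  atan2(sum(a * axis), (sum(diag(R)) - 1) / 2)
}

#' Rotation from intrinsic Z-X-Y Euler angles
#'
#' `R = Rz(z) %*% Rx(x) %*% Ry(y)`. This is the parameterization used at the
#' I/O boundary (posture CSV columns `euler_z/x/y_deg`).
#'
#' @param z,x,y Angles in radians.
#' @return 3x3 rotation matrix.
#' @export
rot_from_euler_zxy <- function(z, x, y) {
  cz <- cos(z); sz <- sin(z); cx <- cos(x); sx <- sin(x); cy <- cos(y); sy <- sin(y)
  matrix(c(
    cz * cy - sz * sx * sy,  sz * cy + cz * sx * sy, -cx * sy,
    -sz * cx,                cz * cx,                 sx,
    cz * sy + sz * sx * cy,  sz * sy - cz * sx * cy,  cx * cy
  ), nrow = 3, ncol = 3)
}

#' Intrinsic Z-X-Y Euler angles of a rotation
#' @param R 3x3 rotation matrix.
#' @return Numeric 3-vector `c(z, x, y)` in radians.
#' @export
euler_zxy <- function(R) {
  x <- asin(max(-1, min(1, R[3, 2])))
  if (abs(R[3, 2]) < 1 - 1e-12) {
    z <- atan2(-R[1, 2], R[2, 2])
    y <- atan2(-R[3, 1], R[3, 3])
  } else {
    # gimbal lock: y is unrecoverable, fold into z
    z <- atan2(R[2, 1], R[1, 1])
    y <- 0
  }
  c(z = z, x = x, y = y)
}

#' Rotation from a unit quaternion
#' @param w,x,y,z Quaternion components (normalized internally).
#' @return 3x3 rotation matrix.
#' @export
rot_from_quat <- function(w, x, y, z) {
  n <- sqrt(w^2 + x^2 + y^2 + z^2)
  if (n < 1e-12) stop("zero quaternion")
  w <- w / n; x <- x / n; y <- y / n; z <- z / n
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z),     2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2),     2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x),     1 - 2 * (x^2 + y^2)
  ), nrow = 3, ncol = 3)
}

# ---- posture frames ----------------------------------------------------

#' One static body configuration
#'
#' Holds the root pose (rotation `R_1`, position `d_1` in meters) and, for
#' every non-root body, the joint rotation expressed relative to its parent
#' frame. Hinge-joint rotations are checked to be rotations about the
#' declared hinge axis.
#'
#' @param tree A [kinematic_tree()].
#' @param root_rotation 3x3 rotation of the root body.
#' @param root_position Numeric 3-vector, meters.
#' @param joint_rotation Named list of 3x3 rotations covering every non-root
#'   body.
#' @return Object of class `posture_frame`.
#' @export
posture_frame <- function(tree, root_rotation = diag(3),
                          root_position = c(0, 0, 0), joint_rotation = list()) {
  assert_rotation(root_rotation, "root_rotation")
  root_position <- as.numeric(root_position)
  if (length(root_position) != 3L || !all(is.finite(root_position))) {
    stop("root_position must be a finite 3-vector")
  }
  non_root <- setdiff(tree$ids, tree$root)
  missing <- setdiff(non_root, names(joint_rotation))
  if (length(missing)) {
    stop("joint_rotation missing for bodies: ", paste(missing, collapse = ", "))
  }
  for (b in non_root) {
    R <- joint_rotation[[b]]
    assert_rotation(R, paste0("joint_rotation[['", b, "']]"))
    if (tree$joint[[b]] == "hinge") {
      ax <- tree$hinge_axis[[b]]
      ang <- hinge_angle(R, ax)
      if (max(abs(R - hinge_rotation(ax, ang))) > 1e-8) {
        stop("rotation of hinge body ", b, " is not about its declared axis")
      }
    }
  }
  structure(list(root_rotation = root_rotation,
                 root_position = root_position,
                 joint_rotation = joint_rotation[non_root]),
            class = "posture_frame")
}

body_rotation <- function(tree, posture, body) {
  if (body == tree$root) posture$root_rotation else posture$joint_rotation[[body]]
}

#' Cumulative rotation from the global frame to a body frame
#'
#' The product of joint rotations along the root-to-body path, root rotation
#' first: the orientation of `body`'s local frame in the global frame.
#'
#' @inheritParams path_from_root
#' @param posture A [posture_frame()].
#' @return 3x3 rotation matrix.
#' @export
path_rotation <- function(tree, posture, body) {
  path <- path_from_root(tree, body)
  R <- diag(3)
  for (b in path) R <- R %*% body_rotation(tree, posture, b)
  R
}

# ---- homogeneous transforms -------------------------------------------

#' Rigid transform (rotation + translation)
#' @param rotation 3x3 rotation matrix.
#' @param translation Numeric 3-vector, meters.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  assert_rotation(rotation)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return `a %then% b` as a [rigid_transform()]: `x -> a(b(x))`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$translation + a$rotation %*% b$translation))
}

#' Apply a rigid transform to a point
#' @param h A [rigid_transform()].
#' @param p Numeric 3-vector.
#' @return Numeric 3-vector.
#' @export
apply_transform <- function(h, p) {
  as.numeric(h$rotation %*% p + h$translation)
}

#' Forward kinematics: global pose of every body
#'
#' Walks the tree composing per-body transforms `(R_i, d_i)`: body `k`'s
#' transform maps points in body-k local coordinates to the global frame.
#' The root transform is `(R_1, d_1)` with `d_1` taken from the posture's
#' root position.
#'
#' @inheritParams path_rotation
#' @param d Named list (or 3 x n matrix with body-id column names) of
#'   displacement 3-vectors: `d[[k]]` is the position of body k's joint in
#'   its parent's frame. The root entry, if present, is ignored in favor of
#'   `posture$root_position`.
#' @return Named list of [rigid_transform()]s, one per body.
#' @export
forward_body_transforms <- function(tree, posture, d) {
  if (is.matrix(d)) d <- as_vec_list(d)
  missing <- setdiff(setdiff(tree$ids, tree$root), names(d))
  if (length(missing)) {
    stop("displacement missing for bodies: ", paste(missing, collapse = ", "))
  }
  out <- vector("list", tree$n_bodies)
  names(out) <- tree$ids
  out[[tree$root]] <- rigid_transform(posture$root_rotation, posture$root_position)
  for (b in tree$order) {
    if (b == tree$root) next
    p <- as.character(tree$parent[[b]])
    out[[b]] <- compose_transform(out[[p]],
                                  rigid_transform(posture$joint_rotation[[b]],
                                                  d[[b]]))
  }
  out
}

as_vec_list <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == 3)
  out <- lapply(seq_len(ncol(m)), function(j) m[, j])
  names(out) <- colnames(m)
  out
}

# ---- per-joint angle channels -----------------------------------------

#' Angle-channel layout of a tree
#'
#' Non-root bodies contribute, in depth-first order, three channels
#' (intrinsic Z-X-Y Euler angles) for spherical joints and one channel for
#' hinge joints. This layout is shared by the posture CSV format, the
#' static-posture detector and the synthetic stream generator.
#'
#' @param tree A [kinematic_tree()].
#' @return Data frame with columns `body`, `axis`, `channel` (column name).
#' @export
angle_channels <- function(tree) {
  rows <- list()
  for (b in setdiff(tree$order, tree$root)) {
    if (tree$joint[[b]] == "spherical") {
      for (ax in c("z", "x", "y")) {
        rows[[length(rows) + 1L]] <-
          data.frame(body = b, axis = ax,
                     channel = sprintf("b%s_euler_%s_deg", b, ax))
      }
    } else {
      rows[[length(rows) + 1L]] <-
        data.frame(body = b, axis = "hinge",
                   channel = sprintf("b%s_hinge_deg", b))
    }
  }
  do.call(rbind, rows)
}

#' Build a posture from a flat angle vector
#'
#' @inheritParams angle_channels
#' @param angles_deg Numeric vector in the [angle_channels()] layout, degrees.
#' @param root_rotation,root_position Root pose.
#' @return A [posture_frame()].
#' @export
posture_from_angles <- function(tree, angles_deg, root_rotation = diag(3),
                                root_position = c(0, 0, 0)) {
  ch <- angle_channels(tree)
  if (length(angles_deg) != nrow(ch)) {
    stop("expected ", nrow(ch), " angle channels, got ", length(angles_deg))
  }
  a <- angles_deg * pi / 180
  jr <- list()
  i <- 1L
  for (b in setdiff(tree$order, tree$root)) {
    if (tree$joint[[b]] == "spherical") {
      jr[[b]] <- rot_from_euler_zxy(a[i], a[i + 1L], a[i + 2L])
      i <- i + 3L
    } else {
      jr[[b]] <- hinge_rotation(tree$hinge_axis[[b]], a[i])
      i <- i + 1L
    }
  }
  posture_frame(tree, root_rotation, root_position, jr)
}

#' Flat angle vector of a posture
#' @inheritParams path_rotation
#' @return Numeric vector (degrees) in the [angle_channels()] layout.
#' @export
angles_from_posture <- function(tree, posture) {
  out <- numeric(0)
  for (b in setdiff(tree$order, tree$root)) {
    R <- posture$joint_rotation[[b]]
    if (tree$joint[[b]] == "spherical") {
      out <- c(out, euler_zxy(R))
    } else {
      out <- c(out, hinge_angle(R, tree$hinge_axis[[b]]))
    }
  }
  out * 180 / pi
}

# ---- serialization -----------------------------------------------------

#' Write / read a kinematic tree as JSON
#'
#' Format: `{"bodies": [{"id", "parent", "joint", "axis"}]}` with `parent`
#' null for the root and `axis` present only for hinge joints.
#'
#' @param tree A [kinematic_tree()].
#' @param path File path.
#' @return `read_tree_json` returns a [kinematic_tree()].
#' @export
write_tree_json <- function(tree, path) {
  bodies <- lapply(tree$ids, function(b) {
    entry <- list(id = b, joint = tree$joint[[b]])
    if (!is.na(tree$parent[[b]])) {
      entry$parent <- as.character(tree$parent[[b]])
    }
    if (tree$joint[[b]] == "hinge") entry$axis <- tree$hinge_axis[[b]]
    entry
  })
  jsonlite::write_json(list(bodies = bodies), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path)
  ids <- vapply(obj$bodies, function(b) as.character(b$id), "")
  parent <- vapply(obj$bodies, function(b)
    if (is.null(b$parent)) NA_integer_ else as.integer(b$parent), 1L)
  names(parent) <- ids
  joint <- vapply(obj$bodies, function(b) b$joint, "")
  names(joint) <- ids
  hinge_axis <- list()
  for (b in obj$bodies) {
    if (!is.null(b$axis)) hinge_axis[[as.character(b$id)]] <- unlist(b$axis)
  }
  kinematic_tree(parent, joint, hinge_axis)
}

#' Write / read posture frames as CSV
#'
#' One row per frame: `frame_index`, `time_s`, the [angle_channels()]
#' columns in degrees, and the root position `root_px_m/py/pz` plus root
#' Euler angles `root_euler_z/x/y_deg`.
#'
#' @param postures List of [posture_frame()]s.
#' @param tree A [kinematic_tree()].
#' @param path File path.
#' @param time_s Optional vector of timestamps (defaults to frame index at
#'   60 Hz).
#' @return `read_posture_csv` returns a list of [posture_frame()]s.
#' @export
write_posture_csv <- function(postures, tree, path, time_s = NULL) {
  ch <- angle_channels(tree)
  if (is.null(time_s)) time_s <- (seq_along(postures) - 1) / 60
  rows <- lapply(seq_along(postures), function(i) {
    p <- postures[[i]]
    ang <- angles_from_posture(tree, p)
    re <- euler_zxy(p$root_rotation) * 180 / pi
    c(frame_index = i - 1L, time_s = time_s[i],
      stats::setNames(ang, ch$channel),
      root_euler_z_deg = re[1], root_euler_x_deg = re[2],
      root_euler_y_deg = re[3],
      root_px_m = p$root_position[1], root_py_m = p$root_position[2],
      root_pz_m = p$root_position[3])
  })
  df <- as.data.frame(do.call(rbind, rows))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_posture_csv
#' @export
read_posture_csv <- function(path, tree) {
  df <- utils::read.csv(path)
  ch <- angle_channels(tree)
  missing <- setdiff(ch$channel, names(df))
  if (length(missing)) {
    stop("posture CSV missing columns: ", paste(missing, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    rr <- rot_from_euler_zxy(df$root_euler_z_deg[i] * pi / 180,
                             df$root_euler_x_deg[i] * pi / 180,
                             df$root_euler_y_deg[i] * pi / 180)
    posture_from_angles(tree, as.numeric(df[i, ch$channel]),
                        root_rotation = rr,
                        root_position = c(df$root_px_m[i], df$root_py_m[i],
                                          df$root_pz_m[i]))
  })
}
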