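#' Ground-truth segment inertial parameters
#'
#' Masses `m_i` (kg), local CoM offsets `C_i` (meters, body frame) and
#' inter-joint displacements `d_i` (meters, parent frame) for every body of
#' a tree, plus the total mass `M = sum(m_i)`.
#'
#' @param mass Named numeric vector of segment masses (kg), one per body.
#' @param local_com Named list (or 3 x n matrix) of CoM offsets in each
#'   body's local frame.
#' @param displacement Named list (or 3 x n matrix) of joint displacements
#'   in the parent frame; the root entry is a nominal root position, usually
#'   zero (the posture's root position overrides it in all computations).
#' @param total_mass Total mass (kg); defaults to `sum(mass)` and must agree
#'   with it to 1e-9.
#' @return Object of class `segment_parameters`.
#' @export
segment_parameters <- function(mass, local_com, displacement,
                               total_mass = sum(mass)) {
  if (is.matrix(local_com)) local_com <- as_vec_list(local_com)
  if (is.matrix(displacement)) displacement <- as_vec_list(displacement)
  ids <- names(mass)
  if (is.null(ids)) stop("`mass` must be named by body id")
  if (any(mass <= 0)) stop("all segment masses must be > 0")
  if (abs(total_mass - sum(mass)) > 1e-9) {
    stop("total_mass must equal sum(mass) within 1e-9")
  }
  for (b in ids) {
    if (is.null(local_com[[b]])) stop("local_com missing for body ", b)
    if (is.null(displacement[[b]])) stop("displacement missing for body ", b)
  }
  structure(list(mass = mass,
                 local_com = lapply(local_com[ids], as.numeric),
                 displacement = lapply(displacement[ids], as.numeric),
                 total_mass = total_mass),
            class = "segment_parameters")
}

#' Whole-body CoM as the mass-weighted sum of segment CoMs
#'
#' The classical segmental CoM: each segment's local CoM offset is carried
#' to the global frame by the forward kinematics and the results are
#' averaged with mass weights. Used throughout as the ground-truth forward
#' model against which the serial-chain form is checked.
#'
#' @param tree A [kinematic_tree()].
#' @param params A [segment_parameters()].
#' @param posture A [posture_frame()].
#' @return Global CoM position, numeric 3-vector (meters).
#' @export
brute_force_com <- function(tree, params, posture) {
  missing <- setdiff(tree$ids, names(params$mass))
  if (length(missing)) {
    stop("parameters missing for bodies: ", paste(missing, collapse = ", "))
  }
  H <- forward_body_transforms(tree, posture, params$displacement)
  com <- c(0, 0, 0)
  for (b in tree$ids) {
    com <- com + params$mass[[b]] * apply_transform(H[[b]], params$local_com[[b]])
  }
  com / params$total_mass
}

#' Subtree mass
#' @param tree A [kinematic_tree()].
#' @param mass Named numeric vector of masses.
#' @param body Body id.
#' @return Sum of masses over `body` and all its descendants.
#' @export
subtree_mass <- function(tree, mass, body) {
  body <- as.character(body)
  m <- mass[[body]]
  for (ch in tree$children[[body]]) m <- m + subtree_mass(tree, mass, ch)
  m
}

#' The subject-specific serial-chain link vectors
#'
#' Reparameterizes the branched-chain CoM as the end-effector of a virtual
#' serial chain: `CoM = d_1 + sum_j Rpath(j) v_j`, where `Rpath(j)` is the
#' cumulative root-to-body rotation. Collecting coefficients of the expanded
#' weighted sum gives the closed form
#' `v_j = (m_j C_j + sum_{c in children(j)} M_subtree(c) d_c) / M`,
#' which is validated against [brute_force_com()] in the test suite.
#'
#' @inheritParams brute_force_com
#' @return Object of class `sesc_vector`: `body_order` (depth-first),
#'   `links` (named list of 3-vectors, meters) and `stacked` (3n-vector).
#' @export
sesc_vector_from_parameters <- function(tree, params) {
  links <- list()
  for (b in tree$order) {
    v <- params$mass[[b]] * params$local_com[[b]]
    for (ch in tree$children[[b]]) {
      v <- v + subtree_mass(tree, params$mass, ch) * params$displacement[[ch]]
    }
    links[[b]] <- v / params$total_mass
  }
  sesc_vector(links, tree$order)
}

#' Construct a SESC vector from link vectors
#' @param links Named list of 3-vectors (meters), one per body.
#' @param body_order Character vector giving the stacking order.
#' @return Object of class `sesc_vector`.
#' @export
sesc_vector <- function(links, body_order = names(links)) {
  missing <- setdiff(body_order, names(links))
  if (length(missing)) stop("links missing for bodies: ",
                            paste(missing, collapse = ", "))
  links <- lapply(links[body_order], as.numeric)
  structure(list(body_order = body_order, links = links,
                 stacked = as.numeric(unlist(links, use.names = FALSE))),
            class = "sesc_vector")
}

#' Rebuild a SESC vector from its stacked form
#' @param stacked Numeric 3n-vector.
#' @param body_order Character vector of n body ids.
#' @return Object of class `sesc_vector`.
#' @export
sesc_vector_from_stacked <- function(stacked, body_order) {
  n <- length(body_order)
  if (length(stacked) != 3L * n) stop("stacked length must be 3 * n_bodies")
  links <- lapply(seq_len(n), function(j) stacked[(3 * j - 2):(3 * j)])
  names(links) <- body_order
  sesc_vector(links, body_order)
}

#' Posture regressor of the serial-chain CoM model
#'
#' For a posture, the CoM is linear in `(d_1, V)`:
#' `CoM = [I | Rpath(1) | ... | Rpath(n)] [d_1; v_1; ...; v_n]`.
#' `full` is the 3 x (3 + 3n) matrix of that form; `horizontal` keeps only
#' the AP (x) and ML (y) rows of the 3 x 3n rotation part, which is what the
#' CoP can observe.
#'
#' @inheritParams path_rotation
#' @return Object of class `regressor_row` with elements `full`,
#'   `horizontal` and `body_order`.
#' @export
build_regressor_row <- function(tree, posture) {
  n <- tree$n_bodies
  R <- matrix(0, 3, 3 * n)
  for (j in seq_along(tree$order)) {
    R[, (3 * j - 2):(3 * j)] <- path_rotation(tree, posture, tree$order[j])
  }
  structure(list(full = cbind(diag(3), R),
                 horizontal = R[1:2, , drop = FALSE],
                 body_order = tree$order),
            class = "regressor_row")
}

#' Serial-chain CoM prediction
#'
#' `CoM = d_1 + sum_j Rpath(j) v_j`, evaluated from a precomputed regressor
#' row. Once the link vectors are identified, this gives the full 3-D CoM
#' from joint angles alone.
#'
#' @param row A [build_regressor_row()] result.
#' @param d1 Root position, numeric 3-vector (meters).
#' @param V A [sesc_vector()] (its `body_order` must match the row's).
#' @return Global CoM position, numeric 3-vector (meters).
#' @export
estimate_com <- function(row, d1, V) {
  if (!identical(row$body_order, V$body_order)) {
    stop("regressor row and SESC vector use different body orders")
  }
  if (ncol(row$full) != 3L + length(V$stacked)) {
    stop("dimension mismatch between regressor row and SESC vector")
  }
  as.numeric(row$full %*% c(as.numeric(d1), V$stacked))
}

#' Write / read a SESC vector as JSON
#'
#' Format: `{"body_order": [...], "v": [[x,y,z], ...], "units": "m"}`.
#'
#' @param V A [sesc_vector()].
#' @param path File path.
#' @return `read_sesc_json` returns a [sesc_vector()].
#' @export
write_sesc_json <- function(V, path) {
  jsonlite::write_json(
    list(body_order = V$body_order,
         v = lapply(unname(V$links), as.numeric),
         units = "m"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sesc_json
#' @export
read_sesc_json <- function(path) {
  obj <- jsonlite::read_json(path)
  order <- as.character(unlist(obj$body_order))
  links <- lapply(obj$v, function(v) as.numeric(unlist(v)))
  names(links) <- order
  sesc_vector(links, order)
}
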