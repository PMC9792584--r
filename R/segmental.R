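#' Anthropometric table for segmental analysis
#'
#' A table-driven description of how to place segment masses and CoMs from
#' body measurements: per body, the fraction of total body mass, the CoM
#' position as a ratio of segment length along a declared longitudinal axis
#' (unit vector in the body frame), and — for non-root bodies — the joint
#' placement as a direction (unit vector in the parent frame) and a scale
#' relative to the parent's segment length. The displacement entries let a
#' table place branched joints (e.g. the two hips) exactly, which a single
#' per-segment length cannot.
#'
#' @param mass_fraction Named numeric vector, fractions of total body mass
#'   (must sum to 1 within 1e-6).
#' @param com_ratio Named numeric vector in `[0, 1]`: CoM position along the
#'   segment axis as a fraction of segment length.
#' @param com_axis Named list of unit 3-vectors (body frame).
#' @param d_scale Named numeric vector (non-root bodies): joint displacement
#'   magnitude as a multiple of the parent's segment length.
#' @param d_axis Named list of unit 3-vectors (parent frame).
#' @param source_label Character provenance label.
#' @return Object of class `anthropometric_table`.
#' @export
anthropometric_table <- function(mass_fraction, com_ratio, com_axis,
                                 d_scale, d_axis,
                                 source_label = "unlabeled") {
  ids <- names(mass_fraction)
  if (is.null(ids)) stop("mass_fraction must be named by body id")
  if (abs(sum(mass_fraction) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 within 1e-6")
  }
  if (any(mass_fraction < 0) || any(mass_fraction > 1)) {
    stop("mass fractions must lie in [0, 1]")
  }
  if (any(com_ratio < 0 - 1e-12) || any(com_ratio > 1 + 1e-12)) {
    stop("com_ratio entries must lie in [0, 1]")
  }
  for (b in ids) {
    if (is.null(com_axis[[b]])) stop("com_axis missing for body ", b)
    check_unit_axis(com_axis[[b]], tol = 1e-6)
  }
  for (b in names(d_scale)) check_unit_axis(d_axis[[b]], tol = 1e-6)
  structure(list(mass_fraction = mass_fraction,
                 com_ratio = com_ratio[ids],
                 com_axis = lapply(com_axis[ids], as.numeric),
                 d_scale = d_scale,
                 d_axis = lapply(d_axis[names(d_scale)], as.numeric),
                 source_label = source_label),
            class = "anthropometric_table")
}

#' Subject body measurements for segmental analysis
#'
#' @param total_mass Total body mass, kg.
#' @param segment_length Named numeric vector of segment lengths, meters.
#' @return Object of class `subject_measurements`.
#' @export
subject_measurements <- function(total_mass, segment_length) {
  if (total_mass <= 0) stop("total_mass must be > 0")
  if (any(segment_length <= 0)) stop("all segment lengths must be > 0")
  structure(list(total_mass = total_mass, segment_length = segment_length),
            class = "subject_measurements")
}

#' Segment parameters implied by an anthropometric table
#'
#' Scales the table to a subject: `m_i = fraction_i * M`,
#' `C_i = com_ratio_i * length_i * com_axis_i`, and for non-root bodies
#' `d_i = d_scale_i * length_parent(i) * d_axis_i`. The root displacement is
#' zero (the posture's root position is used at evaluation time).
#'
#' @param tree A [kinematic_tree()].
#' @param table An [anthropometric_table()].
#' @param meas A [subject_measurements()].
#' @return A [segment_parameters()].
#' @export
params_from_table <- function(tree, table, meas) {
  missing <- setdiff(tree$ids, names(table$mass_fraction))
  if (length(missing)) {
    stop("table missing bodies: ", paste(missing, collapse = ", "))
  }
  missing <- setdiff(tree$ids, names(meas$segment_length))
  if (length(missing)) {
    stop("measurements missing bodies: ", paste(missing, collapse = ", "))
  }
  mass <- table$mass_fraction[tree$ids] * meas$total_mass
  local_com <- lapply(tree$ids, function(b) {
    table$com_ratio[[b]] * meas$segment_length[[b]] * table$com_axis[[b]]
  })
  names(local_com) <- tree$ids
  displacement <- list()
  for (b in tree$ids) {
    if (b == tree$root) {
      displacement[[b]] <- c(0, 0, 0)
    } else {
      if (is.null(table$d_axis[[b]]) || is.na(table$d_scale[b])) {
        stop("table missing displacement entry for body ", b)
      }
      p <- as.character(tree$parent[[b]])
      displacement[[b]] <- table$d_scale[[b]] * meas$segment_length[[p]] *
        table$d_axis[[b]]
    }
  }
  segment_parameters(mass, local_com, displacement)
}

#' Encode exact segment parameters as an anthropometric table
#'
#' The inverse of [params_from_table()]: given ground-truth parameters and
#' the subject's segment lengths, build the table that reproduces them
#' exactly. Used to construct calibrated (or deliberately mis-calibrated)
#' comparator tables in simulations.
#'
#' @param tree A [kinematic_tree()].
#' @param params A [segment_parameters()].
#' @param meas A [subject_measurements()].
#' @param source_label Provenance label for the table.
#' @return An [anthropometric_table()].
#' @export
table_from_parameters <- function(tree, params, meas,
                                  source_label = "derived from parameters") {
  fraction <- params$mass[tree$ids] / params$total_mass
  com_ratio <- numeric(0)
  com_axis <- list()
  for (b in tree$ids) {
    C <- params$local_com[[b]]
    len <- vnorm(C)
    if (len < 1e-12) {
      com_ratio[b] <- 0
      com_axis[[b]] <- c(0, 0, 1)
    } else {
      com_ratio[b] <- len / meas$segment_length[[b]]
      com_axis[[b]] <- C / len
    }
  }
  d_scale <- numeric(0)
  d_axis <- list()
  for (b in setdiff(tree$ids, tree$root)) {
    d <- params$displacement[[b]]
    p <- as.character(tree$parent[[b]])
    len <- vnorm(d)
    if (len < 1e-12) {
      d_scale[b] <- 0
      d_axis[[b]] <- c(0, 0, 1)
    } else {
      d_scale[b] <- len / meas$segment_length[[p]]
      d_axis[[b]] <- d / len
    }
  }
  anthropometric_table(fraction, com_ratio, com_axis, d_scale, d_axis,
                       source_label)
}

#' Segmental-analysis CoM estimate
#'
#' The comparator method: place segment masses and CoMs from an
#' anthropometric table scaled to the subject's measurements, then take the
#' mass-weighted sum ([brute_force_com()]). Its accuracy is limited by how
#' well the table matches the subject's true mass distribution — the point
#' the serial-chain identification is designed to overcome.
#'
#' @inheritParams params_from_table
#' @param posture A [posture_frame()].
#' @return Global CoM position, numeric 3-vector (meters).
#' @export
segmental_com <- function(tree, table, meas, posture) {
  brute_force_com(tree, params_from_table(tree, table, meas), posture)
}

#' Write / read an anthropometric table as JSON
#'
#' Format: `{"source_label", "segments": [{"id", "mass_fraction",
#' "com_ratio", "axis", "d_scale", "d_axis"}]}`.
#'
#' @param table An [anthropometric_table()].
#' @param path File path.
#' @return `read_table_json` returns an [anthropometric_table()].
#' @export
write_table_json <- function(table, path) {
  segments <- lapply(names(table$mass_fraction), function(b) {
    entry <- list(id = b,
                  mass_fraction = table$mass_fraction[[b]],
                  com_ratio = table$com_ratio[[b]],
                  axis = table$com_axis[[b]])
    if (!is.null(table$d_axis[[b]])) {
      entry$d_scale <- table$d_scale[[b]]
      entry$d_axis <- table$d_axis[[b]]
    }
    entry
  })
  jsonlite::write_json(list(source_label = table$source_label,
                            segments = segments),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_table_json
#' @export
read_table_json <- function(path) {
  obj <- jsonlite::read_json(path)
  ids <- vapply(obj$segments, function(s) as.character(s$id), "")
  mf <- stats::setNames(vapply(obj$segments, function(s) s$mass_fraction, 1), ids)
  cr <- stats::setNames(vapply(obj$segments, function(s) s$com_ratio, 1), ids)
  ca <- stats::setNames(lapply(obj$segments, function(s) unlist(s$axis)), ids)
  ds <- numeric(0)
  da <- list()
  for (s in obj$segments) {
    if (!is.null(s$d_scale)) {
      ds[as.character(s$id)] <- s$d_scale
      da[[as.character(s$id)]] <- unlist(s$d_axis)
    }
  }
  anthropometric_table(mf, cr, ca, ds, da, obj$source_label)
}
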