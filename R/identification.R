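#' One static observation: a posture and its CoP reading
#'
#' During static equilibrium the CoP recorded by a force platform is the
#' ground projection of the CoM, so each held posture contributes two scalar
#' equations (AP and ML) to the identification of the serial-chain link
#' vectors.
#'
#' @param posture A [posture_frame()].
#' @param cop Numeric 2-vector `(AP, ML)` in meters.
#' @return Object of class `static_observation`.
#' @export
static_observation <- function(posture, cop) {
  cop <- as.numeric(cop)
  if (length(cop) != 2L || !all(is.finite(cop))) {
    stop("cop must be a finite 2-vector (AP, ML) in meters")
  }
  structure(list(posture = posture, cop = cop), class = "static_observation")
}

#' Minimum number of static postures for identification
#'
#' The stacked horizontal system has `3n` unknowns and each posture supplies
#' two equations, so at least `m = ceil(3n/2)` distinct postures are needed
#' for the design matrix to have more rows than columns.
#'
#' @param n_bodies Number of bodies in the model.
#' @return Smallest integer `m` with `2m >= 3 * n_bodies`.
#' @export
minimum_postures <- function(n_bodies) {
  if (n_bodies < 1) stop("n_bodies must be >= 1")
  as.integer(ceiling(3 * n_bodies / 2))
}

#' Stack static observations into the least-squares system
#'
#' Each observation contributes the AP and ML rows of its regressor and the
#' right-hand side `CoP - d_1` restricted to the horizontal axes. The
#' returned system solves `A %*% V = b` for the stacked link vector.
#'
#' @param tree A [kinematic_tree()].
#' @param observations List of [static_observation()]s.
#' @return List with `A` (2m x 3n matrix), `b` (length-2m vector),
#'   `body_order` and `n_obs`; class `sesc_system`.
#' @export
stack_system <- function(tree, observations) {
  m <- length(observations)
  if (m < 1L) stop("need at least one observation")
  n <- tree$n_bodies
  A <- matrix(0, 2 * m, 3 * n)
  b <- numeric(2 * m)
  for (k in seq_len(m)) {
    obs <- observations[[k]]
    row <- build_regressor_row(tree, obs$posture)
    A[(2 * k - 1):(2 * k), ] <- row$horizontal
    b[(2 * k - 1):(2 * k)] <- obs$cop - obs$posture$root_position[1:2]
  }
  structure(list(A = A, b = b, body_order = tree$order, n_obs = m),
            class = "sesc_system")
}

# Minimum-norm least-squares solve via SVD with a relative singular-value
# cutoff; returns solution plus rank/conditioning diagnostics.
pinv_solve <- function(A, b, rel_tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > rel_tol * max(sv$d)
  rank <- sum(keep)
  x <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  cond <- if (min(sv$d) > 0) max(sv$d) / min(sv$d) else Inf
  list(x = as.numeric(x), rank = rank, condition_number = cond,
       singular_values = sv$d)
}

#' Identify the subject-specific SESC vector by pseudoinverse
#'
#' Solves the stacked horizontal system in the minimum-norm least-squares
#' sense (Moore-Penrose pseudoinverse, computed by SVD with a relative
#' singular-value cutoff). A rank-deficient design — e.g. repeated postures —
#' raises a warning, not an error, and the minimum-norm solution is still
#' returned.
#'
#' @param system A [stack_system()] result.
#' @param min_m Minimum number of postures required; defaults to
#'   `ceil(3n/2)` for the system's model size.
#' @param rel_tol Relative singular-value cutoff for the pseudoinverse.
#' @return Object of class `identification_result`: `V` ([sesc_vector()]),
#'   `n_postures_used`, `rank`, `condition_number`, `residual_rms` (meters)
#'   and `singular_values`.
#' @export
identify_sesc <- function(system, min_m = NULL, rel_tol = 1e-10) {
  n3 <- ncol(system$A)
  if (is.null(min_m)) min_m <- minimum_postures(n3 / 3)
  if (system$n_obs < min_m) {
    stop("insufficient postures: ", system$n_obs, " observed, ", min_m,
         " required")
  }
  sol <- pinv_solve(system$A, system$b, rel_tol)
  if (sol$rank < n3) {
    warning("rank-deficient identification: rank ", sol$rank, " < ", n3,
            "; returning the minimum-norm solution")
  }
  resid <- system$A %*% sol$x - system$b
  structure(list(V = sesc_vector_from_stacked(sol$x, system$body_order),
                 n_postures_used = system$n_obs,
                 rank = sol$rank,
                 condition_number = sol$condition_number,
                 residual_rms = sqrt(mean(resid^2)),
                 singular_values = sol$singular_values),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat("SESC identification:", x$n_postures_used, "postures, rank", x$rank,
      "/", length(x$V$stacked), "\n")
  cat(sprintf("  condition number %.3g, residual RMS %.3g m\n",
              x$condition_number, x$residual_rms))
  invisible(x)
}

#' Split observations into identification and evaluation sets
#'
#' Disjoint, exhaustive partition of the recorded postures; by default 75%
#' go to identification and 25% to evaluation. The identification-set size
#' is `round(fraction * m)` with halves rounded away from zero, and the
#' split is reproducible under a fixed seed.
#'
#' @param observations List (typically of [static_observation()]s).
#' @param fraction_identify Fraction assigned to identification, in (0, 1).
#' @param seed Integer seed making the random split reproducible.
#' @param method `"random"` (default) or `"sequential"` (first block
#'   identifies).
#' @param min_identify Minimum allowed identification-set size (e.g.
#'   [minimum_postures()] of the model); violation is an error.
#' @return List with `identify` and `evaluate` (sublists), `identify_idx`,
#'   `evaluate_idx`, `seed` and `method`.
#' @export
split_postures <- function(observations, fraction_identify = 0.75, seed = 1L,
                           method = c("random", "sequential"),
                           min_identify = 0L) {
  method <- match.arg(method)
  m <- length(observations)
  if (m < 1L) stop("empty observation list")
  if (fraction_identify <= 0 || fraction_identify >= 1) {
    stop("fraction_identify must be in (0, 1)")
  }
  n_id <- as.integer(floor(fraction_identify * m + 0.5))  # half away from zero
  n_id <- max(1L, min(m - 1L, n_id))
  if (n_id < min_identify) {
    stop("insufficient postures: identification set of ", n_id,
         " is below the required ", min_identify)
  }
  idx <- if (method == "random") {
    sort(with_seed(seed, sample.int(m, n_id)))
  } else {
    seq_len(n_id)
  }
  list(identify = observations[idx],
       evaluate = observations[setdiff(seq_len(m), idx)],
       identify_idx = idx,
       evaluate_idx = setdiff(seq_len(m), idx),
       seed = seed, method = method)
}

#' Predict horizontal (or full) CoM for a set of postures
#'
#' @param tree A [kinematic_tree()].
#' @param V A [sesc_vector()].
#' @param postures List of [posture_frame()]s.
#' @return Matrix (length(postures) x 3) of CoM predictions in meters.
#' @export
predict_com <- function(tree, V, postures) {
  out <- t(vapply(postures, function(p) {
    estimate_com(build_regressor_row(tree, p), p$root_position, V)
  }, numeric(3)))
  colnames(out) <- c("ap", "ml", "vert")
  out
}
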