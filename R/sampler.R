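# Metropolis sampling of confined worm-like chains.
#
# All moves are rigid rotations of contiguous locus ranges, so rod lengths
# are preserved exactly and tethered loci stay on the nuclear surface by
# construction (only norm-preserving rotations ever touch them).

rotate_about <- function(points, anchor, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  cth <- cos(angle); sth <- sin(angle)
  v <- sweep(points, 2, anchor)
  dotu <- drop(v %*% u)
  crossu <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
                  u[3] * v[, 1] - u[1] * v[, 3],
                  u[1] * v[, 2] - u[2] * v[, 1])
  out <- v * cth + crossu * sth + outer(dotu * (1 - cth), u)
  sweep(out, 2, anchor, "+")
}

#' Crankshaft move
#'
#' Rotates the loci strictly between `i` and `j` about the axis through
#' positions `i` and `j`. Endpoints (and everything outside the segment) are
#' unmoved; rod lengths are preserved exactly.
#'
#' @param conf A `conformation` matrix.
#' @param i,j Locus indices (1-based) with `j - i >= 2`.
#' @param angle Rotation angle in radians.
#' @return The proposed `conformation`, or `NULL` when the axis is degenerate
#'   (coincident endpoint positions), in which case the move is a rejected
#'   no-op.
#' @export
crankshaft_move <- function(conf, i, j, angle) {
  N <- nrow(conf)
  if (!(i >= 1 && j <= N && j - i >= 2)) stop("need 1 <= i < j <= N, j - i >= 2")
  axis <- conf[j, ] - conf[i, ]
  if (sqrt(sum(axis^2)) < 1e-9) return(NULL)
  sel <- (i + 1):(j - 1)
  conf[sel, ] <- rotate_about(conf[sel, , drop = FALSE], conf[i, ], axis, angle)
  conf
}

#' Pivot move
#'
#' Rotates all loci on one side of locus `i` about an arbitrary axis through
#' position `i`. Only valid when the rotated side contains no tethered locus.
#'
#' @param conf A `conformation` matrix.
#' @param i Pivot locus (1-based).
#' @param angle Rotation angle in radians.
#' @param side `"right"` rotates loci `i+1 .. N`, `"left"` rotates `1 .. i-1`.
#' @param axis Unit 3-vector; a random axis is drawn when `NULL`.
#' @return The proposed `conformation`.
#' @export
pivot_move <- function(conf, i, angle, side = c("right", "left"), axis = NULL) {
  side <- match.arg(side)
  N <- nrow(conf)
  if (is.null(axis)) axis <- rand_unit()
  sel <- if (side == "right") seq_len(N) > i else seq_len(N) < i
  if (!any(sel)) return(conf)
  conf[sel, ] <- rotate_about(conf[sel, , drop = FALSE], conf[i, ], axis, angle)
  conf
}

#' Arm rotation move
#'
#' Rotates all loci on one side of locus `i` about the axis through the
#' nucleus centre and position `i`. Every rotated locus keeps its distance
#' from the centre, and the rod crossing the pivot is preserved, so the move
#' respects confinement and on-sphere tethers exactly. This is the move that
#' lets the two telomeres of a doubly tethered chain change their relative
#' position on the sphere.
#'
#' @inheritParams pivot_move
#' @return The proposed `conformation`, or `NULL` when position `i` coincides
#'   with the centre (degenerate axis).
#' @export
arm_rotation_move <- function(conf, i, angle, side = c("right", "left")) {
  side <- match.arg(side)
  N <- nrow(conf)
  axis <- conf[i, ]
  if (sqrt(sum(axis^2)) < 1e-9) return(NULL)
  sel <- if (side == "right") seq_len(N) > i else seq_len(N) < i
  if (!any(sel)) return(conf)
  conf[sel, ] <- rotate_about(conf[sel, , drop = FALSE], c(0, 0, 0), axis, angle)
  conf
}

#' Rigid rotation move
#'
#' Rotates the whole conformation about an axis through the nucleus centre.
#' Preserves every norm (hence confinement and tethering) and all internal
#' geometry; only the clustering energy can change.
#'
#' @param conf A `conformation` matrix.
#' @param axis Unit 3-vector through the origin.
#' @param angle Rotation angle in radians.
#' @return The proposed `conformation`.
#' @export
rigid_rotation_move <- function(conf, axis, angle) {
  conf[] <- rotate_about(unclass(conf), c(0, 0, 0), axis, angle)
  conf
}

#' Sampling schedule
#'
#' @param n_total Total attempted Metropolis steps (one "sample" = one
#'   attempted step).
#' @param n_burn_in Discarded prefix (< `n_total`).
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param move_mix Probabilities over the move classes `crankshaft`, `pivot`,
#'   `arm_rotation`, `rigid_rotation`. `NULL` resolves a tether-mode-specific
#'   default at run time: untethered 0.70/0.15/0/0.15, centromere-tethered
#'   0.55/0.30/0/0.15 (pivots restricted to centromere-free sides),
#'   telomere-tethered 0.70/0/0.15/0.15 (pivot weight reassigned, as both
#'   ends are tethered).
#' @param max_step_angle Initial proposal amplitude in radians (in (0, pi]).
#' @param adapt Auto-tune amplitudes during burn-in only, targeting 30-50%
#'   acceptance per move class; frozen afterwards to preserve stationarity.
#' @return An object of class `sampler_schedule`.
#' @export
sampler_schedule <- function(n_total, n_burn_in, thin = 40, seed = 1,
                             move_mix = NULL, max_step_angle = pi / 2,
                             adapt = TRUE) {
  if (n_burn_in >= n_total) stop("n_burn_in must be smaller than n_total")
  if (thin < 1) stop("thin must be >= 1")
  if (max_step_angle <= 0 || max_step_angle > pi)
    stop("max_step_angle must lie in (0, pi]")
  if (!is.null(move_mix)) {
    if (length(move_mix) != 4 || any(move_mix < 0) ||
        abs(sum(move_mix) - 1) > 1e-8)
      stop("move_mix must be 4 non-negative probabilities summing to 1")
  }
  structure(list(n_total = n_total, n_burn_in = n_burn_in, thin = thin,
                 seed = as.integer(seed), move_mix = move_mix,
                 max_step_angle = max_step_angle, adapt = isTRUE(adapt)),
            class = "sampler_schedule")
}

resolve_move_mix <- function(mode) {
  switch(mode,
         none = c(0.70, 0.15, 0.00, 0.15),
         centromere = c(0.55, 0.30, 0.00, 0.15),
         telomeres = c(0.70, 0.00, 0.15, 0.15))
}

# Metropolis acceptance decision; consumes one uniform draw on the boundary
# cases only when needed.
metropolis_accept <- function(delta_e, beta = 1) {
  if (is.nan(delta_e)) return(FALSE)
  if (delta_e <= 0) return(TRUE)
  if (!is.finite(delta_e)) return(FALSE)
  stats::runif(1) < exp(-beta * delta_e)
}

#' Single Metropolis step (reference implementation)
#'
#' Draws one move from the schedule's move mix, evaluates the full energy
#' difference with the R energy functions and applies the Metropolis
#' acceptance rule. This is the plain reference path used for small-system
#' validation; production sampling uses [run_chain()], whose compiled
#' incremental energies are cross-checked against this full recomputation.
#'
#' @param conf A feasible `conformation`.
#' @param model An [energy_model()].
#' @param schedule A [sampler_schedule()].
#' @return A list with the (possibly unchanged) `conformation` and an
#'   `accepted` flag.
#' @export
metropolis_step <- function(conf, model, schedule) {
  N <- nrow(conf)
  mode <- model$tether$mode
  mix <- schedule$move_mix
  if (is.null(mix)) mix <- resolve_move_mix(mode)
  type <- sample.int(4, 1, prob = mix)
  amp <- schedule$max_step_angle
  angle <- stats::runif(1, -amp, amp)
  cen <- model$spec$centromere_index
  pick <- function(v) v[sample.int(length(v), 1)] # length-1 safe

  proposal <- switch(type,
    { # crankshaft: segment not strictly containing a tethered interior locus
      lims <- if (mode == "centromere") {
        if (stats::runif(1) < (cen - 1) / max(N - 2, 1)) c(1, cen) else c(cen, N)
      } else c(1, N)
      if (lims[2] - lims[1] < 2) NULL
      else {
        i <- pick(seq(lims[1], lims[2] - 2))
        j <- pick(seq(i + 2, lims[2]))
        crankshaft_move(conf, i, j, angle)
      }
    },
    { # pivot: rotated side must be free of tethered loci
      if (mode == "telomeres") NULL
      else if (mode == "centromere") {
        if (stats::runif(1) < 0.5 && cen < N - 1) {
          i <- pick(seq(cen, N - 1))
          pivot_move(conf, i, angle, "right")
        } else if (cen > 2) {
          i <- pick(seq(2, cen))
          pivot_move(conf, i, angle, "left")
        } else NULL
      } else {
        i <- pick(seq_len(N - 1))
        pivot_move(conf, i, angle, "right")
      }
    },
    { # arm rotation
      i <- pick(seq(2, N - 1))
      arm_rotation_move(conf, i, angle,
                        if (stats::runif(1) < 0.5) "right" else "left")
    },
    rigid_rotation_move(conf, rand_unit(), angle))

  if (is.null(proposal)) return(list(conformation = conf, accepted = FALSE))
  delta <- total_energy(proposal, model)$total_kT -
    total_energy(conf, model)$total_kT
  if (metropolis_accept(delta, model$beta))
    list(conformation = proposal, accepted = TRUE)
  else
    list(conformation = conf, accepted = FALSE)
}

#' Run a Markov chain and collect the retained ensemble
#'
#' Metropolis MCMC over conformations under the Boltzmann distribution of the
#' model's energy, using constraint-preserving rotation moves (see
#' [sampler_schedule()] for the move mix). The first `n_burn_in` attempted
#' steps are discarded and the remainder thinned by `thin`. Runs are
#' deterministic given `schedule$seed`.
#'
#' @param model An [energy_model()].
#' @param schedule A [sampler_schedule()].
#' @param init Optional starting `conformation`; a fresh feasible one is grown
#'   when `NULL`.
#' @return An object of class `wlc_ensemble`: retained positions as an
#'   `n_loci x 3 x retained_count` array (nm), provenance copies of spec,
#'   model and schedule, the retained count, and the post-burn-in acceptance
#'   rate.
#' @examples
#' \donttest{
#' chrI <- chromosome_spec(240000, 151000)
#' m <- energy_model(chrI, persistence_nm = 200)
#' ens <- run_chain(m, sampler_schedule(20000, 6000, thin = 40, seed = 1))
#' ens$retained_count
#' }
#' @export
run_chain <- function(model, schedule, init = NULL) {
  stopifnot(inherits(model, "energy_model"),
            inherits(schedule, "sampler_schedule"))
  set.seed(schedule$seed)
  if (is.null(init)) init <- initialize_conformation(model)
  mix <- schedule$move_mix
  if (is.null(mix)) mix <- resolve_move_mix(model$tether$mode)
  amp <- rep(schedule$max_step_angle, 4)
  res <- .run_chain_cpp(unclass(init), model_for_cpp(model),
                        schedule$n_total, schedule$n_burn_in, schedule$thin,
                        mix, amp, schedule$adapt)
  structure(list(
    positions = res$samples,
    spec = model$spec,
    model = model,
    schedule = schedule,
    retained_count = as.integer(res$retained_count),
    acceptance_rate = res$acceptance_rate,
    step_angles = res$step_angles,
    final_conformation = as_conformation(res$final_positions)
  ), class = "wlc_ensemble")
}

#' @export
print.wlc_ensemble <- function(x, ...) {
  cat(sprintf(
    "<wlc_ensemble> %s, %s tether (nu %g), l_p %g nm: %d retained samples (acceptance %.2f)\n",
    x$spec$name, x$model$tether$mode, x$model$tether$nu, x$model$persistence_nm,
    x$retained_count, x$acceptance_rate))
  invisible(x)
}

#' Extract one retained conformation from an ensemble
#'
#' @param ensemble A `wlc_ensemble`.
#' @param k Retained-sample index (1-based).
#' @return A `conformation` matrix.
#' @export
ensemble_conformation <- function(ensemble, k) {
  if (k < 1 || k > ensemble$retained_count) stop("sample index out of range")
  as_conformation(ensemble$positions[, , k])
}
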