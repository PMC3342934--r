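#' Bending energy of a conformation
#'
#' Discrete worm-like-chain bending energy
#' `g*beta * sum_j (1 - t_j . t_{j+1})` over consecutive unit rod vectors.
#' Zero iff the chain is straight.
#'
#' @param conf A `conformation` matrix (n_loci x 3, nm).
#' @param model An [energy_model()].
#' @return Scalar energy in kT (>= 0).
#' @export
bending_energy <- function(conf, model) {
  if (nrow(conf) != model$spec$n_loci)
    stop("locus count of conformation does not match the model's spec")
  rods <- diff(conf)
  rods <- rods / sqrt(rowSums(rods^2))
  n <- nrow(rods)
  if (n < 2) return(0)
  cosines <- rowSums(rods[-n, , drop = FALSE] * rods[-1, , drop = FALSE])
  model$bending_modulus_kT * sum(1 - cosines)
}

#' Confinement energy (hard-core sphere)
#'
#' Returns 0 when every locus lies inside (or on) the nuclear sphere and
#' `Inf` otherwise. The boundary is allowed -- tethered loci live there. A
#' numerical allowance of 1e-6 nm absorbs rounding on surface loci.
#'
#' @param conf A `conformation` matrix.
#' @param geometry A [nuclear_geometry()].
#' @return 0 or `Inf` (the infeasibility sentinel).
#' @export
confinement_energy <- function(conf, geometry) {
  R <- geometry$radius_nm
  if (all(rowSums(conf^2) <= (R + 1e-6)^2)) 0 else Inf
}

#' Clustering energy of tethered loci
#'
#' von Mises-Fisher potential pulling tethered loci toward the mean direction:
#' `-nu * (mu . x_hat)` for the centromere, or the sum of two such independent
#' terms for the telomeres. The vMF normalising constants are omitted: `nu`
#' is fixed within a run so they cancel in every Metropolis ratio (add them
#' back when absolute log-densities are required).
#'
#' @param conf A `conformation` matrix.
#' @param model An [energy_model()] with tether mode `"centromere"` or
#'   `"telomeres"`.
#' @return Scalar energy in kT (in `[-nu, nu]` per tethered locus).
#' @export
clustering_energy <- function(conf, model) {
  tether <- model$tether
  if (tether$mode == "none")
    stop("clustering_energy is undefined for tether mode 'none'")
  if (tether$nu == 0) return(0)
  term <- function(i) {
    x <- conf[i, ]
    -tether$nu * sum(tether$mu * x) / sqrt(sum(x^2))
  }
  if (tether$mode == "centromere") term(model$spec$centromere_index)
  else term(1) + term(model$spec$n_loci)
}

#' Intrachromosomal excluded-volume energy
#'
#' Optional hard-sphere check between loci of the same chromosome: `Inf` if
#' any pair of loci further apart than the adjacency window along the contour
#' approaches within `ev_min_dist_nm`, else 0. Pairs with
#' `|i - j| <= ceiling(ev_min_dist_nm / bond)` are exempt, because contour
#' neighbours necessarily violate the hard sphere whenever rods are shorter
#' than the hard-sphere distance.
#'
#' @param conf A `conformation` matrix.
#' @param model An [energy_model()]; returns 0 unless
#'   `model$excluded_volume` is `TRUE`.
#' @return 0 or `Inf`.
#' @export
excluded_volume_energy <- function(conf, model) {
  if (!isTRUE(model$excluded_volume)) return(0)
  N <- nrow(conf)
  w <- ceiling(model$ev_min_dist_nm / model$spec$bond_length_nm)
  d <- as.matrix(stats::dist(conf))
  idx <- abs(row(d) - col(d)) > w
  if (any(d[idx] < model$ev_min_dist_nm)) Inf else 0
}

#' Total energy with per-term breakdown
#'
#' @param conf A `conformation` matrix.
#' @param model An [energy_model()].
#' @return A list of class `energy_breakdown` with `bending_kT`,
#'   `confinement_kT`, `clustering_kT`, `excluded_volume_kT` and `total_kT`.
#'   Confinement and excluded-volume terms are exactly 0 or `Inf`.
#' @export
total_energy <- function(conf, model) {
  bend <- bending_energy(conf, model)
  confn <- confinement_energy(conf, model$geometry)
  clus <- if (model$tether$mode == "none") 0 else clustering_energy(conf, model)
  ev <- excluded_volume_energy(conf, model)
  structure(list(
    bending_kT = bend,
    confinement_kT = confn,
    clustering_kT = clus,
    excluded_volume_kT = ev,
    total_kT = bend + confn + clus + ev
  ), class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(
    "<energy_breakdown> total %g kT (bend %.4g, confine %g, cluster %.4g, ev %g)\n",
    x$total_kT, x$bending_kT, x$confinement_kT, x$clustering_kT,
    x$excluded_volume_kT))
  invisible(x)
}
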