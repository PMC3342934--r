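#' Build a discretised chromosome specification
#'
#' Maps a genomic length onto a discretised chromatin fibre. The chromosome is
#' treated as a 30-nm-fibre worm-like chain whose contour length is the dsDNA
#' length (`length_bp * rise_nm_per_bp`) divided by the fibre compaction
#' factor, discretised into `n_loci` loci joined by `n_loci - 1` inextensible
#' rods of equal length.
#'
#' @param length_bp Genomic length in base pairs (> 0).
#' @param centromere_bp Genomic position of the centromere in base pairs
#'   (between 0 and `length_bp`).
#' @param n_loci Number of loci in the discretisation (>= 2); 300 matches the
#'   production discretisation, at which the discrete chain closely
#'   approximates the continuous worm-like chain.
#' @param compaction_factor Dimensionless contour compression of the fibre
#'   relative to dsDNA (default 40, appropriate for the 30-nm fibre).
#' @param rise_nm_per_bp Helical rise of B-form dsDNA in nm per base pair
#'   (default 0.34).
#' @param name Optional chromosome label.
#'
#' @return An object of class `chromosome_spec` with derived fields
#'   `contour_length_nm`, `bond_length_nm` and `centromere_index` (1-based
#'   locus index of the centromere).
#' @examples
#' chrI <- chromosome_spec(240000, 151000, name = "chrI")
#' chrI$contour_length_nm  # 2040 nm
#' @export
chromosome_spec <- function(length_bp, centromere_bp, n_loci = 300,
                            compaction_factor = 40, rise_nm_per_bp = 0.34,
                            name = "chromosome") {
  if (!is.numeric(length_bp) || length(length_bp) != 1 || length_bp <= 0)
    stop("length_bp must be a single positive number")
  if (!is.numeric(centromere_bp) || length(centromere_bp) != 1 ||
      centromere_bp < 0 || centromere_bp > length_bp)
    stop("centromere_bp must lie within [0, length_bp]")
  if (!is.numeric(n_loci) || length(n_loci) != 1 || n_loci < 2 ||
      n_loci != round(n_loci))
    stop("n_loci must be an integer >= 2")
  if (compaction_factor <= 0) stop("compaction_factor must be positive")
  if (rise_nm_per_bp <= 0) stop("rise_nm_per_bp must be positive")
  n_loci <- as.integer(n_loci)
  contour <- length_bp * rise_nm_per_bp / compaction_factor
  bond <- contour / (n_loci - 1)
  cen_idx <- as.integer(round(centromere_bp / length_bp * (n_loci - 1))) + 1L
  structure(list(
    name = name,
    length_bp = length_bp,
    centromere_bp = centromere_bp,
    compaction_factor = compaction_factor,
    rise_nm_per_bp = rise_nm_per_bp,
    n_loci = n_loci,
    contour_length_nm = contour,
    bond_length_nm = bond,
    centromere_index = cen_idx
  ), class = "chromosome_spec")
}

#' @export
print.chromosome_spec <- function(x, ...) {
  cat(sprintf("<chromosome_spec> %s: %g bp, %d loci\n", x$name, x$length_bp,
              x$n_loci))
  cat(sprintf("  contour %.1f nm, rod %.3f nm, centromere locus %d (%g bp)\n",
              x$contour_length_nm, x$bond_length_nm, x$centromere_index,
              x$centromere_bp))
  invisible(x)
}

#' Nuclear geometry
#'
#' Spherical nucleus centred at the origin with a spindle pole body (SPB)
#' direction; clustering forces point at the SPB. The SPB itself has no
#' physical extent in the model.
#'
#' @param radius_nm Nuclear radius in nm (default 1000, i.e. a 2 um nucleus).
#' @param spb_direction Unit 3-vector toward the SPB (default `c(0, 0, 1)`).
#' @return An object of class `nuclear_geometry`.
#' @export
nuclear_geometry <- function(radius_nm = 1000, spb_direction = c(0, 0, 1)) {
  if (!is.numeric(radius_nm) || length(radius_nm) != 1 || radius_nm <= 0)
    stop("radius_nm must be a single positive number")
  if (length(spb_direction) != 3 || !is.numeric(spb_direction))
    stop("spb_direction must be a numeric 3-vector")
  n <- sqrt(sum(spb_direction^2))
  if (abs(n - 1) > 1e-12) {
    if (n == 0) stop("spb_direction must be non-zero")
    spb_direction <- spb_direction / n
  }
  structure(list(radius_nm = radius_nm, spb_direction = spb_direction),
            class = "nuclear_geometry")
}

#' Tether and clustering specification
#'
#' Declares which loci are constrained to the nuclear surface and the
#' von Mises-Fisher (vMF) clustering applied to them. `nu = 0` leaves the
#' tethered loci uniformly distributed over the surface; increasing `nu`
#' concentrates them about the mean direction `mu` (the SPB).
#'
#' @param mode One of `"none"`, `"centromere"`, `"telomeres"`.
#' @param nu vMF concentration parameter (>= 0); ignored for `mode = "none"`.
#' @param mu Unit 3-vector, clustering mean direction (default SPB axis).
#' @return An object of class `tether_spec`.
#' @export
tether_spec <- function(mode = c("none", "centromere", "telomeres"), nu = 0,
                        mu = c(0, 0, 1)) {
  mode <- match.arg(mode)
  if (!is.numeric(nu) || length(nu) != 1 || nu < 0)
    stop("nu must be a single number >= 0")
  if (length(mu) != 3 || !is.numeric(mu)) stop("mu must be a numeric 3-vector")
  n <- sqrt(sum(mu^2))
  if (n == 0) stop("mu must be non-zero")
  mu <- mu / n
  structure(list(mode = mode, nu = nu, mu = mu), class = "tether_spec")
}

#' Energy model for a confined worm-like chain
#'
#' Combines a chromosome specification, the nuclear geometry, the tether
#' specification and the bending stiffness into the full energy model used by
#' the sampler. The discrete bending modulus follows the standard
#' discretised-WLC correspondence `g*beta = l_p / b` (persistence length over
#' rod length). Energies are expressed in kT with `beta = 1` by default.
#'
#' @param spec A [chromosome_spec()].
#' @param persistence_nm Persistence length in nm (0.2 um flexible,
#'   2.0 um rigid in the meiotic regime studied here).
#' @param geometry A [nuclear_geometry()].
#' @param tether A [tether_spec()].
#' @param excluded_volume Enable the optional intrachromosomal hard-sphere
#'   check between non-neighbouring loci.
#' @param ev_min_dist_nm Hard-sphere distance for the excluded-volume check
#'   (default 40 nm). Loci within `ceiling(ev_min_dist_nm / bond)` positions
#'   along the contour are exempt, since contour neighbours necessarily sit
#'   closer than the hard-sphere distance when rods are shorter than it.
#' @param beta Thermodynamic beta (default 1; energies in kT).
#' @return An object of class `energy_model`.
#' @examples
#' chrI <- chromosome_spec(240000, 151000)
#' m <- energy_model(chrI, persistence_nm = 200,
#'                   tether = tether_spec("telomeres", nu = 50))
#' m$bending_modulus_kT
#' @export
energy_model <- function(spec, persistence_nm, geometry = nuclear_geometry(),
                         tether = tether_spec("none"),
                         excluded_volume = FALSE, ev_min_dist_nm = 40,
                         beta = 1) {
  stopifnot(inherits(spec, "chromosome_spec"),
            inherits(geometry, "nuclear_geometry"),
            inherits(tether, "tether_spec"))
  if (!is.numeric(persistence_nm) || persistence_nm < 0)
    stop("persistence_nm must be >= 0")
  if (beta <= 0) stop("beta must be positive")
  if (ev_min_dist_nm <= 0) stop("ev_min_dist_nm must be positive")
  structure(list(
    spec = spec,
    geometry = geometry,
    tether = tether,
    persistence_nm = persistence_nm,
    bending_modulus_kT = persistence_nm / spec$bond_length_nm,
    excluded_volume = excluded_volume,
    ev_min_dist_nm = ev_min_dist_nm,
    beta = beta
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(
    "<energy_model> %s, l_p %g nm (g*beta %.2f), tether %s (nu %g), R %g nm\n",
    x$spec$name, x$persistence_nm, x$bending_modulus_kT, x$tether$mode,
    x$tether$nu, x$geometry$radius_nm))
  invisible(x)
}

# flat list consumed by the C++ engine (0-based centromere, coded mode)
model_for_cpp <- function(model) {
  mode_code <- match(model$tether$mode, c("none", "centromere", "telomeres")) - 1L
  list(
    n_loci = model$spec$n_loci,
    bond_length_nm = model$spec$bond_length_nm,
    radius_nm = model$geometry$radius_nm,
    centromere_index0 = model$spec$centromere_index - 1L,
    mode_code = mode_code,
    bending_modulus_kT = model$bending_modulus_kT,
    nu = model$tether$nu,
    beta = model$beta,
    mu = as.numeric(model$tether$mu),
    excluded_volume = isTRUE(model$excluded_volume),
    ev_min_dist_nm = model$ev_min_dist_nm
  )
}

as_conformation <- function(positions) {
  storage.mode(positions) <- "double"
  class(positions) <- c("conformation", "matrix", "array")
  positions
}

#' Construct a feasible initial conformation
#'
#' Grows a chain satisfying every hard constraint of the model: equal rod
#' lengths, confinement inside the nucleus, and (where applicable) tethered
#' loci exactly on the nuclear surface. For the telomere-tethered mode the
#' chain is grown from one tethered end under a reachability constraint that
#' guarantees the far end can be closed onto the sphere, and the final rod
#' direction is solved exactly (uniformly over the feasible circle).
#'
#' The result is only a feasible starting point, not an equilibrium draw;
#' equilibration is the job of the sampler's burn-in. Growth directions are
#' biased along the previous rod with the model's stiffness so that initial
#' bending energies are moderate, falling back to uniform directions when
#' confinement leaves no stiff-compatible step.
#'
#' Consumes R's RNG stream: call `set.seed()` first for reproducibility.
#'
#' @param model An [energy_model()].
#' @param max_restarts Chain-level retry budget before giving up.
#' @return A `conformation`: an `n_loci` x 3 matrix of positions in nm,
#'   row i = locus i (telomeres are rows 1 and `n_loci`).
#' @export
initialize_conformation <- function(model, max_restarts = 100) {
  stopifnot(inherits(model, "energy_model"))
  N <- model$spec$n_loci
  b <- model$spec$bond_length_nm
  R <- model$geometry$radius_nm
  if (b > 2 * R)
    stop("rod length exceeds the nuclear diameter: no feasible conformation")
  mode <- model$tether$mode
  g <- model$bending_modulus_kT

  for (attempt in seq_len(max_restarts)) {
    pos <- switch(mode,
      none = grow_free(N, b, R, g, from = c(0, 0, 0)),
      centromere = {
        cen <- model$spec$centromere_index
        x0 <- R * rvmf(1, model$tether$mu, model$tether$nu)[1, ]
        up <- grow_free(N - cen + 1, b, R, g, from = x0)
        down <- grow_free(cen, b, R, g, from = x0)
        if (is.null(up) || is.null(down)) NULL
        else if (cen == 1) up
        else rbind(down[cen:2, , drop = FALSE], up)
      },
      telomeres = {
        x0 <- R * rvmf(1, model$tether$mu, model$tether$nu)[1, ]
        grow_closed(N, b, R, g, from = x0)
      })
    if (!is.null(pos)) {
      conf <- as_conformation(pos)
      rep <- validate_conformation(conf, model)
      if (rep$ok) return(conf)
    }
  }
  stop("initialize_conformation: no feasible conformation found after ",
       max_restarts, " restarts")
}

# grow a free chain of n loci starting at `from`, all loci inside the sphere
grow_free <- function(n, b, R, g, from) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- from
  dir <- rand_unit()
  for (i in seq_len(n - 1)) {
    step <- feasible_step(pos[i, ], dir, b, R, g)
    if (is.null(step)) return(NULL)
    pos[i + 1, ] <- pos[i, ] + b * step
    dir <- step
  }
  pos
}

# grow from a surface point; keep the sphere reachable for the final locus and
# close the last rod exactly onto the surface
grow_closed <- function(n, b, R, g, from) {
  pos <- matrix(0, n, 3)
  pos[1, ] <- from
  dir <- -from / sqrt(sum(from^2)) # head inward first
  for (i in seq_len(n - 2)) {
    remaining <- (n - 1 - i) * b
    step <- feasible_step(pos[i, ], dir, b, R, g, min_norm = R - remaining)
    if (is.null(step)) return(NULL)
    pos[i + 1, ] <- pos[i, ] + b * step
    dir <- step
  }
  p <- pos[n - 1, ]
  np <- sqrt(sum(p^2))
  # unit direction u with |p + b u| = R: circle  p.u = c0
  c0 <- (R^2 - np^2 - b^2) / (2 * b)
  if (abs(c0) > np) return(NULL)
  phat <- p / np
  cosphi <- c0 / np
  perp <- rand_perp(phat)
  u <- cosphi * phat + sqrt(max(0, 1 - cosphi^2)) * perp
  pos[n, ] <- p + b * u
  pos[n, ] <- pos[n, ] * (R / sqrt(sum(pos[n, ]^2))) # exact to rounding
  pos
}

# one growth step from point p with previous direction dir: vMF(dir, g) biased,
# falling back to uniform; candidate must stay inside the sphere and, when
# min_norm is set, keep |x| >= min_norm (sphere reachability)
feasible_step <- function(p, dir, b, R, g, min_norm = -Inf) {
  for (k in 1:60) {
    cand <- if (k <= 20 && g > 0) rvmf(1, dir, g)[1, ] else rand_unit()
    x <- p + b * cand
    nx <- sqrt(sum(x^2))
    if (nx <= R && nx >= min_norm) return(cand)
  }
  NULL
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

rand_perp <- function(u) {
  repeat {
    v <- stats::rnorm(3)
    w <- v - sum(v * u) * u
    n <- sqrt(sum(w^2))
    if (n > 1e-9) return(w / n)
  }
}

#' Validate a conformation against the hard constraints of a model
#'
#' Pure reporting function: checks rod lengths (relative tolerance 1e-9),
#' confinement (norms at most the nuclear radius, with a 1e-6 nm numerical
#' allowance for loci lying exactly on the surface) and, for tethered modes,
#' that the tethered loci sit on the sphere within 1e-6 nm.
#'
#' @param conf A `conformation` matrix (n_loci x 3, nm).
#' @param model An [energy_model()].
#' @return A list with element `ok` plus per-check pass flags and maximum
#'   violation magnitudes.
#' @export
validate_conformation <- function(conf, model) {
  stopifnot(inherits(model, "energy_model"))
  N <- model$spec$n_loci
  if (nrow(conf) != N || ncol(conf) != 3)
    stop("conformation must be an n_loci x 3 matrix")
  b <- model$spec$bond_length_nm
  R <- model$geometry$radius_nm

  rods <- diff(conf)
  rod_len <- sqrt(rowSums(rods^2))
  rod_dev <- max(abs(rod_len - b)) / b
  norms <- sqrt(rowSums(conf^2))
  conf_excess <- max(norms - R)

  tether_dev <- 0
  mode <- model$tether$mode
  if (mode == "centromere") {
    tether_dev <- abs(norms[model$spec$centromere_index] - R)
  } else if (mode == "telomeres") {
    tether_dev <- max(abs(norms[c(1, N)] - R))
  }

  checks <- list(
    rod_lengths = list(pass = rod_dev <= 1e-9, max_rel_deviation = rod_dev),
    confinement = list(pass = conf_excess <= 1e-6, max_excess_nm = conf_excess),
    tether = list(pass = tether_dev <= 1e-6, max_deviation_nm = tether_dev)
  )
  list(ok = all(vapply(checks, function(ch) ch$pass, logical(1))),
       checks = checks)
}
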