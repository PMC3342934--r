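# Closed-form and brute-force oracles used by the test-suite: discrete
# Kratky-Porod statistics, von Mises-Fisher sampling, a direct (non-MCMC)
# unconfined chain grower, and the discretisation-convergence scan.

#' Discrete Kratky-Porod mean squared end-to-end distance
#'
#' Exact unconfined statistics of a freely rotating discrete chain whose
#' joint angles follow the Boltzmann weight `exp(g*beta*cos)`:
#' `p = <cos theta> = coth(g*beta) - 1/(g*beta)` and
#' `<R^2> = b^2 * (n (1+p)/(1-p) - 2 p (1-p^n) / (1-p)^2)`.
#' The `g*beta = 0` branch gives the freely jointed chain `<R^2> = n b^2`.
#'
#' @param n_rods Number of rods n (>= 1).
#' @param bond_nm Rod length b in nm.
#' @param g_beta Dimensionless bending modulus (>= 0).
#' @return A list of class `wlc_prediction` with `mean_sq_end_to_end_nm2`,
#'   `mean_cos_theta` and the parameters.
#' @export
discrete_wlc_r2 <- function(n_rods, bond_nm, g_beta) {
  stopifnot(n_rods >= 1, bond_nm > 0, g_beta >= 0)
  p <- mean_cos_kratky_porod(g_beta)
  r2 <- if (p == 0) n_rods * bond_nm^2
  else bond_nm^2 * (n_rods * (1 + p) / (1 - p) -
                      2 * p * (1 - p^n_rods) / (1 - p)^2)
  structure(list(mean_sq_end_to_end_nm2 = r2, mean_cos_theta = p,
                 n_rods = n_rods, bond_nm = bond_nm, g_beta = g_beta),
            class = "wlc_prediction")
}

# coth(g) - 1/g, evaluated stably near 0
mean_cos_kratky_porod <- function(g) {
  if (g == 0) return(0)
  if (g < 1e-4) return(g / 3 - g^3 / 45)
  1 / tanh(g) - 1 / g
}

#' Mean resultant length of the von Mises-Fisher distribution on the sphere
#'
#' For the vMF distribution on the 2-sphere with concentration `nu`, the mean
#' resultant length is `coth(nu) - 1/nu`, with limit 0 at `nu = 0` (uniform)
#' and 1 as `nu -> Inf`.
#'
#' @param nu Concentration parameter (>= 0).
#' @return Scalar in `[0, 1)`.
#' @export
vmf_mean_resultant <- function(nu) {
  stopifnot(nu >= 0)
  mean_cos_kratky_porod(nu)
}

#' Draw from the von Mises-Fisher distribution on the unit sphere
#'
#' Inverse-CDF sampling of the polar cosine (`W = 1 + log(u + (1-u)
#' exp(-2 nu)) / nu`) with a uniform azimuth, rotated into the frame of the
#' mean direction. `nu = 0` yields the uniform distribution on the sphere.
#' Consumes R's RNG stream.
#'
#' @param n Number of draws.
#' @param mu Mean direction (3-vector, normalised internally).
#' @param nu Concentration (>= 0).
#' @return An `n x 3` matrix of unit vectors.
#' @export
rvmf <- function(n, mu = c(0, 0, 1), nu = 0) {
  stopifnot(n >= 1, nu >= 0, length(mu) == 3)
  mu <- mu / sqrt(sum(mu^2))
  u <- stats::runif(n)
  w <- if (nu == 0) 2 * u - 1
  else 1 + log(u + (1 - u) * exp(-2 * nu)) / nu
  w <- pmin(1, pmax(-1, w))
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  local <- cbind(s * cos(phi), s * sin(phi), w)
  # orthonormal frame (e1, e2, mu)
  ref <- if (abs(mu[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * mu) * mu
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  local %*% rbind(e1, e2, mu)
}

#' Grow unconfined discrete worm-like chains directly (no MCMC)
#'
#' Independent brute-force sampler for unconfined chains: each rod direction
#' is drawn from the vMF distribution centred on the previous rod with
#' concentration `g_beta`, which is exactly the Boltzmann weight of the
#' discrete bending energy. Shares no sampling code with the Metropolis
#' engine, so it serves as an independent oracle for it.
#'
#' @param n_chains Number of independent chains.
#' @param n_rods Rods per chain.
#' @param bond_nm Rod length (nm).
#' @param g_beta Dimensionless bending modulus.
#' @return A list with `r2` (squared end-to-end distances, nm^2, length
#'   `n_chains`) and `mean_cos` (per-chain mean joint cosine).
#' @export
grow_unconfined_chains <- function(n_chains, n_rods, bond_nm, g_beta) {
  stopifnot(n_chains >= 1, n_rods >= 1)
  d <- rvmf(n_chains, c(0, 0, 1), 0) # first rod directions, uniform
  pos <- bond_nm * d
  cos_sum <- rep(0, n_chains)
  if (n_rods >= 2) {
    for (k in 2:n_rods) {
      d_new <- rvmf_rows(d, g_beta)
      cos_sum <- cos_sum + rowSums(d * d_new)
      d <- d_new
      pos <- pos + bond_nm * d
    }
  }
  list(r2 = rowSums(pos^2),
       mean_cos = if (n_rods >= 2) cos_sum / (n_rods - 1) else rep(NA_real_, n_chains))
}

# vectorised vMF draw: one sample per row of the mean-direction matrix
rvmf_rows <- function(mu, nu) {
  n <- nrow(mu)
  u <- stats::runif(n)
  w <- if (nu == 0) 2 * u - 1
  else 1 + log(u + (1 - u) * exp(-2 * nu)) / nu
  w <- pmin(1, pmax(-1, w))
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  # rowwise orthonormal frames
  use_z <- abs(mu[, 3]) < 0.9
  ref <- cbind(ifelse(use_z, 0, 1), 0, ifelse(use_z, 1, 0))
  dot <- rowSums(ref * mu)
  e1 <- ref - dot * mu
  e1 <- e1 / sqrt(rowSums(e1^2))
  e2 <- cbind(mu[, 2] * e1[, 3] - mu[, 3] * e1[, 2],
              mu[, 3] * e1[, 1] - mu[, 1] * e1[, 3],
              mu[, 1] * e1[, 2] - mu[, 2] * e1[, 1])
  (s * cos(phi)) * e1 + (s * sin(phi)) * e2 + w * mu
}

#' Discretisation-convergence scan
#'
#' Re-runs one condition at several discretisation numbers N while holding the
#' contour length and persistence length fixed (so the rod length shrinks as N
#' grows), and reports the mean pairwise intra-chromosome distance. Used to
#' verify that the discrete chain has converged to the continuous worm-like
#' chain at the production N.
#'
#' @param chromosome Chromosome name (see [make_condition()]) or a
#'   template [chromosome_spec()] whose `n_loci` is re-set per scan point.
#' @param persistence_nm Persistence length (nm).
#' @param condition Condition preset name (see [make_condition()]).
#' @param n_list Vector of locus counts to scan.
#' @param n_samples Retained conformations per chain.
#' @param n_chains Independent replicate chains per scan point; the statistic
#'   is averaged across them (replicates also expose the Monte Carlo spread,
#'   reported as `sd_chains`).
#' @param seed Integer seed.
#' @return A data frame with one row per N: `n_loci`, `mean_pairwise_nd`
#'   (chain average), `sd_chains`, `retained` (per chain).
#' @export
convergence_scan <- function(chromosome, persistence_nm, condition,
                             n_list = c(10, 25, 50, 75, 150, 300),
                             n_samples = 1000, n_chains = 3, seed = 1) {
  template <- if (inherits(chromosome, "chromosome_spec")) chromosome
  else chromosome_presets()[[match.arg(chromosome, names(chromosome_presets()))]]
  rows <- lapply(seq_along(n_list), function(k) {
    N <- n_list[k]
    spec <- chromosome_spec(template$length_bp, template$centromere_bp,
                            n_loci = N, name = template$name)
    model <- condition_model(condition, spec, persistence_nm)
    n_total <- ceiling(n_samples * 40 / 0.7)
    stats_c <- vapply(seq_len(n_chains), function(ch) {
      sched <- sampler_schedule(n_total, ceiling(0.3 * n_total), thin = 40,
                                seed = seed + 1000L * k + ch)
      ens <- run_chain(model, sched)
      map <- intra_ldm(ens)
      mean(map$values[row(map$values) != col(map$values)])
    }, numeric(1))
    data.frame(n_loci = N, mean_pairwise_nd = mean(stats_c),
               sd_chains = if (n_chains > 1) stats::sd(stats_c) else NA_real_,
               retained = floor((n_total - ceiling(0.3 * n_total)) / 40))
  })
  do.call(rbind, rows)
}
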