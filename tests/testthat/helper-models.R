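# Shared fixture builders. Everything is generated in code; chains are kept
# deliberately small so the default run stays fast.

# spec with an (approximately) prescribed rod length
spec_with_bond <- function(n_loci, bond_nm, centromere_frac = 0.5,
                           name = "toy") {
  length_bp <- bond_nm * (n_loci - 1) * 40 / 0.34
  chromosome_spec(length_bp, centromere_frac * length_bp, n_loci = n_loci,
                  name = name)
}

toy_model <- function(n_loci = 30, bond_nm = 10, persistence_nm = 50,
                      mode = "none", nu = 0, radius_nm = 1000, ...) {
  spec <- spec_with_bond(n_loci, bond_nm)
  energy_model(spec, persistence_nm = persistence_nm,
               geometry = nuclear_geometry(radius_nm),
               tether = tether_spec(mode, nu = nu), ...)
}

# wrap a list of conformations (matrices) as a wlc_ensemble
fake_ensemble <- function(conf_list, model) {
  N <- model$spec$n_loci
  M <- length(conf_list)
  pos <- array(0, dim = c(N, 3, M))
  for (k in seq_len(M)) pos[, , k] <- conf_list[[k]]
  structure(list(positions = pos, spec = model$spec, model = model,
                 schedule = sampler_schedule(2, 1, 1, seed = 1),
                 retained_count = M, acceptance_rate = NA_real_,
                 step_angles = NULL,
                 final_conformation = if (M > 0) conf_list[[M]] else NULL),
            class = "wlc_ensemble")
}

# straight chain along +x starting at the origin
straight_chain <- function(n_loci, bond_nm) {
  cbind((seq_len(n_loci) - 1) * bond_nm, 0, 0)
}

rod_lengths <- function(conf) sqrt(rowSums(diff(conf)^2))

rand_axis <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

as_conf <- function(m) {
  storage.mode(m) <- "double"
  class(m) <- c("conformation", "matrix", "array")
  m
}

# mean resultant length of a set of unit (or to-normalise) vectors
mean_resultant <- function(x) {
  x <- x / sqrt(rowSums(x^2))
  sqrt(sum(colMeans(x)^2))
}

# reduced sampling schedules used by the statistical tests; sizes are chosen
# so each run finishes in about a second while retaining >= 10^4 states
test_schedule <- function(seed, n_total = 1e6, thin = 40) {
  sampler_schedule(n_total, 0.3 * n_total, thin = thin, seed = seed)
}
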