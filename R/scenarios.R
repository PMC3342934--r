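# Named presets reproducing the experimental grid (conditions x chromosomes x
# persistence lengths) and drivers that turn a preset into simulated
# ensembles plus the analytics bundle.

#' Condition, chromosome and schedule vocabularies
#'
#' `condition_presets()` maps condition names to tether mode and clustering
#' strength: `no_tether` (none), `rabl` (centromere tethered, nu = 50),
#' `telomeres_tethered` (telomeres, nu = 0), `early_bouquet` (telomeres,
#' nu = 5), `loose_bouquet` (telomeres, nu = 10), `tight_bouquet` (telomeres,
#' nu = 50). The loose-bouquet level follows the figure labelling of the
#' bouquet series (5/10/50); the intermediate level nu = 20 remains available
#' through an explicit `nu` override in [make_condition()].
#'
#' `chromosome_presets()` provides the three budding-yeast chromosomes the
#' grid uses, with approximate centromere positions (not precisely determined
#' by the model; every experiment records the value used): chrI 240 kb
#' (centromere ~151 kb), chrXVI 950 kb (~556 kb), chrIV 1530 kb (~450 kb).
#'
#' `scale_presets()` gives the sampling schedules: `paper` is the full
#' production schedule (10M attempted steps, 3M burn-in, thin 40 -> 175,000
#' retained); `desk` is a workstation-scale run (4M steps, 1.2M burn-in,
#' thin 40 -> 70,000 retained) that keeps the same 30% burn-in fraction and
#' thinning while reducing total sampling 2.5-fold.
#'
#' @return Named lists describing the vocabularies.
#' @export
condition_presets <- function() {
  list(
    no_tether = list(mode = "none", nu = NA_real_),
    rabl = list(mode = "centromere", nu = 50),
    telomeres_tethered = list(mode = "telomeres", nu = 0),
    early_bouquet = list(mode = "telomeres", nu = 5),
    loose_bouquet = list(mode = "telomeres", nu = 10),
    tight_bouquet = list(mode = "telomeres", nu = 50)
  )
}

#' @rdname condition_presets
#' @export
chromosome_presets <- function() {
  list(
    chrI = chromosome_spec(240000, 151000, name = "chrI"),
    chrXVI = chromosome_spec(950000, 556000, name = "chrXVI"),
    chrIV = chromosome_spec(1530000, 450000, name = "chrIV")
  )
}

#' @rdname condition_presets
#' @export
scale_presets <- function() {
  list(
    paper = list(n_total = 1e7, n_burn_in = 3e6, thin = 40),
    desk = list(n_total = 4e6, n_burn_in = 1.2e6, thin = 40)
  )
}

condition_model <- function(condition, spec, persistence_nm, nu = NULL,
                            geometry = nuclear_geometry(),
                            excluded_volume = FALSE) {
  presets <- condition_presets()
  condition <- match.arg(condition, names(presets))
  p <- presets[[condition]]
  tether <- if (p$mode == "none") tether_spec("none")
  else tether_spec(p$mode, nu = if (is.null(nu)) p$nu else nu,
                   mu = geometry$spb_direction)
  energy_model(spec, persistence_nm = persistence_nm, geometry = geometry,
               tether = tether, excluded_volume = excluded_volume)
}

#' Resolve a named condition into spec, model and schedule
#'
#' @param condition Condition name (see [condition_presets()]).
#' @param chromosome Chromosome name (`"chrI"`, `"chrXVI"`, `"chrIV"`) or a
#'   [chromosome_spec()].
#' @param persistence_nm Persistence length in nm (200 flexible, 2000 rigid).
#' @param scale `"paper"`, `"desk"`, or a list with `n_total`, `n_burn_in`,
#'   `thin`.
#' @param seed Integer seed for the schedule.
#' @param nu Optional clustering-strength override (e.g. the intermediate
#'   level 20).
#' @param geometry Nuclear geometry (default 2 um nucleus, SPB on +z).
#' @param excluded_volume Enable the intrachromosomal hard-sphere term.
#' @return A list with `spec`, `model`, `schedule` and the resolved names.
#' @examples
#' cond <- make_condition("tight_bouquet", "chrI", 200, "desk", seed = 7)
#' cond$model$bending_modulus_kT  # ~29.31
#' @export
make_condition <- function(condition, chromosome, persistence_nm,
                           scale = "desk", seed = 1, nu = NULL,
                           geometry = nuclear_geometry(),
                           excluded_volume = FALSE) {
  spec <- if (inherits(chromosome, "chromosome_spec")) chromosome
  else chromosome_presets()[[match.arg(chromosome, names(chromosome_presets()))]]
  if (is.null(spec)) stop("unknown chromosome")
  model <- condition_model(condition, spec, persistence_nm, nu = nu,
                           geometry = geometry,
                           excluded_volume = excluded_volume)
  sc <- if (is.list(scale)) scale
  else scale_presets()[[match.arg(scale, names(scale_presets()))]]
  schedule <- sampler_schedule(sc$n_total, sc$n_burn_in, thin = sc$thin,
                               seed = seed)
  list(condition = match.arg(condition, names(condition_presets())),
       spec = spec, model = model, schedule = schedule,
       persistence_nm = persistence_nm, seed = as.integer(seed))
}

# homologues use distinct sub-seeds derived from the run seed by fixed
# offsets, so the pair is independent but reproducible from one integer
sub_seed <- function(seed, copy) as.integer(seed) * 100L + as.integer(copy)

#' Simulate a homologue pair and assemble its analytics bundle
#'
#' Runs two independent chains of the same condition (sub-seeded from `seed`),
#' pairs their retained samples by index as nuclei, and computes the allelic
#' profile with standard deviations, the telomere cloud and (optionally) the
#' full homologue distance map with allelic/ectopic rank-score curves.
#' Correlation between homologues arises only through the shared clustering
#' direction; the energy contains no inter-chromosome terms.
#'
#' @param condition,chromosome,persistence_nm,scale,nu,geometry,excluded_volume
#'   Passed to [make_condition()].
#' @param seed Run seed; homologues use sub-seeds `seed*100 + 1` and
#'   `seed*100 + 2`.
#' @param full_map Compute the full N x N homologue map and rank curves
#'   (needed for ectopic statistics); when `FALSE` only the allelic diagonal
#'   is accumulated, which is much cheaper.
#' @param keep_ensembles Keep the raw ensembles in the bundle (memory-heavy
#'   for production scales).
#' @param n_cloud_cells Nuclei in the telomere cloud.
#' @return An object of class `experiment_bundle`.
#' @export
run_homologue_experiment <- function(condition, chromosome, persistence_nm,
                                     scale = "desk", seed = 1, nu = NULL,
                                     geometry = nuclear_geometry(),
                                     excluded_volume = FALSE,
                                     full_map = TRUE, keep_ensembles = FALSE,
                                     n_cloud_cells = 500) {
  cond <- make_condition(condition, chromosome, persistence_nm, scale, seed,
                         nu = nu, geometry = geometry,
                         excluded_volume = excluded_volume)
  ens_a <- run_chain(cond$model, schedule_with_seed(cond$schedule,
                                                    sub_seed(seed, 1)))
  ens_b <- run_chain(cond$model, schedule_with_seed(cond$schedule,
                                                    sub_seed(seed, 2)))
  bundle_from_pair(cond, ens_a, ens_b, kind = "homologue",
                   full_map = full_map, keep_ensembles = keep_ensembles,
                   n_cloud_cells = n_cloud_cells)
}

#' Simulate a heterologue pair and assemble its analytics bundle
#'
#' As [run_homologue_experiment()] but for two different chromosomes sharing
#' the condition, persistence length and geometry (hence the clustering
#' direction). The 300 x 300 cross map yields 90,000 mean distances ranked
#' into 300 bins.
#'
#' @inheritParams run_homologue_experiment
#' @param chromosome_a,chromosome_b The two chromosome names or specs.
#' @return An object of class `experiment_bundle` (kind `"heterologue"`).
#' @export
run_heterologue_experiment <- function(condition, chromosome_a, chromosome_b,
                                       persistence_nm, scale = "desk",
                                       seed = 1, nu = NULL,
                                       geometry = nuclear_geometry(),
                                       excluded_volume = FALSE,
                                       keep_ensembles = FALSE,
                                       n_cloud_cells = 500) {
  cond_a <- make_condition(condition, chromosome_a, persistence_nm, scale,
                           seed, nu = nu, geometry = geometry,
                           excluded_volume = excluded_volume)
  cond_b <- make_condition(condition, chromosome_b, persistence_nm, scale,
                           seed, nu = nu, geometry = geometry,
                           excluded_volume = excluded_volume)
  ens_a <- run_chain(cond_a$model, schedule_with_seed(cond_a$schedule,
                                                      sub_seed(seed, 1)))
  ens_b <- run_chain(cond_b$model, schedule_with_seed(cond_b$schedule,
                                                      sub_seed(seed, 2)))
  bundle_from_pair(cond_a, ens_a, ens_b, kind = "heterologue",
                   full_map = TRUE, keep_ensembles = keep_ensembles,
                   n_cloud_cells = n_cloud_cells)
}

schedule_with_seed <- function(schedule, seed) {
  schedule$seed <- as.integer(seed)
  schedule
}

bundle_from_pair <- function(cond, ens_a, ens_b, kind, full_map,
                             keep_ensembles, n_cloud_cells) {
  nd <- 2 * ens_a$model$geometry$radius_nm
  if (full_map) {
    map <- inter_ldm(ens_a, ens_b, kind = kind)
    profile <- allelic_profile_any(map)
    allelic_rank <- if (kind == "homologue")
      rank_scores(diag(map$values), length(diag(map$values))) else NULL
    # ectopic means bin in groups of 300: 89,700 -> 299 bins, 90,000 -> 300
    ect <- if (kind == "homologue") ectopic_means(map) else as.vector(map$values)
    ect_rank <- rank_scores(ect, length(ect) %/% 300L)
  } else {
    st <- .allelic_stats_cpp(ens_a$positions, ens_b$positions)
    map <- NULL
    profile <- data.frame(locus = seq_along(st$diag_mean_nm),
                          mean_nd = st$diag_mean_nm / nd,
                          sd_nd = st$diag_sd_nm / nd)
    allelic_rank <- rank_scores(profile$mean_nd, nrow(profile))
    ect_rank <- NULL
  }
  cloud <- list(a = telomere_cloud(ens_a, min(n_cloud_cells, ens_a$retained_count)),
                b = telomere_cloud(ens_b, min(n_cloud_cells, ens_b$retained_count)))
  structure(list(
    kind = kind,
    condition = cond$condition,
    spec_a = ens_a$spec, spec_b = ens_b$spec,
    persistence_nm = cond$persistence_nm,
    seed = cond$seed,
    schedule = cond$schedule,
    retained_count = ens_a$retained_count,
    acceptance_rates = c(a = ens_a$acceptance_rate, b = ens_b$acceptance_rate),
    map = map,
    allelic_profile = profile,
    allelic_rank = allelic_rank,
    ectopic_rank = ect_rank,
    telomere_cloud = cloud,
    ensembles = if (keep_ensembles) list(a = ens_a, b = ens_b) else NULL
  ), class = "experiment_bundle")
}

allelic_profile_any <- function(map) {
  if (map$kind == "homologue") return(allelic_profile(map))
  data.frame(locus = seq_len(nrow(map$values)), mean_nd = diag(map$values),
             sd_nd = if (is.null(map$diag_sd)) NA_real_ else map$diag_sd)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat(sprintf(
    "<experiment_bundle> %s %s, %s%s, l_p %g nm, seed %d: %d nuclei\n",
    x$condition, x$kind, x$spec_a$name,
    if (x$kind == "heterologue") paste0(" x ", x$spec_b$name) else " pair",
    x$persistence_nm, x$seed, x$retained_count))
  cat(sprintf("  allelic profile %.3f-%.3f ND\n",
              min(x$allelic_profile$mean_nd), max(x$allelic_profile$mean_nd)))
  invisible(x)
}

#' Rabl-to-bouquet time course
#'
#' Runs the six stationary conditions that mimic time-course sampling of the
#' Rabl-to-tight-bouquet transition -- `no_tether`, `rabl`,
#' `telomeres_tethered`, `early_bouquet`, `loose_bouquet`, `tight_bouquet`,
#' in that fixed order -- for one chromosome and persistence length, and
#' compares each tethered condition's intrachromosomal mean distances against
#' the `no_tether` baseline with KS and Wilcoxon rank-sum tests.
#'
#' @inheritParams run_homologue_experiment
#' @return A list of class `timecourse` with `bundles` (named, fixed order)
#'   and `comparisons` (each condition vs `no_tether`).
#' @export
run_timecourse <- function(chromosome, persistence_nm, scale = "desk",
                           seed = 1, geometry = nuclear_geometry(),
                           full_map = FALSE) {
  conds <- c("no_tether", "rabl", "telomeres_tethered", "early_bouquet",
             "loose_bouquet", "tight_bouquet")
  bundles <- list()
  intra_means <- list()
  for (k in seq_along(conds)) {
    b <- run_homologue_experiment(conds[k], chromosome, persistence_nm,
                                  scale = scale, seed = seed + k,
                                  geometry = geometry, full_map = full_map,
                                  keep_ensembles = TRUE)
    imap <- intra_ldm(b$ensembles$a)
    intra_means[[conds[k]]] <- imap$values[row(imap$values) != col(imap$values)]
    b$ensembles <- NULL
    bundles[[conds[k]]] <- b
  }
  baseline <- intra_means$no_tether
  comparisons <- lapply(intra_means[-1], compare_conditions, means_b = baseline)
  structure(list(bundles = bundles, comparisons = comparisons,
                 chromosome = chromosome, persistence_nm = persistence_nm,
                 seed = seed),
            class = "timecourse")
}
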