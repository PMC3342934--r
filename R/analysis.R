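# Ensemble analytics: locus distance maps (LDMs), allelic profiles,
# rank-score curves, telomere clouds and condition comparisons.

new_distance_map <- function(values_nm, kind, n_samples, specs,
                             radius_nm, diag_sd_nm = NULL) {
  nd <- 2 * radius_nm
  values <- values_nm / nd
  if (any(values < 0) || any(values > 1))
    stop("distance map entries must lie in [0, 1] nuclear diameters")
  structure(list(
    values = values,
    values_nm = values_nm,
    kind = kind,
    n_samples = n_samples,
    specs = specs,
    nd_nm = nd,
    diag_sd = if (is.null(diag_sd_nm)) NULL else diag_sd_nm / nd
  ), class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> %s, %d x %d loci, %g samples, range %.3f-%.3f ND\n",
              x$kind, nrow(x$values), ncol(x$values), x$n_samples,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Intra-chromosome locus distance map
#'
#' Entry (i, j) is the ensemble mean of the Euclidean distance between loci i
#' and j of the same chromosome, expressed as a fraction of the nuclear
#' diameter (ND). Symmetric with zero diagonal.
#'
#' @param ensemble A `wlc_ensemble` from [run_chain()].
#' @return A `distance_map` of kind `"intra"`.
#' @export
intra_ldm <- function(ensemble) {
  if (ensemble$retained_count < 1) stop("empty ensemble")
  res <- .ldm_intra_cpp(ensemble$positions)
  new_distance_map(res$mean_nm, "intra", res$n_samples,
                   list(a = ensemble$spec),
                   ensemble$model$geometry$radius_nm)
}

#' Inter-chromosome locus distance map
#'
#' Pairs the k-th retained sample of each ensemble as one nucleus and averages
#' the cross distances: entry (i, j) is the mean over nuclei of the distance
#' between locus i of chromosome A and locus j of chromosome B, in ND
#' fractions. For homologues the diagonal holds the allelic distances (not
#' zero); for heterologues the map is not symmetric in general.
#'
#' @param ensemble_a,ensemble_b Ensembles with equal retained counts and the
#'   same nuclear geometry. Chains must have been simulated with the shared
#'   clustering direction for the pairing to represent one nucleus.
#' @param kind `"homologue"` or `"heterologue"`.
#' @return A `distance_map` carrying the per-locus standard deviation of the
#'   allelic (diagonal) distances.
#' @export
inter_ldm <- function(ensemble_a, ensemble_b,
                      kind = c("homologue", "heterologue")) {
  kind <- match.arg(kind)
  if (ensemble_a$retained_count != ensemble_b$retained_count)
    stop("retained counts differ; ensembles cannot be paired by index")
  ga <- ensemble_a$model$geometry
  gb <- ensemble_b$model$geometry
  if (abs(ga$radius_nm - gb$radius_nm) > 1e-9 ||
      max(abs(ga$spb_direction - gb$spb_direction)) > 1e-12)
    stop("ensembles were simulated in different nuclear geometries")
  res <- .ldm_cross_cpp(ensemble_a$positions, ensemble_b$positions)
  new_distance_map(res$mean_nm, kind, res$n_samples,
                   list(a = ensemble_a$spec, b = ensemble_b$spec),
                   ga$radius_nm, diag_sd_nm = res$diag_sd_nm)
}

#' Allelic profile of a homologue distance map
#'
#' The diagonal of the homologue map ordered telomere to telomere: the mean
#' distance between allelic loci, with the per-locus standard deviation of the
#' allelic distance across nuclei alongside.
#'
#' @param map A `distance_map` of kind `"homologue"`.
#' @return A data frame with columns `locus`, `mean_nd`, `sd_nd`.
#' @export
allelic_profile <- function(map) {
  if (!inherits(map, "distance_map") || map$kind != "homologue")
    stop("allelic_profile requires a homologue distance map")
  data.frame(locus = seq_len(nrow(map$values)),
             mean_nd = diag(map$values),
             sd_nd = if (is.null(map$diag_sd)) NA_real_ else map$diag_sd)
}

#' Ectopic (off-diagonal) means of a homologue distance map
#'
#' All entries of the homologue map except the allelic diagonal: for 300 loci,
#' the 89,700 mean distances between nonallelic locus pairs.
#'
#' @param map A `distance_map` of kind `"homologue"`.
#' @return Numeric vector of length `N^2 - N` (ND fractions).
#' @export
ectopic_means <- function(map) {
  if (!inherits(map, "distance_map") || map$kind != "homologue")
    stop("ectopic_means requires a homologue distance map")
  v <- map$values
  v[row(v) != col(v)]
}

#' Rank-score curve
#'
#' Sorts a vector of mean distances ascending (stable sort), partitions it
#' into equal consecutive bins and averages each bin. Inputs are expected to
#' divide evenly into the requested bins (300 allelic means into 300 bins;
#' 90,000 heterologue means into 300 bins of 300; 89,700 ectopic means into
#' 299 bins of 300); any other size is an error rather than a silent
#' truncation.
#'
#' @param means Numeric vector of mean distances (ND fractions).
#' @param n_bins Number of bins; must divide `length(means)`.
#' @return An object of class `rank_score_curve` with the non-decreasing
#'   `binned_means`, the `bin_size` and `n_input_means`.
#' @examples
#' rank_scores(c(3, 1, 2, 6, 5, 4), 3)$binned_means  # 1.5 3.5 5.5
#' @export
rank_scores <- function(means, n_bins) {
  if (length(means) == 0) stop("empty input")
  if (length(means) %% n_bins != 0)
    stop("n_bins (", n_bins, ") does not divide the number of means (",
         length(means), ")")
  bin_size <- length(means) %/% n_bins
  sorted <- sort(means, method = "radix")
  binned <- colMeans(matrix(sorted, nrow = bin_size))
  structure(list(binned_means = binned, bin_size = bin_size,
                 n_input_means = length(means)),
            class = "rank_score_curve")
}

#' @export
print.rank_score_curve <- function(x, ...) {
  cat(sprintf("<rank_score_curve> %d means in %d bins of %d; range %.3f-%.3f\n",
              x$n_input_means, length(x$binned_means), x$bin_size,
              min(x$binned_means), max(x$binned_means)))
  invisible(x)
}

#' Two-sample condition comparison
#'
#' Compares two vectors of mean distances with the two-sided two-sample
#' Kolmogorov-Smirnov test and the Wilcoxon rank-sum test (`stats::ks.test`
#' and `stats::wilcox.test`; the rank-sum test uses the normal approximation
#' with continuity and tie corrections for large samples and the exact
#' distribution below 50 total observations without ties). Because LDM means
#' contain many near-ties the KS test is always the asymptotic variant.
#'
#' @param means_a,means_b Non-empty numeric vectors.
#' @return An object of class `condition_comparison` with the two statistics,
#'   p-values and sample sizes.
#' @export
compare_conditions <- function(means_a, means_b) {
  if (length(means_a) == 0 || length(means_b) == 0) stop("empty input")
  n <- length(means_a) + length(means_b)
  ks <- suppressWarnings(stats::ks.test(means_a, means_b, exact = FALSE))
  wx <- suppressWarnings(stats::wilcox.test(means_a, means_b,
                                            exact = n < 50, correct = TRUE))
  structure(list(
    ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
    wilcoxon_statistic = unname(wx$statistic), wilcoxon_p = wx$p.value,
    n_a = length(means_a), n_b = length(means_b)
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<condition_comparison> n = %d vs %d: KS D = %.4f (p = %.3g), Wilcoxon W = %g (p = %.3g)\n",
    x$n_a, x$n_b, x$ks_statistic, x$ks_p, x$wilcoxon_statistic, x$wilcoxon_p))
  invisible(x)
}

#' Telomere cloud
#'
#' Positions of the two chain ends from `n_cells` evenly spaced retained
#' samples -- the per-nucleus telomere dots drawn next to allelic profiles.
#'
#' @param ensemble A `wlc_ensemble`.
#' @param n_cells Number of nuclei to sample (<= retained count).
#' @return A list with `tel1` and `tel2`, each an `n_cells x 3` matrix (nm).
#' @export
telomere_cloud <- function(ensemble, n_cells = 500) {
  M <- ensemble$retained_count
  if (n_cells > M) stop("n_cells exceeds the retained sample count")
  idx <- unique(round(seq(1, M, length.out = n_cells)))
  N <- ensemble$spec$n_loci
  list(tel1 = t(ensemble$positions[1, , idx]),
       tel2 = t(ensemble$positions[N, , idx]))
}
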