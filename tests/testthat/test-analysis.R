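test_that("intra-chromosome maps reduce to the exact chain geometry", {
  model <- toy_model(n_loci = 30, bond_nm = 10)
  b <- model$spec$bond_length_nm
  nd <- 2 * model$geometry$radius_nm
  ens <- fake_ensemble(list(straight_chain(30, b)), model)
  map <- intra_ldm(ens)
  expected <- abs(outer(1:30, 1:30, "-")) * b / nd
  expect_equal(map$values, expected, tolerance = 1e-12)
  expect_identical(diag(map$values), rep(0, 30))
  expect_equal(map$values, t(map$values))
  expect_s3_class(map, "distance_map")
  expect_error(intra_ldm(fake_ensemble(list(), model)))
})

test_that("rank curve of a rigid straight chain equals the sorted pair multiset", {
  model <- toy_model(n_loci = 30, bond_nm = 10)
  b <- model$spec$bond_length_nm
  nd <- 2 * model$geometry$radius_nm
  map <- intra_ldm(fake_ensemble(list(straight_chain(30, b)), model))
  off <- map$values[row(map$values) != col(map$values)] # 870 values
  curve <- rank_scores(off, 30)
  oracle <- sort(as.vector(abs(outer(1:30, 1:30, "-"))[row(diag(30)) !=
                                                         col(diag(30))]) *
                   b / nd)
  expect_equal(curve$binned_means, colMeans(matrix(oracle, nrow = 29)),
               tolerance = 1e-12)
  expect_true(all(diff(curve$binned_means) >= 0))
})

test_that("inter-chromosome maps pair samples by index", {
  model <- toy_model(n_loci = 12, bond_nm = 8)
  set.seed(21)
  confs <- replicate(5, initialize_conformation(model), simplify = FALSE)
  ens <- fake_ensemble(confs, model)

  self <- inter_ldm(ens, ens, kind = "homologue")
  expect_identical(diag(self$values), rep(0, 12)) # self-pairing degenerate
  expect_equal(self$values, t(self$values))

  origin <- fake_ensemble(list(matrix(0, 12, 3)), model)
  other <- fake_ensemble(confs[1], model)
  map <- inter_ldm(origin, other, kind = "heterologue")
  norms <- sqrt(rowSums(confs[[1]]^2)) / (2 * model$geometry$radius_nm)
  expect_equal(map$values, matrix(norms, 12, 12, byrow = TRUE),
               tolerance = 1e-12)

  expect_error(inter_ldm(ens, origin), "retained counts")
  big <- toy_model(n_loci = 12, bond_nm = 8, radius_nm = 2000)
  expect_error(inter_ldm(ens, fake_ensemble(confs, big)), "geometr")
})

test_that("allelic profiles and ectopic means read the homologue map", {
  model <- toy_model(n_loci = 3, bond_nm = 10)
  a <- fake_ensemble(list(straight_chain(3, 10)), model)
  bconf <- straight_chain(3, 10)
  bconf[, 2] <- 100
  b <- fake_ensemble(list(bconf), model)
  map <- inter_ldm(a, b, kind = "homologue")

  prof <- allelic_profile(map)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$mean_nd, rep(100 / 2000, 3)) # constant diagonal

  ect <- ectopic_means(map)
  expect_length(ect, 3^2 - 3)
  expect_gte(max(ect), max(map$values[abs(row(map$values) -
                                            col(map$values)) == 1]))

  imap <- intra_ldm(a)
  expect_error(allelic_profile(imap), "homologue")
  expect_error(ectopic_means(imap), "homologue")
})

test_that("rank scoring sorts, bins evenly and refuses ragged input", {
  expect_equal(rank_scores(c(3, 1, 2, 6, 5, 4), 3)$binned_means,
               c(1.5, 3.5, 5.5))
  expect_equal(rank_scores(rep(0.7, 12), 4)$binned_means, rep(0.7, 4))
  rk <- rank_scores(runif(89700), 299)
  expect_equal(rk$bin_size, 300)
  expect_true(all(diff(rk$binned_means) >= 0))
  expect_error(rank_scores(runif(10), 3), "divide")
  expect_error(rank_scores(numeric(0), 3), "empty")
})

test_that("condition comparisons behave on degenerate and calibrated input", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  same <- compare_conditions(x, x)
  expect_equal(same$ks_statistic, 0)
  expect_gt(same$wilcoxon_p, 0.99)

  disjoint <- compare_conditions(1:50, 101:150)
  expect_equal(disjoint$ks_statistic, 1)
  expect_lt(disjoint$ks_p, 0.01)

  # type-I calibration: independent null samples rejected at ~alpha
  set.seed(99)
  reps <- 400
  rej <- matrix(FALSE, reps, 2)
  for (r in seq_len(reps)) {
    cc <- compare_conditions(rnorm(200), rnorm(200))
    rej[r, ] <- c(cc$ks_p, cc$wilcoxon_p) < 0.05
  }
  se <- 3 * sqrt(0.05 * 0.95 / reps) # ~0.033
  expect_lt(abs(mean(rej[, 1]) - 0.05), se + 0.02) # KS is conservative-discrete
  expect_lt(abs(mean(rej[, 2]) - 0.05), se)
})

test_that("telomere clouds subsample evenly spaced retained nuclei", {
  model <- toy_model(n_loci = 10, bond_nm = 20, persistence_nm = 100,
                     mode = "telomeres", nu = 5)
  ens <- run_chain(model, sampler_schedule(8000, 2000, thin = 20, seed = 3))
  cl <- telomere_cloud(ens, n_cells = ens$retained_count)
  expect_equal(nrow(cl$tel1), ens$retained_count)
  R <- model$geometry$radius_nm
  expect_equal(sqrt(rowSums(cl$tel1^2)), rep(R, nrow(cl$tel1)),
               tolerance = 1e-9)
  expect_equal(sqrt(rowSums(cl$tel2^2)), rep(R, nrow(cl$tel2)),
               tolerance = 1e-9)
  expect_error(telomere_cloud(ens, ens$retained_count + 1), "exceeds")
})
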