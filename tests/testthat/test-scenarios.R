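test_that("condition presets resolve names to the documented models", {
  tb <- make_condition("tight_bouquet", "chrI", 200, "desk", seed = 7)
  expect_equal(tb$model$tether$mode, "telomeres")
  expect_equal(tb$model$tether$nu, 50)
  expect_equal(tb$model$bending_modulus_kT, 200 / (2040 / 299))
  expect_equal(tb$schedule$thin, 40)
  expect_gte((tb$schedule$n_total - tb$schedule$n_burn_in) /
               tb$schedule$thin, 10000)

  nt <- make_condition("no_tether", "chrIV", 2000, "paper", seed = 1)
  expect_equal(nt$model$tether$mode, "none")
  expect_equal(nt$schedule$n_total, 1e7)
  expect_equal(nt$schedule$n_burn_in, 3e6)

  rb <- make_condition("rabl", "chrXVI", 200, "desk", seed = 3)
  expect_equal(rb$model$tether$mode, "centromere")
  expect_equal(rb$model$tether$nu, 50)
  expect_equal(rb$spec$centromere_index,
               round(556000 / 950000 * 299) + 1)

  # the nu ladder of the time-course vocabulary
  nus <- vapply(c("telomeres_tethered", "early_bouquet", "loose_bouquet",
                  "tight_bouquet"),
                function(cn) make_condition(cn, "chrI", 200)$model$tether$nu,
                numeric(1))
  expect_equal(unname(nus), c(0, 5, 10, 50))
  # intermediate clustering remains available as an explicit override
  expect_equal(make_condition("loose_bouquet", "chrI", 200,
                              nu = 20)$model$tether$nu, 20)

  expect_error(make_condition("bouquet_of_flowers", "chrI", 200), "arg")
  expect_error(make_condition("rabl", "chrII", 200), "arg")
})

test_that("homologue experiments are reproducible and correctly shaped", {
  sc <- list(n_total = 40000, n_burn_in = 12000, thin = 40)
  b1 <- run_homologue_experiment("tight_bouquet", "chrI", 200, scale = sc,
                                 seed = 5)
  b2 <- run_homologue_experiment("tight_bouquet", "chrI", 200, scale = sc,
                                 seed = 5)
  expect_identical(b1$allelic_profile, b2$allelic_profile)
  expect_identical(b1$map$values, b2$map$values)

  expect_equal(nrow(b1$allelic_profile), 300)
  expect_length(ectopic_means(b1$map), 89700)
  expect_equal(b1$ectopic_rank$bin_size, 300)
  expect_length(b1$ectopic_rank$binned_means, 299)
  expect_equal(nrow(b1$telomere_cloud$a$tel1), 500)
  expect_true(all(b1$map$values >= 0 & b1$map$values <= 1))

  # diagonal-only accumulation agrees with the full map's diagonal
  b3 <- run_homologue_experiment("tight_bouquet", "chrI", 200, scale = sc,
                                 seed = 5, full_map = FALSE)
  expect_equal(b3$allelic_profile$mean_nd, diag(b1$map$values))
  expect_equal(b3$allelic_profile$sd_nd, b1$map$diag_sd)
})

test_that("heterologue experiments cross two chromosomes in one nucleus", {
  sc <- list(n_total = 30000, n_burn_in = 9000, thin = 40)
  h <- run_heterologue_experiment("tight_bouquet", "chrI", "chrIV", 200,
                                  scale = sc, seed = 9)
  expect_equal(dim(h$map$values), c(300, 300))
  expect_equal(h$map$kind, "heterologue")
  expect_length(as.vector(h$map$values), 90000)
  expect_length(h$ectopic_rank$binned_means, 300)
  expect_equal(h$spec_a$name, "chrI")
  expect_equal(h$spec_b$name, "chrIV")

  # same-chromosome limit: the cross map is a homologue map in distribution
  hh <- run_heterologue_experiment("no_tether", "chrI", "chrI", 200,
                                   scale = sc, seed = 4)
  expect_equal(dim(hh$map$values), c(300, 300))
})

test_that("the time course runs the six conditions in fixed order", {
  sc <- list(n_total = 24000, n_burn_in = 8000, thin = 40)
  tc <- run_timecourse("chrI", 200, scale = sc, seed = 31)
  expect_identical(names(tc$bundles),
                   c("no_tether", "rabl", "telomeres_tethered",
                     "early_bouquet", "loose_bouquet", "tight_bouquet"))
  expect_identical(names(tc$comparisons),
                   c("rabl", "telomeres_tethered", "early_bouquet",
                     "loose_bouquet", "tight_bouquet"))
  cc <- tc$comparisons$rabl
  expect_true(is.finite(cc$ks_p) && cc$ks_p >= 0 && cc$ks_p <= 1)
  expect_true(is.finite(cc$wilcoxon_p))
})
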