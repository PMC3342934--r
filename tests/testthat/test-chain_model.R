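test_that("chromosome discretisation arithmetic is exact", {
  chrI <- chromosome_spec(240000, 151000)
  expect_equal(chrI$contour_length_nm, 2040)
  expect_equal(chrI$bond_length_nm, 2040 / 299)
  expect_equal(chrI$centromere_index, 189) # locus 189 of 300 (0-based 188)

  chrIV <- chromosome_spec(1530000, 450000)
  expect_equal(chrIV$contour_length_nm, 13005)

  # two-locus degenerate chain: a single rod, centromere at the first locus
  rod <- chromosome_spec(5000, 0, n_loci = 2)
  expect_equal(rod$bond_length_nm, rod$contour_length_nm)
  expect_equal(rod$centromere_index, 1)
})

test_that("discretisation is scale-consistent in genomic length", {
  for (L in c(1e5, 7.7e5, 2.4e6)) {
    a <- chromosome_spec(L, L / 3)
    b <- chromosome_spec(2 * L, 2 * L / 3)
    expect_identical(b$contour_length_nm, 2 * a$contour_length_nm)
    expect_identical(b$bond_length_nm, 2 * a$bond_length_nm)
  }
})

test_that("invalid chromosome specifications are rejected with diagnostics", {
  expect_error(chromosome_spec(-1, 0), "positive")
  expect_error(chromosome_spec(1000, 2000), "centromere_bp")
  expect_error(chromosome_spec(1000, 500, n_loci = 1), "n_loci")
  expect_error(nuclear_geometry(-5), "positive")
  expect_error(tether_spec("centromere", nu = -1), "nu")
  expect_error(tether_spec("sideways"), "arg")
})

test_that("initial conformations satisfy every hard constraint in all modes", {
  # many seeds, all three tether modes: rods equal, confinement respected,
  # tethered loci exactly on the nuclear surface
  for (mode in c("none", "centromere", "telomeres")) {
    model <- toy_model(n_loci = 40, bond_nm = 52, persistence_nm = 200,
                       mode = mode, nu = if (mode == "none") 0 else 20)
    for (seed in 1:334) {
      set.seed(seed)
      conf <- initialize_conformation(model)
      rep <- validate_conformation(conf, model)
      if (!rep$ok) fail(sprintf("mode %s seed %d: %s", mode, seed,
                                paste(names(Filter(function(ch) !ch$pass,
                                                   rep$checks)),
                                      collapse = ", ")))
    }
    succeed()
  }
})

test_that("initialization is deterministic given the seed", {
  model <- toy_model(n_loci = 50, bond_nm = 30, mode = "telomeres", nu = 5)
  set.seed(99); a <- initialize_conformation(model)
  set.seed(99); b <- initialize_conformation(model)
  expect_identical(unclass(a), unclass(b))
})

test_that("validation flags confinement and rod-length violations", {
  model <- toy_model(n_loci = 10, bond_nm = 10, radius_nm = 1000)
  conf <- straight_chain(10, 10)

  bad <- conf
  bad[5, ] <- c(1001, 0, 0)
  rep <- validate_conformation(as_conf(bad), model)
  expect_false(rep$checks$confinement$pass)
  expect_gt(rep$checks$confinement$max_excess_nm, 0.5)

  stretched <- conf
  stretched[10, 1] <- stretched[10, 1] + 0.1 # 1% longer final rod
  rep <- validate_conformation(as_conf(stretched), model)
  expect_false(rep$checks$rod_lengths$pass)
  expect_equal(rep$checks$rod_lengths$max_rel_deviation, 0.01)

  set.seed(1)
  fresh <- initialize_conformation(model)
  expect_true(validate_conformation(fresh, model)$ok)
})
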