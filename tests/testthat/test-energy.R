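test_that("bending energy matches closed forms on constructed chains", {
  model <- toy_model(n_loci = 6, bond_nm = 10, persistence_nm = 70)
  g <- model$bending_modulus_kT # 7

  expect_equal(bending_energy(as_conf(straight_chain(6, 10)), model), 0)

  # every consecutive rod pair perpendicular: staircase x,y,x,y,...
  stair <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(20, 10, 0),
                 c(20, 20, 0), c(30, 20, 0))
  expect_equal(bending_energy(as_conf(stair), model), g * 4) # N - 2 joints

  # single 180-degree reversal at one joint, remaining joints straight
  hairpin <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0), c(10, 0, 0),
                   c(0, 0, 0), c(-10, 0, 0))
  expect_equal(bending_energy(as_conf(hairpin), model), 2 * g)

  expect_error(bending_energy(as_conf(straight_chain(5, 10)), model),
               "locus count")
})

test_that("confinement is hard-core with an inclusive boundary", {
  geom <- nuclear_geometry(1000)
  inside <- as_conf(rbind(c(0, 0, 0), c(500, 0, 0)))
  expect_identical(confinement_energy(inside, geom), 0)
  out <- as_conf(rbind(c(0, 0, 0), c(1000.001, 0, 0)))
  expect_identical(confinement_energy(out, geom), Inf)
  boundary <- as_conf(rbind(c(0, 0, 0), c(1000, 0, 0)))
  expect_identical(confinement_energy(boundary, geom), 0)
})

test_that("clustering energy is the vMF potential of the tethered loci", {
  R <- 1000
  cen_model <- toy_model(n_loci = 9, bond_nm = 10, mode = "centromere",
                         nu = 50)
  cen <- cen_model$spec$centromere_index
  conf <- straight_chain(9, 10)
  conf[cen, ] <- c(0, 0, R) # tethered centromere exactly at the SPB
  expect_equal(clustering_energy(as_conf(conf), cen_model), -50)

  tel_model <- toy_model(n_loci = 9, bond_nm = 10, mode = "telomeres",
                         nu = 50)
  south <- straight_chain(9, 10)
  south[1, ] <- c(0, 0, -R) # both telomeres antipodal to the SPB
  south[9, ] <- c(0, 0, -R)
  expect_equal(clustering_energy(as_conf(south), tel_model), 100)

  nu0 <- toy_model(n_loci = 9, bond_nm = 10, mode = "telomeres", nu = 0)
  expect_identical(clustering_energy(as_conf(south), nu0), 0)

  none <- toy_model(n_loci = 9, bond_nm = 10, mode = "none")
  expect_error(clustering_energy(as_conf(south), none), "none")
})

test_that("excluded volume rejects close non-neighbours and nothing else", {
  model <- toy_model(n_loci = 20, bond_nm = 6.8, persistence_nm = 200,
                     excluded_volume = TRUE)
  conf <- straight_chain(20, 6.8)
  # straight chain: only contour neighbours are within 40 nm, all exempt
  expect_identical(excluded_volume_energy(as_conf(conf), model), 0)

  folded <- conf
  folded[15, ] <- conf[2, ] + c(0, 39, 0) # |i-j| = 13 > window, 39 nm apart
  expect_identical(excluded_volume_energy(as_conf(folded), model), Inf)

  off <- toy_model(n_loci = 20, bond_nm = 6.8, excluded_volume = FALSE)
  expect_identical(excluded_volume_energy(as_conf(folded), off), 0)
})

test_that("total energy is componentwise consistent and propagates Inf", {
  model <- toy_model(n_loci = 12, bond_nm = 15, persistence_nm = 60,
                     mode = "telomeres", nu = 7, radius_nm = 400)
  set.seed(3)
  conf <- initialize_conformation(model)
  e <- total_energy(conf, model)
  expect_equal(e$total_kT, e$bending_kT + e$confinement_kT + e$clustering_kT +
                 e$excluded_volume_kT)
  expect_equal(e$bending_kT, bending_energy(conf, model))
  expect_equal(e$clustering_kT, clustering_energy(conf, model))

  escaped <- unclass(conf)
  escaped[6, ] <- c(0, 0, 500)
  e2 <- total_energy(as_conf(escaped), model)
  expect_identical(e2$confinement_kT, Inf)
  expect_identical(e2$total_kT, Inf)

  flat <- toy_model(n_loci = 12, bond_nm = 15)
  e3 <- total_energy(as_conf(straight_chain(12, 15)), flat)
  expect_identical(e3$total_kT, 0)
})

test_that("energy is invariant under the model's rotational symmetries", {
  # untethered: any rigid rotation about the origin leaves the energy alone
  model <- toy_model(n_loci = 25, bond_nm = 20, persistence_nm = 100)
  set.seed(8)
  conf <- initialize_conformation(model)
  e0 <- total_energy(conf, model)$total_kT
  for (k in 1:5) {
    rot <- rigid_rotation_move(conf, rand_axis(), runif(1, -pi, pi))
    expect_equal(total_energy(rot, model)$total_kT, e0, tolerance = 1e-9)
  }

  # tethered and clustered: rotations about the SPB axis are still symmetries
  tb <- toy_model(n_loci = 25, bond_nm = 20, persistence_nm = 100,
                  mode = "telomeres", nu = 50)
  set.seed(9)
  conf <- initialize_conformation(tb)
  e0 <- total_energy(conf, tb)$total_kT
  for (ang in c(-2.1, 0.3, 1.7)) {
    rot <- rigid_rotation_move(conf, c(0, 0, 1), ang)
    expect_equal(total_energy(rot, tb)$total_kT, e0, tolerance = 1e-9)
  }
})

test_that("incremental sampler energies agree with full recomputation", {
  # 10,000 random moves per tether mode; worst discrepancy below 1e-8 kT
  for (mode in c("none", "centromere", "telomeres")) {
    model <- toy_model(n_loci = 60, bond_nm = 25, persistence_nm = 150,
                       mode = mode, nu = if (mode == "none") 0 else 30)
    set.seed(17)
    conf <- initialize_conformation(model)
    mix <- meioMC:::resolve_move_mix(mode)
    worst <- meioMC:::.delta_check_cpp(unclass(conf),
                                       meioMC:::model_for_cpp(model),
                                       10000L, mix, pi / 3)
    expect_lt(worst, 1e-8)
  }
})
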