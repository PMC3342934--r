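test_that("crankshaft rotations preserve chain geometry exactly", {
  model <- toy_model(n_loci = 20, bond_nm = 30, persistence_nm = 90)
  set.seed(4)
  conf <- initialize_conformation(model)
  b <- model$spec$bond_length_nm

  expect_equal(unclass(crankshaft_move(conf, 3, 11, 0)), unclass(conf))
  expect_equal(unclass(crankshaft_move(conf, 3, 11, 2 * pi)), unclass(conf),
               tolerance = 1e-12)

  for (k in 1:20) {
    i <- sample(1:17, 1); j <- sample((i + 2):20, 1)
    prop <- crankshaft_move(conf, i, j, runif(1, -pi, pi))
    expect_equal(prop[c(i, j), ], unclass(conf)[c(i, j), ]) # endpoints fixed
    out <- setdiff(1:20, i:j)
    expect_equal(prop[out, ], unclass(conf)[out, ])
    expect_equal(rod_lengths(prop), rod_lengths(conf), tolerance = 1e-12)
  }

  # coincident endpoint positions give a degenerate axis: rejected as no-op
  pinched <- unclass(conf)
  pinched[9, ] <- pinched[2, ]
  expect_null(crankshaft_move(as_conf(pinched), 2, 9, 1))
})

test_that("pivot, arm and rigid rotations preserve the right invariants", {
  model <- toy_model(n_loci = 15, bond_nm = 40, persistence_nm = 120,
                     mode = "telomeres", nu = 10)
  set.seed(5)
  conf <- initialize_conformation(model)

  expect_equal(unclass(pivot_move(conf, 7, 0)), unclass(conf))
  # pivot at the penultimate locus moves only the terminal locus
  prop <- pivot_move(conf, 14, 0.8, "right")
  expect_equal(prop[1:14, ], unclass(conf)[1:14, ])
  expect_false(isTRUE(all.equal(prop[15, ], unclass(conf)[15, ])))
  expect_equal(rod_lengths(prop), rod_lengths(conf), tolerance = 1e-12)

  # arm rotation: norms preserved for every locus, rods preserved
  arm <- arm_rotation_move(conf, 6, 1.3, "right")
  expect_equal(sqrt(rowSums(arm^2)), sqrt(rowSums(unclass(conf)^2)),
               tolerance = 1e-12)
  expect_equal(rod_lengths(arm), rod_lengths(conf), tolerance = 1e-12)
  expect_equal(arm[1:6, ], unclass(conf)[1:6, ])

  # rigid rotation: bending unchanged; antipodal telomere flip costs +2 nu each
  rot <- rigid_rotation_move(conf, rand_axis(), runif(1, -pi, pi))
  expect_equal(bending_energy(rot, model), bending_energy(conf, model),
               tolerance = 1e-9)
  about_spb <- rigid_rotation_move(conf, c(0, 0, 1), 2.2)
  expect_equal(clustering_energy(about_spb, model),
               clustering_energy(conf, model), tolerance = 1e-9)
})

test_that("the acceptance rule matches the Boltzmann factor", {
  # +1 kT proposals must be accepted at rate exp(-1) (binomial, 3 SE)
  set.seed(42)
  n <- 1e5
  hits <- sum(vapply(seq_len(n),
                     function(i) meioMC:::metropolis_accept(1, beta = 1),
                     logical(1)))
  p <- exp(-1)
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
  expect_true(meioMC:::metropolis_accept(0))    # dE = 0 always accepted
  expect_true(meioMC:::metropolis_accept(-3))
  expect_false(meioMC:::metropolis_accept(Inf)) # infeasible always rejected
})

test_that("single reference Metropolis steps keep the state feasible", {
  model <- toy_model(n_loci = 12, bond_nm = 30, persistence_nm = 60,
                     mode = "telomeres", nu = 5, radius_nm = 500)
  sched <- sampler_schedule(100, 50, seed = 1)
  set.seed(11)
  conf <- initialize_conformation(model)
  for (k in 1:100) {
    st <- metropolis_step(conf, model, sched)
    conf <- st$conformation
  }
  expect_true(validate_conformation(conf, model)$ok)
})

test_that("run_chain is deterministic and honours the schedule bookkeeping", {
  model <- toy_model(n_loci = 25, bond_nm = 30, persistence_nm = 90,
                     mode = "telomeres", nu = 10)
  sched <- sampler_schedule(20000, 6000, thin = 40, seed = 7)
  a <- run_chain(model, sched)
  b <- run_chain(model, sched)
  expect_identical(a$positions, b$positions)
  expect_equal(a$retained_count, floor((20000 - 6000) / 40))

  one <- run_chain(model, sampler_schedule(640, 600, thin = 40, seed = 2))
  expect_equal(one$retained_count, 1)

  # every retained conformation satisfies the hard constraints
  for (k in seq_len(a$retained_count))
    expect_true(validate_conformation(ensemble_conformation(a, k), model)$ok)
})

test_that("the stationary distribution matches the Boltzmann weights", {
  # 4-locus unconfined chain: the two joint cosines are iid with density
  # proportional to exp(g cos); chi-squared test of the binned MCMC marginal
  # against the exact bin probabilities
  spec <- spec_with_bond(4, 50)
  model <- energy_model(spec, persistence_nm = 50, # g*beta = 1
                        geometry = nuclear_geometry(1e6))
  ens <- run_chain(model, sampler_schedule(6e5, 1e5, thin = 50, seed = 123))
  rods <- ens$positions[2:4, , ] - ens$positions[1:3, , ]
  len <- sqrt(rods[, 1, ]^2 + rods[, 2, ]^2 + rods[, 3, ]^2)
  cosj <- (rods[1, 1, ] * rods[2, 1, ] + rods[1, 2, ] * rods[2, 2, ] +
             rods[1, 3, ] * rods[2, 3, ]) / (len[1, ] * len[2, ])
  cosj <- c(cosj, (rods[2, 1, ] * rods[3, 1, ] + rods[2, 2, ] * rods[3, 2, ] +
                     rods[2, 3, ] * rods[3, 3, ]) / (len[2, ] * len[3, ]))
  breaks <- seq(-1, 1, length.out = 11)
  counts <- table(cut(cosj, breaks, include.lowest = TRUE))
  g <- model$bending_modulus_kT
  probs <- diff(exp(g * breaks)) / (exp(g) - exp(-g))
  pval <- suppressWarnings(stats::chisq.test(as.vector(counts),
                                             p = probs)$p.value)
  expect_gt(pval, 0.01)
})
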