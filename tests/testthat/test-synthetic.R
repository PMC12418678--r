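test_that("X-H bond normalization moves only hydrogens along the bond", {
  ## C-H of 0.95 A along +x -> H at 1.09 A along +x
  g <- molecule_geometry(c("C", "H"), rbind(c(0, 0, 0), c(0.95, 0, 0)),
                         bonds = rbind(c(1, 2)))
  g2 <- normalize_xh_bonds(g, target_lengths = c(C = 1.09))
  expect_equal(g2$pos[2, ] * hcfit:::BOHR_A, c(1.09, 0, 0), tolerance = 1e-12)
  expect_identical(g2$pos[1, ], g$pos[1, ])
  ## direction preserved for an oblique bond
  g3 <- molecule_geometry(c("O", "H"), rbind(c(0, 0, 0), c(0.6, 0.6, 0.3)),
                          bonds = rbind(c(1, 2)))
  g4 <- normalize_xh_bonds(g3)
  d0 <- g3$pos[2, ] / sqrt(sum(g3$pos[2, ]^2))
  d1 <- g4$pos[2, ] / sqrt(sum(g4$pos[2, ]^2))
  expect_lt(max(abs(d0 - d1)), 1e-12)
  ## H with two bonds is a geometry error
  gb <- molecule_geometry(c("C", "H", "C"),
                          rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                          bonds = rbind(c(1, 2), c(2, 3)))
  expect_error(normalize_xh_bonds(gb), class = "hcfit_geometry_error")
})

test_that("ground-truth sampling is seeded and charge-consistent", {
  for (g in c("water", "ammonia", "alanine", "mghex")) {
    sp <- synthetic_spec(g, seed = 99)
    m1 <- sample_ground_truth(sp)
    m2 <- sample_ground_truth(sp)
    expect_identical(pack_parameters(m1), pack_parameters(m2))
    m3 <- sample_ground_truth(synthetic_spec(g, seed = 100))
    expect_false(identical(pack_parameters(m1), pack_parameters(m3)))
    ## total electrons: sum(Z) - net charge, exactly
    tot <- sum(vapply(m1$atoms, analytic_atom_charge, numeric(1), model = m1))
    expect_equal(tot, sum(m1$geometry$Z) - m1$geometry$net_charge,
                 tolerance = 1e-10)
    ## kappa draws inside the configured range
    for (a in m1$atoms) {
      expect_true(a$kappa >= sp$kappa_range[1] && a$kappa <= sp$kappa_range[2])
      expect_true(a$kappa_prime >= sp$kappa_range[1] &&
                    a$kappa_prime <= sp$kappa_range[2])
    }
  }
})

test_that("bond bumps are charge-neutral and peak at bond midpoints", {
  sp <- synthetic_spec("water", seed = 5, bump_amplitude = 0.08)
  truth <- sample_ground_truth(sp)
  ref <- add_nonrepresentable(truth, sp)
  expect_equal(sum(ref$bumps$q), 0, tolerance = 1e-14)
  ## grid integral of the perturbation alone vanishes
  spec <- centered_grid(truth$geometry, n = 64, pad = 6)
  pert <- density_field(ref, spec)$values -
    density_field(truth, spec)$values
  expect_lt(abs(sum(pert) * spec$step^3), 1e-6)
  ## maximum on a bond midpoint
  p <- grid_points(spec)
  i <- which.max(pert)
  mid <- (truth$geometry$pos[1, ] + truth$geometry$pos[2, ]) / 2
  mid2 <- (truth$geometry$pos[1, ] + truth$geometry$pos[3, ]) / 2
  dmin <- min(sqrt(sum((p[i, ] - mid)^2)), sqrt(sum((p[i, ] - mid2)^2)))
  expect_lt(dmin, spec$step * sqrt(3))
  ## amplitude zero means reference == truth everywhere
  sp0 <- synthetic_spec("water", seed = 5, bump_amplitude = 0)
  ref0 <- add_nonrepresentable(sample_ground_truth(sp0), sp0)
  expect_null(ref0$bumps)
})

test_that("case generation is deterministic and internally consistent", {
  sp <- synthetic_spec("ammonia", seed = 3)
  c1 <- generate_case(sp, a = 8, s_max = 0.4, friedel_unique = TRUE)
  c2 <- generate_case(sp, a = 8, s_max = 0.4, friedel_unique = TRUE)
  expect_identical(c1$F_target$F, c2$F_target$F)
  ## with bumps the reference differs from the truth-model density
  spec <- centered_grid(c1$geometry, n = 32, pad = 5)
  dref <- density_field(c1$reference, spec)
  dtru <- density_field(c1$truth_model, spec)
  expect_gt(max(abs(dref$values - dtru$values)), 0)
  ## without bumps the reference is exactly the truth model
  sp0 <- synthetic_spec("ammonia", seed = 3, nonrepresentable = FALSE)
  c0 <- generate_case(sp0, a = 8, s_max = 0.4, friedel_unique = TRUE)
  d0 <- density_field(c0$reference, spec)
  dt0 <- density_field(c0$truth_model, spec)
  expect_identical(d0$values, dt0$values)
})

test_that("case bundles round-trip through the directory format", {
  sp <- synthetic_spec("water", seed = 8)
  cs <- generate_case(sp, grid = grid_spec(c(-6, -6, -6), 1, 13),
                      a = 8, s_max = 0.35, friedel_unique = TRUE)
  d <- file.path(tempdir(), "bundle-test")
  write_case_bundle(cs, d)
  expect_true(all(file.exists(file.path(d,
    c("geometry.xyz", "truth_model.txt", "f_target.txt",
      "reference_density.cube", "reference_esp.cube", "manifest.json")))))
  g2 <- read_xyz(file.path(d, "geometry.xyz"))
  expect_equal(g2$pos, cs$geometry$pos, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(nrow(g2$bonds), nrow(cs$geometry$bonds))
  sf2 <- read_sf(file.path(d, "f_target.txt"))
  expect_equal(sf2$F, cs$F_target$F, tolerance = 1e-15)
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  expect_equal(man$seed, 8)
})
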