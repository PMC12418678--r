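test_that("grid construction honours the cube convention", {
  spec <- grid_spec(c(0, 0, 0), 0.5, 2)
  g <- make_grid(spec)
  expect_equal(g$n_points, 8)
  pts <- grid_points(spec)
  expect_equal(nrow(pts), 8L)
  ## corners of the cube, z fastest
  expect_equal(pts[1, ], c(0, 0, 0))
  expect_equal(pts[2, ], c(0, 0, 0.5))
  expect_equal(pts[8, ], c(0.5, 0.5, 0.5))
  expect_error(grid_spec(c(0, 0, 0), 0.5, 1), class = "hcfit_domain_error")
  expect_error(grid_spec(c(0, 0, 0), -0.1, 4), class = "hcfit_domain_error")
})

test_that("density fields integrate to the model electron count", {
  m <- perturbed_water()
  ## near the reference step (0.09 bohr) even the 1s core is
  ## quadrature-accurate
  spec <- centered_grid(m$geometry, n = 160, pad = 6)
  f_all <- density_field(m, spec)
  f_val <- density_field(m, spec, include_core = FALSE)
  ne <- sum(vapply(m$atoms, analytic_atom_charge, numeric(1), model = m))
  expect_lt(abs(field_integral(f_val) - (ne - 2)) / (ne - 2), 0.002)
  expect_lt(abs(field_integral(f_all) - ne) / ne, 0.01)
  ## dropping the cores removes the core electron count (2 for O)
  expect_lt(abs(field_integral(f_all) - field_integral(f_val) - 2), 0.02)
  ## difference maps are exact linear field arithmetic
  dif <- field_subtract(f_all, f_val)
  expect_identical(dif$values, f_all$values - f_val$values)
})

test_that("electrostatic potential has Coulombic limits", {
  ## bare nucleus: Z / r
  g <- molecule_geometry("H", matrix(0, 1, 3), units = "bohr")
  m <- molecule_model(g, bank = "hydrogenic-test", h_bond_oriented = FALSE)
  m$atoms[[1]]$P_val <- 0  # strip the electron
  expect_equal(model_esp(m, matrix(c(2, 0, 0), 1, 3)), 0.5, tolerance = 1e-10)
  ## neutral atom is screened at long range
  m$atoms[[1]]$P_val <- 1
  expect_lt(abs(model_esp(m, matrix(c(40, 0, 0), 1, 3))), 1e-6)
  ## far field of a net-positive model is positive
  m$atoms[[1]]$P_val <- 0.5
  expect_gt(model_esp(m, matrix(c(15, 0, 0), 1, 3)), 0)
})

test_that("ESP satisfies the Poisson equation against the density", {
  ## finite-difference Laplacian of V vs -4 pi rho_total on a fine grid,
  ## away from the nucleus (multipoles included)
  m <- perturbed_water()
  h <- 0.02
  ctr <- c(0.9, 0.4, -0.3)
  offs <- rbind(c(0, 0, 0), h * diag(3), -h * diag(3))
  pts <- sweep(offs, 2, ctr, `+`)
  V <- model_esp(m, pts)
  lap <- (sum(V[2:7]) - 6 * V[1]) / h^2
  rho_e <- model_density(m, matrix(ctr, 1, 3))  # electrons, positive
  expect_lt(abs(lap - 4 * pi * rho_e) / (4 * pi * rho_e), 5e-3)
})

test_that("direct-sum ESP of a gridded density approximates the analytic ESP", {
  g1 <- molecule_geometry("H", matrix(0, 1, 3), units = "bohr")
  m1 <- make_iam(molecule_model(g1, bank = "hydrogenic-test",
                                h_bond_oriented = FALSE))
  spec <- grid_spec_centered(g1, 0.5, 24)
  dfield <- density_field(m1, spec)
  pts <- matrix(c(3, 0, 0, 0, 4, 0), 2, 3, byrow = TRUE)
  got <- esp_direct_sum(dfield, g1, pts)
  want <- model_esp(m1, pts)
  expect_lt(max(abs(got - want)), 0.02)
})

test_that("cube files round-trip bit-identically", {
  m <- perturbed_water()
  spec <- centered_grid(m$geometry, n = 12, pad = 4)
  fld <- esp_field(m, spec)
  f <- tempfile(fileext = ".cube")
  write_cube(fld, f, geom = m$geometry, sidecar = TRUE)
  fld2 <- read_cube(f)
  expect_identical(fld2$values, fld$values)
  expect_equal(fld2$spec$origin, fld$spec$origin, tolerance = 1e-10)
  expect_equal(fld2$spec$step, fld$spec$step, tolerance = 1e-14)
  expect_identical(fld2$kind, "esp")
  expect_true(file.exists(paste0(f, ".json")))
  ## truncated value block is rejected
  lines <- readLines(f)
  writeLines(lines[1:(length(lines) - 40)], f)
  expect_error(read_cube(f), class = "hcfit_parse_error")
})

test_that("density and ESP fields share one point enumeration", {
  ## a delta-like source (tight Gaussian bump reference) peaks at the
  ## same linear index in both fields
  g <- molecule_geometry(c("H", "H"), rbind(c(-0.7, 0, 0), c(0.7, 0, 0)),
                         bonds = rbind(c(1, 2)), units = "bohr")
  truth <- molecule_model(g, bank = "hydrogenic-test",
                          h_bond_oriented = FALSE)
  sp <- synthetic_spec("water", seed = 1, bump_amplitude = 2, bump_width = 0.12)
  ref <- add_nonrepresentable(truth, sp)
  spec <- grid_spec_centered(g, 0.25, 25)  # odd n: midpoint on-grid
  fd <- density_field(ref, spec)
  fv <- esp_field(ref, spec)
  ## the electron blob is the density maximum and the ESP minimum, at
  ## the same linear index under the shared enumeration
  expect_equal(which.max(fd$values), which.min(fv$values))
})
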