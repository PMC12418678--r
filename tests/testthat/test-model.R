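test_that("density-normalized harmonics integrate |d_lm| to 2", {
  for (l in 1:4) for (m in 0:l) for (s in if (m == 0) "+" else c("+", "-")) {
    ## Lebedev-free check: product quadrature over the sphere
    nt <- 400; np <- 400
    ct <- seq(-1 + 1 / nt, 1 - 1 / nt, length.out = nt)
    ph <- seq(0, 2 * pi, length.out = np + 1)[-1]
    st <- sqrt(1 - ct^2)
    ux <- outer(st, cos(ph)); uy <- outer(st, sin(ph))
    uz <- matrix(ct, nt, np)
    v <- hcfit:::dlm_eval(l, m, s, as.vector(ux), as.vector(uy), as.vector(uz))
    integ <- sum(abs(v)) * (2 / nt) * (2 * pi / np)
    expect_lt(abs(integ - 2), 0.01)
  }
})

test_that("local frames are orthonormal and bond-oriented for hydrogens", {
  geom <- builtin_geometry("water")
  fr <- build_local_frames(geom)
  for (f in fr) {
    expect_lt(max(abs(crossprod(f$R) - diag(3))), 1e-10)
    expect_gt(det(f$R), 0)  # right-handed by default
  }
  ## H local z points from H to O
  for (i in 2:3) {
    zax <- fr[[i]]$R[, 3]
    dir <- (geom$pos[1, ] - geom$pos[i, ])
    expect_lt(max(abs(zax - dir / sqrt(sum(dir^2)))), 1e-12)
  }
  ## isolated hydrogen cannot get a bond-oriented frame
  lone <- molecule_geometry("H", matrix(0, 1, 3), units = "bohr")
  expect_error(build_local_frames(lone), class = "hcfit_frame_error")
})

test_that("parameter vector packs ties once and round-trips exactly", {
  m <- perturbed_water()
  p <- pack_parameters(m)
  ## the two equivalent hydrogens share one parameter set
  expect_false(any(grepl("^3:", names(p))))
  m2 <- unpack_parameters(m, p)
  expect_identical(pack_parameters(m2), p)
  ## bond-oriented H carries only m = 0 terms up to l = 2
  expect_identical(sort(names(m$atoms[[2]]$Plm)), sort(c("1,0,+", "2,0,+")))
  ## random round trip
  set.seed(5)
  p3 <- p + runif(length(p), -0.01, 0.01)
  expect_identical(unname(pack_parameters(unpack_parameters(m, p3))),
                   unname(p3))
  ## inconsistent tied values are rejected at pack time
  m_bad <- m
  m_bad$atoms[[2]]$P_val <- m_bad$atoms[[2]]$P_val + 0.1
  expect_error(pack_parameters(m_bad), class = "hcfit_constraint_error")
})

test_that("atom density reduces to spherical terms and scales as kappa^3", {
  geom <- molecule_geometry("O", matrix(0, 1, 3), units = "bohr")
  m <- molecule_model(geom, h_bond_oriented = FALSE)
  e <- m$bank$entries$O
  r <- c(0.4, 1, 2)
  pts <- cbind(r, 0, 0)
  ## all P_lm zero, kappa 1: core + valence spherical densities
  expect_close(model_density(m, pts),
               spherical_density(e, "core", r) + spherical_density(e, "valence", r),
               1e-12)
  ## kappa^3 rho(kappa r) scaling of the valence term
  m2 <- m; m2$atoms[[1]]$kappa <- 2
  v2 <- model_density(m2, pts, include_core = FALSE)
  expect_close(v2, 8 * spherical_density(e, "valence", 2 * r), 1e-12)
  ## dipole term is antisymmetric under z -> -z
  m3 <- m; m3$atoms[[1]]$Plm["1,0,+"] <- 0.3
  zp <- matrix(c(0, 0, 0.8), 1, 3); zm <- -zp
  dif <- model_density(m3, zp) - model_density(m3, zm)
  expect_close(dif,
               2 * 0.3 * deformation_radial(e, 1, 0.8) *
                 hcfit:::dlm_eval(1, 0, "+", 0, 0, 1),
               1e-12)
})

test_that("analytic atom charges obey spherical-harmonic orthogonality", {
  m <- perturbed_water()
  a <- m$atoms[[1]]
  base <- analytic_atom_charge(a, m)
  expect_equal(base, 2 * a$P_core + a$P_val, tolerance = 1e-12)
  a$Plm["2,1,+"] <- 0.3  # l >= 1 terms integrate to zero
  expect_equal(analytic_atom_charge(a, m), base, tolerance = 1e-12)
  ## molecule electron count bookkeeping
  tot <- sum(vapply(m$atoms, analytic_atom_charge, numeric(1), model = m))
  expect_equal(tot, sum(m$geometry$Z) - m$geometry$net_charge,
               tolerance = 1e-9)
  ## quadrature agreement on a grid fine enough for the 1s cores
  spec <- centered_grid(m$geometry, n = 160, pad = 6)
  expect_lt(abs(field_integral(density_field(m, spec)) - tot) / tot, 0.005)
})

test_that("make_iam resets to neutral spherical atoms and is idempotent", {
  m <- perturbed_water()
  iam <- make_iam(m)
  for (a in iam$atoms) {
    expect_equal(a$kappa, 1)
    expect_equal(a$kappa_prime, 1)
    expect_true(all(a$Plm == 0))
  }
  expect_equal(iam$atoms[[1]]$P_val, 6)
  expect_identical(make_iam(iam), iam)
  ## IAM one-atom density is spherically symmetric
  g1 <- molecule_geometry("C", matrix(0, 1, 3), units = "bohr")
  m1 <- make_iam(molecule_model(g1, h_bond_oriented = FALSE))
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3),
                c(-0.3, 0.4, sqrt(0.75)))
  for (r in c(0.5, 1.5)) {
    v <- model_density(m1, r * dirs)
    expect_lt(diff(range(v)), 1e-12)
  }
})

test_that("densities are invariant under joint rotation of geometry and frames", {
  m <- perturbed_water()
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- R %*% matrix(c(1, 0, 0, 0, cos(0.4), sin(0.4), 0, -sin(0.4), cos(0.4)), 3, 3)
  m_rot <- m
  m_rot$geometry$pos <- m$geometry$pos %*% t(R2)
  for (i in seq_along(m$atoms))
    m_rot$atoms[[i]]$frame$R <- R2 %*% m$atoms[[i]]$frame$R
  pts <- matrix(rnorm(60, sd = 1.5), 20, 3)
  expect_close(model_density(m_rot, pts %*% t(R2)), model_density(m, pts), 1e-10)
})

test_that("model parameter files round-trip", {
  m <- perturbed_water()
  f <- tempfile()
  write_model_params(m, f)
  m2 <- read_model_params(f, m$geometry, m$bank)
  expect_equal(pack_parameters(m2), pack_parameters(m), tolerance = 1e-15)
})
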