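make_field <- function(values, spec) hcfit:::new_scalar_field(spec, "esp", values)

test_that("Pearson correlation matches hand values and affine invariance", {
  spec <- grid_spec(c(0, 0, 0), 1, 2)
  pad <- rep(0, 5)
  a <- make_field(c(1, 2, 3, pad), spec)
  b <- make_field(c(1, 2, 4, pad), spec)
  ## hand evaluation on the informative points is polluted by the padding
  ## zeros here, so use plain 3-vectors through the same code path
  expect_equal(cor(c(1, 2, 3), c(1, 2, 4)), 9 / (2 * sqrt(21)),
               tolerance = 1e-12)
  expect_equal(pearson_cc(a, a), 1.0)
  neg <- make_field(-a$values, spec)
  expect_equal(pearson_cc(a, neg), -1.0)
  ## positive affine transforms leave CC unchanged
  aff <- make_field(2.5 * b$values + 0.7, spec)
  expect_equal(pearson_cc(a, aff), pearson_cc(a, b), tolerance = 1e-12)
  expect_error(pearson_cc(a, make_field(rep(1, 8), spec)),
               class = "hcfit_degenerate_error")
  spec2 <- grid_spec(c(0, 0, 0), 2, 2)
  expect_error(pearson_cc(a, make_field(b$values, spec2)),
               class = "hcfit_alignment_error")
})

test_that("error metrics match the defining formulas", {
  em <- error_metrics(c(1, -1, 2), c(0, 0, 0))
  expect_equal(em[["me"]], 2 / 3, tolerance = 1e-14)
  expect_equal(em[["mae"]], 4 / 3, tolerance = 1e-14)
  expect_equal(em[["rmse"]], sqrt(2), tolerance = 1e-14)
  expect_equal(unname(error_metrics(c(3, 1), c(3, 1))), c(0, 0, 0))
  expect_error(error_metrics(1:3, 1:2), class = "hcfit_alignment_error")
  ## |ME| <= MAE <= RMSE on random inputs
  set.seed(7)
  for (i in 1:200) {
    em <- error_metrics(rnorm(17), rnorm(17))
    expect_true(abs(em[["me"]]) <= em[["mae"]] + 1e-14)
    expect_true(em[["mae"]] <= em[["rmse"]] + 1e-14)
  }
})

## analytic two-Gaussian density used for basin tests
two_gaussian_field <- function(n = 48, w = c(1.0, 1.4), A = c(1, 0.55),
                               sep = 3.2) {
  spec <- grid_spec(c(-6, -6, -6), 12 / (n - 1), n)
  p <- grid_points(spec)
  c1 <- c(-sep / 2, 0, 0); c2 <- c(sep / 2, 0, 0)
  d1 <- (p[, 1] - c1[1])^2 + p[, 2]^2 + p[, 3]^2
  d2 <- (p[, 1] - c2[1])^2 + p[, 2]^2 + p[, 3]^2
  vals <- A[1] * exp(-d1 / w[1]^2) + A[2] * exp(-d2 / w[2]^2)
  geom <- molecule_geometry(c("H", "H"), rbind(c1, c2), units = "bohr")
  list(field = hcfit:::new_scalar_field(spec, "density", vals),
       geom = geom, centers = rbind(c1, c2), w = w, A = A)
}

test_that("basin assignment matches a trajectory-integration oracle", {
  tg <- two_gaussian_field()
  bm <- assign_basins(tg$field, tg$geom)
  expect_equal(nrow(bm$attractors), 2L)
  expect_equal(sort(bm$attractors$atom), c(1L, 2L))
  ## oracle: analytic gradient ascent from every voxel above the floor
  p <- grid_points(tg$field$spec)
  act <- which(!bm$escaped)
  x <- p[act, , drop = FALSE]
  grad <- function(x) {
    g <- matrix(0, nrow(x), 3)
    for (i in 1:2) {
      d <- sweep(x, 2, tg$centers[i, ])
      e <- tg$A[i] * exp(-rowSums(d^2) / tg$w[i]^2)
      g <- g - 2 * d * e / tg$w[i]^2
    }
    g
  }
  for (it in 1:400) {
    g <- grad(x)
    gn <- sqrt(rowSums(g^2))
    x <- x + 0.05 * g / pmax(gn, 1e-12)
  }
  oracle <- ifelse((x[, 1] - tg$centers[1, 1])^2 + x[, 2]^2 + x[, 3]^2 <
                     (x[, 1] - tg$centers[2, 1])^2 + x[, 2]^2 + x[, 3]^2,
                   1L, 2L)
  got <- bm$attractors$atom[bm$label[act]]
  expect_gt(mean(got == oracle), 0.995)
})

test_that("unified-basin integration conserves charge and vanishes on itself", {
  tg <- two_gaussian_field(n = 40)
  bm <- assign_basins(tg$field, tg$geom)
  pops <- integrate_basins(bm, tg$field, tg$field)
  expect_true(all(pops$delta == 0))
  tot <- attr(pops, "total")
  expect_equal(tot[["N"]], field_integral(tg$field), tolerance = 1e-12)
  expect_equal(sum(pops$N), field_integral(tg$field), tolerance = 1e-12)
  ## symmetric dimer splits evenly
  sym <- two_gaussian_field(n = 40, w = c(1, 1), A = c(1, 1))
  bs <- assign_basins(sym$field, sym$geom)
  ps <- integrate_basins(bs, sym$field, sym$field)
  expect_lt(abs(ps$N[1] - ps$N[2]), 1e-10)
  ## a perturbed density integrated over the same basins
  pert <- hcfit:::new_scalar_field(tg$field$spec, "density",
                                   tg$field$values * 1.01)
  pp <- integrate_basins(bm, pert, tg$field)
  expect_equal(sum(pp$N), 1.01 * sum(pops$N), tolerance = 1e-12)
  expect_error(integrate_basins(bm, pert,
                                hcfit:::new_scalar_field(
                                  grid_spec(c(0, 0, 0), 1, 40), "density",
                                  pert$values)),
               class = "hcfit_alignment_error")
})

test_that("isosurface of a Gaussian has the closed-form radius and area", {
  n <- 96
  spec <- grid_spec(rep(-4, 3), 8 / (n - 1), n)
  p <- grid_points(spec)
  fld <- hcfit:::new_scalar_field(spec, "density", exp(-rowSums(p^2)))
  mesh <- extract_isosurface(fld, 0.1)
  r_exp <- sqrt(log(10))
  r_got <- sqrt(rowSums(mesh$centroid^2))
  expect_lt(max(abs(r_got - r_exp)), 0.01)
  expect_lt(abs(sum(mesh$area) - 4 * pi * r_exp^2) / (4 * pi * r_exp^2), 0.02)
  ## refining the grid reduces the area error
  n2 <- 192
  spec2 <- grid_spec(rep(-4, 3), 8 / (n2 - 1), n2)
  p2 <- grid_points(spec2)
  fld2 <- hcfit:::new_scalar_field(spec2, "density", exp(-rowSums(p2^2)))
  mesh2 <- extract_isosurface(fld2, 0.1)
  err1 <- abs(sum(mesh$area) - 4 * pi * r_exp^2)
  err2 <- abs(sum(mesh2$area) - 4 * pi * r_exp^2)
  expect_lt(err2, err1)
  expect_error(extract_isosurface(fld, 2),
               class = "hcfit_empty_surface_error")
})

test_that("surface-averaged ESP has Coulombic and parity limits", {
  n <- 80
  spec <- grid_spec(rep(-4, 3), 8 / (n - 1), n)
  p <- grid_points(spec)
  dens <- hcfit:::new_scalar_field(spec, "density", exp(-rowSums(p^2) / 4))
  ## level chosen so the iso-sphere has radius 2
  mesh <- extract_isosurface(dens, exp(-1))
  ## constant field averages to itself
  cf <- hcfit:::new_scalar_field(spec, "esp", rep(1.7, n^3))
  expect_equal(surface_average_esp(mesh, cf)$mean, 1.7, tolerance = 1e-12)
  ## unit point charge at the centre: mean V = q / r = 0.5
  r <- pmax(sqrt(rowSums(p^2)), 1e-6)
  pc <- hcfit:::new_scalar_field(spec, "esp", 1 / r)
  s <- surface_average_esp(mesh, pc)
  expect_lt(abs(s$mean - 0.5), 0.005)
  expect_true(s$min <= s$mean && s$mean <= s$max)
  ## point dipole: odd parity cancels
  dip <- hcfit:::new_scalar_field(spec, "esp", p[, 3] / pmax(r, 0.5)^3)
  expect_lt(abs(surface_average_esp(mesh, dip)$mean), 2e-3)
  ## weighted and unweighted means agree on a smooth case
  expect_lt(abs(surface_average_esp(mesh, pc, weighted = FALSE)$mean - 0.5),
            0.005)
  ## meshes outside the grid are rejected
  small <- grid_spec(rep(-1, 3), 2 / (n - 1), n)
  expect_error(surface_average_esp(mesh,
                                   hcfit:::new_scalar_field(small, "esp",
                                                            rep(1, n^3))),
               class = "hcfit_bounds_error")
})

test_that("meshes export to OBJ", {
  tg <- two_gaussian_field(n = 24)
  mesh <- extract_isosurface(tg$field, 0.3)
  f <- tempfile(fileext = ".obj")
  write_obj(mesh, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^v ", lines)), 3 * nrow(mesh$tri))
  expect_equal(sum(grepl("^f ", lines)), nrow(mesh$tri))
})
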