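## Scalar fields (electron density, electrostatic potential) on cubic
## grids, plus Gaussian cube I/O.
##
## Grid convention follows the cube format: isotropic step, x slowest /
## z fastest point enumeration, edge length step * (npoints - 1).
## Atomic units throughout: density e bohr^-3, ESP hartree e^-1.

#' Cubic grid specification
#'
#' @param origin grid corner, bohr (length-3).
#' @param step isotropic spacing, bohr.
#' @param npoints points per axis (>= 2); the edge spans
#'   `step * (npoints - 1)`.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(origin, step, npoints) {
  if (step <= 0) stop_hc("step must be positive", class = "hcfit_domain_error")
  npoints <- as.integer(npoints)
  if (npoints < 2L) stop_hc("npoints must be >= 2", class = "hcfit_domain_error")
  structure(list(origin = as.numeric(origin), step = step, npoints = npoints),
            class = "grid_spec")
}

#' Grid centered on a geometry's centroid
#'
#' @param geom `mol_geometry` (or a length-3 center, bohr).
#' @param step spacing in bohr.
#' @param npoints points per axis.
#' @export
grid_spec_centered <- function(geom, step, npoints) {
  ctr <- if (inherits(geom, "mol_geometry")) colMeans(geom$pos) else as.numeric(geom)
  edge <- step * (npoints - 1)
  grid_spec(ctr - edge / 2, step, npoints)
}

#' Enumerate a grid
#'
#' @param spec `grid_spec`.
#' @return list with the three axis coordinate vectors, the total point
#'   count and the edge length (bohr).  Use [grid_points()] to
#'   materialize the full point matrix.
#' @export
make_grid <- function(spec) {
  ax <- function(i) spec$origin[i] + spec$step * (seq_len(spec$npoints) - 1)
  list(x = ax(1), y = ax(2), z = ax(3),
       n_points = as.double(spec$npoints)^3,
       edge = spec$step * (spec$npoints - 1))
}

#' @rdname make_grid
#' @return `grid_points` returns the n^3 x 3 coordinate matrix in cube
#'   order (x slowest, z fastest).
#' @export
grid_points <- function(spec) {
  g <- make_grid(spec)
  n <- spec$npoints
  cbind(rep(g$x, each = n * n),
        rep(rep(g$y, each = n), times = n),
        rep(g$z, times = n * n))
}

new_scalar_field <- function(spec, kind, values, provenance = "model") {
  if (length(values) != as.double(spec$npoints)^3)
    stop_hc("value count %d does not match %d^3", length(values), spec$npoints)
  structure(list(spec = spec, kind = kind, values = values,
                 provenance = provenance),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field (%s, %s): %d^3 points, step %.6g bohr, range [%.4g, %.4g]\n",
              x$kind, x$provenance, x$spec$npoints, x$spec$step,
              min(x$values), max(x$values)))
  invisible(x)
}

same_spec <- function(a, b, tol = 1e-9) {
  sa <- a$spec; sb <- b$spec
  sa$npoints == sb$npoints && abs(sa$step - sb$step) < tol &&
    all(abs(sa$origin - sb$origin) < tol)
}

#' Pointwise difference of two fields on a shared grid
#'
#' The deformation-map construction: e.g. reference density minus model
#' density.
#' @param a,b `scalar_field`s with identical specs.
#' @export
field_subtract <- function(a, b) {
  if (!same_spec(a, b))
    stop_hc("grids differ", class = "hcfit_alignment_error")
  new_scalar_field(a$spec, a$kind, a$values - b$values,
                   provenance = paste0(a$provenance, "-", b$provenance))
}

#' Integrated electron count of a density field
#' @param field density `scalar_field`.
#' @export
field_integral <- function(field) sum(field$values) * field$spec$step^3

## evaluate fun(points) over the grid in chunks to bound memory
.eval_on_grid <- function(spec, fun, chunk = 1048576L) {
  n <- spec$npoints
  n3 <- as.double(n)^3
  if (n3 <= chunk) return(fun(grid_points(spec)))
  g <- make_grid(spec)
  out <- numeric(n3)
  i <- 1
  while (i <= n3) {
    j <- min(i + chunk - 1, n3)
    idx <- (i:j) - 1
    ix <- idx %/% (n * n); rem <- idx - ix * n * n
    iy <- rem %/% n; iz <- rem - iy * n
    out[i:j] <- fun(cbind(g$x[ix + 1], g$y[iy + 1], g$z[iz + 1]))
    i <- j + 1
  }
  out
}

#' Electron density on a grid
#'
#' @param source an `mm_model` or `synthetic_reference`.
#' @param spec `grid_spec`.
#' @param include_core include core electron density (default TRUE: the
#'   valence-only refined models are expanded back with core electrons
#'   for grid work).
#' @param cell optional cubic cell edge (bohr) for minimum-image
#'   periodization (FFT-oracle grids that tile a unit cell).
#' @return density `scalar_field`.
#' @export
density_field <- function(source, spec, include_core = TRUE, cell = NULL) {
  UseMethod("density_field")
}

#' @export
density_field.mm_model <- function(source, spec, include_core = TRUE,
                                   cell = NULL) {
  vals <- .eval_on_grid(spec, function(p)
    model_density(source, p, include_core = include_core, cell = cell))
  new_scalar_field(spec, "density", vals, provenance = "model")
}

#' Electrostatic potential on a grid
#'
#' `V(r) = sum_A Z_A / |R_A - r| - (electron term)`, atomic units.  For
#' pseudo-atom models the electron term is analytic through the
#' inside/outside radial-moment decomposition of each Slater component.
#' A grid point within 1e-6 bohr of a nucleus gets the nuclear term
#' evaluated at a 1e-6 bohr offset.
#'
#' @param source `mm_model` or `synthetic_reference`.
#' @param spec `grid_spec`.
#' @return esp `scalar_field` (hartree / e).
#' @export
esp_field <- function(source, spec) UseMethod("esp_field")

#' @export
esp_field.mm_model <- function(source, spec) {
  vals <- .eval_on_grid(spec, function(p) model_esp(source, p))
  new_scalar_field(spec, "esp", vals, provenance = "model")
}

## lower/upper incomplete gamma, integer order
.gamma_low <- function(k, x) stats::pgamma(x, k) * gamma(k)
.gamma_up  <- function(k, x) stats::pgamma(x, k, lower.tail = FALSE) * gamma(k)

## ESP of one spherical density expansion (terms tt) at radii r:
## 4 pi [ (1/r) int_0^r rho s^2 ds + int_r^inf rho s ds ]
.sphere_esp_terms <- function(tt, r) {
  out <- numeric(length(r))
  rs <- pmax(r, 1e-12)
  for (i in seq_len(nrow(tt))) {
    z <- tt$zeta[i]; n <- tt$n[i]
    out <- out + tt$coeff[i] * 4 * pi *
      (.gamma_low(n + 3, z * rs) / (rs * z^(n + 3)) +
       .gamma_up(n + 2, z * rs) / z^(n + 2))
  }
  out
}

.scale_terms <- function(tt, kappa) {
  if (kappa == 1) return(tt)
  tt$coeff <- tt$coeff * kappa^(tt$n + 3)
  tt$zeta <- tt$zeta * kappa
  tt
}

#' Electrostatic potential of a multipole model at arbitrary points
#'
#' @param model `mm_model`.
#' @param points m x 3 matrix, bohr.
#' @return ESP values in hartree / e.
#' @export
model_esp <- function(model, points) {
  out <- numeric(nrow(points))
  for (a in model$atoms) {
    entry <- databank_entry(model$bank, a$element)
    rc <- .atom_relative(a, model$geometry, points)
    r <- pmax(rc$r, 1e-6)           # capped nuclear-coincidence handling
    out <- out + entry$Z / r
    ## electron terms (negative sign)
    el <- a$P_core * .sphere_esp_terms(entry$core_terms, rc$r) +
      (a$P_val / entry$n_val) *
        .sphere_esp_terms(.scale_terms(entry$valence_terms, a$kappa), rc$r)
    nz <- which(a$Plm != 0)
    if (length(nz)) {
      kp <- a$kappa_prime
      rs <- pmax(rc$r, 1e-12)
      rad <- list()
      for (k in nz) {
        lms <- strsplit(names(a$Plm)[k], ",")[[1]]
        l <- as.integer(lms[1]); m <- as.integer(lms[2]); s <- lms[3]
        lk <- as.character(l)
        if (is.null(rad[[lk]])) {
          n <- entry$def_n[l + 1L]; zt <- entry$def_zeta[l + 1L] * kp
          Nn <- zt^(n + 3) / fact(n + 2)
          x <- zt * rs
          rad[[lk]] <- 4 * pi / (2 * l + 1) * Nn *
            (.gamma_low(n + l + 3, x) / zt^(n + l + 3) / rs^(l + 1) +
             rs^l * .gamma_up(n - l + 2, x) / zt^(n - l + 2))
        }
        el <- el + a$Plm[k] * rad[[lk]] *
          dlm_eval(l, m, s, rc$ux, rc$uy, rc$uz)
      }
    }
    out <- out - el
  }
  out
}

#' Electrostatic potential by direct summation over a gridded density
#'
#' Brute-force Coulomb sum over all voxels of a density field plus the
#' nuclear terms; O(N_grid x N_points), intended for small cross-check
#' grids only.
#'
#' @param density density `scalar_field`.
#' @param geom `mol_geometry` providing the nuclei.
#' @param points m x 3 matrix, bohr.
#' @export
esp_direct_sum <- function(density, geom, points) {
  vox <- grid_points(density$spec)
  dv <- density$spec$step^3
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d2 <- (vox[, 1] - points[i, 1])^2 + (vox[, 2] - points[i, 2])^2 +
      (vox[, 3] - points[i, 3])^2
    d <- sqrt(pmax(d2, (density$spec$step / 2)^2))  # self-voxel softening
    out[i] <- -sum(density$values * dv / d)
  }
  for (a in seq_len(n_atoms(geom))) {
    d <- sqrt(rowSums(sweep(points, 2, geom$pos[a, ])^2))
    out <- out + geom$Z[a] / pmax(d, 1e-6)
  }
  out
}

## --- Gaussian cube I/O -----------------------------------------------

#' Write / read Gaussian cube files
#'
#' Bohr units, z-fastest value order, values written with full double
#' precision so a write/read round trip is bit-identical.  Only
#' axis-aligned isotropic cubic grids are supported.  An optional JSON
#' sidecar records the field kind and provenance tag.
#'
#' @param field `scalar_field`.
#' @param path output file.
#' @param geom optional `mol_geometry` written into the atom block.
#' @param sidecar write `<path>.json` metadata.
#' @export
write_cube <- function(field, path, geom = NULL, sidecar = FALSE) {
  spec <- field$spec
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("hcfit scalar field",
               sprintf("kind=%s provenance=%s", field$kind, field$provenance)),
             con)
  nat <- if (is.null(geom)) 0L else n_atoms(geom)
  writeLines(sprintf("%5d %.17E %.17E %.17E", nat,
                     spec$origin[1], spec$origin[2], spec$origin[3]), con)
  for (i in 1:3) {
    v <- c(0, 0, 0); v[i] <- spec$step
    writeLines(sprintf("%5d %.17E %.17E %.17E", spec$npoints,
                       v[1], v[2], v[3]), con)
  }
  if (nat > 0)
    for (i in seq_len(nat))
      writeLines(sprintf("%5d %11.6f %19.11E %19.11E %19.11E", geom$Z[i],
                         as.numeric(geom$Z[i]), geom$pos[i, 1],
                         geom$pos[i, 2], geom$pos[i, 3]), con)
  v <- field$values
  pad <- (-length(v)) %% 6L
  m <- matrix(c(sprintf("%.17E", v), rep("", pad)), ncol = 6L, byrow = TRUE)
  writeLines(apply(m, 1, paste, collapse = " "), con)
  if (sidecar)
    jsonlite::write_json(list(kind = field$kind, provenance = field$provenance,
                              step = spec$step, npoints = spec$npoints,
                              origin = spec$origin),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  meta <- lines[2]
  kind <- sub(".*kind=(\\S+).*", "\\1", meta)
  prov <- sub(".*provenance=(\\S+).*", "\\1", meta)
  if (!kind %in% c("density", "esp")) { kind <- "density"; prov <- "reference" }
  hdr <- strsplit(trimws(lines[3]), "\\s+")[[1]]
  nat <- as.integer(hdr[1])
  origin <- as.numeric(hdr[2:4])
  axes <- t(vapply(4:6, function(i)
    as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]), numeric(4)))
  n <- as.integer(axes[, 1])
  if (length(unique(n)) != 1L)
    stop_hc("anisotropic grids unsupported", class = "hcfit_format_error")
  vecs <- axes[, 2:4]
  if (any(abs(vecs[row(vecs) != col(vecs)]) > 1e-12) ||
      length(unique(round(diag(vecs), 12))) != 1L)
    stop_hc("non-orthogonal or anisotropic cube axes unsupported",
            class = "hcfit_format_error")
  first_val <- 7L + abs(nat)
  vals <- as.numeric(unlist(strsplit(trimws(lines[first_val:length(lines)]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != as.double(n[1])^3)
    stop_hc("cube value count %d does not match header %d^3",
            length(vals), n[1], class = "hcfit_parse_error")
  new_scalar_field(grid_spec(origin, diag(vecs)[1], n[1]), kind, vals,
                   provenance = prov)
}
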