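## Seedable synthetic test cases standing in for the DFT-wavefunction
## stage: a ground-truth multipole model drawn around neutral-atom
## values, optionally augmented with small charge-neutral Gaussian
## "bond bumps" that no multipole model can represent exactly, plus the
## derived valence-only structure factors and reference grids.

#' Specification of a synthetic case
#'
#' @param geometry_name built-in geometry (see [builtin_geometry()]).
#' @param seed integer seed; identical specs generate bit-identical
#'   cases.
#' @param d_pval max |deviation| of valence populations from neutral
#'   values, electrons.
#' @param d_plm max |multipole population|, electrons.
#' @param kappa_range interval for kappa and kappa' draws (within the
#'   physically sane (0.5, 2)).
#' @param bump_amplitude electrons moved per bond bump pair.
#' @param bump_width Gaussian sigma of the bumps, bohr.
#' @param nonrepresentable add the bond bumps (TRUE) or make the
#'   reference exactly representable by the truth model (FALSE).
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(geometry_name = "water", seed = 1L,
                           d_pval = 0.2, d_plm = 0.06,
                           kappa_range = c(0.9, 1.1),
                           bump_amplitude = 0.05, bump_width = 0.3,
                           nonrepresentable = TRUE) {
  stopifnot(kappa_range[1] > 0.5, kappa_range[2] < 2.0,
            bump_amplitude >= 0, bump_width > 0, d_pval >= 0, d_plm >= 0)
  structure(list(geometry_name = geometry_name, seed = as.integer(seed),
                 d_pval = d_pval, d_plm = d_plm, kappa_range = kappa_range,
                 bump_amplitude = bump_amplitude, bump_width = bump_width,
                 nonrepresentable = isTRUE(nonrepresentable)),
            class = "synthetic_spec")
}

#' Draw a seeded ground-truth multipole model
#'
#' Valence populations are drawn uniformly around the neutral-atom
#' values and then shifted (respecting constraint ties) so the total
#' electron count equals `sum(Z) - net_charge` exactly; multipole
#' populations are uniform in `[-d_plm, d_plm]`; kappa and kappa' are
#' uniform over `kappa_range`.  All draws pass through one seeded RNG.
#'
#' @param spec `synthetic_spec`.
#' @param bank radial databank.
#' @return ground-truth `mm_model`.
#' @export
sample_ground_truth <- function(spec, bank = builtin_databank("slater-rules")) {
  geom <- normalize_xh_bonds(builtin_geometry(spec$geometry_name))
  model <- molecule_model(geom, bank)
  groups <- .fit_groups(model)
  with_seed(spec$seed, {
    p <- pack_parameters(model)
    ## population draws
    pv_keys <- character(0); pv_mult <- numeric(0)
    for (gk in names(groups$pop)) {
      mem <- groups$pop[[gk]]
      if (mem$kind[1] == "Pval") {
        p[gk] <- p[gk] + runif(1, -spec$d_pval, spec$d_pval)
        pv_keys <- c(pv_keys, gk); pv_mult <- c(pv_mult, nrow(mem))
      } else {
        p[gk] <- runif(1, -spec$d_plm, spec$d_plm)
      }
    }
    ## kappa draws
    for (gk in names(groups$kap))
      p[gk] <- runif(1, spec$kappa_range[1], spec$kappa_range[2])
    ## electroneutrality bookkeeping: total electrons = sum(Z) - charge
    entries <- lapply(model$atoms, function(a) databank_entry(bank, a$element))
    nval <- vapply(entries, `[[`, numeric(1), "n_val")
    target_dev <- -geom$net_charge
    cur_dev <- sum(vapply(seq_along(pv_keys), function(i) {
      mem <- groups$pop[[pv_keys[i]]]
      pv_mult[i] * (p[pv_keys[i]] - nval[mem$atom[1]])
    }, numeric(1)))
    shift <- (target_dev - cur_dev) / sum(pv_mult)
    for (gk in pv_keys) p[gk] <- p[gk] + shift
    unpack_parameters(model, p)
  })
}

#' Add non-representable bond-density features
#'
#' Per bond, a positive Gaussian of `bump_amplitude` electrons at the
#' bond midpoint is compensated by two Gaussians of half that charge
#' removed at the bonded atoms, so the perturbation is exactly charge
#' neutral analytically and keeps each atom's local charge roughly
#' neutral.
#'
#' @param truth ground-truth `mm_model`.
#' @param spec `synthetic_spec` (amplitude/width; if
#'   `nonrepresentable = FALSE` or zero amplitude no bumps are added).
#' @return object of class `synthetic_reference` evaluable by
#'   [density_field()] and [esp_field()].
#' @export
add_nonrepresentable <- function(truth, spec) {
  geom <- truth$geometry
  bumps <- NULL
  if (spec$nonrepresentable && spec$bump_amplitude > 0 && nrow(geom$bonds)) {
    rows <- list()
    for (b in seq_len(nrow(geom$bonds))) {
      i <- geom$bonds[b, 1]; j <- geom$bonds[b, 2]
      mid <- (geom$pos[i, ] + geom$pos[j, ]) / 2
      A <- spec$bump_amplitude
      rows[[length(rows) + 1L]] <- data.frame(
        x = c(mid[1], geom$pos[i, 1], geom$pos[j, 1]),
        y = c(mid[2], geom$pos[i, 2], geom$pos[j, 2]),
        z = c(mid[3], geom$pos[i, 3], geom$pos[j, 3]),
        q = c(A, -A / 2, -A / 2), width = spec$bump_width)
    }
    bumps <- do.call(rbind, rows)
  }
  structure(list(model = truth, bumps = bumps, geometry = geom),
            class = "synthetic_reference")
}

## Gaussian charge density of all bumps at points (minimum-image when a
## cell is given)
.bump_density <- function(bumps, points, cell = NULL) {
  out <- numeric(nrow(points))
  if (is.null(bumps)) return(out)
  for (i in seq_len(nrow(bumps))) {
    w <- bumps$width[i]
    dd <- cbind(points[, 1] - bumps$x[i], points[, 2] - bumps$y[i],
                points[, 3] - bumps$z[i])
    if (!is.null(cell)) dd <- dd - cell * round(dd / cell)
    d2 <- rowSums(dd^2)
    out <- out + bumps$q[i] * (2 * pi * w^2)^(-1.5) * exp(-d2 / (2 * w^2))
  }
  out
}

## electron-term ESP of the bumps (enters V with a minus sign)
.bump_esp <- function(bumps, points) {
  out <- numeric(nrow(points))
  if (is.null(bumps)) return(out)
  for (i in seq_len(nrow(bumps))) {
    w <- bumps$width[i]
    d <- sqrt((points[, 1] - bumps$x[i])^2 + (points[, 2] - bumps$y[i])^2 +
                (points[, 3] - bumps$z[i])^2)
    d <- pmax(d, 1e-9)
    ## 2*pnorm(x) - 1 = erf(x / sqrt(2)) evaluated on d/w
    out <- out - bumps$q[i] * (2 * stats::pnorm(d / w) - 1) / d
  }
  out
}

## analytic Fourier transform of the bumps on an hkl set
.bump_structure_factors <- function(bumps, hkl) {
  F <- complex(nrow(hkl$hkl))
  if (is.null(bumps)) return(F)
  a_bohr <- hkl$a / BOHR_A
  q <- 2 * pi * sqrt(rowSums(hkl$hkl^2)) / a_bohr
  for (i in seq_len(nrow(bumps))) {
    ph <- exp(complex(imaginary = 2 * pi *
                        as.vector(hkl$hkl %*% c(bumps$x[i], bumps$y[i], bumps$z[i])) /
                        a_bohr))
    F <- F + bumps$q[i] * exp(-q^2 * bumps$width[i]^2 / 2) * ph
  }
  F
}

#' @export
density_field.synthetic_reference <- function(source, spec,
                                              include_core = TRUE,
                                              cell = NULL) {
  vals <- .eval_on_grid(spec, function(p)
    model_density(source$model, p, include_core = include_core, cell = cell) +
      .bump_density(source$bumps, p, cell = cell))
  new_scalar_field(spec, "density", vals, provenance = "reference")
}

#' @export
esp_field.synthetic_reference <- function(source, spec) {
  vals <- .eval_on_grid(spec, function(p)
    model_esp(source$model, p) + .bump_esp(source$bumps, p))
  new_scalar_field(spec, "esp", vals, provenance = "reference")
}

#' Assemble a complete synthetic case
#'
#' Builds the ground-truth model, the reference density source, the
#' valence-only target structure factors (analytic multipole transform
#' plus the analytic Gaussian transform of the bumps) and, if a grid is
#' given, the reference density and ESP fields.  Fully reproducible
#' from its arguments.
#'
#' @param spec `synthetic_spec`.
#' @param grid optional `grid_spec` for the reference fields.
#' @param a,s_max,friedel_unique reciprocal-lattice parameters
#'   (defaults: the 30 Angstrom pseudo-cubic cell at
#'   sin(theta)/lambda <= 1.1).
#' @param bank radial databank.
#' @return list of class `synthetic_case`.
#' @export
generate_case <- function(spec, grid = NULL, a = 30, s_max = 1.1,
                          friedel_unique = TRUE,
                          bank = builtin_databank("slater-rules")) {
  truth <- sample_ground_truth(spec, bank)
  reference <- add_nonrepresentable(truth, spec)
  hkl <- generate_hkl(a, s_max, friedel_unique = friedel_unique)
  F_target <- structure_factors(truth, hkl, include_core = FALSE)
  F_target$F <- F_target$F + .bump_structure_factors(reference$bumps, hkl)
  fields <- NULL
  if (!is.null(grid))
    fields <- list(density = density_field(reference, grid),
                   esp = esp_field(reference, grid))
  structure(list(spec = spec, geometry = truth$geometry, truth_model = truth,
                 reference = reference, F_target = F_target, fields = fields),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic_case '%s' (seed %d): %d atoms, %d reflections%s\n",
              x$spec$geometry_name, x$spec$seed, n_atoms(x$geometry),
              length(x$F_target$F),
              if (!is.null(x$reference$bumps)) ", non-representable bumps" else ""))
  invisible(x)
}

#' Write a case bundle directory
#'
#' Geometry (XYZ), truth-model parameters, target structure factors,
#' reference fields (cube) and a JSON manifest with the generating spec.
#' @param case `synthetic_case`.
#' @param dir output directory (created).
#' @export
write_case_bundle <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_xyz(case$geometry, file.path(dir, "geometry.xyz"))
  write_model_params(case$truth_model, file.path(dir, "truth_model.txt"))
  write_sf(case$F_target, file.path(dir, "f_target.txt"))
  if (!is.null(case$fields)) {
    write_cube(case$fields$density, file.path(dir, "reference_density.cube"),
               geom = case$geometry, sidecar = TRUE)
    write_cube(case$fields$esp, file.path(dir, "reference_esp.cube"),
               geom = case$geometry, sidecar = TRUE)
  }
  jsonlite::write_json(unclass(case$spec), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
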