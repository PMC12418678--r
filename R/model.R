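## Hansen-Coppens pseudo-atom models.
##
## Per atom the density is
##   rho(r) = P_core rho_core(r) + P_val kappa^3 rho_val(kappa r)
##          + sum_l kappa'^3 R_l(kappa' r) sum_m P_lm d_lm(theta, phi)
## with r measured from the nucleus in the atom's local frame and d_lm
## the density-normalized real spherical harmonics.  Heavy atoms carry
## multipoles up to hexadecapoles (l = 4), hydrogens up to quadrupoles
## (l = 2) restricted to bond-oriented m = 0 terms.  P_core is fixed at
## 1 and never refined.

DEFAULT_KAPPA_BOUNDS <- c(0.5, 2.0)

param_key <- function(atom, kind, term = NULL) {
  if (is.null(term)) sprintf("%d:%s", atom, kind)
  else sprintf("%d:Plm:%s", atom, term)
}

#' Construct a multipole model for a geometry
#'
#' Atoms start at independent-atom (IAM) values: neutral spherical
#' atoms, `P_val = n_val`, `kappa = kappa' = 1`, all multipole
#' populations zero.  Constraint groups (symmetry-equivalent atoms
#' sharing the full parameter set, chemically identical hydrogens
#' sharing kappa and kappa') are taken from the geometry metadata.
#'
#' @param geom `mol_geometry`.
#' @param bank `radial_databank` (name or object).
#' @param lmax_heavy multipole truncation for non-hydrogens (default 4,
#'   hexadecapoles).
#' @param lmax_h truncation for hydrogens (default 2, quadrupoles).
#' @param h_bond_oriented restrict hydrogens to m = 0 terms in a frame
#'   with z along the X-H bond.
#' @param use_P00 include an l = 0 deformation population (off by
#'   default; the spherical valence is carried by `P_val`, `kappa`).
#' @param frames optional precomputed frames (see
#'   [build_local_frames()]).
#' @return object of class `mm_model`.
#' @export
molecule_model <- function(geom, bank = builtin_databank("slater-rules"),
                           lmax_heavy = 4L, lmax_h = 2L,
                           h_bond_oriented = TRUE, use_P00 = FALSE,
                           frames = NULL) {
  if (is.character(bank)) bank <- load_databank(bank)
  if (is.null(frames))
    frames <- build_local_frames(geom, h_bond_oriented = h_bond_oriented)
  atoms <- lapply(seq_len(n_atoms(geom)), function(i) {
    el <- geom$element[i]
    entry <- databank_entry(bank, el)
    is_h <- el == "H"
    lmax <- min(if (is_h) lmax_h else lmax_heavy, entry$lmax)
    terms <- multipole_terms(lmax, lmin = if (use_P00) 0L else 1L,
                             m0_only = is_h && h_bond_oriented)
    keys <- if (nrow(terms)) term_key(terms$l, terms$m, terms$s) else character(0)
    list(index = i, element = el, P_core = 1, P_val = entry$n_val,
         kappa = 1, kappa_prime = 1,
         Plm = setNames(numeric(length(keys)), keys),
         lmax = lmax, frame = frames[[i]])
  })
  constraints <- .default_constraints(geom, atoms,
                                      h_bond_oriented = h_bond_oriented)
  structure(list(geometry = geom, atoms = atoms, constraints = constraints,
                 bank = bank, h_bond_oriented = h_bond_oriented),
            class = "mm_model")
}

## tie groups: full parameter sets across symmetry-equivalent atoms,
## kappa/kappa' across chemically identical hydrogens; overlapping
## groups are merged so the final groups are disjoint
.default_constraints <- function(geom, atoms, h_bond_oriented) {
  ties <- list()
  for (grp in geom$equiv_groups) {
    a1 <- atoms[[grp[1]]]
    for (kind in c("Pval", "kappa", "kappap"))
      ties[[length(ties) + 1L]] <- param_key(grp, kind)
    for (tk in names(a1$Plm))
      ties[[length(ties) + 1L]] <- param_key(grp, "Plm", tk)
  }
  for (grp in geom$h_kappa_groups) {
    if (length(grp) < 2L) next
    ties[[length(ties) + 1L]] <- param_key(grp, "kappa")
    ties[[length(ties) + 1L]] <- param_key(grp, "kappap")
  }
  list(ties = .merge_groups(ties), fixed = character(0),
       h_bond_oriented = h_bond_oriented)
}

.merge_groups <- function(groups) {
  if (!length(groups)) return(groups)
  out <- list()
  for (g in groups) {
    hit <- which(vapply(out, function(o) any(g %in% o), logical(1)))
    if (length(hit)) {
      merged <- sort(unique(c(unlist(out[hit]), g)))
      out <- out[-hit]; out[[length(out) + 1L]] <- merged
    } else out[[length(out) + 1L]] <- sort(unique(g))
  }
  out
}

## --- parameter vector (pack / unpack) --------------------------------

#' Table of refinable parameters of a model
#'
#' One row per (atom, parameter); tied parameters share a `group`
#' representative key, fixed parameters are flagged not free.
#' @param model `mm_model`.
#' @return data.frame with columns `key`, `atom`, `kind`, `term`,
#'   `value`, `group`, `free`.
#' @export
parameter_table <- function(model) {
  rows <- list()
  for (a in model$atoms) {
    rows[[length(rows) + 1L]] <- data.frame(
      key = c(param_key(a$index, "Pval"), param_key(a$index, "kappa"),
              param_key(a$index, "kappap")),
      atom = a$index, kind = c("Pval", "kappa", "kappap"), term = NA_character_,
      value = c(a$P_val, a$kappa, a$kappa_prime), stringsAsFactors = FALSE)
    if (length(a$Plm))
      rows[[length(rows) + 1L]] <- data.frame(
        key = param_key(a$index, "Plm", names(a$Plm)),
        atom = a$index, kind = "Plm", term = names(a$Plm),
        value = unname(a$Plm), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$group <- tab$key
  for (g in model$constraints$ties) {
    idx <- match(g, tab$key)
    idx <- idx[!is.na(idx)]
    if (length(idx) > 1L) tab$group[idx] <- tab$key[idx[1]]
  }
  tab$free <- !(tab$key %in% model$constraints$fixed)
  tab
}

#' Pack the model into a flat named parameter vector
#'
#' Tied parameters appear once (their values must agree at pack time),
#' fixed parameters are excluded; `unpack_parameters()` inverts exactly.
#' @param model `mm_model`.
#' @return named numeric vector.
#' @export
pack_parameters <- function(model) {
  tab <- parameter_table(model)
  tab <- tab[tab$free, ]
  reps <- !duplicated(tab$group)
  for (g in unique(tab$group[duplicated(tab$group)])) {
    v <- tab$value[tab$group == g]
    if (max(v) - min(v) > 1e-9)
      stop_hc("tied parameters in group '%s' have inconsistent values", g,
              class = "hcfit_constraint_error")
  }
  setNames(tab$value[reps], tab$group[reps])
}

#' @rdname pack_parameters
#' @param p named vector as returned by `pack_parameters`.
#' @export
unpack_parameters <- function(model, p) {
  tab <- parameter_table(model)
  tab$new <- tab$value
  idx <- tab$free & tab$group %in% names(p)
  tab$new[idx] <- p[tab$group[idx]]
  for (a in seq_along(model$atoms)) {
    sub <- tab[tab$atom == a, ]
    model$atoms[[a]]$P_val <- sub$new[sub$kind == "Pval"]
    model$atoms[[a]]$kappa <- sub$new[sub$kind == "kappa"]
    model$atoms[[a]]$kappa_prime <- sub$new[sub$kind == "kappap"]
    pl <- sub[sub$kind == "Plm", ]
    if (nrow(pl)) model$atoms[[a]]$Plm[pl$term] <- pl$new
  }
  model
}

## --- density evaluation ----------------------------------------------

## relative coordinates of points about an atom: r and local-frame unit
## direction components; a non-NULL cell (bohr) applies the
## minimum-image convention, periodizing the density over the cell
.atom_relative <- function(atom, geom, points, cell = NULL) {
  rel <- sweep(points, 2, geom$pos[atom$index, ])
  if (!is.null(cell)) rel <- rel - cell * round(rel / cell)
  r <- sqrt(rowSums(rel * rel))
  ul <- rel %*% atom$frame$R          # columns: local x, y, z
  safe <- pmax(r, 1e-300)
  list(r = r, ux = ul[, 1] / safe, uy = ul[, 2] / safe, uz = ul[, 3] / safe)
}

#' Density of one pseudo-atom at arbitrary points
#'
#' @param atom one element of `model$atoms`.
#' @param model the owning `mm_model` (for databank and geometry).
#' @param points m x 3 matrix, bohr.
#' @param include_core include the `P_core rho_core` term.
#' @return density values, e bohr^-3.
#' @export
atom_density <- function(atom, model, points, include_core = TRUE,
                         cell = NULL) {
  entry <- databank_entry(model$bank, atom$element)
  if (!is.null(cell)) {
    ## periodized evaluation.  Diffuse atoms (slow radial decay relative
    ## to the cell) get the full first-image-shell sum: with the
    ## relative vector wrapped to [-cell/2, cell/2], the 8 corner images
    ## s_i in {0, -sign(rel_i)} bound the truncation error by
    ## exp(-zeta cell); compact atoms keep the single minimum image.
    zmin <- min(c(entry$valence_terms$zeta * atom$kappa,
                  entry$def_zeta[seq_len(atom$lmax + 1L)] * atom$kappa_prime))
    if (zmin * cell < 55) {
      rel <- sweep(points, 2, model$geometry$pos[atom$index, ])
      rel <- rel - cell * round(rel / cell)
      out <- numeric(nrow(points))
      at0 <- atom
      geom0 <- model$geometry
      flip <- function(v) ifelse(v >= 0, -1, 1)  # opposite-side image
      zero <- numeric(nrow(rel))
      for (sx in 0:1) for (sy in 0:1) for (sz in 0:1) {
        sh <- cbind(if (sx) flip(rel[, 1]) else zero,
                    if (sy) flip(rel[, 2]) else zero,
                    if (sz) flip(rel[, 3]) else zero) * cell
        geom0$pos[atom$index, ] <- c(0, 0, 0)
        model0 <- model; model0$geometry <- geom0
        out <- out + atom_density(at0, model0, rel + sh,
                                  include_core = include_core, cell = NULL)
      }
      return(out)
    }
  }
  rc <- .atom_relative(atom, model$geometry, points, cell = cell)
  r <- rc$r
  ## the stored valence density integrates to n_val electrons; P_val
  ## scales the per-electron shape
  out <- (atom$P_val / entry$n_val) * atom$kappa^3 *
    spherical_density(entry, "valence", atom$kappa * r)
  if (include_core && atom$P_core != 0)
    out <- out + atom$P_core * spherical_density(entry, "core", r)
  nz <- which(atom$Plm != 0)
  if (length(nz)) {
    kp <- atom$kappa_prime
    rad <- list()
    for (k in nz) {
      lms <- strsplit(names(atom$Plm)[k], ",")[[1]]
      l <- as.integer(lms[1]); m <- as.integer(lms[2]); s <- lms[3]
      lk <- as.character(l)
      if (is.null(rad[[lk]]))
        rad[[lk]] <- kp^3 * deformation_radial(entry, l, kp * r)
      out <- out + atom$Plm[k] * rad[[lk]] *
        dlm_eval(l, m, s, rc$ux, rc$uy, rc$uz)
    }
  }
  out
}

#' Total model density at arbitrary points
#'
#' @param model `mm_model`.
#' @param points m x 3 matrix, bohr.
#' @param include_core include core densities (`FALSE` gives the
#'   valence-only density used at the structure-factor stage).
#' @param cell optional cubic cell edge (bohr): evaluate the density
#'   periodized over the cell by the minimum-image convention (used
#'   when a grid tiles a unit cell, e.g. for the FFT oracle).
#' @return density values, e bohr^-3.
#' @export
model_density <- function(model, points, include_core = TRUE, cell = NULL) {
  out <- numeric(nrow(points))
  for (a in model$atoms)
    out <- out + atom_density(a, model, points, include_core = include_core,
                              cell = cell)
  out
}

#' Analytic electron count of a pseudo-atom
#'
#' All l >= 1 deformation terms integrate to zero by spherical-harmonic
#' orthogonality, so the count is
#' `P_core n_core + P_val + P_00` (the last only if an l = 0
#' deformation population is present).
#' @param atom pseudo-atom.
#' @param model owning model.
#' @return electrons.
#' @export
analytic_atom_charge <- function(atom, model) {
  entry <- databank_entry(model$bank, atom$element)
  p00 <- if ("0,0,+" %in% names(atom$Plm)) atom$Plm[["0,0,+"]] else 0
  atom$P_core * entry$n_core + atom$P_val + p00
}

#' Reduce a model to the independent atom model (IAM)
#'
#' Multipole populations (l >= 1) are set to zero, monopole populations
#' to the free-atom values and the kappa parameters to unity.
#' Idempotent.
#' @param model `mm_model`.
#' @return `mm_model`.
#' @export
make_iam <- function(model) {
  for (i in seq_along(model$atoms)) {
    entry <- databank_entry(model$bank, model$atoms[[i]]$element)
    model$atoms[[i]]$P_val <- entry$n_val
    model$atoms[[i]]$kappa <- 1
    model$atoms[[i]]$kappa_prime <- 1
    model$atoms[[i]]$Plm[] <- 0
    if ("0,0,+" %in% names(model$atoms[[i]]$Plm))
      model$atoms[[i]]$Plm[["0,0,+"]] <- 0
  }
  model
}

#' @export
print.mm_model <- function(x, ...) {
  npar <- length(pack_parameters(x))
  cat(sprintf("mm_model: %d pseudo-atoms, %d free parameters, databank '%s'\n",
              length(x$atoms), npar, x$bank$name))
  invisible(x)
}

## --- model parameter file --------------------------------------------

#' Write / read model parameters as plain text
#'
#' Per atom: a header `ATOM <index> <element> <P_val> <kappa> <kappa'>`,
#' a `FRAME` line with the 9 rotation-matrix entries (local axes in
#' columns), then one `POP <l,m,s> <value>` line per multipole term.
#' @param model `mm_model`.
#' @param path file path.
#' @export
write_model_params <- function(model, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# hcfit multipole model parameters", con)
  for (a in model$atoms) {
    writeLines(sprintf("ATOM %d %s %.17g %.17g %.17g", a$index, a$element,
                       a$P_val, a$kappa, a$kappa_prime), con)
    writeLines(paste("FRAME", paste(sprintf("%.17g", as.vector(a$frame$R)),
                                    collapse = " ")), con)
    for (k in names(a$Plm))
      writeLines(sprintf("POP %s %.17g", k, a$Plm[[k]]), con)
  }
  invisible(path)
}

#' @rdname write_model_params
#' @param geom,bank geometry and databank to attach on read.
#' @export
read_model_params <- function(path, geom, bank = builtin_databank("slater-rules")) {
  if (is.character(bank)) bank <- load_databank(bank)
  model <- molecule_model(geom, bank)
  lines <- readLines(path)
  cur <- 0L
  for (ln in lines) {
    ln <- trimws(sub("#.*$", "", ln))
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "ATOM") {
      cur <- as.integer(tok[2])
      model$atoms[[cur]]$P_val <- as.numeric(tok[4])
      model$atoms[[cur]]$kappa <- as.numeric(tok[5])
      model$atoms[[cur]]$kappa_prime <- as.numeric(tok[6])
    } else if (tok[1] == "FRAME") {
      model$atoms[[cur]]$frame$R <- matrix(as.numeric(tok[-1]), 3, 3)
    } else if (tok[1] == "POP") {
      model$atoms[[cur]]$Plm[tok[2]] <- as.numeric(tok[3])
    }
  }
  model
}
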