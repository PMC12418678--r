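## Molecular geometries: element symbols, nuclear charges, Cartesian
## positions (stored in bohr), a bond list and a net charge.  Built-in
## idealized test molecules cover the typical bonding motifs of
## pseudo-atom databank work (bent AX2, pyramidal AX3, an amino-acid
## fragment, an octahedral hexaaqua-magnesium dication).

.Z_TABLE <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
              P = 15, S = 16, Cl = 17, Br = 35, I = 53)

element_Z <- function(symbol) {
  z <- .Z_TABLE[symbol]
  if (anyNA(z)) stop_hc("unknown element(s): %s",
                        paste(symbol[is.na(z)], collapse = " "))
  unname(z)
}

#' Construct a molecular geometry
#'
#' @param element character vector of element symbols.
#' @param pos n x 3 matrix of positions.
#' @param bonds two-column integer matrix (may have zero rows).
#' @param net_charge integer molecular charge.
#' @param units `"angstrom"` or `"bohr"` for `pos`.
#' @param h_kappa_groups list of integer vectors: chemically identical
#'   hydrogens that share kappa/kappa' during refinement.
#' @param equiv_groups list of integer vectors: symmetry-equivalent atoms
#'   that share the full multipole parameter set.
#' @return object of class `mol_geometry`; positions in bohr.
#' @export
molecule_geometry <- function(element, pos, bonds = NULL, net_charge = 0L,
                              units = c("angstrom", "bohr"),
                              h_kappa_groups = list(), equiv_groups = list()) {
  units <- match.arg(units)
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  if (ncol(pos) != 3L || nrow(pos) != length(element))
    stop_hc("pos must be length(element) x 3")
  if (!all(is.finite(pos))) stop_hc("non-finite positions")
  if (units == "angstrom") pos <- pos / BOHR_A
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) && (max(bonds) > length(element) || min(bonds) < 1L))
    stop_hc("bond indices out of range")
  structure(list(element = element, Z = element_Z(element), pos = pos,
                 bonds = bonds, net_charge = as.integer(net_charge),
                 h_kappa_groups = h_kappa_groups,
                 equiv_groups = equiv_groups),
            class = "mol_geometry")
}

n_atoms <- function(geom) length(geom$element)

bonded_neighbors <- function(geom, i) {
  b <- geom$bonds
  sort(unique(c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])))
}

#' @export
print.mol_geometry <- function(x, ...) {
  cat(sprintf("mol_geometry: %d atoms (%s), %d bonds, charge %+d\n",
              n_atoms(x), paste(unique(x$element), collapse = ""),
              nrow(x$bonds), x$net_charge))
  invisible(x)
}

## --- built-in idealized geometries -----------------------------------

.rot_about <- function(axis, theta) {
  ## Rodrigues rotation matrix
  a <- unit3(axis); c1 <- cos(theta); s1 <- sin(theta)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) * c1 + s1 * K + (1 - c1) * tcrossprod(a)
}

.perp_pair <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  p <- unit3(ref - sum(ref * u) * u)
  list(p = p, q = c(u[2] * p[3] - u[3] * p[2],
                    u[3] * p[1] - u[1] * p[3],
                    u[1] * p[2] - u[2] * p[1]))
}

.build_water <- function() {
  th <- 104.52 * pi / 360  # half angle
  r <- 0.9572
  pos <- rbind(c(0, 0, 0),
               c(r * sin(th), 0, r * cos(th)),
               c(-r * sin(th), 0, r * cos(th)))
  molecule_geometry(c("O", "H", "H"), pos,
                    bonds = rbind(c(1, 2), c(1, 3)),
                    h_kappa_groups = list(c(2L, 3L)),
                    equiv_groups = list(c(2L, 3L)))
}

.build_ammonia <- function() {
  r <- 1.012
  cb <- sqrt((2 * cos(106.7 * pi / 180) + 1) / 3)  # cos of angle to C3 axis
  sb <- sqrt(1 - cb^2)
  phi <- c(0, 2 * pi / 3, 4 * pi / 3)
  pos <- rbind(c(0, 0, 0),
               cbind(r * sb * cos(phi), r * sb * sin(phi), -r * cb))
  molecule_geometry(c("N", "H", "H", "H"), pos,
                    bonds = cbind(1L, 2:4),
                    h_kappa_groups = list(2:4),
                    equiv_groups = list(2:4))
}

.build_alanine <- function() {
  ## idealized neutral alanine CH3-CH(NH2)-COOH, literature-typical
  ## bond lengths/angles; constructed, not experimental coordinates
  t1 <- c(1, 1, 1) / sqrt(3); t2 <- c(1, -1, -1) / sqrt(3)
  t3 <- c(-1, 1, -1) / sqrt(3); t4 <- c(-1, -1, 1) / sqrt(3)
  CA <- c(0, 0, 0)
  C  <- CA + 1.52 * t1
  N  <- CA + 1.46 * t2
  CB <- CA + 1.53 * t3
  HA <- CA + 1.09 * t4
  ## carboxyl in the plane spanned by t1 and p
  b <- -t1; pp <- .perp_pair(t1)$p
  dir_at <- function(theta) cos(theta) * b + sin(theta) * pp
  O1 <- C + 1.21 * dir_at(121 * pi / 180)
  O2 <- C + 1.34 * dir_at(-114 * pi / 180)
  u2 <- unit3(C - O2)
  HO <- O2 + 0.97 * (cos(106 * pi / 180) * (-u2) +
                     sin(106 * pi / 180) * pp)
  amine_h <- function(back, phi0) {
    pq <- .perp_pair(back)
    al <- 109 * pi / 180
    cos(al) * back + sin(al) * (cos(phi0) * pq$p + sin(phi0) * pq$q)
  }
  bN <- -t2
  HN1 <- N + 1.01 * amine_h(bN, 2 * pi / 3)
  HN2 <- N + 1.01 * amine_h(bN, 4 * pi / 3)
  bB <- -t3
  HB <- lapply(c(0, 2 * pi / 3, 4 * pi / 3), function(ph)
    CB + 1.09 * amine_h(bB, ph + pi / 6))
  pos <- rbind(CA, C, N, CB, HA, O1, O2, HO, HN1, HN2,
               HB[[1]], HB[[2]], HB[[3]])
  el <- c("C", "C", "N", "C", "H", "O", "O", "H", "H", "H", "H", "H", "H")
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6), c(2, 7),
                 c(7, 8), c(3, 9), c(3, 10), c(4, 11), c(4, 12), c(4, 13))
  molecule_geometry(el, pos, bonds,
                    h_kappa_groups = list(5L, 8L, c(9L, 10L), c(11L, 12L, 13L)))
}

.build_mghex <- function() {
  ## [Mg(H2O)6]^2+, idealized octahedron; each water plane contains the
  ## Mg-O axis so all six waters are equivalent
  d <- 2.07; roh <- 0.967; th <- 104.5 * pi / 360
  axes <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  planes <- rbind(c(0, 1, 0), c(0, 1, 0), c(0, 0, 1),
                  c(0, 0, 1), c(1, 0, 0), c(1, 0, 0))
  el <- "Mg"; pos <- matrix(0, 1, 3); bonds <- NULL
  h_groups <- integer(0); o_group <- integer(0)
  for (i in 1:6) {
    a <- axes[i, ]; p <- planes[i, ]
    O <- d * a
    oi <- nrow(pos) + 1L
    pos <- rbind(pos, O,
                 O + roh * (cos(th) * a + sin(th) * p),
                 O + roh * (cos(th) * a - sin(th) * p))
    el <- c(el, "O", "H", "H")
    bonds <- rbind(bonds, c(1L, oi), c(oi, oi + 1L), c(oi, oi + 2L))
    o_group <- c(o_group, oi); h_groups <- c(h_groups, oi + 1L, oi + 2L)
  }
  molecule_geometry(el, pos, bonds, net_charge = 2L,
                    h_kappa_groups = list(h_groups),
                    equiv_groups = list(o_group, h_groups))
}

#' Built-in idealized geometries
#'
#' @param name one of `"water"`, `"ammonia"`, `"alanine"`, `"mghex"`
#'   (hexaaqua-magnesium dication).
#' @return `mol_geometry` (positions in bohr).
#' @export
builtin_geometry <- function(name = c("water", "ammonia", "alanine", "mghex")) {
  name <- match.arg(name)
  switch(name,
         water = .build_water(), ammonia = .build_ammonia(),
         alanine = .build_alanine(), mghex = .build_mghex())
}

#' Move hydrogens to standard X-H bond lengths
#'
#' Each hydrogen (which must have exactly one bonded heavy neighbour) is
#' moved along the existing X->H direction to the target length for the
#' heavy element, emulating the normalization of X-H distances to average
#' neutron-diffraction values.  Heavy atoms are untouched.
#'
#' @param geom `mol_geometry`.
#' @param target_lengths named numeric, Angstrom per heavy element.
#'   Defaults are typical neutron averages for C/N/O-H.
#' @return modified `mol_geometry`.
#' @export
normalize_xh_bonds <- function(geom,
                               target_lengths = c(C = 1.089, N = 1.015, O = 0.967)) {
  for (i in which(geom$element == "H")) {
    nb <- bonded_neighbors(geom, i)
    if (length(nb) != 1L)
      stop_hc("hydrogen %d has %d bonds; expected exactly 1", i, length(nb),
              class = "hcfit_geometry_error")
    x <- nb[1]
    tl <- target_lengths[[geom$element[x]]]
    if (is.null(tl)) next
    dir <- unit3(geom$pos[i, ] - geom$pos[x, ])
    geom$pos[i, ] <- geom$pos[x, ] + dir * (tl / BOHR_A)
  }
  geom
}

#' Read / write XYZ with bond and charge extension records
#'
#' Standard XYZ (Angstrom); the comment line carries `charge=<n>` and
#' bond records follow the atom block as lines `BOND <i> <j>`.
#' @param path file path.
#' @return `mol_geometry`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  chg <- 0L
  m <- regmatches(lines[2], regexpr("charge=(-?[0-9]+)", lines[2]))
  if (length(m)) chg <- as.integer(sub("charge=", "", m))
  at <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  el <- vapply(at, `[[`, "", 1L)
  pos <- t(vapply(at, function(x) as.numeric(x[2:4]), numeric(3)))
  bonds <- NULL
  rest <- lines[-seq_len(2 + n)]
  for (ln in rest) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 3L && tok[1] == "BOND")
      bonds <- rbind(bonds, as.integer(tok[2:3]))
  }
  molecule_geometry(el, pos, bonds, chg, units = "angstrom")
}

#' @rdname read_xyz
#' @param geom geometry to write.
#' @export
write_xyz <- function(geom, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(as.character(n_atoms(geom)), con)
  writeLines(sprintf("charge=%d", geom$net_charge), con)
  pa <- geom$pos * BOHR_A
  for (i in seq_len(n_atoms(geom)))
    writeLines(sprintf("%-2s %18.12f %18.12f %18.12f", geom$element[i],
                       pa[i, 1], pa[i, 2], pa[i, 3]), con)
  for (k in seq_len(nrow(geom$bonds)))
    writeLines(sprintf("BOND %d %d", geom$bonds[k, 1], geom$bonds[k, 2]), con)
  invisible(path)
}
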