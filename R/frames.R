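## Local Cartesian frames orienting each pseudo-atom's multipoles.
## Hydrogens get a bond-oriented frame (local z along H -> neighbour),
## which together with the m = 0 restriction realizes bond-oriented
## hydrogen multipoles.

#' Build local frames for every atom
#'
#' Default rules: for a hydrogen, local z points from H to its single
#' bonded neighbour; for a heavy atom, z points to its lowest-index
#' bonded neighbour and the x reference is the next bonded neighbour
#' (falling back to a neighbour-of-neighbour, then to a global axis).
#' Explicit per-atom rules may override: a rule is a list with fields
#' `z` and `x` (atom index or numeric direction) and `handedness`.
#'
#' @param geom `mol_geometry`.
#' @param rules optional list indexed by atom number.
#' @param h_bond_oriented require every H to have exactly one bond.
#' @return list of `local_frame` objects (fields `origin_atom`, `R`
#'   with columns = local x, y, z axes in global coordinates,
#'   `handedness`).
#' @export
build_local_frames <- function(geom, rules = NULL, h_bond_oriented = TRUE) {
  n <- n_atoms(geom)
  lapply(seq_len(n), function(i) {
    rule <- if (!is.null(rules) && length(rules) >= i) rules[[i]] else NULL
    if (is.null(rule)) {
      nb <- bonded_neighbors(geom, i)
      if (geom$element[i] == "H" && h_bond_oriented) {
        if (length(nb) != 1L)
          stop_hc("hydrogen %d has %d bonded neighbours; bond-oriented frames need exactly 1",
                  i, length(nb), class = "hcfit_frame_error")
        rule <- list(z = nb[1], x = NULL)
      } else if (length(nb) >= 2L) {
        rule <- list(z = nb[1], x = nb[2])
      } else if (length(nb) == 1L) {
        nn <- setdiff(bonded_neighbors(geom, nb[1]), i)
        rule <- list(z = nb[1], x = if (length(nn)) nn[1] else NULL)
      } else {
        rule <- list(z = c(0, 0, 1), x = c(1, 0, 0))
      }
    }
    resolve <- function(def) {
      if (is.null(def)) return(NULL)
      if (length(def) == 1L && is.numeric(def) && def == round(def) && def >= 1)
        geom$pos[def, ] - geom$pos[i, ]
      else as.numeric(def)
    }
    ez <- unit3(resolve(rule$z))
    xr <- resolve(rule$x)
    if (is.null(xr)) xr <- .any_perp(ez)
    ex <- xr - sum(xr * ez) * ez
    if (vnorm(ex) < 1e-8) ex <- .any_perp(ez) else ex <- unit3(ex)
    hand <- rule$handedness %||% 1
    ey <- hand * c(ez[2] * ex[3] - ez[3] * ex[2],
                   ez[3] * ex[1] - ez[1] * ex[3],
                   ez[1] * ex[2] - ez[2] * ex[1])
    structure(list(origin_atom = i, R = cbind(ex, ey, ez), handedness = hand),
              class = "local_frame")
  })
}

## deterministic unit vector perpendicular to u: reject the global axis
## most parallel to u, orthogonalize the least parallel one
.any_perp <- function(u) {
  ax <- diag(3)[, which.min(abs(u)), drop = TRUE]
  unit3(ax - sum(ax * u) * u)
}
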