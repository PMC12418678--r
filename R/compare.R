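## Charge-density comparison statistics: Pearson correlation of ESP
## grids, unified-basin QTAIM populations, iso-density surfaces and
## surface-averaged ESP error metrics.

#' Pearson correlation between two grids
#'
#' @param grid_a,grid_b `scalar_field`s on identical specs.
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_cc <- function(grid_a, grid_b) {
  if (!same_spec(grid_a, grid_b))
    stop_hc("grids differ", class = "hcfit_alignment_error")
  if (sd(grid_a$values) == 0 || sd(grid_b$values) == 0)
    stop_hc("zero variance grid", class = "hcfit_degenerate_error")
  cor(grid_a$values, grid_b$values)
}

#' Mean, mean-absolute and root-mean-square error
#'
#' `ME = mean(v - ref)`, `MAE = mean |v - ref|`,
#' `RMSE = sqrt(mean((v - ref)^2))`; optional weights give weighted
#' means.
#'
#' @param values,reference equal-length numeric vectors.
#' @param weights optional non-negative weights.
#' @return named vector `c(me, mae, rmse)`.
#' @export
error_metrics <- function(values, reference, weights = NULL) {
  if (length(values) != length(reference))
    stop_hc("length mismatch", class = "hcfit_alignment_error")
  if (!length(values)) stop_hc("empty input", class = "hcfit_alignment_error")
  d <- values - reference
  if (is.null(weights)) weights <- rep(1, length(d))
  w <- weights / sum(weights)
  c(me = sum(w * d), mae = sum(w * abs(d)), rmse = sqrt(sum(w * d^2)))
}

## --- QTAIM basins on a grid ------------------------------------------

## 26-neighbour offsets in fixed lexicographic (dx, dy, dz) order: the
## deterministic tie-break (first offset wins on equal slope)
.NB_OFFSETS <- local({
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  g <- g[order(g$dx, g$dy, g$dz), ]
  cbind(dx = g$dx, dy = g$dy, dz = g$dz)
})

#' Partition a density grid into atomic basins
#'
#' Near-grid steepest ascent: every voxel above the escape floor points
#' to the 26-neighbour with the largest positive density slope
#' (difference over Euclidean neighbour distance); chains are resolved
#' to their attracting maxima, which are matched to the nearest nucleus.
#' Voxels below the floor (default 1e-10 e bohr^-3) are labelled
#' escaped and assigned to the nearest attractor so the partition
#' conserves the total grid charge exactly.
#'
#' @param reference_density density `scalar_field` (basins are always
#'   generated on the reference grid).
#' @param geom `mol_geometry` whose nuclei claim the attractors.
#' @param floor escape threshold, e bohr^-3.
#' @return object of class `basin_map`: `label` (attractor id per
#'   voxel), `escaped` (logical), `attractors` (data.frame with
#'   position, peak density and assigned atom), `warnings`.
#' @export
assign_basins <- function(reference_density, geom, floor = 1e-10) {
  spec <- reference_density$spec
  n <- spec$npoints
  v <- reference_density$values
  n3 <- length(v)
  arr <- array(v, dim = c(n, n, n))  # [iz, iy, ix]
  pad <- array(-Inf, dim = c(n + 2L, n + 2L, n + 2L))
  pad[2:(n + 1), 2:(n + 1), 2:(n + 1)] <- arr
  core <- 2:(n + 1)
  nxt <- seq_len(n3)
  best <- numeric(n3)  # best positive slope so far; 0 = self (attractor)
  for (o in seq_len(nrow(.NB_OFFSETS))) {
    dx <- .NB_OFFSETS[o, 1]; dy <- .NB_OFFSETS[o, 2]; dz <- .NB_OFFSETS[o, 3]
    nb <- pad[core + dz, core + dy, core + dx]
    slope <- (as.vector(nb) - v) / (spec$step * sqrt(dx^2 + dy^2 + dz^2))
    upd <- which(slope > best)
    if (length(upd)) {
      best[upd] <- slope[upd]
      nxt[upd] <- upd + (dz + dy * n + dx * n * n)
    }
  }
  escaped <- v < floor
  nxt[escaped] <- which(escaped)  # frozen; overridden below
  ## resolve pointer chains (doubling)
  repeat {
    nxt2 <- nxt[nxt]
    if (identical(nxt2, nxt)) break
    nxt <- nxt2
  }
  roots <- sort(unique(nxt[!escaped]))
  ## attractor coordinates
  g <- make_grid(spec)
  root_xyz <- function(lin) {
    idx <- lin - 1L
    ix <- idx %/% (n * n); rem <- idx - ix * n * n
    iy <- rem %/% n; iz <- rem - iy * n
    cbind(g$x[ix + 1], g$y[iy + 1], g$z[iz + 1])
  }
  apos <- root_xyz(roots)
  ## merge attractor fragments: a discretized flat maximum can yield
  ## several adjacent self-pointing voxels; absorb any root within 2.5
  ## steps of a higher-density root (deterministic: highest peak wins)
  if (length(roots) > 1L) {
    ord <- order(-v[roots])
    keeper <- integer(length(roots))
    for (oi in ord) {
      if (keeper[oi]) next
      d2 <- (apos[, 1] - apos[oi, 1])^2 + (apos[, 2] - apos[oi, 2])^2 +
        (apos[, 3] - apos[oi, 3])^2
      near <- which(d2 <= (2.5 * spec$step)^2 & keeper == 0L)
      keeper[near] <- oi
    }
    if (length(unique(keeper)) < length(roots)) {
      nxt[!escaped] <- roots[keeper[match(nxt[!escaped], roots)]]
      roots <- sort(unique(nxt[!escaped]))
      apos <- root_xyz(roots)
    }
  }
  warnings <- character(0)
  atom <- integer(length(roots))
  for (i in seq_along(roots)) {
    d <- sqrt(rowSums(sweep(geom$pos, 2, apos[i, ])^2))
    j <- which.min(d)
    if (d[j] <= 1.0) atom[i] <- j
    else {
      atom[i] <- NA_integer_
      warnings <- c(warnings,
                    sprintf("non-nuclear attractor at (%.3f, %.3f, %.3f), peak %.3e",
                            apos[i, 1], apos[i, 2], apos[i, 3], v[roots[i]]))
    }
  }
  label <- match(nxt, roots)
  ## refinement pass: the 26-direction quantization of near-grid ascent
  ## drifts along the long, flat chains of the low-density exterior and
  ## mislabels single voxels on basin boundaries.  Both sets are
  ## re-assigned by following the trilinearly interpolated density
  ## gradient (a continuous trajectory) until it reaches a reliably
  ## labelled voxel: dense (rho >= refine_floor) and off the boundary.
  refine_floor <- 1e-3
  if (length(roots) > 1L) {
    lab_pad <- array(0L, dim = c(n + 2L, n + 2L, n + 2L))
    lab0 <- label; lab0[escaped] <- 0L
    lab_pad[core, core, core] <- array(lab0, dim = c(n, n, n))
    is_bnd <- rep(FALSE, n3)
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      nblab <- as.vector(lab_pad[core + o[3], core + o[2], core + o[1]])
      is_bnd <- is_bnd | (nblab != lab0 & nblab > 0L)
    }
    is_refine <- (is_bnd | v < refine_floor) & !escaped
    bnd <- which(is_refine)
    if (length(bnd)) {
      ## central-difference gradient of log(rho): parallel to the
      ## density gradient but numerically faithful in the exponential
      ## tails (unit-step scale suffices)
      lpad <- log(pmax(pad, 1e-300))
      gpad <- function(d) {
        hi <- lpad[core + d[3], core + d[2], core + d[1]]
        lo <- lpad[core - d[3], core - d[2], core - d[1]]
        hi[!is.finite(hi)] <- 0; lo[!is.finite(lo)] <- 0
        (hi - lo) / 2
      }
      gx <- gpad(c(1, 0, 0)); gy <- gpad(c(0, 1, 0)); gz <- gpad(c(0, 0, 1))
      interp3 <- function(f1, f2, f3, fx, fy, fz) {
        i0x <- pmin(floor(fx), n - 2); i0y <- pmin(floor(fy), n - 2)
        i0z <- pmin(floor(fz), n - 2)
        wx <- fx - i0x; wy <- fy - i0y; wz <- fz - i0z
        o1 <- o2 <- o3 <- numeric(length(fx))
        for (b in 0:7) {
          dx <- b %% 2L; dy <- (b %/% 2L) %% 2L; dz <- b %/% 4L
          lin <- (i0x + dx) * n * n + (i0y + dy) * n + (i0z + dz) + 1
          wt <- (if (dx) wx else 1 - wx) * (if (dy) wy else 1 - wy) *
            (if (dz) wz else 1 - wz)
          o1 <- o1 + wt * f1[lin]; o2 <- o2 + wt * f2[lin]
          o3 <- o3 + wt * f3[lin]
        }
        list(x = o1, y = o2, z = o3)
      }
      idx <- bnd - 1L
      fx <- idx %/% (n * n); rem <- idx - fx * n * n
      fy <- rem %/% n; fz <- rem - fy * n
      fx <- as.numeric(fx); fy <- as.numeric(fy); fz <- as.numeric(fz)
      newlab <- label[bnd]
      activeset <- seq_along(bnd)
      hstep <- 0.35
      for (it in 1:400) {
        if (!length(activeset)) break
        ## Heun step on the normalized interpolated gradient
        g1 <- interp3(gx, gy, gz, fx[activeset], fy[activeset], fz[activeset])
        n1 <- pmax(sqrt(g1$x^2 + g1$y^2 + g1$z^2), 1e-300)
        px <- pmin(pmax(fx[activeset] + hstep * g1$x / n1, 0), n - 1)
        py <- pmin(pmax(fy[activeset] + hstep * g1$y / n1, 0), n - 1)
        pz <- pmin(pmax(fz[activeset] + hstep * g1$z / n1, 0), n - 1)
        g2 <- interp3(gx, gy, gz, px, py, pz)
        n2 <- pmax(sqrt(g2$x^2 + g2$y^2 + g2$z^2), 1e-300)
        fx[activeset] <- pmin(pmax(fx[activeset] +
          hstep * (g1$x / n1 + g2$x / n2) / 2, 0), n - 1)
        fy[activeset] <- pmin(pmax(fy[activeset] +
          hstep * (g1$y / n1 + g2$y / n2) / 2, 0), n - 1)
        fz[activeset] <- pmin(pmax(fz[activeset] +
          hstep * (g1$z / n1 + g2$z / n2) / 2, 0), n - 1)
        cur <- round(fx[activeset]) * n * n + round(fy[activeset]) * n +
          round(fz[activeset]) + 1
        done <- !is_refine[cur] & !escaped[cur]
        if (any(done)) {
          newlab[activeset[done]] <- label[cur[done]]
          activeset <- activeset[!done]
        }
      }
      label[bnd] <- newlab
    }
  }
  ## escaped voxels: nearest attractor by distance, for exact conservation
  if (any(escaped)) {
    eidx <- which(escaped)
    exyz <- root_xyz(eidx)
    dmin <- rep(Inf, length(eidx)); amin <- rep(1L, length(eidx))
    for (i in seq_along(roots)) {
      d2 <- (exyz[, 1] - apos[i, 1])^2 + (exyz[, 2] - apos[i, 2])^2 +
        (exyz[, 3] - apos[i, 3])^2
      upd <- d2 < dmin
      dmin[upd] <- d2[upd]; amin[upd] <- i
    }
    label[eidx] <- amin
  }
  structure(list(spec = spec, label = label, escaped = escaped,
                 attractors = data.frame(id = seq_along(roots),
                                         x = apos[, 1], y = apos[, 2],
                                         z = apos[, 3],
                                         peak = v[roots], atom = atom),
                 warnings = warnings),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat(sprintf("basin_map: %d attractor(s), %d/%d voxels escaped\n",
              nrow(x$attractors), sum(x$escaped), length(x$label)))
  if (length(x$warnings)) cat(paste(" !", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' Integrate electron density over unified basins
#'
#' The basins generated once on the reference grid are used to integrate
#' both the density under study and the reference density, so
#' population differences are not affected by basin-boundary
#' differences.
#'
#' @param map `basin_map`.
#' @param density density `scalar_field` of the system under study.
#' @param reference_density reference density on the same spec.
#' @return data.frame (class `basin_populations`) with one row per atom:
#'   `N` (electrons in the system under study), `N_ref`, `delta`.
#' @export
integrate_basins <- function(map, density, reference_density) {
  if (!same_spec(density, reference_density) ||
      !isTRUE(all.equal(map$spec$origin, density$spec$origin)) ||
      map$spec$npoints != density$spec$npoints)
    stop_hc("specs differ", class = "hcfit_alignment_error")
  dv <- map$spec$step^3
  natt <- nrow(map$attractors)
  sum_by <- function(vals) {
    s <- numeric(natt)
    agg <- rowsum(vals, map$label)
    s[as.integer(rownames(agg))] <- agg
    s * dv
  }
  Ns <- sum_by(density$values)
  Nr <- sum_by(reference_density$values)
  atoms <- sort(unique(map$attractors$atom))
  per_atom <- function(Nx) vapply(atoms, function(a)
    sum(Nx[which(map$attractors$atom == a)]), numeric(1))
  out <- data.frame(atom = atoms, N = per_atom(Ns), N_ref = per_atom(Nr))
  out$delta <- out$N - out$N_ref
  attr(out, "total") <- c(N = sum(Ns), N_ref = sum(Nr))
  class(out) <- c("basin_populations", "data.frame")
  out
}

## --- iso-density surfaces (marching tetrahedra) ----------------------

## six tetrahedra tiling the unit cube around the 0-7 main diagonal;
## corner code b = dx + 2 dy + 4 dz
.TET_TABLE <- rbind(c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L),
                    c(0L, 2L, 3L, 7L), c(0L, 2L, 6L, 7L),
                    c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

#' Extract a triangulated iso-density surface
#'
#' Marching-tetrahedra level set: each grid cube is split into six
#' tetrahedra, crossing edges are interpolated linearly and triangulated.
#'
#' @param reference_density density `scalar_field`.
#' @param level iso value (a.u.), strictly inside the field's range.
#' @return object of class `surface_mesh`: `tri` (m x 9 matrix, vertex
#'   triplets), `area` (per triangle, bohr^2), `centroid` (m x 3),
#'   `level`.
#' @export
extract_isosurface <- function(reference_density, level) {
  spec <- reference_density$spec
  n <- spec$npoints
  v <- reference_density$values
  if (level <= min(v) || level >= max(v))
    stop_hc("level %g outside field range [%g, %g]", level, min(v), max(v),
            class = "hcfit_empty_surface_error")
  arr <- array(v, dim = c(n, n, n))  # [iz, iy, ix]
  m <- n - 1L
  ## 8 corner values for every cube, corner code b = dx + 2dy + 4dz
  corner_vals <- vector("list", 8L)
  corner_off <- matrix(0L, 8L, 3L)
  for (b in 0:7) {
    dx <- b %% 2L; dy <- (b %/% 2L) %% 2L; dz <- b %/% 4L
    corner_off[b + 1L, ] <- c(dx, dy, dz)
    corner_vals[[b + 1L]] <- as.vector(arr[(1:m) + dz, (1:m) + dy, (1:m) + dx])
  }
  V <- do.call(cbind, corner_vals)     # ncubes x 8
  keep <- which(matrixStats_rowMins(V) < level & matrixStats_rowMaxs(V) > level)
  if (!length(keep))
    stop_hc("no crossing cubes at level %g", level,
            class = "hcfit_empty_surface_error")
  ## cube base coordinates (0-based indices, z fastest within cubes)
  idx <- keep - 1L
  cx <- idx %/% (m * m); rem <- idx - cx * m * m
  cy <- rem %/% m; cz <- rem - cy * m
  base <- cbind(spec$origin[1] + spec$step * cx,
                spec$origin[2] + spec$step * cy,
                spec$origin[3] + spec$step * cz)
  Vk <- V[keep, , drop = FALSE]
  tris <- list()
  interp <- function(ia, ib, sel) {
    va <- Vk[sel, ia + 1L]; vb <- Vk[sel, ib + 1L]
    t <- (level - va) / (vb - va)
    pa <- corner_off[ia + 1L, ]; pb <- corner_off[ib + 1L, ]
    base[sel, , drop = FALSE] +
      spec$step * (rep(1, length(sel)) %o% pa + t %o% (pb - pa))
  }
  for (tt in seq_len(nrow(.TET_TABLE))) {
    cn <- .TET_TABLE[tt, ]
    above <- (Vk[, cn + 1L] > level)
    code <- above %*% c(1L, 2L, 4L, 8L)
    for (cs in 1:14) {
      sel <- which(code == cs)
      if (!length(sel)) next
      bits <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      hi <- cn[bits]; lo <- cn[!bits]
      if (length(hi) == 1L || length(lo) == 1L) {
        lone <- if (length(hi) == 1L) hi else lo
        oth <- if (length(hi) == 1L) lo else hi
        p1 <- interp(lone, oth[1], sel)
        p2 <- interp(lone, oth[2], sel)
        p3 <- interp(lone, oth[3], sel)
        tris[[length(tris) + 1L]] <- cbind(p1, p2, p3)
      } else {
        ## 2 above / 2 below: quad over the four crossing edges
        q1 <- interp(hi[1], lo[1], sel)
        q2 <- interp(hi[1], lo[2], sel)
        q3 <- interp(hi[2], lo[2], sel)
        q4 <- interp(hi[2], lo[1], sel)
        tris[[length(tris) + 1L]] <- cbind(q1, q2, q3)
        tris[[length(tris) + 1L]] <- cbind(q1, q3, q4)
      }
    }
  }
  tri <- do.call(rbind, tris)
  e1 <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  e2 <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cxv <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- 0.5 * sqrt(rowSums(cxv^2))
  ok <- area > 1e-20
  tri <- tri[ok, , drop = FALSE]; area <- area[ok]
  centroid <- (tri[, 1:3] + tri[, 4:6] + tri[, 7:9]) / 3
  structure(list(level = level, tri = tri, area = area, centroid = centroid),
            class = "surface_mesh")
}

## row min/max without extra deps
matrixStats_rowMins <- function(x) do.call(pmin, as.data.frame(x))
matrixStats_rowMaxs <- function(x) do.call(pmax, as.data.frame(x))

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: level %g, %d triangles, area %.4g bohr^2\n",
              x$level, nrow(x$tri), sum(x$area)))
  invisible(x)
}

#' Trilinear interpolation of a field at arbitrary points
#'
#' @param field `scalar_field`.
#' @param points m x 3 matrix, bohr; must lie inside the grid box.
#' @export
field_interpolate <- function(field, points) {
  spec <- field$spec
  n <- spec$npoints
  f <- sweep(points, 2, spec$origin) / spec$step
  if (any(f < -1e-9) || any(f > n - 1 + 1e-9))
    stop_hc("point outside grid box", class = "hcfit_bounds_error")
  f <- pmin(pmax(f, 0), n - 1 - 1e-12)
  i0 <- floor(f)
  w <- f - i0
  acc <- numeric(nrow(points))
  for (b in 0:7) {
    dx <- b %% 2L; dy <- (b %/% 2L) %% 2L; dz <- b %/% 4L
    lin <- (i0[, 1] + dx) * n * n + (i0[, 2] + dy) * n + (i0[, 3] + dz) + 1
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    acc <- acc + wt * field$values[lin]
  }
  acc
}

#' Surface-averaged electrostatic potential
#'
#' Area-weighted mean of the ESP interpolated at triangle centroids
#' (the discrete surface integral divided by total area); an unweighted
#' point-sampled mode is available for cross-checking.  Min and max are
#' taken over centroids.
#'
#' @param mesh `surface_mesh`.
#' @param esp esp `scalar_field` covering the mesh.
#' @param weighted area-weighted (default) or plain centroid mean.
#' @return list of class `surface_stats`: `level`, `mean`, `min`,
#'   `max`, plus the centroid `values` and `areas` for error metrics.
#' @export
surface_average_esp <- function(mesh, esp, weighted = TRUE) {
  vals <- field_interpolate(esp, mesh$centroid)
  w <- if (weighted) mesh$area else rep(1, length(vals))
  structure(list(level = mesh$level,
                 mean = sum(w * vals) / sum(w),
                 min = min(vals), max = max(vals),
                 values = vals, areas = mesh$area),
            class = "surface_stats")
}

#' Export a mesh in Wavefront OBJ format
#' @param mesh `surface_mesh`.
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  nt <- nrow(mesh$tri)
  vs <- rbind(mesh$tri[, 1:3], mesh$tri[, 4:6], mesh$tri[, 7:9])
  ord <- as.vector(t(cbind(seq_len(nt), seq_len(nt) + nt, seq_len(nt) + 2 * nt)))
  vs <- vs[ord, , drop = FALSE]
  writeLines(sprintf("v %.8f %.8f %.8f", vs[, 1], vs[, 2], vs[, 3]), con)
  i <- 3 * (seq_len(nt) - 1)
  writeLines(sprintf("f %d %d %d", i + 1, i + 2, i + 3), con)
  invisible(path)
}
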