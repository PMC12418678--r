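## Static structure factors of an isolated molecule in a large
## pseudo-cubic cell.
##
## Convention: F(H) = integral rho(r) exp(+2 pi i H . r_frac) dV, cubic
## metric s = sin(theta)/lambda = |(h,k,l)| / (2a).  The aspherical term
## transforms analytically through the Fourier-Bessel integral of the
## single-Slater radial functions; a grid-FFT numeric oracle provides an
## independent check.

#' Generate the reciprocal lattice of a pseudo-cubic cell
#'
#' All integer triples with `0 < |(h,k,l)|/(2a) <= s_max`; the origin is
#' strictly excluded, the upper bound is inclusive.  Lexicographic
#' ordering in (h, k, l).
#'
#' @param a cubic cell edge, Angstrom.
#' @param s_max resolution limit sin(theta)/lambda, Angstrom^-1.
#' @param friedel_unique keep exactly one of each +/-H pair.
#' @return object of class `hkl_set` with fields `a`, `s_max`, `hkl`
#'   (integer matrix), `s` (Angstrom^-1), `friedel_unique`.
#' @export
generate_hkl <- function(a, s_max, friedel_unique = FALSE) {
  if (a <= 0 || s_max <= 0)
    stop_hc("a and s_max must be positive", class = "hcfit_domain_error")
  hmax <- floor(2 * a * s_max)
  rng <- seq.int(-hmax, hmax)
  g <- expand.grid(l = rng, k = rng, h = rng)  # h slowest for lexicographic order
  hkl <- cbind(g$h, g$k, g$l)
  n2 <- rowSums(hkl^2)
  keep <- n2 > 0 & n2 <= (2 * a * s_max)^2
  if (friedel_unique)
    keep <- keep & (hkl[, 1] > 0 |
                      (hkl[, 1] == 0 & hkl[, 2] > 0) |
                      (hkl[, 1] == 0 & hkl[, 2] == 0 & hkl[, 3] > 0))
  hkl <- hkl[keep, , drop = FALSE]
  ord <- order(hkl[, 1], hkl[, 2], hkl[, 3])
  hkl <- hkl[ord, , drop = FALSE]
  structure(list(a = a, s_max = s_max, hkl = hkl,
                 s = sqrt(rowSums(hkl^2)) / (2 * a),
                 friedel_unique = friedel_unique),
            class = "hkl_set")
}

#' @export
print.hkl_set <- function(x, ...) {
  cat(sprintf("hkl_set: a = %g A, s_max = %g A^-1, %d reflections%s\n",
              x$a, x$s_max, nrow(x$hkl),
              if (x$friedel_unique) " (Friedel-unique)" else ""))
  invisible(x)
}

## spherical Bessel j_l(x) = sum_k [ sc_k sin(x) + cc_k cos(x) ] / x^k
.JL_SIN <- list(c(`1` = 1), c(`2` = 1), c(`3` = 3, `1` = -1),
                c(`4` = 15, `2` = -6), c(`5` = 105, `3` = -45, `1` = 1))
.JL_COS <- list(numeric(0), c(`1` = -1), c(`2` = -3),
                c(`3` = -15, `1` = 1), c(`4` = -105, `2` = 10))

sph_bessel <- function(l, x) {
  out <- numeric(length(x))
  big <- abs(x) > 0.5
  if (any(big)) {
    xb <- x[big]; acc <- 0
    for (k in names(.JL_SIN[[l + 1L]]))
      acc <- acc + .JL_SIN[[l + 1L]][[k]] * sin(xb) / xb^as.integer(k)
    for (k in names(.JL_COS[[l + 1L]]))
      acc <- acc + .JL_COS[[l + 1L]][[k]] * cos(xb) / xb^as.integer(k)
    out[big] <- acc
  }
  if (any(!big)) {  # ascending series, 12 terms: |x| <= 0.5 is ample
    xs <- x[!big]; term <- xs^l / dfact_odd(l); acc <- term
    for (j in 1:12) {
      term <- -term * xs^2 / (2 * j * (2 * l + 2 * j + 1))
      acc <- acc + term
    }
    out[!big] <- acc
  }
  out
}

## G(m, l; zeta, q) = integral_0^inf r^m exp(-zeta r) j_l(q r) dr.
## Closed form termwise (valid for m >= l + 1), with an ascending series
## in q below q = 0.2 zeta where the termwise form cancels badly.
.G_integral <- function(m, l, zeta, q) {
  out <- numeric(length(q))
  lo <- q <= 0.2 * zeta
  if (any(lo)) {
    qs <- q[lo]
    term <- qs^l * fact(m + l) / (zeta^(m + l + 1) * dfact_odd(l))
    acc <- term
    for (j in 0:60) {
      term <- -term * qs^2 * (m + l + 2 * j + 1) * (m + l + 2 * j + 2) /
        (zeta^2 * 2 * (j + 1) * (2 * l + 2 * j + 3))
      acc <- acc + term
      if (max(abs(term)) < 1e-17 * max(abs(acc), 1e-300)) break
    }
    out[lo] <- acc
  }
  if (any(!lo)) {
    qh <- q[!lo]
    den <- complex(real = zeta, imaginary = -qh)
    acc <- numeric(length(qh))
    for (k in names(.JL_SIN[[l + 1L]])) {
      ki <- as.integer(k)
      acc <- acc + .JL_SIN[[l + 1L]][[k]] / qh^ki *
        Im(fact(m - ki) / den^(m - ki + 1))
    }
    for (k in names(.JL_COS[[l + 1L]])) {
      ki <- as.integer(k)
      acc <- acc + .JL_COS[[l + 1L]][[k]] / qh^ki *
        Re(fact(m - ki) / den^(m - ki + 1))
    }
    out[!lo] <- acc
  }
  out
}

#' Fourier-Bessel transform of a normalized Slater radial function
#'
#' `<j_l>(q) = integral N r^n exp(-zeta r) j_l(q r) r^2 dr` with
#' `N = zeta^(n+3)/(n+2)!`.  `<j_0>(0) = 1`; `<j_l>(0) = 0` for l >= 1.
#'
#' @param l Bessel order 0..4.
#' @param n radial power (`n >= l - 1` for the closed form; smaller
#'   valid n fall back to quadrature).
#' @param zeta Slater exponent, bohr^-1.
#' @param q momentum transfer `2 pi |S|`, bohr^-1 (vectorized).
#' @param method `"closed"` (default) or `"quadrature"` (adaptive
#'   integration cross-check).
#' @return dimensionless transform values.
#' @export
slater_jl_transform <- function(l, n, zeta, q,
                                method = c("closed", "quadrature")) {
  method <- match.arg(method)
  if (l < 0L || l > 4L || n < 0L || (l >= 1L && n < 1L))
    stop_hc("invalid (l = %d, n = %d)", l, n, class = "hcfit_domain_error")
  if (zeta <= 0) stop_hc("zeta must be positive", class = "hcfit_domain_error")
  if (any(q < 0)) stop_hc("q must be >= 0", class = "hcfit_domain_error")
  N <- zeta^(n + 3) / fact(n + 2)
  if (method == "quadrature" || n < l - 1L) {
    up <- RADIAL_RMAX / zeta * 4
    return(vapply(q, function(qi)
      N * integrate(function(r) r^(n + 2) * exp(-zeta * r) * sph_bessel(l, qi * r),
                    0, up, rel.tol = 1e-11, abs.tol = 1e-13,
                    subdivisions = 2000L)$value,
      numeric(1)))
  }
  N * .G_integral(n + 2L, l, zeta, q)
}

## spherical scattering factor of a density expansion (already carrying
## its own coefficients): f(q) = sum_i c_i 4 pi G(n_i + 2, 0; zeta_i, q)
.density_form_factor <- function(tt, q) {
  out <- numeric(length(q))
  for (i in seq_len(nrow(tt)))
    out <- out + tt$coeff[i] * 4 * pi * .G_integral(tt$n[i] + 2L, 0L, tt$zeta[i], q)
  out
}

## per-reflection geometry shared by all atoms of a model
.hkl_cache <- function(hkl, a_bohr) {
  H <- hkl$hkl
  hn <- sqrt(rowSums(H^2))
  list(H = H, q = 2 * pi * hn / a_bohr,
       u = H / hn,  # global unit directions
       a_bohr = a_bohr)
}

## complex multipole basis of one atom: the vector dF/dP for each
## population, and the spherical pieces; phase included
.atom_sf_terms <- function(atom, model, cache, include_core = FALSE) {
  entry <- databank_entry(model$bank, atom$element)
  x <- model$geometry$pos[atom$index, ]
  phase <- exp(complex(imaginary = 2 * pi *
                         as.vector(cache$H %*% x) / cache$a_bohr))
  ## per-electron valence form factor: the stored density integrates to
  ## n_val, P_val scales the unit-normalized shape
  fval <- .density_form_factor(entry$valence_terms, cache$q / atom$kappa) /
    entry$n_val
  out <- list(phase = phase, fval = fval * phase)
  if (include_core)
    out$fcore <- .density_form_factor(entry$core_terms, cache$q) * phase
  if (length(atom$Plm)) {
    ul <- cache$u %*% atom$frame$R
    jl <- list()
    basis <- vector("list", length(atom$Plm))
    names(basis) <- names(atom$Plm)
    for (k in seq_along(atom$Plm)) {
      lms <- strsplit(names(atom$Plm)[k], ",")[[1]]
      l <- as.integer(lms[1]); m <- as.integer(lms[2]); s <- lms[3]
      lk <- as.character(l)
      if (is.null(jl[[lk]]))
        jl[[lk]] <- slater_jl_transform(l, entry$def_n[l + 1L],
                                        entry$def_zeta[l + 1L],
                                        cache$q / atom$kappa_prime)
      basis[[k]] <- (4 * pi * (1i)^l) * jl[[lk]] *
        dlm_eval(l, m, s, ul[, 1], ul[, 2], ul[, 3]) * phase
    }
    out$basis <- basis
  }
  out
}

.atom_sf <- function(atom, model, cache, include_core) {
  tm <- .atom_sf_terms(atom, model, cache, include_core = include_core)
  F <- atom$P_val * tm$fval
  if (include_core) F <- F + atom$P_core * tm$fcore
  if (!is.null(tm$basis))
    for (k in seq_along(tm$basis))
      if (atom$Plm[k] != 0) F <- F + atom$Plm[k] * tm$basis[[k]]
  F
}

#' Analytic static structure factors of a multipole model
#'
#' @param model `mm_model`.
#' @param hkl `hkl_set`.
#' @param include_core include core scattering (`FALSE` gives the
#'   valence-only structure factors used in the refinement).
#' @return object of class `sf_set`: fields `hkl`, `F` (complex,
#'   electrons), `valence_only`.
#' @export
structure_factors <- function(model, hkl, include_core = FALSE) {
  cache <- .hkl_cache(hkl, hkl$a / BOHR_A)
  F <- complex(nrow(hkl$hkl))
  for (a in model$atoms)
    F <- F + .atom_sf(a, model, cache, include_core = include_core)
  structure(list(hkl = hkl, F = F, valence_only = !include_core),
            class = "sf_set")
}

#' @export
print.sf_set <- function(x, ...) {
  cat(sprintf("sf_set: %d reflections, %s\n", length(x$F),
              if (x$valence_only) "valence-only" else "with core"))
  invisible(x)
}

#' Grid-FFT oracle for structure factors
#'
#' Treats the field as one period of the cell: the grid must tile the
#' cell, i.e. `npoints * step` equals the cell edge.  The discrete
#' Fourier transform of the sampled density, scaled by the voxel volume,
#' is indexed at the requested reflections.  Independent of the analytic
#' route; used to validate it.
#'
#' @param field `scalar_field` (density).
#' @param hkl `hkl_set` whose cell edge matches the field box.
#' @return `sf_set`.
#' @export
fft_oracle <- function(field, hkl) {
  spec <- field$spec
  n <- spec$npoints
  a_bohr <- hkl$a / BOHR_A
  if (abs(n * spec$step - a_bohr) > 1e-6 * a_bohr)
    stop_hc("field box (%g bohr) does not tile the cell (%g bohr)",
            n * spec$step, a_bohr, class = "hcfit_resolution_error")
  hmax <- max(abs(hkl$hkl))
  if (hmax > n / 2 - 1)
    stop_hc("grid too coarse: max index %d exceeds Nyquist limit %d",
            hmax, as.integer(n / 2 - 1), class = "hcfit_resolution_error")
  arr <- array(field$values, dim = c(n, n, n))  # x slowest -> dim order (z,y,x)
  Fg <- fft(arr, inverse = TRUE) * spec$step^3
  idx <- (hkl$hkl %% n) + 1L
  F <- Fg[cbind(idx[, 3], idx[, 2], idx[, 1])]
  ## shift for the grid origin
  F <- F * exp(complex(imaginary = 2 * pi *
                         as.vector(hkl$hkl %*% spec$origin) / a_bohr))
  structure(list(hkl = hkl, F = F, valence_only = NA),
            class = "sf_set")
}

#' Read / write structure-factor files
#'
#' Whitespace-separated text `h k l F_real F_imag` with a header line
#' recording the cell edge, resolution limit and valence-only flag.
#' @param sf `sf_set`.
#' @param path file path.
#' @export
write_sf <- function(sf, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# a=%.10g s_max=%.10g valence_only=%d friedel_unique=%d",
                     sf$hkl$a, sf$hkl$s_max, as.integer(isTRUE(sf$valence_only)),
                     as.integer(sf$hkl$friedel_unique)), con)
  writeLines(sprintf("%d %d %d %.17g %.17g", sf$hkl$hkl[, 1], sf$hkl$hkl[, 2],
                     sf$hkl$hkl[, 3], Re(sf$F), Im(sf$F)), con)
  invisible(path)
}

#' @rdname write_sf
#' @export
read_sf <- function(path) {
  lines <- readLines(path)
  tok <- strsplit(sub("^#\\s*", "", lines[1]), "\\s+")[[1]]
  kv <- setNames(as.numeric(sub(".*=", "", tok)), sub("=.*", "", tok))
  a <- kv[["a"]]; s_max <- kv[["s_max"]]
  vo <- kv[["valence_only"]] == 1; fu <- kv[["friedel_unique"]] == 1
  dat <- read.table(text = lines[-1])
  hkl <- structure(list(a = a, s_max = s_max,
                        hkl = as.matrix(dat[, 1:3]),
                        s = sqrt(rowSums(as.matrix(dat[, 1:3])^2)) / (2 * a),
                        friedel_unique = fu),
                   class = "hkl_set")
  structure(list(hkl = hkl,
                 F = complex(real = dat[, 4], imaginary = dat[, 5]),
                 valence_only = vo),
            class = "sf_set")
}
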