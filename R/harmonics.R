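## Density-normalized real spherical harmonics d_lm (l <= 4).
##
## The aspherical pseudo-atom term uses angular functions normalized so
## that a population of P_lm electrons moves |P_lm| electrons between the
## positive and negative lobes: integral of |d_lm| over the sphere is 2
## for l >= 1, and d_00 = 1/(4*pi) (integral 1).  Any such d_lm is a fixed
## multiple of the orthonormal real spherical harmonic, so Fourier and
## Poisson identities for Y_lm carry over unchanged.

.hc_cache <- new.env(parent = emptyenv())

## m-th derivatives of the Legendre polynomials P_l, as coefficient
## vectors in ascending powers of z:  Q_lm(z) = d^m P_l / dz^m, so that
## P_l^m(z) = (1-z^2)^(m/2) Q_lm(z)  (no Condon-Shortley phase).
.legendre_deriv <- list(
  list(c(1)),                                     # l = 0
  list(c(0, 1), c(1)),                            # l = 1
  list(c(-0.5, 0, 1.5), c(0, 3), c(3)),           # l = 2
  list(c(0, -1.5, 0, 2.5), c(-1.5, 0, 7.5),
       c(0, 15), c(15)),                          # l = 3
  list(c(3, 0, -30, 0, 35) / 8, c(0, -7.5, 0, 17.5),
       c(-7.5, 0, 52.5), c(0, 105), c(105))       # l = 4
)

.polyval_asc <- function(coef, x) {
  ## Horner in ascending-coefficient order
  y <- rep(coef[length(coef)], length(x))
  if (length(coef) > 1L)
    for (i in seq(length(coef) - 1L, 1L)) y <- y * x + coef[i]
  y
}

## |integral| of |Q_lm(x)| (1-x^2)^(m/2) over [-1, 1], split at the real
## roots of Q_lm so each piece is smooth.
.theta_norm_integral <- function(l, m) {
  coef <- .legendre_deriv[[l + 1L]][[m + 1L]]
  f <- function(x) abs(.polyval_asc(coef, x)) * (1 - x^2)^(m / 2)
  brk <- c(-1, 1)
  if (length(coef) > 1L) {
    rts <- polyroot(coef)
    re <- Re(rts)[abs(Im(rts)) < 1e-10]
    brk <- sort(unique(c(-1, re[re > -1 & re < 1], 1)))
  }
  tot <- 0
  for (i in seq_len(length(brk) - 1L))
    tot <- tot + integrate(f, brk[i], brk[i + 1L],
                           rel.tol = 1e-13, abs.tol = 1e-14)$value
  tot
}

## Normalization constant N_lm of the density-normalized harmonic.
dlm_norm <- function(l, m) {
  key <- paste0("Nlm_", l, "_", m)
  val <- .hc_cache[[key]]
  if (!is.null(val)) return(val)
  if (l == 0L) {
    val <- 1 / (4 * pi)
  } else {
    phi <- if (m == 0L) 2 * pi else 4
    val <- 2 / (phi * .theta_norm_integral(l, m))
  }
  .hc_cache[[key]] <- val
  val
}

#' Evaluate a density-normalized real spherical harmonic
#'
#' @param l integer 0..4.
#' @param m integer 0..l.
#' @param sgn `"+"` (cosine-type) or `"-"` (sine-type); `m = 0` admits
#'   only `"+"`.
#' @param ux,uy,uz components of unit direction vectors (recycled
#'   together); need not be exactly unit length, the polynomial form in
#'   direction cosines is used as given.
#' @return numeric vector of d_lm values.
#' @keywords internal
dlm_eval <- function(l, m, sgn, ux, uy, uz) {
  if (l < 0L || l > 4L || m < 0L || m > l)
    stop_hc("unsupported (l = %d, m = %d)", l, m, class = "hcfit_capability_error")
  if (m == 0L && sgn != "+")
    stop_hc("m = 0 has no sine component")
  qv <- .polyval_asc(.legendre_deriv[[l + 1L]][[m + 1L]], uz)
  if (m == 0L) {
    ang <- qv
  } else {
    w <- complex(real = ux, imaginary = uy)^m
    ang <- qv * if (sgn == "+") Re(w) else Im(w)
  }
  dlm_norm(l, m) * ang
}

#' Table of multipole (l, m, sgn) terms up to lmax
#'
#' @param lmax highest l included.
#' @param lmin lowest l included (default 1; the deformation monopole
#'   l = 0 is off by default in models).
#' @param m0_only if TRUE keep only m = 0 terms (bond-oriented hydrogens).
#' @return data.frame with columns `l`, `m`, `s`.
#' @keywords internal
multipole_terms <- function(lmax, lmin = 1L, m0_only = FALSE) {
  if (lmax < lmin) return(data.frame(l = integer(), m = integer(), s = character(),
                                     stringsAsFactors = FALSE))
  out <- list()
  for (l in seq(lmin, lmax)) {
    ms <- if (m0_only) 0L else 0L:l
    for (m in ms) {
      out[[length(out) + 1L]] <- data.frame(l = l, m = m, s = "+",
                                            stringsAsFactors = FALSE)
      if (m > 0L && !m0_only)
        out[[length(out) + 1L]] <- data.frame(l = l, m = m, s = "-",
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

## canonical key for one angular term, e.g. "2,1,-"
term_key <- function(l, m, s) paste(l, m, s, sep = ",")
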