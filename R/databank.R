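## Slater-type radial-function databanks.
##
## An entry stores the *density* expansions directly: the spherical core
## and spherical valence densities are sums  sum_i c_i r^(n_i) exp(-z_i r)
## (e bohr^-3), pre-squared from orbital products offline, and the
## aspherical deformation uses one normalized single-Slater radial
## function per l:  R_l(r) = N r^(n_l) exp(-z_l r),
## N = z_l^(n_l+3)/(n_l+2)!  so that  integral R_l r^2 dr = 1.

RADIAL_RMAX <- 60  # bohr; exp(-zeta*r) underflows far earlier for physical zeta

new_element_entry <- function(symbol, Z, n_core, n_val,
                              core_terms, valence_terms,
                              def_n, def_zeta, lmax) {
  stopifnot(Z > 0, n_core >= 0, n_val >= 0)
  chk <- function(tt, what) {
    if (nrow(tt) && any(tt$zeta <= 0))
      stop_hc("%s: non-positive Slater exponent in %s terms", symbol, what,
              class = "hcfit_validation_error")
    if (nrow(tt) && any(tt$n < 0))
      stop_hc("%s: negative radial power in %s terms", symbol, what,
              class = "hcfit_validation_error")
  }
  chk(core_terms, "core"); chk(valence_terms, "valence")
  if (lmax >= 1) {
    if (any(def_zeta[seq_len(lmax + 1L)] <= 0))
      stop_hc("%s: non-positive deformation exponent", symbol,
              class = "hcfit_validation_error")
    if (any(def_n[-1L][seq_len(lmax)] < 1))
      stop_hc("%s: deformation n_l must be >= 1 for l >= 1", symbol,
              class = "hcfit_validation_error")
  }
  structure(list(symbol = symbol, Z = as.integer(Z),
                 n_core = n_core, n_val = n_val,
                 core_terms = core_terms, valence_terms = valence_terms,
                 def_n = def_n, def_zeta = def_zeta,
                 lmax = as.integer(lmax)),
            class = "element_entry")
}

slater_terms <- function(coeff, n, zeta) {
  data.frame(coeff = as.numeric(coeff), n = as.integer(n),
             zeta = as.numeric(zeta))
}

## integral of a density expansion over all space (4*pi r^2 weight), exact
.terms_integral <- function(tt) {
  if (!nrow(tt)) return(0)
  sum(tt$coeff * 4 * pi * fact(tt$n + 2L) / tt$zeta^(tt$n + 3L))
}

#' Spherical core or valence density of a databank entry
#'
#' @param entry an element entry from a [load_databank()] databank.
#' @param component `"core"` or `"valence"`.
#' @param r radii in bohr (vectorized), `r >= 0`.
#' @return density in e bohr^-3.
#' @export
spherical_density <- function(entry, component = c("core", "valence"), r) {
  component <- match.arg(component)
  if (any(r < 0)) stop_hc("negative radius", class = "hcfit_domain_error")
  tt <- if (component == "core") entry$core_terms else entry$valence_terms
  out <- numeric(length(r))
  for (i in seq_len(nrow(tt)))
    out <- out + tt$coeff[i] * r^tt$n[i] * exp(-tt$zeta[i] * r)
  out
}

#' Normalized deformation radial function R_l
#'
#' Single-Slater form `N r^n exp(-zeta r)` with
#' `N = zeta^(n+3)/(n+2)!`, so `integral R_l r^2 dr = 1`.
#'
#' @param entry element entry.
#' @param l multipole order, `0 <= l <= entry$lmax`.
#' @param r radii in bohr (vectorized).
#' @return radial value in bohr^-3.
#' @export
deformation_radial <- function(entry, l, r) {
  if (l < 0L || l > entry$lmax)
    stop_hc("element %s supports l <= %d (asked %d)", entry$symbol,
            entry$lmax, l, class = "hcfit_capability_error")
  if (any(r < 0)) stop_hc("negative radius", class = "hcfit_domain_error")
  n <- entry$def_n[[l + 1L]]
  z <- entry$def_zeta[[l + 1L]]
  z^(n + 3) / fact(n + 2) * r^n * exp(-z * r)
}

.validate_entry <- function(entry, tol = 1e-6) {
  for (comp in c("core", "valence")) {
    nexp <- if (comp == "core") entry$n_core else entry$n_val
    got <- .terms_integral(if (comp == "core") entry$core_terms else entry$valence_terms)
    if (abs(got - nexp) > tol)
      stop_hc("%s: %s density integrates to %.8f, expected %g",
              entry$symbol, comp, got, nexp, class = "hcfit_validation_error")
  }
  invisible(entry)
}

#' Load a radial-function databank
#'
#' `source` is either the name of a built-in databank
#' (`"hydrogenic-test"`, `"slater-rules"`) or a path to a plain-text
#' databank file.  File schema, per element: a header line
#' `ELEM <symbol> <Z> <n_core> <n_val> <lmax>`, then `CORE` / `VAL`
#' section markers followed by term lines `<coeff> <n> <zeta>`, then
#' `DEF l=<l> n=<n> zeta=<z>` lines.  `#` starts a comment.
#'
#' Normalization invariants (core and valence densities integrate to
#' their electron counts) are verified on load.
#'
#' @param source built-in name or file path.
#' @return object of class `radial_databank`.
#' @export
load_databank <- function(source) {
  if (source %in% c("hydrogenic-test", "slater-rules"))
    return(builtin_databank(source))
  if (!file.exists(source))
    stop_hc("databank '%s' is neither a built-in nor a file", source,
            class = "hcfit_lookup_error")
  lines <- readLines(source)
  entries <- list(); cur <- NULL; section <- NULL
  flush_cur <- function(cur) {
    e <- new_element_entry(cur$symbol, cur$Z, cur$n_core, cur$n_val,
                           do.call(rbind, cur$core) %||% slater_terms(numeric(0), integer(0), numeric(0)),
                           do.call(rbind, cur$val) %||% slater_terms(numeric(0), integer(0), numeric(0)),
                           cur$def_n, cur$def_zeta, cur$lmax)
    .validate_entry(e)
  }
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    tok <- strsplit(ln, "\\s+")[[1]]
    if (tok[1] == "ELEM") {
      if (length(tok) != 6L)
        stop_hc("line %d: malformed ELEM header", i, class = "hcfit_parse_error")
      if (!is.null(cur)) entries[[cur$symbol]] <- flush_cur(cur)
      lmax <- as.integer(tok[6])
      cur <- list(symbol = tok[2], Z = as.integer(tok[3]),
                  n_core = as.numeric(tok[4]), n_val = as.numeric(tok[5]),
                  lmax = lmax, core = list(), val = list(),
                  def_n = rep(NA_integer_, lmax + 1L),
                  def_zeta = rep(NA_real_, lmax + 1L))
      section <- NULL
    } else if (tok[1] %in% c("CORE", "VAL")) {
      section <- tok[1]
    } else if (tok[1] == "DEF") {
      kv <- sub("^.*=", "", tok[-1])
      names(kv) <- sub("=.*$", "", tok[-1])
      l <- as.integer(kv[["l"]]); n <- as.integer(kv[["n"]])
      z <- as.numeric(kv[["zeta"]])
      if (is.na(l) || is.na(n) || is.na(z) || l > cur$lmax)
        stop_hc("line %d: malformed DEF line", i, class = "hcfit_parse_error")
      if (z <= 0)
        stop_hc("line %d: non-positive zeta", i, class = "hcfit_validation_error")
      cur$def_n[l + 1L] <- n; cur$def_zeta[l + 1L] <- z
    } else {
      if (is.null(section))
        stop_hc("line %d: term line outside CORE/VAL section", i,
                class = "hcfit_parse_error")
      v <- suppressWarnings(as.numeric(tok))
      if (length(v) != 3L || anyNA(v))
        stop_hc("line %d: malformed term line", i, class = "hcfit_parse_error")
      if (v[3] <= 0)
        stop_hc("line %d: non-positive zeta", i, class = "hcfit_validation_error")
      tt <- slater_terms(v[1], v[2], v[3])
      if (section == "CORE") cur$core[[length(cur$core) + 1L]] <- tt
      else cur$val[[length(cur$val) + 1L]] <- tt
    }
  }
  if (!is.null(cur)) entries[[cur$symbol]] <- flush_cur(cur)
  structure(list(name = basename(source), entries = entries),
            class = "radial_databank")
}

#' Write a databank to its plain-text file format
#' @param bank a `radial_databank`.
#' @param path output file.
#' @export
write_databank <- function(bank, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# radial-function databank: %s", bank$name), con)
  for (e in bank$entries) {
    writeLines(sprintf("ELEM %s %d %.10g %.10g %d",
                       e$symbol, e$Z, e$n_core, e$n_val, e$lmax), con)
    wt <- function(tag, tt) {
      writeLines(tag, con)
      for (i in seq_len(nrow(tt)))
        writeLines(sprintf("  %.17g %d %.17g", tt$coeff[i], tt$n[i], tt$zeta[i]), con)
    }
    wt("CORE", e$core_terms); wt("VAL", e$valence_terms)
    for (l in 0:e$lmax)
      if (!is.na(e$def_n[l + 1L]))
        writeLines(sprintf("DEF l=%d n=%d zeta=%.17g",
                           l, e$def_n[l + 1L], e$def_zeta[l + 1L]), con)
  }
  invisible(path)
}

## single-shell density entry helper: n_el electrons in r^n exp(-zeta r),
## coefficient chosen so the 4*pi r^2 integral is exactly n_el
.shell <- function(n_el, n, zeta)
  slater_terms(n_el * zeta^(n + 3) / (4 * pi * fact(n + 2)), n, zeta)

#' Built-in databanks
#'
#' `"hydrogenic-test"`: hydrogen only, exact 1s density
#' `rho_val = (1/pi) exp(-2r)`.
#'
#' `"slater-rules"`: a synthetic databank for H, C, N, O, Mg, Cl whose
#' shell exponents follow Slater screening rules (each shell a single
#' Slater density term, exactly normalized to its electron count).  It is
#' *not* a reproduction of any published table; it plays the structural
#' role of the Clementi-Roetti-like or Su-Coppens-Macchi-like banks.
#' Deformation exponents equal the valence density exponent, with
#' conventional powers n_l (H: 1,2 for l = 1,2; first row: 2,2,3,4;
#' third row: 4,4,4,4).
#'
#' @param name built-in name.
#' @return `radial_databank`.
#' @export
builtin_databank <- function(name = c("slater-rules", "hydrogenic-test")) {
  name <- match.arg(name)
  empty <- slater_terms(numeric(0), integer(0), numeric(0))
  if (name == "hydrogenic-test") {
    h <- new_element_entry("H", 1, 0, 1, empty, .shell(1, 0, 2),
                           def_n = c(0L, 1L, 2L), def_zeta = c(2, 2, 2), lmax = 2L)
    return(structure(list(name = name, entries = list(H = .validate_entry(h))),
                     class = "radial_databank"))
  }
  ## Slater screening: zeta_orb = (Z - s)/n*, density exponent 2*zeta_orb.
  mk1row <- function(sym, Z, nval, z1s, zval) {
    new_element_entry(sym, Z, 2, nval,
                      .shell(2, 0, 2 * z1s), .shell(nval, 2, 2 * zval),
                      def_n = c(0L, 2L, 2L, 3L, 4L),
                      def_zeta = rep(2 * zval, 5), lmax = 4L)
  }
  mk3row <- function(sym, Z, nval, z1s, z2, zval) {
    core <- rbind(.shell(2, 0, 2 * z1s), .shell(8, 2, 2 * z2))
    new_element_entry(sym, Z, 10, nval,
                      core, .shell(nval, 4, 2 * zval),
                      def_n = c(0L, 4L, 4L, 4L, 4L),
                      def_zeta = rep(2 * zval, 5), lmax = 4L)
  }
  entries <- list(
    H  = new_element_entry("H", 1, 0, 1, empty, .shell(1, 0, 2),
                           def_n = c(0L, 1L, 2L), def_zeta = c(2, 2, 2),
                           lmax = 2L),
    C  = mk1row("C", 6, 4, 5.70, 1.625),
    N  = mk1row("N", 7, 5, 6.70, 1.95),
    O  = mk1row("O", 8, 6, 7.70, 2.275),
    Mg = mk3row("Mg", 12, 2, 11.70, 3.925, 0.95),
    Cl = mk3row("Cl", 17, 7, 16.70, 6.425, 2.0333333333333333)
  )
  entries <- lapply(entries, .validate_entry)
  structure(list(name = name, entries = entries), class = "radial_databank")
}

databank_entry <- function(bank, element) {
  e <- bank$entries[[element]]
  if (is.null(e))
    stop_hc("element '%s' not present in databank '%s'", element, bank$name,
            class = "hcfit_lookup_error")
  e
}

#' @export
print.radial_databank <- function(x, ...) {
  cat(sprintf("radial_databank '%s': %d element(s): %s\n", x$name,
              length(x$entries), paste(names(x$entries), collapse = " ")))
  invisible(x)
}
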