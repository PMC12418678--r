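## Constrained least-squares fitting of multipole parameters to target
## structure factors, with the scale factor fixed (default 1.0).
##
## Populations enter the structure factors linearly, so their Jacobian
## columns are exact basis vectors; kappa and kappa' columns come from
## central finite differences on the affected atom's contribution.  A
## Levenberg-damped Gauss-Newton step with rejection keeps the residual
## norm non-increasing.

#' Refinement configuration
#'
#' @param mode `"complex"` fits real and imaginary parts of F (the
#'   theoretical phases are known); `"modulus"` fits amplitudes |F| as a
#'   conventional refinement program would.
#' @param scale_k fixed scale factor k (never refined).
#' @param max_iterations Gauss-Newton iteration cap.
#' @param gradient_tolerance relative gradient-norm convergence
#'   threshold.
#' @param step_damping initial fraction of the Gauss-Newton step.
#' @param kappa_bounds box bounds applied to every kappa-type parameter.
#' @param electroneutrality constrain the total valence population to
#'   `sum(n_val) - net_charge`.  F(000) is excluded by `0 < s`, so the
#'   total charge is only weakly constrained by the data; this optional
#'   constraint (off by default) pins it.  Imposed as a stiff
#'   pseudo-observation.
#' @return list of class `refinement_config`.
#' @export
refinement_config <- function(mode = c("complex", "modulus"), scale_k = 1.0,
                              max_iterations = 50L,
                              gradient_tolerance = 1e-10,
                              step_damping = 1.0,
                              kappa_bounds = DEFAULT_KAPPA_BOUNDS,
                              electroneutrality = FALSE) {
  mode <- match.arg(mode)
  stopifnot(scale_k > 0, gradient_tolerance > 0,
            step_damping > 0, step_damping <= 1)
  structure(list(mode = mode, scale_k = scale_k,
                 max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 step_damping = step_damping, kappa_bounds = kappa_bounds,
                 electroneutrality = isTRUE(electroneutrality)),
            class = "refinement_config")
}

#' Read a refinement configuration file
#'
#' Plain-text `key = value` lines (TOML-style; `#` comments) with the
#' keys of [refinement_config()]; `kappa_bounds` takes two
#' comma-separated numbers.
#' @param path file path.
#' @return `refinement_config`.
#' @export
read_refinement_config <- function(path) {
  kv <- list()
  for (ln in readLines(path)) {
    ln <- trimws(sub("#.*$", "", ln))
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop_hc("malformed config line: '%s'", ln, class = "hcfit_parse_error")
    key <- trimws(parts[1]); val <- trimws(gsub("[\"']", "", parts[2]))
    kv[[key]] <- switch(key,
      mode = val,
      scale_k = as.numeric(val),
      max_iterations = as.integer(val),
      gradient_tolerance = as.numeric(val),
      step_damping = as.numeric(val),
      kappa_bounds = as.numeric(strsplit(val, ",")[[1]]),
      electroneutrality = toupper(val) %in% c("TRUE", "YES", "1"),
      stop_hc("unknown config key '%s'", key, class = "hcfit_parse_error"))
  }
  do.call(refinement_config, kv)
}

#' Crystallographic R factor
#'
#' `R = sum | |F_obs| - k |F_calc| | / sum |F_obs|`.
#'
#' @param F_obs,F_calc `sf_set` objects on identical hkl sets (or bare
#'   complex/numeric vectors of equal length).
#' @param k scale factor.
#' @return dimensionless R.
#' @export
r_factor <- function(F_obs, F_calc, k = 1.0) {
  if (inherits(F_obs, "sf_set") && inherits(F_calc, "sf_set")) {
    if (!identical(dim(F_obs$hkl$hkl), dim(F_calc$hkl$hkl)) ||
        !all(F_obs$hkl$hkl == F_calc$hkl$hkl))
      stop_hc("hkl sets differ", class = "hcfit_alignment_error")
    fo <- Mod(F_obs$F); fc <- Mod(F_calc$F)
  } else {
    fo <- Mod(F_obs); fc <- Mod(F_calc)
    if (length(fo) != length(fc))
      stop_hc("length mismatch", class = "hcfit_alignment_error")
  }
  den <- sum(fo)
  if (den == 0) stop_hc("sum |F_obs| is zero", class = "hcfit_degenerate_error")
  sum(abs(fo - k * fc)) / den
}

## assemble F, the analytic population design matrix A (one column per
## free population group) and FD kappa columns K, for the current model
.build_system <- function(model, cache, include_core, groups) {
  nref <- length(cache$q)
  cols <- vector("list", length(groups$pop))  # population columns, built lazily
  K <- if (length(groups$kap))
    matrix(0i, nref, length(groups$kap)) else NULL
  Fconst <- complex(nref)
  ## key -> destination: population column index, or the constant part
  dest <- new.env(parent = emptyenv())
  for (j in seq_along(groups$pop))
    for (key in groups$pop[[j]]$key) assign(key, j, envir = dest)
  fixed_val <- new.env(parent = emptyenv())
  if (nrow(groups$fixed_pop))
    for (r in seq_len(nrow(groups$fixed_pop)))
      assign(groups$fixed_pop$key[r], groups$fixed_pop$value[r],
             envir = fixed_val)
  dk_atom <- vector("list", length(model$atoms))   # dF/dkappa per atom
  dp_atom <- vector("list", length(model$atoms))   # dF/dkappa' per atom
  route <- function(key, vec) {
    j <- dest[[key]]
    if (!is.null(j)) {
      cols[[j]] <<- if (is.null(cols[[j]])) vec else cols[[j]] + vec
    } else {
      v <- fixed_val[[key]]
      if (!is.null(v) && v != 0) Fconst <<- Fconst + v * vec
    }
  }
  for (a in model$atoms) {
    entry <- databank_entry(model$bank, a$element)
    x <- model$geometry$pos[a$index, ]
    phase <- exp(complex(imaginary = 2 * pi *
                           as.vector(cache$H %*% x) / cache$a_bohr))
    hk <- 1e-6 * a$kappa
    nv <- entry$n_val  # stored valence density integrates to n_val
    f0 <- .density_form_factor(entry$valence_terms, cache$q / a$kappa) / nv
    fp <- .density_form_factor(entry$valence_terms, cache$q / (a$kappa + hk)) / nv
    fm <- .density_form_factor(entry$valence_terms, cache$q / (a$kappa - hk)) / nv
    route(param_key(a$index, "Pval"), f0 * phase)
    dk_atom[[a$index]] <- a$P_val * (fp - fm) / (2 * hk) * phase
    if (include_core)
      Fconst <- Fconst + a$P_core *
        .density_form_factor(entry$core_terms, cache$q) * phase
    dp <- complex(nref)
    if (length(a$Plm)) {
      ul <- cache$u %*% a$frame$R
      hp <- 1e-6 * a$kappa_prime
      jl0 <- jlp <- jlm <- list()
      for (k in seq_along(a$Plm)) {
        lms <- strsplit(names(a$Plm)[k], ",")[[1]]
        l <- as.integer(lms[1]); m <- as.integer(lms[2]); s <- lms[3]
        lk <- as.character(l)
        if (is.null(jl0[[lk]])) {
          nlz <- entry$def_n[l + 1L]; zl <- entry$def_zeta[l + 1L]
          jl0[[lk]] <- slater_jl_transform(l, nlz, zl, cache$q / a$kappa_prime)
          jlp[[lk]] <- slater_jl_transform(l, nlz, zl, cache$q / (a$kappa_prime + hp))
          jlm[[lk]] <- slater_jl_transform(l, nlz, zl, cache$q / (a$kappa_prime - hp))
        }
        ang <- (4 * pi * (1i)^l) *
          dlm_eval(l, m, s, ul[, 1], ul[, 2], ul[, 3]) * phase
        route(param_key(a$index, "Plm", names(a$Plm)[k]), ang * jl0[[lk]])
        if (a$Plm[k] != 0)
          dp <- dp + a$Plm[k] * ang * (jlp[[lk]] - jlm[[lk]]) / (2 * hp)
      }
    }
    dp_atom[[a$index]] <- dp
  }
  for (j in seq_along(groups$kap)) {
    g <- groups$kap[[j]]
    col <- complex(nref)
    for (r in seq_len(nrow(g)))
      col <- col + if (g$kind[r] == "kappa") dk_atom[[g$atom[r]]]
      else dp_atom[[g$atom[r]]]
    K[, j] <- col
  }
  A <- if (length(cols)) do.call(cbind, cols) else matrix(0i, nref, 0)
  list(A = A, K = K, Fconst = Fconst)
}

## group bookkeeping shared by an entire fit: pack-order group list split
## into population-like and kappa-like parameters
.fit_groups <- function(model) {
  tab <- parameter_table(model)
  free <- tab[tab$free, ]
  gkeys <- free$group[!duplicated(free$group)]
  kinds <- free$kind[match(gkeys, free$group)]
  pop <- list(); kap <- list(); order_kind <- character(0)
  for (i in seq_along(gkeys)) {
    mem <- free[free$group == gkeys[i], c("key", "atom", "kind", "value")]
    if (kinds[i] %in% c("Pval", "Plm")) pop[[gkeys[i]]] <- mem
    else kap[[gkeys[i]]] <- mem
  }
  fixed <- tab[!tab$free & tab$kind %in% c("Pval", "Plm"), ]
  list(pop = pop, kap = kap, fixed_pop = fixed,
       pop_keys = names(pop), kap_keys = names(kap))
}

#' Fit a multipole model to target structure factors
#'
#' Minimizes `sum |F_target - k F_model|^2` (complex mode) or
#' `sum (|F_target| - k |F_model|)^2` (modulus mode) over the packed
#' parameter vector, with constraint ties enforced exactly, kappa-type
#' parameters box-bounded, and the scale factor fixed.  Non-convergence
#' within `max_iterations` is reported in the result, not an error.
#'
#' @param F_target `sf_set` (valence-only flag decides whether the model
#'   structure factors include core scattering).
#' @param start starting `mm_model` (conventionally the IAM).
#' @param config `refinement_config`.
#' @param verbose print per-iteration residual and R factor.
#' @return object of class `refinement_result`: fields `model`,
#'   `r_factor`, `iterations`, `converged`, `residual_norm`, `log`.
#' @export
fit_multipole_model <- function(F_target, start,
                                config = refinement_config(),
                                verbose = FALSE) {
  stopifnot(inherits(F_target, "sf_set"), inherits(start, "mm_model"))
  include_core <- !isTRUE(F_target$valence_only)
  k <- config$scale_k
  cache <- .hkl_cache(F_target$hkl, F_target$hkl$a / BOHR_A)
  groups <- .fit_groups(start)
  model <- start
  p <- pack_parameters(model)
  kap_idx <- match(groups$kap_keys, names(p))
  pop_idx <- match(groups$pop_keys, names(p))
  tF <- F_target$F
  ## optional electroneutrality constraint as a stiff pseudo-observation
  en <- NULL
  if (isTRUE(config$electroneutrality)) {
    mults <- vapply(groups$pop, function(g)
      if (g$kind[1] == "Pval") nrow(g) else 0, numeric(1))
    nval_tot <- sum(vapply(model$atoms, function(a)
      databank_entry(model$bank, a$element)$n_val, numeric(1)))
    en <- list(cvec = c(mults, numeric(length(groups$kap))),
               target = nval_tot - model$geometry$net_charge,
               w = 1e3 * sqrt(sum(Mod(tF)^2) + 1))
  }
  resid_of <- function(Fm, pv) {
    base <- if (config$mode == "complex") {
      d <- tF - k * Fm
      c(Re(d), Im(d))
    } else Mod(tF) - k * Mod(Fm)
    if (!is.null(en))
      base <- c(base, en$w * (en$target -
                                sum(en$cvec[seq_along(pop_idx)] * pv[pop_idx])))
    base
  }
  Fm_of <- function(sys, pv) as.vector(sys$A %*% pv[pop_idx]) + sys$Fconst
  sys <- .build_system(model, cache, include_core, groups)
  Fm <- Fm_of(sys, p)
  rr <- resid_of(Fm, p)
  rnorm2 <- sum(rr^2)
  lambda <- 1e-10
  it <- 0L; converged <- FALSE; g0 <- NULL
  log <- list()
  while (it < config$max_iterations) {
    J <- cbind(sys$A, sys$K)  # complex dF/dp, pack order pop then kappa
    if (config$mode == "complex") {
      Js <- k * rbind(Re(J), Im(J))
    } else {
      w <- Conj(Fm) / pmax(Mod(Fm), 1e-300)
      Js <- k * Re(sweep(J, 1, w, `*`))
    }
    if (!is.null(en)) Js <- rbind(Js, en$w * en$cvec)
    ## active-set handling of the kappa box bounds: a parameter pinned
    ## at a bound with its gradient pointing outward is frozen for this
    ## step, so the joint step for the remaining parameters stays
    ## consistent (naive clipping stalls on the bound face)
    if (length(kap_idx)) {
      kcol <- length(pop_idx) + seq_along(kap_idx)
      gk <- crossprod(Js[, kcol, drop = FALSE], rr)
      frozen <- (p[kap_idx] >= config$kappa_bounds[2] - 1e-10 & gk > 0) |
        (p[kap_idx] <= config$kappa_bounds[1] + 1e-10 & gk < 0)
      if (any(frozen)) Js[, kcol[frozen]] <- 0
    }
    g <- crossprod(Js, rr)
    if (is.null(g0)) {
      g0 <- max(abs(g), 1e-300)
      ## singular-system check at the starting point, restricted to
      ## active columns (a kappa' column is structurally zero while all
      ## multipole populations are zero, e.g. at the IAM start; it
      ## activates as soon as populations move and is not an error)
      cn <- sqrt(colSums(Js^2))
      act <- which(cn > 1e-12 * max(cn))
      M0 <- crossprod(Js[, act, drop = FALSE])
      rk <- qr(M0, tol = 1e-12)$rank
      if (rk < length(act)) {
        ev <- eigen(M0, symmetric = TRUE)
        null_idx <- act[abs(ev$vectors[, length(act)]) > 0.3]
        stop_hc("rank-deficient normal matrix; null space involves: %s",
                paste(c(groups$pop_keys, groups$kap_keys)[null_idx],
                      collapse = " "),
                class = "hcfit_rank_error")
      }
    }
    if (max(abs(g)) <= config$gradient_tolerance * g0) { converged <- TRUE; break }
    M <- crossprod(Js)
    dM <- diag(M)
    accepted <- FALSE
    for (try in 1:20) {
      ridge <- pmax(dM, 1e-8 * max(dM))  # keeps inactive columns solvable
      step <- tryCatch(
        solve(M + lambda * diag(ridge, ncol(M)), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        ## residual is t - k F(p); minimizing over delta gives p + delta
        ## (step is ordered as the J columns: populations then kappas)
        p_try <- p
        p_try[c(pop_idx, kap_idx)] <- p[c(pop_idx, kap_idx)] +
          config$step_damping * as.vector(step)
        ## project kappa-type parameters into bounds
        if (length(kap_idx))
          p_try[kap_idx] <- pmin(pmax(p_try[kap_idx], config$kappa_bounds[1]),
                                 config$kappa_bounds[2])
        model_try <- unpack_parameters(model, p_try)
        sys_try <- .build_system(model_try, cache, include_core, groups)
        Fm_try <- Fm_of(sys_try, p_try)
        rr_try <- resid_of(Fm_try, p_try)
        if (sum(rr_try^2) <= rnorm2 * (1 + 1e-14)) {
          accepted <- TRUE
          lambda <- max(lambda / 10, 1e-12)
          dp_max <- max(abs(p_try - p))
          p <- p_try; model <- model_try; sys <- sys_try
          Fm <- Fm_try; rr <- rr_try; rnorm2 <- sum(rr^2)
          if (dp_max < 1e-11) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    it <- it + 1L
    log[[it]] <- data.frame(iteration = it, residual_norm = sqrt(rnorm2),
                            r_factor = r_factor(tF, Fm, k), lambda = lambda)
    if (verbose)
      cat(sprintf("iter %3d  |r| = %.6e  R = %.3e  lambda = %.1e\n",
                  it, sqrt(rnorm2), log[[it]]$r_factor, lambda))
    if (!accepted) break  # no acceptable step: stop (converged stays FALSE
                          # unless the gradient test already passed)
    if (converged) break
  }
  if (!converged) {
    ## final gradient test (a zero-residual start converges in 0 iterations)
    J <- cbind(sys$A, sys$K)
    Js <- if (config$mode == "complex") k * rbind(Re(J), Im(J))
    else k * Re(sweep(J, 1, Conj(Fm) / pmax(Mod(Fm), 1e-300), `*`))
    if (!is.null(en)) Js <- rbind(Js, en$w * en$cvec)
    g <- crossprod(Js, rr)
    if (max(abs(g)) <= config$gradient_tolerance * (g0 %||% max(abs(g), 1e-300)))
      converged <- TRUE
  }
  structure(list(model = model,
                 r_factor = r_factor(tF, Fm, k),
                 iterations = it, converged = converged,
                 residual_norm = sqrt(rnorm2),
                 parameters = p,
                 log = if (length(log)) do.call(rbind, log) else NULL),
            class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement_result: R = %.3e, %d iteration(s), %s\n",
              x$r_factor, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
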