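#' Decomposition solver configuration
#'
#' @param solver `"newton"` (damped Newton on the 2x2 nonlinear system,
#'   default) or `"polynomial"` (calibrated inverse map).
#' @param tolerance convergence tolerance on the log-attenuation residual.
#' @param max_iterations Newton iteration cap.
#' @param polynomial_order total degree of the calibrated polynomial inverse.
#' @param allow_negative keep negative thicknesses (default TRUE: clamping
#'   biases the noise statistics of the basis images).
#' @return object of class `decomposition_config`.
#' @export
decompositionConfig <- function(solver = c("newton", "polynomial"),
                                tolerance = 1e-9, max_iterations = 50,
                                polynomial_order = 3, allow_negative = TRUE) {
  solver <- match.arg(solver)
  stopifnot(tolerance > 0, max_iterations >= 1)
  structure(list(solver = solver, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 polynomial_order = as.integer(polynomial_order),
                 allow_negative = isTRUE(allow_negative)),
            class = "decomposition_config")
}

#' Dual-energy basis system
#'
#' Precomputes, for a pair of spectra, the detector-weighted normalized
#' spectral weights and the Al/PMMA linear attenuation coefficients on the
#' energy grid.  Rejects spectrum pairs whose monoenergetic-equivalent 2x2
#' matrix is ill-conditioned (condition number > 1e6).
#'
#' @param spectrum_low,spectrum_high `spectrum` objects (e.g. 80 and 140 kVp).
#' @param response detector response, see [detectorWeights()].
#' @return object of class `basis_system`.
#' @export
basisSystem <- function(spectrum_low, spectrum_high, response = "ei") {
  sp <- list(.check_spectrum(spectrum_low), .check_spectrum(spectrum_high))
  stopifnot(identical(sp[[1]]$energies, sp[[2]]$energies))
  E <- sp[[1]]$energies
  w <- lapply(sp, function(s) {
    v <- s$fluence * detectorWeights(E, response)
    v / sum(v)
  })
  a <- linearAttenuation("aluminum", E)
  b <- linearAttenuation("pmma", E)
  M <- rbind(c(sum(w[[1]] * a), sum(w[[1]] * b)),
             c(sum(w[[2]] * a), sum(w[[2]] * b)))
  if (kappa(M) > 1e6)
    stop("spectrum pair is too similar for material decomposition ",
         "(condition number > 1e6)")
  structure(list(energies = E, w_low = w[[1]], w_high = w[[2]],
                 mu_al = a, mu_pmma = b, mono_matrix = M,
                 kvp = c(sp[[1]]$kvp, sp[[2]]$kvp)),
            class = "basis_system")
}

#' Default 80/140 kVp basis system
#' @inheritParams basisSystem
#' @export
defaultBasisSystem <- function(response = "ei") {
  key <- paste0("basis_system_", response)
  if (is.null(.decbct[[key]]))
    .decbct[[key]] <- basisSystem(defaultSpectrum(80), defaultSpectrum(140),
                                  response = response)
  .decbct[[key]]
}

# transmission-weighted sums shared by forward model and Jacobian;
# returns for each spectrum: L, and effective mu_al / mu_pmma under the
# object-hardened spectrum
.dual_eval <- function(t_al, t_pmma, system, jacobian = FALSE) {
  Tm <- exp(-(outer(t_al, system$mu_al) + outer(t_pmma, system$mu_pmma)))
  out <- list()
  for (s in c("low", "high")) {
    w <- system[[paste0("w_", s)]]
    den <- as.vector(Tm %*% w)
    out[[paste0("L_", s)]] <- -log(den)
    if (jacobian) {
      out[[paste0("a_", s)]] <- as.vector(Tm %*% (w * system$mu_al)) / den
      out[[paste0("b_", s)]] <- as.vector(Tm %*% (w * system$mu_pmma)) / den
    }
  }
  out
}

#' Dual-energy forward model
#'
#' Predicted log attenuation under each spectrum for given Al/PMMA equivalent
#' thicknesses:
#' `L_s = -ln( sum_E S_s(E) w(E) exp(-mu_Al(E) t_al - mu_PMMA(E) t_pmma)
#'             / sum_E S_s(E) w(E) )`.
#'
#' @param t_al,t_pmma thicknesses in cm (vectorized, equal length).
#' @param system a `basis_system` (default: 80/140 kVp package spectra).
#' @return matrix with columns `L_low`, `L_high`.
#' @export
forwardDual <- function(t_al, t_pmma, system = defaultBasisSystem()) {
  stopifnot(length(t_al) == length(t_pmma), all(is.finite(c(t_al, t_pmma))))
  ev <- .dual_eval(t_al, t_pmma, system)
  cbind(L_low = ev$L_low, L_high = ev$L_high)
}

#' Invert the dual-energy forward model for one or more rays
#'
#' Damped Newton iteration on the 2x2 system `forwardDual(t) = (L_low,
#' L_high)`, vectorized over rays.  The Jacobian entries are the effective
#' (object-hardened) attenuation coefficients, so the iteration is
#' well-behaved over the whole attainable range; the step is halved when the
#' residual norm does not decrease.
#'
#' @param L_low,L_high measured log attenuations (equal-length vectors).
#' @param system a `basis_system`.
#' @param config a `decomposition_config`.
#' @return list: `t_al`, `t_pmma` (cm), `converged` logical vector,
#'   `iterations` used.
#' @export
solveRay <- function(L_low, L_high, system = defaultBasisSystem(),
                     config = decompositionConfig()) {
  stopifnot(length(L_low) == length(L_high),
            all(is.finite(c(L_low, L_high))))
  n <- length(L_low)
  b_eff <- sum(system$w_high * system$mu_pmma)
  t1 <- numeric(n)
  t2 <- L_high / b_eff
  res_norm <- function(t1, t2, target_low, target_high) {
    ev <- .dual_eval(t1, t2, system)
    pmax(abs(ev$L_low - target_low), abs(ev$L_high - target_high))
  }
  rn <- res_norm(t1, t2, L_low, L_high)
  active <- rn > config$tolerance
  iter <- 0L
  while (any(active) && iter < config$max_iterations) {
    iter <- iter + 1L
    idx <- which(active)
    ev <- .dual_eval(t1[idx], t2[idx], system, jacobian = TRUE)
    r1 <- ev$L_low - L_low[idx]
    r2 <- ev$L_high - L_high[idx]
    det <- ev$a_low * ev$b_high - ev$b_low * ev$a_high
    if (any(abs(det) < 1e-14))
      stop("singular Jacobian in decomposition")
    d1 <- (ev$b_high * r1 - ev$b_low * r2) / det
    d2 <- (-ev$a_high * r1 + ev$a_low * r2) / det
    lam <- rep(1, length(idx))
    old <- rn[idx]
    for (h in 1:6) {                       # elementwise step halving
      n1 <- t1[idx] - lam * d1
      n2 <- t2[idx] - lam * d2
      new <- res_norm(n1, n2, L_low[idx], L_high[idx])
      worse <- new > old & new > config$tolerance
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    t1[idx] <- n1; t2[idx] <- n2; rn[idx] <- new
    active[idx] <- new > config$tolerance
  }
  if (!config$allow_negative) {
    t1 <- pmax(t1, 0); t2 <- pmax(t2, 0)
  }
  list(t_al = t1, t_pmma = t2, converged = rn <= config$tolerance,
       iterations = iter)
}

#' Decompose a dual-energy scan pair into basis-thickness sinograms
#'
#' Elementwise [solveRay()] over matched 80/140 kVp log-sinograms (processed
#' in chunks to bound memory).  Records the fraction of rays that did not
#' reach tolerance (their last iterate is kept).
#'
#' @param p_low,p_high `projection_set`s with identical angles and detector
#'   dimensions (low and high kVp).
#' @param config a `decomposition_config`.
#' @param system a `basis_system`; defaults to the spectra implied by the two
#'   protocol kVp settings.
#' @return object of class `basis_sinogram`: matrices `t_al`, `t_pmma` (cm),
#'   `angles`, `frac_nonconverged`, provenance.
#' @export
decompose <- function(p_low, p_high, config = decompositionConfig(),
                      system = NULL) {
  stopifnot(inherits(p_low, "projection_set"), inherits(p_high, "projection_set"))
  if (!isTRUE(all.equal(p_low$angles, p_high$angles)))
    stop("projection sets have mismatched angles")
  if (!all(dim(p_low$line_integrals) == dim(p_high$line_integrals)))
    stop("projection sets have mismatched dimensions")
  if (is.null(system))
    system <- basisSystem(defaultSpectrum(p_low$kvp), defaultSpectrum(p_high$kvp))
  if (config$solver == "polynomial") {
    cal <- .decbct$poly_cache
    if (is.null(cal) || cal$order != config$polynomial_order) {
      wedge <- makeStepWedge(system)
      cal <- calibratePolynomial(wedge, config$polynomial_order)
      .decbct$poly_cache <- cal
    }
    pred <- predict(cal, as.vector(p_low$line_integrals),
                    as.vector(p_high$line_integrals))
    t1 <- pred$t_al; t2 <- pred$t_pmma
    nc <- 0
  } else {
    ll <- as.vector(p_low$line_integrals)
    lh <- as.vector(p_high$line_integrals)
    t1 <- numeric(length(ll)); t2 <- numeric(length(ll)); ncv <- logical(length(ll))
    chunk <- 40000L
    for (s in seq(1, length(ll), by = chunk)) {
      e <- min(s + chunk - 1L, length(ll))
      sol <- solveRay(ll[s:e], lh[s:e], system, config)
      t1[s:e] <- sol$t_al; t2[s:e] <- sol$t_pmma; ncv[s:e] <- !sol$converged
    }
    nc <- mean(ncv)
  }
  dm <- dim(p_low$line_integrals)
  structure(list(t_al = matrix(t1, dm[1], dm[2]),
                 t_pmma = matrix(t2, dm[1], dm[2]),
                 angles = p_low$angles, frac_nonconverged = nc,
                 kvp = c(p_low$kvp, p_high$kvp), config = config),
            class = "basis_sinogram")
}

#' @export
print.basis_sinogram <- function(x, ...) {
  cat(sprintf("<basis sinogram>  %d views x %d elements, %.2g%% non-converged\n",
              nrow(x$t_al), ncol(x$t_al), 100 * x$frac_nonconverged))
  invisible(x)
}

#' Synthetic step-wedge measurements for polynomial calibration
#'
#' Noiseless forward projections of a regular (t_al, t_pmma) thickness grid.
#'
#' @param system a `basis_system`.
#' @param t_al,t_pmma wedge thickness levels (cm).
#' @return data.frame with `t_al`, `t_pmma`, `L_low`, `L_high`.
#' @export
makeStepWedge <- function(system = defaultBasisSystem(),
                          t_al = seq(0, 4, length.out = 9),
                          t_pmma = seq(0, 30, length.out = 9)) {
  g <- expand.grid(t_al = t_al, t_pmma = t_pmma)
  L <- forwardDual(g$t_al, g$t_pmma, system)
  cbind(g, L_low = L[, 1], L_high = L[, 2])
}

.poly_design <- function(L1, L2, order) {
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i))
    cols[[paste0("p", i, j)]] <- L1^i * L2^j
  do.call(cbind, cols)
}

#' Calibrate a polynomial inverse decomposition map
#'
#' Least-squares fit of 2D polynomials mapping `(L_low, L_high)` to each basis
#' thickness over a step-wedge grid; the fast alternative to the Newton
#' solver.
#'
#' @param wedge data.frame from [makeStepWedge()] (or measured equivalents).
#' @param order total polynomial degree; must leave the fit over-determined.
#' @return object of class `poly_decomposition` with a `predict()` method and
#'   `max_residual_cm` on the training grid.
#' @export
calibratePolynomial <- function(wedge, order = 3) {
  X <- .poly_design(wedge$L_low, wedge$L_high, order)
  if (nrow(X) < ncol(X))
    stop("polynomial order too high for the number of wedge points")
  fit_al <- lm.fit(X, wedge$t_al)
  fit_pmma <- lm.fit(X, wedge$t_pmma)
  resid <- pmax(abs(fit_al$residuals), abs(fit_pmma$residuals))
  structure(list(order = order, coef_al = coef(fit_al),
                 coef_pmma = coef(fit_pmma),
                 max_residual_cm = max(resid)),
            class = "poly_decomposition")
}

#' @export
predict.poly_decomposition <- function(object, L_low, L_high, ...) {
  X <- .poly_design(L_low, L_high, object$order)
  list(t_al = as.vector(X %*% object$coef_al),
       t_pmma = as.vector(X %*% object$coef_pmma))
}
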