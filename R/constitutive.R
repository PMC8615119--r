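#' Holzapfel-Ogden material parameters
#'
#' Container for the eight material descriptors of the invariant-based
#' anisotropic hyperelastic strain-energy function used for the aortic wall:
#' an isotropic exponential matrix term (`a`, `b`), two exponential fiber
#' terms along the fiber (f) and sheet (s) axes (`a_f`, `b_f`, `a_s`, `b_s`),
#' and a fiber-sheet coupling term (`a_fs`, `b_fs`). For the aneurysmal
#' aorta the coupling term is switched off (`a_fs = b_fs = 0`).
#'
#' @param a Isotropic stiffness-like modulus (MPa), must be > 0.
#' @param b Isotropic exponent (dimensionless), must be > 0.
#' @param a_f,b_f Fiber-direction modulus (MPa) and exponent, >= 0.
#' @param a_s,b_s Sheet-direction modulus (MPa) and exponent, >= 0.
#' @param a_fs,b_fs Fiber-sheet coupling modulus (MPa) and exponent, >= 0;
#'   both default to 0.
#'
#' @return An object of class `ho_params`: a named list of the eight
#'   parameters, serializable with [ho_params_to_json()].
#' @examples
#' ho_params(a = 0.24, b = 6.6, a_f = 0.05, b_f = 5.0, a_s = 0.02, b_s = 2.0)
#' @export
ho_params <- function(a, b, a_f = 0, b_f = 0, a_s = 0, b_s = 0,
                      a_fs = 0, b_fs = 0) {
  p <- list(a = a, b = b, a_f = a_f, b_f = b_f, a_s = a_s, b_s = b_s,
            a_fs = a_fs, b_fs = b_fs)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    stop("all material parameters must be finite scalars", call. = FALSE)
  }
  if (a <= 0 || b <= 0) {
    stop("`a` and `b` must be strictly positive", call. = FALSE)
  }
  if (any(unlist(p[c("a_f", "b_f", "a_s", "b_s", "a_fs", "b_fs")]) < 0)) {
    stop("anisotropic parameters must be non-negative", call. = FALSE)
  }
  structure(p, class = "ho_params")
}

#' @export
print.ho_params <- function(x, ...) {
  cat("<ho_params>  (moduli in MPa, exponents dimensionless)\n")
  cat(sprintf("  a    = %-8.4g b    = %-8.4g\n", x$a, x$b))
  cat(sprintf("  a_f  = %-8.4g b_f  = %-8.4g\n", x$a_f, x$b_f))
  cat(sprintf("  a_s  = %-8.4g b_s  = %-8.4g\n", x$a_s, x$b_s))
  cat(sprintf("  a_fs = %-8.4g b_fs = %-8.4g\n", x$a_fs, x$b_fs))
  invisible(x)
}

#' ATAA material descriptors
#'
#' The fitted aneurysmal-wall parameter set used as the package's reference
#' material: a = 0.24 MPa, b = 6.6, a_f = 0.05 MPa, b_f = 5.0,
#' a_s = 0.02 MPa, b_s = 2.0, with the fiber-sheet coupling off.
#'
#' @return An `ho_params` object.
#' @examples
#' ataa_params()
#' @export
ataa_params <- function() {
  ho_params(a = 0.24, b = 6.6, a_f = 0.05, b_f = 5.0, a_s = 0.02, b_s = 2.0)
}

#' Fiber architecture of the wall
#'
#' Fixes the in-plane fiber axis f at an angle `gamma` from the
#' circumferential direction; the sheet axis s is the in-plane direction
#' orthogonal to f. The aneurysmal wall uses 34 degrees (multiphoton-imaging
#' derived); the healthy reference uses 42 degrees.
#'
#' @param gamma Fiber angle in degrees from the circumferential direction,
#'   in `[0, 90]`. Default 34.
#' @return An object of class `fiber_architecture`.
#' @export
fiber_architecture <- function(gamma = 34) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma < 0 || gamma > 90) {
    stop("`gamma` must be a single angle in [0, 90] degrees", call. = FALSE)
  }
  structure(list(gamma = gamma), class = "fiber_architecture")
}

#' Planar-biaxial deformation states
#'
#' Builds a tibble of incompressible plane-stress biaxial deformation states
#' from in-plane principal stretches. The radial (through-thickness) stretch
#' follows from exact incompressibility,
#' `lambda_rad = 1 / (lambda_circ * lambda_long)`.
#'
#' @param lambda_circ,lambda_long Positive in-plane stretches
#'   (circumferential, longitudinal); recycled to a common length.
#' @return A tibble with columns `lambda_circ`, `lambda_long`, `lambda_rad`.
#' @examples
#' deformation_state(1.1, 1.1)
#' @export
deformation_state <- function(lambda_circ, lambda_long) {
  n <- max(length(lambda_circ), length(lambda_long))
  lc <- rep_len(lambda_circ, n)
  ll <- rep_len(lambda_long, n)
  if (any(!is.finite(lc)) || any(!is.finite(ll)) || any(lc <= 0) || any(ll <= 0)) {
    stop("stretches must be finite and strictly positive", call. = FALSE)
  }
  tibble::tibble(lambda_circ = lc, lambda_long = ll, lambda_rad = 1 / (lc * ll))
}

#' Kinematic invariants of a biaxial state
#'
#' Computes the four strain invariants driving the strain energy: the trace
#' invariant `I1 = trace(C)` and the squared fiber/sheet stretches
#' `I4f = f.C.f`, `I4s = s.C.s`, plus the coupling invariant `I8fs = f.C.s`,
#' for a diagonal biaxial deformation with the fiber axis at `gamma` degrees
#' from circumferential and the sheet axis orthogonal in the tangent plane.
#'
#' @param state A tibble from [deformation_state()].
#' @param arch A [fiber_architecture()].
#' @return A tibble with columns `I1`, `I4f`, `I4s`, `I8fs`.
#' @examples
#' compute_invariants(deformation_state(1.1, 1.05), fiber_architecture(34))
#' @export
compute_invariants <- function(state, arch = fiber_architecture()) {
  stopifnot(all(c("lambda_circ", "lambda_long", "lambda_rad") %in% names(state)))
  if (any(state$lambda_circ <= 0) || any(state$lambda_long <= 0)) {
    stop("stretches must be strictly positive", call. = FALSE)
  }
  g <- arch$gamma * pi / 180
  c2 <- cos(g)^2
  s2 <- sin(g)^2
  sc <- sin(g) * cos(g)
  lc2 <- state$lambda_circ^2
  ll2 <- state$lambda_long^2
  lr2 <- state$lambda_rad^2
  tibble::tibble(
    I1   = lc2 + ll2 + lr2,
    I4f  = lc2 * c2 + ll2 * s2,
    I4s  = lc2 * s2 + ll2 * c2,
    I8fs = (ll2 - lc2) * sc
  )
}

# partial derivatives of the strain energy wrt its invariants; the I4 terms
# are tension-only (active when I4 > 1) so compressed fibers carry no load
ho_dpsi <- function(params, inv) {
  p <- params
  dI1 <- (p$a / 2) * exp(p$b * (inv$I1 - 3))
  e4f <- pmax(inv$I4f - 1, 0)
  e4s <- pmax(inv$I4s - 1, 0)
  dI4f <- p$a_f * e4f * exp(p$b_f * e4f^2)
  dI4s <- p$a_s * e4s * exp(p$b_s * e4s^2)
  dI8 <- if (p$a_fs > 0) p$a_fs * inv$I8fs * exp(p$b_fs * inv$I8fs^2) else
    rep(0, length(inv$I8fs))
  list(dI1 = dI1, dI4f = dI4f, dI4s = dI4s, dI8 = dI8)
}

#' Strain-energy density
#'
#' Evaluates the anisotropic hyperelastic strain-energy density
#' \deqn{\Psi = \frac{a}{2b}\{e^{b(I_1-3)}-1\}
#'   + \sum_{i=f,s}\frac{a_i}{2b_i}\{e^{b_i(I_{4i}-1)^2}-1\}
#'   + \frac{a_{fs}}{2b_{fs}}\{e^{b_{fs}I_{8fs}^2}-1\}}
#' in MPa. The fiber terms contribute only in tension (`I4 > 1`), the
#' standard switch for exponential fiber models; the energy is normalised to
#' zero at the identity deformation.
#'
#' @param inv A tibble of invariants from [compute_invariants()].
#' @param params An [ho_params()] object.
#' @return A numeric vector of energy densities (MPa).
#' @examples
#' inv <- compute_invariants(deformation_state(1.08, 1.08))
#' strain_energy(inv, ataa_params())
#' @export
strain_energy <- function(inv, params) {
  p <- params
  e4f <- pmax(inv$I4f - 1, 0)
  e4s <- pmax(inv$I4s - 1, 0)
  psi <- (p$a / (2 * p$b)) * (exp(p$b * (inv$I1 - 3)) - 1)
  if (p$a_f > 0) {
    psi <- psi + if (p$b_f > 0) {
      (p$a_f / (2 * p$b_f)) * (exp(p$b_f * e4f^2) - 1)
    } else {
      (p$a_f / 2) * e4f^2  # b_i -> 0 limit of the exponential term
    }
  }
  if (p$a_s > 0) {
    psi <- psi + if (p$b_s > 0) {
      (p$a_s / (2 * p$b_s)) * (exp(p$b_s * e4s^2) - 1)
    } else {
      (p$a_s / 2) * e4s^2
    }
  }
  if (p$a_fs > 0 && p$b_fs > 0) {
    psi <- psi + (p$a_fs / (2 * p$b_fs)) * (exp(p$b_fs * inv$I8fs^2) - 1)
  }
  if (any(!is.finite(psi))) {
    stop("strain-energy evaluation overflowed (stretch too extreme for the ",
         "exponential terms)", call. = FALSE)
  }
  psi
}

#' First Piola-Kirchhoff stresses of a biaxial state
#'
#' Analytic in-plane first-PK normal stresses for an incompressible
#' plane-stress biaxial deformation. The hydrostatic multiplier is
#' eliminated by the through-thickness condition (radial Cauchy stress
#' zero), which makes the measured components exactly the partial
#' derivatives of the condensed energy
#' `Psi_hat(lc, ll) = Psi(lc, ll, 1/(lc*ll))` with respect to each in-plane
#' stretch. Tension positive, MPa.
#'
#' @param state A tibble from [deformation_state()] (data-frame-first, so
#'   pipelines can chain `deformation_state(...) |> first_pk_stress(...)`).
#' @param params An [ho_params()] object.
#' @param arch A [fiber_architecture()].
#' @return A tibble with columns `P_circ`, `P_long` (MPa).
#' @examples
#' deformation_state(1.05, 1.05) |> first_pk_stress(ataa_params())
#' @export
first_pk_stress <- function(state, params, arch = fiber_architecture()) {
  if (any(state$lambda_circ <= 0) || any(state$lambda_long <= 0)) {
    stop("degenerate deformation state: stretches must be positive",
         call. = FALSE)
  }
  inv <- compute_invariants(state, arch)
  d <- ho_dpsi(params, inv)
  g <- arch$gamma * pi / 180
  c2 <- cos(g)^2
  s2 <- sin(g)^2
  sc <- sin(g) * cos(g)
  lc <- state$lambda_circ
  ll <- state$lambda_long
  lr2 <- state$lambda_rad^2
  # dPsi_hat/dlambda via chain rule; incompressibility gives
  # d(lr^2)/dlc = -2 lr^2 / lc (and symmetrically for ll)
  P_circ <- d$dI1 * (2 * lc - 2 * lr2 / lc) +
    d$dI4f * 2 * lc * c2 + d$dI4s * 2 * lc * s2 + d$dI8 * (-2 * lc * sc)
  P_long <- d$dI1 * (2 * ll - 2 * lr2 / ll) +
    d$dI4f * 2 * ll * s2 + d$dI4s * 2 * ll * c2 + d$dI8 * (2 * ll * sc)
  if (any(!is.finite(P_circ)) || any(!is.finite(P_long))) {
    stop("stress evaluation overflowed (stretch too extreme for the ",
         "exponential terms)", call. = FALSE)
  }
  tibble::tibble(P_circ = P_circ, P_long = P_long)
}

#' Serialize / deserialize material parameters
#'
#' @param params An [ho_params()] object.
#' @param path File path; if `NULL` the JSON string is returned.
#' @return `ho_params_to_json()` returns the path (or JSON string);
#'   `ho_params_from_json()` returns an `ho_params` object.
#' @export
ho_params_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname ho_params_to_json
#' @param json A JSON string or file path produced by [ho_params_to_json()].
#' @export
ho_params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(ho_params, as.list(x))
}
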