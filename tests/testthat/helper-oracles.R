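# Independent oracles used across tests. These re-derive quantities through
# a different code path than the package (explicit tensors, finite
# differences, quadrature) so agreement is informative.

# invariants by explicit 3x3 tensor contraction: C = F^T F with
# F = diag(lc, ll, lr), f and s unit vectors in the tangent plane
oracle_invariants <- function(lc, ll, gamma_deg) {
  lr <- 1 / (lc * ll)
  F <- diag(c(lc, ll, lr))
  C <- t(F) %*% F
  g <- gamma_deg * pi / 180
  f <- c(cos(g), sin(g), 0)
  s <- c(-sin(g), cos(g), 0)
  list(I1 = sum(diag(C)),
       I4f = drop(t(f) %*% C %*% f),
       I4s = drop(t(s) %*% C %*% s),
       I8fs = drop(t(f) %*% C %*% s))
}

# direct transliteration of the strain-energy formula from its invariants
# (tension-only fiber terms), independent of the package's vectorised path
oracle_energy <- function(p, I1, I4f, I4s, I8fs) {
  e4f <- max(I4f - 1, 0)
  e4s <- max(I4s - 1, 0)
  val <- p$a / (2 * p$b) * (exp(p$b * (I1 - 3)) - 1)
  if (p$a_f > 0) val <- val + p$a_f / (2 * p$b_f) * (exp(p$b_f * e4f^2) - 1)
  if (p$a_s > 0) val <- val + p$a_s / (2 * p$b_s) * (exp(p$b_s * e4s^2) - 1)
  if (p$a_fs > 0) val <- val + p$a_fs / (2 * p$b_fs) *
      (exp(p$b_fs * I8fs^2) - 1)
  val
}

# condensed-energy evaluation for the finite-difference stress oracle
oracle_psi_hat <- function(lc, ll, params, arch) {
  inv <- compute_invariants(deformation_state(lc, ll), arch)
  strain_energy(inv, params)
}

# central finite difference of the condensed energy: the plane-stress
# first-PK normal components
oracle_fd_stress <- function(lc, ll, params, arch, h = 1e-6) {
  c(P_circ = (oracle_psi_hat(lc + h, ll, params, arch) -
                oracle_psi_hat(lc - h, ll, params, arch)) / (2 * h),
    P_long = (oracle_psi_hat(lc, ll + h, params, arch) -
                oracle_psi_hat(lc, ll - h, params, arch)) / (2 * h))
}

# net axial force (N) carried by an angular stress profile: trapezoid in
# theta, mean of the two surfaces through the thickness (the bending part is
# antisymmetric through the wall, so the mid value is the through-thickness
# average)
oracle_axial_force <- function(profile, geom) {
  r <- geom$outer_diameter / 2 - geom$thickness / 2
  wide <- tidyr::pivot_wider(profile, names_from = "surface",
                             values_from = "S_L")
  s_mid_kpa <- (wide$inner + wide$outer) / 2
  dtheta <- 2 * pi / nrow(wide)
  sum(s_mid_kpa / 1000 * r * geom$thickness * dtheta)  # kPa -> N/mm^2
}

# the patient circulation fixture is expensive; compute once per test run
patient_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- gen_patient_record()
      p0 <- calibrate(rec)
      p1 <- refine_to_cuff(p0, rec, tol = 1)
      sim <- simulate_circulation(p1)
      cache <<- list(record = rec, initial = p0, refined = p1, sim = sim)
    }
    cache
  }
})
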