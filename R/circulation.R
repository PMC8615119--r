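#' Clinical record driving the circulation calibration
#'
#' Cuff pressures and echocardiographic flow measurements for one patient,
#' the inputs of [calibrate()].
#'
#' @param sbp,dbp,map Systolic, diastolic and mean arterial pressure (mmHg);
#'   must satisfy `dbp < map < sbp`.
#' @param sv Stroke volume (mL).
#' @param co Cardiac output (L/min).
#' @param hr Heart rate (bpm).
#' @param bsa Body surface area (m^2), optional; needed only for the
#'   valvulo-arterial impedance.
#' @param valve_orifice_area Aortic valve orifice area (mm^2), optional.
#' @return An object of class `clinical_record`.
#' @examples
#' clinical_record(132, 84, 102, 64, 4.9, 60)
#' @export
clinical_record <- function(sbp, dbp, map, sv, co, hr, bsa = NULL,
                            valve_orifice_area = NULL) {
  if (!(dbp > 0 && sbp > dbp)) {
    stop("pressures must satisfy sbp > dbp > 0", call. = FALSE)
  }
  if (!(map > dbp && map < sbp)) {
    stop("mean arterial pressure must lie between dbp and sbp", call. = FALSE)
  }
  if (sv <= 0 || co <= 0 || hr <= 0) {
    stop("sv, co and hr must be positive", call. = FALSE)
  }
  structure(list(sbp = sbp, dbp = dbp, map = map, sv = sv, co = co, hr = hr,
                 bsa = bsa, valve_orifice_area = valve_orifice_area),
            class = "clinical_record")
}

#' @export
print.clinical_record <- function(x, ...) {
  cat(sprintf("<clinical_record>  %g/%g mmHg (MAP %g), SV %g mL, CO %g L/min, HR %g bpm\n",
              x$sbp, x$dbp, x$map, x$sv, x$co, x$hr))
  invisible(x)
}

#' Lumped circulation parameters
#'
#' Parameters of the closed-loop model: a time-varying-elastance left
#' ventricle (diode mitral and aortic valves) ejecting through a
#' characteristic impedance `Zc` into a Windkessel compartment (`C` in
#' parallel with the total peripheral resistance `R_total`), refilled from a
#' constant-pressure venous reservoir.
#'
#' @param R_total Total arterial resistance (mmHg.min/L).
#' @param C Arterial compliance (mL/mmHg).
#' @param Zc Characteristic (proximal) impedance (mmHg.min/L).
#' @param Emax,Emin Peak-systolic and diastolic LV elastance (mmHg/mL).
#' @param V0 LV unstressed volume (mL).
#' @param cycle_period Beat period (s).
#' @param systole_duration Systolic activation window (s).
#' @param venous_pressure Filling (venous) pressure (mmHg).
#' @param R_mv Mitral (filling) resistance (mmHg.s/mL).
#' @return An object of class `circ_params`.
#' @export
circ_params <- function(R_total, C, Zc, Emax, Emin, V0 = 10,
                        cycle_period = 0.8, systole_duration = 0.3,
                        venous_pressure = 10, R_mv = 0.01) {
  vals <- c(R_total = R_total, C = C, Zc = Zc, Emax = Emax, Emin = Emin,
            R_mv = R_mv)
  if (any(vals <= 0)) {
    stop("resistances, compliance and elastances must be positive", call. = FALSE)
  }
  if (systole_duration >= cycle_period) {
    stop("systole_duration must be shorter than cycle_period", call. = FALSE)
  }
  structure(list(R_total = R_total, C = C, Zc = Zc, Emax = Emax, Emin = Emin,
                 V0 = V0, cycle_period = cycle_period,
                 systole_duration = systole_duration,
                 venous_pressure = venous_pressure, R_mv = R_mv),
            class = "circ_params")
}

#' @export
print.circ_params <- function(x, ...) {
  cat("<circ_params>\n")
  cat(sprintf("  R_total = %.3f mmHg.min/L   C = %.3f mL/mmHg   Zc = %.4f mmHg.min/L\n",
              x$R_total, x$C, x$Zc))
  cat(sprintf("  Emax = %.3f  Emin = %.4f mmHg/mL   V0 = %g mL   Pven = %g mmHg\n",
              x$Emax, x$Emin, x$V0, x$venous_pressure))
  cat(sprintf("  period = %g s   systole = %g s\n",
              x$cycle_period, x$systole_duration))
  invisible(x)
}

#' Calibrate the lumped circulation from a clinical record
#'
#' Applies the printed clinical formulas: total arterial resistance
#' `R_total = MAP / CO` and initial arterial compliance
#' `C = SV / (SBP - DBP)` (stroke volume over pulse pressure), with the
#' characteristic impedance set to 5% of `R_total`. The beat period defaults
#' to `60 / HR` from the record; matching the record's MAP under the
#' periodic Windkessel identity `MAP = R_total x SV x HR` requires the
#' forward volume per beat to be `CO / HR`, which is only consistent with
#' the record's own heart rate. Elastance bounds are initialised so the
#' isolated beat fills to an end-diastolic volume near `edv_target` and
#' ejects with an ejection fraction near 60%; [refine_to_cuff()] finishes
#' the job against the cuff pressures.
#'
#' @param record A [clinical_record()].
#' @param edv_target Target end-diastolic volume (mL); default 137
#'   (midpoint of the 136-138 mL non-remodeled range).
#' @param cycle_period Beat period (s); default `60 / record$hr`.
#' @param systole_duration Systolic window (s); default 0.3.
#' @param zc_fraction `Zc` as a fraction of `R_total`; default 0.05.
#' @return A [circ_params()] object.
#' @examples
#' calibrate(clinical_record(132, 84, 102, 64, 4.9, 60))
#' @export
calibrate <- function(record, edv_target = 137, cycle_period = NULL,
                      systole_duration = 0.3, zc_fraction = 0.05) {
  stopifnot(inherits(record, "clinical_record"))
  R_total <- record$map / record$co                     # mmHg.min/L
  C <- record$sv / (record$sbp - record$dbp)            # mL/mmHg
  Zc <- zc_fraction * R_total
  T_cycle <- cycle_period %||% (60 / record$hr)
  V0 <- 10
  Pven <- 10
  Emin <- Pven / (edv_target - V0)
  sv_target <- record$co * 1000 / (60 / T_cycle)        # forward mL per beat
  esv_target <- max(edv_target - sv_target, V0 + 5)
  Emax <- record$sbp / (esv_target - V0)
  circ_params(R_total = R_total, C = C, Zc = Zc, Emax = Emax, Emin = Emin,
              V0 = V0, cycle_period = T_cycle,
              systole_duration = systole_duration, venous_pressure = Pven)
}

# double-cosine systolic activation, 0 outside the systolic window
elastance_activation <- function(t_beat, systole_duration) {
  ifelse(t_beat < systole_duration,
         0.5 * (1 - cos(2 * pi * t_beat / systole_duration)), 0)
}

circ_rhs <- function(t, y, p) {
  tb <- t %% p$T
  E <- p$Emin + (p$Emax - p$Emin) * elastance_activation(tb, p$Ts)
  p_lv <- E * (y[1] - p$V0)
  q_ao <- max(0, (p_lv - y[2]) / p$Zc_s)
  q_mv <- max(0, (p$Pven - p_lv) / p$Rmv_s)
  list(c(q_mv - q_ao, (q_ao - y[2] / p$R_s) / p$C))
}

beat_metrics <- function(beat) {
  edv <- max(beat$v_lv); esv <- min(beat$v_lv)
  tibble::tibble(
    EDV = edv, ESV = esv, SV = edv - esv, EF = (edv - esv) / edv,
    SBP = max(beat$p_ao), DBP = min(beat$p_ao),
    MAP = mean(beat$p_ao), peak_p_lv = max(beat$p_lv)
  )
}

#' Simulate the closed-loop circulation to a periodic beat
#'
#' Integrates the two-state ODE system (LV volume, Windkessel pressure)
#' beat by beat with an adaptive stiff solver. Valves are ideal diodes
#' (flow clipped at zero), the LV pressure is `E(t) (V - V0)` with a smooth
#' double-cosine activation over the systolic window, and the reported
#' aortic pressure is the Windkessel compartment pressure (the
#' cuff-equivalent arterial site distal to `Zc`). The run stops when every
#' per-beat metric (EDV, ESV, SBP, DBP, MAP) changes by at most
#' `periodicity_tol` (relative) between consecutive beats, after at least
#' three beats.
#'
#' @param params A [circ_params()] object.
#' @param n_cycles Maximum number of beats (default 30).
#' @param dt Output sampling interval (s); default 0.002.
#' @param periodicity_tol Relative beat-to-beat change declaring
#'   periodicity; default 2e-4 (tight enough that the per-beat volume
#'   balance closes to well under 1e-3 relative).
#' @return An object of class `hemo_trace`: list with `trace` (tibble `t`,
#'   `p_lv`, `p_ao`, `v_lv`, `q_ao` for the whole run), `final_beat` (same
#'   columns, last beat, time rebased to 0), `metrics` (one-row tibble of
#'   final-beat metrics), `n_beats`, `periodic` flag and the `params` used.
#' @export
simulate_circulation <- function(params, n_cycles = 30, dt = 0.002,
                                 periodicity_tol = 2e-4) {
  stopifnot(inherits(params, "circ_params"))
  p <- list(T = params$cycle_period, Ts = params$systole_duration,
            Emax = params$Emax, Emin = params$Emin, V0 = params$V0,
            Pven = params$venous_pressure,
            R_s = params$R_total * 0.06,   # mmHg.min/L -> mmHg.s/mL
            Zc_s = params$Zc * 0.06,
            C = params$C, Rmv_s = params$R_mv)
  y <- c(V = params$V0 + params$venous_pressure / params$Emin, P = 0.9 * 80)
  times_beat <- seq(0, p$T, by = dt)
  prev <- NULL
  periodic <- FALSE
  beats <- vector("list", n_cycles)
  n_done <- 0
  for (k in seq_len(n_cycles)) {
    sol <- deSolve::ode(y = y, times = times_beat, func = circ_rhs, parms = p,
                        method = "lsoda", rtol = 1e-8, atol = 1e-8)
    if (attr(sol, "istate")[1] < 0) {
      warning("ODE integrator reported failure in beat ", k)
      break
    }
    V <- sol[, "V"]; Pwk <- sol[, "P"]
    tb <- sol[, "time"] %% p$T
    E <- p$Emin + (p$Emax - p$Emin) * elastance_activation(tb, p$Ts)
    p_lv <- E * (V - p$V0)
    q_ao <- pmax(0, (p_lv - Pwk) / p$Zc_s)
    beat <- tibble::tibble(t = sol[, "time"] + (k - 1) * p$T,
                           p_lv = p_lv, p_ao = Pwk, v_lv = V, q_ao = q_ao)
    beats[[k]] <- beat
    n_done <- k
    m <- beat_metrics(beat)
    if (!is.null(prev) && k >= 3) {
      rel <- abs(unlist(m[c("EDV", "ESV", "SBP", "DBP", "MAP")]) -
                   unlist(prev[c("EDV", "ESV", "SBP", "DBP", "MAP")])) /
        pmax(abs(unlist(prev[c("EDV", "ESV", "SBP", "DBP", "MAP")])), 1e-9)
      if (all(rel <= periodicity_tol)) { periodic <- TRUE }
    }
    prev <- m
    y <- c(V = unname(V[length(V)]), P = unname(Pwk[length(Pwk)]))
    if (periodic) break
  }
  beats <- beats[seq_len(n_done)]
  # drop the duplicated beat-boundary sample when gluing beats together
  full <- dplyr::bind_rows(lapply(seq_along(beats), function(i) {
    if (i < length(beats)) beats[[i]][-nrow(beats[[i]]), ] else beats[[i]]
  }))
  final <- beats[[length(beats)]]
  final$t <- final$t - final$t[1]
  structure(list(trace = full, final_beat = final,
                 metrics = beat_metrics(final), n_beats = length(beats),
                 periodic = periodic, params = params),
            class = "hemo_trace")
}

#' @export
print.hemo_trace <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<hemo_trace>  %d beats%s\n", x$n_beats,
              if (x$periodic) " (periodic)" else " (NOT periodic)"))
  cat(sprintf("  aortic %0.1f/%0.1f mmHg (mean %0.1f)   EDV %0.1f  ESV %0.1f mL   EF %0.3f\n",
              m$SBP, m$DBP, m$MAP, m$EDV, m$ESV, m$EF))
  invisible(x)
}

#' One-row summary of a simulated trace
#'
#' @param x A `hemo_trace` object.
#' @param ... Unused.
#' @return The final-beat metrics tibble with `n_beats` and `periodic`.
#' @export
glance.hemo_trace <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(n_beats = x$n_beats, periodic = x$periodic))
}

#' Refine circulation parameters against the cuff pressures
#'
#' Iteratively retunes the calibrated model so the periodic beat reproduces
#' the recorded cuff pressures: the arterial compliance is updated by a
#' secant-type multiplicative step on the pulse-pressure error, the
#' per-beat forward volume (through the peak elastance) on the mid-pressure
#' error, and the diastolic elastance keeps the end-diastolic volume at its
#' target. Stops when simulated SBP and DBP are both within `tol` of the
#' record (and EDV within its band), or after `max_iter` iterations, in
#' which case the best parameters found so far are returned with
#' `converged = FALSE`.
#'
#' @param params A [circ_params()] object from [calibrate()].
#' @param record The [clinical_record()] being matched.
#' @param tol Pressure tolerance (mmHg); default 1.
#' @param max_iter Iteration cap; default 25.
#' @param ef_target Prescribed ejection fraction; default 0.60. The EDV
#'   target is chosen inside `edv_range` to bring the loop EF as close as
#'   possible to this value (`EDV = SV / ef_target`, clamped to the range).
#' @param edv_range Admissible end-diastolic volume band (mL); default
#'   `c(136, 138)`, the non-remodeled left ventricle.
#' @param edv_tol Allowed EDV deviation from its target (mL); default 0.5.
#' @return A [circ_params()] object with attributes `converged` (logical)
#'   and `history` (tibble of per-iteration simulated SBP/DBP/MAP/EDV).
#' @export
refine_to_cuff <- function(params, record, tol = 1, max_iter = 25,
                           ef_target = 0.60, edv_range = c(136, 138),
                           edv_tol = 0.5) {
  stopifnot(inherits(params, "circ_params"), inherits(record, "clinical_record"))
  edv_target <- mean(edv_range)
  if (tol <= 0) {
    attr(params, "converged") <- FALSE
    warning("tolerance of 0 mmHg cannot be met in floating point; returning input")
    return(params)
  }
  pp_target <- record$sbp - record$dbp
  mid_target <- (record$sbp + record$dbp) / 2
  best <- params
  best_err <- Inf
  hist <- vector("list", max_iter)
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    sim <- simulate_circulation(params)
    m <- sim$metrics
    hist[[i]] <- tibble::tibble(iter = i, SBP = m$SBP, DBP = m$DBP,
                                MAP = m$MAP, EDV = m$EDV, EF = m$EF,
                                C = params$C, Emax = params$Emax,
                                Emin = params$Emin)
    # the EDV target sits inside the admissible band, at the point bringing
    # the ejection fraction closest to its prescribed value
    edv_target <- min(max(m$SV / ef_target, edv_range[1]), edv_range[2])
    err <- max(abs(m$SBP - record$sbp), abs(m$DBP - record$dbp))
    if (err < best_err) { best <- params; best_err <- err }
    if (err <= tol && abs(m$EDV - edv_target) <= edv_tol) {
      converged <- TRUE
      best <- params
      break
    }
    # damped multiplicative quasi-Newton updates (each knob has a known
    # hyperbolic first-order response: PP ~ SV/C, mid-pressure ~ SV,
    # EDV - V0 ~ Pven/Emin)
    pp_sim <- m$SBP - m$DBP
    mid_sim <- (m$SBP + m$DBP) / 2
    C_new <- params$C * (pp_sim / pp_target)^0.8
    Emax_new <- params$Emax * (mid_target / mid_sim)^1.2
    Emin_new <- params$Emin * ((m$EDV - params$V0) /
                                 (edv_target - params$V0))^0.8
    params <- circ_params(R_total = params$R_total, C = C_new, Zc = params$Zc,
                          Emax = Emax_new, Emin = Emin_new, V0 = params$V0,
                          cycle_period = params$cycle_period,
                          systole_duration = params$systole_duration,
                          venous_pressure = params$venous_pressure,
                          R_mv = params$R_mv)
  }
  attr(best, "converged") <- converged
  attr(best, "history") <- dplyr::bind_rows(hist)
  best
}

#' Pressure-volume loop metrics
#'
#' Derives the ventricular function indices from the final periodic beat:
#' end-diastolic and end-systolic volume, stroke volume, ejection fraction,
#' stroke work (the PV-loop area, mmHg.mL, by the shoelace formula) and the
#' valvulo-arterial impedance `Zva = peak ejection LV pressure / (SV/BSA)`
#' (mmHg/mL/m^2), a global afterload index.
#'
#' @param trace A `hemo_trace` from [simulate_circulation()], or a data
#'   frame with columns `t`, `p_lv`, `p_ao`, `v_lv`, `q_ao` holding one
#'   beat.
#' @param bsa Body surface area (m^2). If missing, `Zva` is reported as
#'   `NA` with a warning.
#' @return A one-row tibble: `EDV`, `ESV`, `SV`, `EF`, `SBP`, `DBP`, `MAP`,
#'   `stroke_work`, `Zva`.
#' @export
pv_metrics <- function(trace, bsa = NULL) {
  beat <- if (inherits(trace, "hemo_trace")) trace$final_beat else
    tibble::as_tibble(trace)
  stopifnot(all(c("p_lv", "p_ao", "v_lv", "q_ao") %in% names(beat)))
  m <- beat_metrics(beat)
  # shoelace area of the closed (V, P_lv) loop
  v <- beat$v_lv; pl <- beat$p_lv
  n <- length(v)
  j <- c(2:n, 1)
  sw <- abs(sum(v * pl[j] - v[j] * pl)) / 2
  ejecting <- beat$q_ao > 0
  peak_ej <- if (any(ejecting)) max(beat$p_lv[ejecting]) else NA_real_
  zva <- if (is.null(bsa)) {
    warning("BSA missing: valvulo-arterial impedance omitted")
    NA_real_
  } else {
    peak_ej / (m$SV / bsa)
  }
  tibble::tibble(EDV = m$EDV, ESV = m$ESV, SV = m$SV, EF = m$EF,
                 SBP = m$SBP, DBP = m$DBP, MAP = m$MAP,
                 stroke_work = sw, Zva = zva)
}

#' Read / write a hemodynamic trace CSV
#'
#' Columns `t`, `p_lv`, `p_ao`, `v_lv`, `q_ao` (s, mmHg, mL, mL/s).
#'
#' @param trace A `hemo_trace` or a data frame with the trace columns.
#' @param path CSV file path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- if (inherits(trace, "hemo_trace")) trace$trace else trace
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "p_lv", "p_ao", "v_lv", "q_ao")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Read / write a clinical record JSON
#'
#' @param record A [clinical_record()].
#' @param path JSON file path.
#' @export
write_record_json <- function(record, path) {
  writeLines(as.character(jsonlite::toJSON(unclass(record), auto_unbox = TRUE,
                                           digits = NA, null = "null")), path)
  invisible(path)
}

#' @rdname write_record_json
#' @export
read_record_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(clinical_record, x[!vapply(x, is.null, logical(1))])
}
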