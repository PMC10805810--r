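# Plug-flow-reactor kinetic model and synthetic HPLC chromatograms.
#
# Chemistry: base-catalysed aldol condensation
#     benzaldehyde (B) + acetone (Ac) --NaOH--> benzylideneacetone (P)
#     P + B                           --NaOH--> dibenzylideneacetone (D)
#     P + Ac                          --NaOH--> higher condensation adduct (X)
# with effective rate laws
#     r1 = k1(T) [B][Ac][OH-],  r2 = k2(T) [P][B][OH-],  r3 = k3(T) [P][Ac]^2[OH-]
# and Arrhenius temperature dependence
#     k(T) = k_ref * exp(-Ea/R * (1/T - 1/T_ref)).
# X lumps the further condensation products of acetone and benzaldehyde
# (it carries one benzylidene unit); it is what makes yield fall at high
# acetone equivalents.  NaOH acts as catalyst ([OH-] constant along the
# reactor).  The reactor is an isothermal PFR: constant density, no axial
# dispersion, integrated over the residence time with classical RK4.  RK4
# preserves the linear benzaldehyde balance
#     [B] + [P] + 2[D] + [X] = [B]_in
# to machine precision.
#
# The rate constants are declared fixtures chosen to reproduce the
# qualitative trends of the real campaign (yield increases with
# temperature; unimodal in acetone equivalents via feed dilution; weak
# residence-time effect at typical conversions).  They are NOT the true
# kinetics of this reaction.

R_GAS <- 8.314462618  # J mol^-1 K^-1

#' Default fixture kinetics for the aldol condensation simulator
#' @return list with `k1_ref`, `k2_ref` (L^2 mol^-2 min^-1), `k3_ref`
#'   (L^3 mol^-3 min^-1, empirical second order in acetone), `Ea1`,
#'   `Ea2`, `Ea3` (J/mol), `T_ref` (K)
#' @export
default_kinetics <- function() {
  list(k1_ref = 1.6, k2_ref = 0.5, k3_ref = 0.010,
       Ea1 = 55000, Ea2 = 70000, Ea3 = 50000, T_ref = 323.15)
}

arrhenius <- function(k_ref, Ea, temp_K, T_ref) {
  k_ref * exp(-Ea / R_GAS * (1 / temp_K - 1 / T_ref))
}

#' Integrate the isothermal PFR over the residence time
#'
#' Vectorised over rows: each row of `inlet` is one reactor run.
#'
#' @param inlet matrix (or data.frame) with columns `B`, `Ac`, `OH`, `P`,
#'   `D` (and optionally `X`) of inlet concentrations in mol/L
#' @param residence_time vector of residence times, min
#' @param temperature vector of reactor temperatures, degC
#' @param kinetics kinetics list, see [default_kinetics()]
#' @param nsteps RK4 steps (fixed grid per run)
#' @return matrix of outlet concentrations, same columns as `inlet`
#' @export
simulate_reactor <- function(inlet, residence_time, temperature,
                             kinetics = default_kinetics(), nsteps = 60L) {
  inlet <- as.matrix(inlet)
  if (!"X" %in% colnames(inlet)) inlet <- cbind(inlet, X = 0)
  X <- inlet[, c("B", "Ac", "OH", "P", "D", "X"), drop = FALSE]
  n <- nrow(X)
  tau <- rep_len(residence_time, n)
  temp <- rep_len(temperature, n)
  if (any(!is.finite(tau)) || any(tau < 0)) stop("residence_time must be finite and >= 0")
  if (any(temp < -50 | temp > 300)) stop("temperature outside physical range (degC): ", temp[which(temp < -50 | temp > 300)[1]])
  TK <- temp + 273.15
  k1 <- arrhenius(kinetics$k1_ref, kinetics$Ea1, TK, kinetics$T_ref)
  k2 <- arrhenius(kinetics$k2_ref, kinetics$Ea2, TK, kinetics$T_ref)
  k3 <- arrhenius(kinetics$k3_ref %||% 0, kinetics$Ea3 %||% 0, TK, kinetics$T_ref)
  OH <- X[, "OH"]
  B <- X[, "B"]; Ac <- X[, "Ac"]; P <- X[, "P"]; D <- X[, "D"]; Xc <- X[, "X"]
  h <- tau / nsteps
  rhs <- function(B, Ac, P) {
    r1 <- k1 * B * Ac * OH
    r2 <- k2 * P * B * OH
    r3 <- k3 * P * Ac^2 * OH
    list(dB = -(r1 + r2), dAc = -(r1 + r3), dP = r1 - r2 - r3, dD = r2, dX = r3)
  }
  for (s in seq_len(nsteps)) {
    f1 <- rhs(B, Ac, P)
    f2 <- rhs(B + h / 2 * f1$dB, Ac + h / 2 * f1$dAc, P + h / 2 * f1$dP)
    f3 <- rhs(B + h / 2 * f2$dB, Ac + h / 2 * f2$dAc, P + h / 2 * f2$dP)
    f4 <- rhs(B + h * f3$dB, Ac + h * f3$dAc, P + h * f3$dP)
    B <- B + h / 6 * (f1$dB + 2 * f2$dB + 2 * f3$dB + f4$dB)
    Ac <- Ac + h / 6 * (f1$dAc + 2 * f2$dAc + 2 * f3$dAc + f4$dAc)
    P <- P + h / 6 * (f1$dP + 2 * f2$dP + 2 * f3$dP + f4$dP)
    D <- D + h / 6 * (f1$dD + 2 * f2$dD + 2 * f3$dD + f4$dD)
    Xc <- Xc + h / 6 * (f1$dX + 2 * f2$dX + 2 * f3$dX + f4$dX)
  }
  if (any(!is.finite(B))) stop("reactor integration diverged; settings: tau=", tau[which(!is.finite(B))[1]])
  cbind(B = pmax(B, 0), Ac = pmax(Ac, 0), OH = OH,
        P = pmax(P, 0), D = pmax(D, 0), X = pmax(Xc, 0))
}

#' Pump flow rates realising a reaction condition on a rig
#'
#' Solves the linear system: total flow Q = V_reactor / residence_time and
#' molar-flow ratios equal to the requested equivalents given the
#' (purity-corrected) feed concentrations.
#'
#' @param condition named vector with `equiv_acetone`, `equiv_naoh`,
#'   `residence_time`, `temperature`
#' @param lab lab fixture block (rig + feeds), see [default_lab()]
#' @return named list: `Q` (named flow vector A/B/C in mL/min), `Q_total`,
#'   `inlet` (named inlet concentrations incl. internal standard and the
#'   effective solvent-borne impurity flag)
#' @export
condition_to_flows <- function(condition, lab) {
  rig <- lab$rig; feeds <- lab$feeds
  tau <- condition[["residence_time"]]
  if (tau < rig$residence_time_range[1] || tau > rig$residence_time_range[2])
    stop("residence time ", tau, " outside rig range")
  Q_total <- rig$reactor_volume / tau
  cA <- feeds$A$conc * feeds$A$purity
  cB <- feeds$B$conc * feeds$B$purity
  cC <- feeds$C$conc * feeds$C$purity
  ea <- condition[["equiv_acetone"]]; en <- condition[["equiv_naoh"]]
  if (ea <= 0 || en <= 0) stop("equivalents must be > 0")
  # Q_B cB / (Q_A cA) = ea ; Q_C cC / (Q_A cA) = en ; Q_A + Q_B + Q_C = Q_total
  QA <- Q_total / (1 + ea * cA / cB + en * cA / cC)
  QB <- ea * QA * cA / cB
  QC <- en * QA * cA / cC
  Q <- c(A = QA, B = QB, C = QC)
  lo <- rig$pump_flow_range[1]; hi <- rig$pump_flow_range[2]
  bad <- names(Q)[Q < lo | Q > hi]
  if (length(bad))
    stop("required flow outside pump range for pump ", bad[1],
         " (", signif(Q[[bad[1]]], 4), " mL/min)")
  inlet <- c(
    B = cA * QA / Q_total,
    Ac = cB * QB / Q_total,
    OH = cC * QC / Q_total,
    P = 0, D = 0,
    IS = feeds$A$is_conc * QA / Q_total
  )
  list(Q = Q, Q_total = Q_total, inlet = inlet)
}

#' Synthesize an HPLC chromatogram from an outlet composition
#'
#' One peak per species above the detection limit, area =
#' response_factor * concentration * (1 + eps) with multiplicative
#' Gaussian noise, small retention jitter within the window.  Feed
#' impurities appear as unidentified points.  Fault modes reproduce the
#' two failure behaviours seen in real campaigns: `is_peak_shift`
#' displaces the internal-standard peak outside its window and leaves a
#' small spurious peak inside it (mis-assigned as the internal standard,
#' giving a grossly superphysical downstream yield); `product_peak_shift`
#' displaces the product peak just outside its window (downstream yield
#' 0%).
#'
#' @param outlet named concentration vector with at least
#'   `B`,`Ac`,`P`,`D`,`IS` (mol/L)
#' @param hplc HPLC fixture block (see [default_hplc()])
#' @param noise list with `area_sd`, `rt_jitter_sd`, `detection_limit`;
#'   set `area_sd = 0` and `rt_jitter_sd = 0` for noise-free output
#' @param fault_mode one of `"none"`, `"is_peak_shift"`,
#'   `"product_peak_shift"`
#' @param unidentified_impurity emit a small unidentified impurity point?
#' @return data.frame `retention_time`, `area`, `species` (NA for
#'   unidentified), with attributes `method_runtime`, `fault_annotation`
#' @export
synthesize_chromatogram <- function(outlet, hplc,
                                    noise = list(area_sd = 0, rt_jitter_sd = 0,
                                                 detection_limit = 1e-4),
                                    fault_mode = "none",
                                    unidentified_impurity = TRUE) {
  stopifnot(fault_mode %in% c("none", "is_peak_shift", "product_peak_shift"))
  species_conc <- c(
    acetone = unname(outlet["Ac"]), benzaldehyde = unname(outlet["B"]),
    benzylideneacetone = unname(outlet["P"]),
    dibenzylideneacetone = unname(outlet["D"])
  )
  species_conc[hplc$internal_standard] <- unname(outlet["IS"])
  # the detector's true response; defaults to the calibrated factors, but a
  # drifted instrument can carry true_response_factors that differ
  rf_true <- hplc$true_response_factors %||% hplc$response_factors
  rt <- numeric(0); area <- numeric(0); sp <- character(0)
  for (s in names(species_conc)) {
    conc <- species_conc[[s]]
    if (!s %in% names(hplc$retention_time)) next
    if (is.na(conc) || conc <= noise$detection_limit) next
    t0 <- hplc$retention_time[[s]]
    jit <- if (noise$rt_jitter_sd > 0) stats::rnorm(1, 0, noise$rt_jitter_sd) else 0
    a <- rf_true[[s]] * conc
    if (noise$area_sd > 0) a <- a * (1 + stats::rnorm(1, 0, noise$area_sd))
    rt <- c(rt, t0 + jit); area <- c(area, max(a, 0)); sp <- c(sp, s)
  }
  if (fault_mode == "is_peak_shift") {
    is_sp <- hplc$internal_standard
    i <- which(sp == is_sp)
    if (length(i)) {
      w <- hplc$retention_windows[[is_sp]]
      rt[i] <- w[2] + 0.6  # displaced well outside its window
      # small spurious peak lands inside the window and will be mis-assigned
      rt <- c(rt, mean(w)); area <- c(area, 0.002 * area[i]); sp <- c(sp, NA)
    }
  }
  if (fault_mode == "product_peak_shift") {
    i <- which(sp == "benzylideneacetone")
    if (length(i)) {
      w <- hplc$retention_windows[["benzylideneacetone"]]
      rt[i] <- w[2] + 0.15  # just outside the window
    }
  }
  if (isTRUE(unidentified_impurity)) {
    rt <- c(rt, 0.8); area <- c(area, 5); sp <- c(sp, NA)
  }
  chrom <- data.frame(retention_time = rt, area = area, species = sp,
                      stringsAsFactors = FALSE)
  chrom <- chrom[chrom$retention_time >= 0 & chrom$retention_time <= hplc$method_runtime + 1, , drop = FALSE]
  rownames(chrom) <- NULL
  attr(chrom, "method_runtime") <- hplc$method_runtime
  attr(chrom, "fault_annotation") <- fault_mode
  chrom
}

#' Noise-free ground-truth objectives for a set of conditions
#'
#' Bypasses the chromatogram: runs flow translation + PFR integration and
#' computes exact yield and run material cost.  This is the oracle the
#' optimiser acceptance tests measure against; vectorised over rows of
#' `conditions`.
#'
#' @param conditions data.frame with columns `equiv_acetone`,
#'   `equiv_naoh`, `residence_time`, `temperature`
#' @param config campaign config (uses the first goal-request lab's
#'   fixtures by default)
#' @param lab_name which lab's feed fixture to use
#' @return data.frame with columns `yield` (percent) and `cost` (currency
#'   per mol benzaldehyde)
#' @export
ground_truth_objectives <- function(conditions, config = default_campaign_config(),
                                    lab_name = config$goal_request$labs[1]) {
  conditions <- as.data.frame(conditions)
  lab <- config$labs[[lab_name]]
  n <- nrow(conditions)
  # closed-form flow split, vectorised (same algebra as condition_to_flows)
  rig <- lab$rig; feeds <- lab$feeds
  cA <- feeds$A$conc * feeds$A$purity
  cB <- feeds$B$conc * feeds$B$purity
  cC <- feeds$C$conc * feeds$C$purity
  tau <- conditions$residence_time
  ea <- conditions$equiv_acetone; en <- conditions$equiv_naoh
  Qt <- rig$reactor_volume / tau
  QA <- Qt / (1 + ea * cA / cB + en * cA / cC)
  QB <- ea * QA * cA / cB
  QC <- en * QA * cA / cC
  lo <- rig$pump_flow_range[1]; hi <- rig$pump_flow_range[2]
  ok <- tau >= rig$residence_time_range[1] & tau <= rig$residence_time_range[2] &
    ea > 0 & en > 0 &
    QA >= lo & QA <= hi & QB >= lo & QB <= hi & QC >= lo & QC <= hi
  inlet <- cbind(B = cA * QA / Qt, Ac = cB * QB / Qt, OH = cC * QC / Qt,
                 P = 0, D = 0)
  yield <- rep(NA_real_, n); cost <- rep(NA_real_, n)
  if (any(ok)) {
    out <- simulate_reactor(inlet[ok, , drop = FALSE],
                            conditions$residence_time[ok],
                            conditions$temperature[ok],
                            kinetics = config$kinetics)
    yield[ok] <- 100 * out[, "P"] / inlet[ok, "B"]
    cost[ok] <- compute_cost(conditions[ok, , drop = FALSE], lab, config$economics)
  }
  data.frame(yield = yield, cost = cost)
}
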