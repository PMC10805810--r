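# Post-processing: chromatogram -> performance indicators.
#
# Yield uses single-point internal-standard quantification:
#   n_product = (A_product / A_IS) * RRF * n_IS,
#   yield%    = 100 * n_product / n_benzaldehyde_basis
# where RRF = RF_IS / RF_product and the internal standard is premixed in
# the benzaldehyde feed, so n_IS / n_B = C_IS_feed / C_B_feed, making the
# quantification an exact inverse of the chromatogram synthesis when
# noise is off.

#' Build a quantification method from a lab fixture
#' @param lab lab fixture block
#' @param abnormal_yield_threshold yields above this (percent) are flagged
#'   abnormal
#' @return list of class `quant_method`
#' @export
quant_method <- function(lab, abnormal_yield_threshold = 103) {
  h <- lab$hplc
  rf <- h$response_factors
  is_sp <- h$internal_standard
  list(
    internal_standard = is_sp,
    retention_windows = h$retention_windows,
    rrf = rf[[is_sp]] / rf,                       # species -> RRF vs IS
    is_over_basis = lab$feeds$A$is_conc / (lab$feeds$A$conc * lab$feeds$A$purity),
    abnormal_yield_threshold = abnormal_yield_threshold
  )
}

#' Assign chromatogram peaks to species by retention window
#'
#' Each peak is assigned to the unique species whose window contains its
#' retention time, else marked unidentified; when several peaks fall in
#' one window, the largest area wins and the rest become unidentified.
#'
#' @param chrom chromatogram data.frame from [synthesize_chromatogram()]
#' @param method a `quant_method`
#' @return chromatogram with an `assigned` column (species name or NA)
#' @export
assign_peaks <- function(chrom, method) {
  if (nrow(chrom) == 0L) stop("empty chromatogram")
  assigned <- rep(NA_character_, nrow(chrom))
  for (s in names(method$retention_windows)) {
    w <- method$retention_windows[[s]]
    hits <- which(chrom$retention_time >= w[1] & chrom$retention_time <= w[2])
    if (length(hits) == 0L) next
    best <- hits[which.max(chrom$area[hits])]
    assigned[best] <- s
  }
  chrom$assigned <- assigned
  chrom
}

#' Compute percent yield from an assigned chromatogram
#'
#' @param assigned chromatogram with `assigned` column
#' @param method a `quant_method`
#' @return list: `yield` (percent; 0 when the product peak is missing),
#'   `is_failure` (TRUE when the internal-standard peak is absent or has
#'   zero area, in which case `yield` is NA)
#' @export
compute_yield <- function(assigned, method) {
  i_is <- which(assigned$assigned == method$internal_standard)
  if (length(i_is) == 0L || assigned$area[i_is[1]] <= 0)
    return(list(yield = NA_real_, is_failure = TRUE))
  a_is <- assigned$area[i_is[1]]
  i_p <- which(assigned$assigned == "benzylideneacetone")
  if (length(i_p) == 0L) return(list(yield = 0, is_failure = FALSE))
  a_p <- assigned$area[i_p[1]]
  rrf <- method$rrf[["benzylideneacetone"]]
  # n_P / n_B = (A_P / A_IS) * RRF * (n_IS / n_B)
  yield <- 100 * (a_p / a_is) * rrf * method$is_over_basis
  list(yield = yield, is_failure = FALSE)
}

#' Run material cost per mole of benzaldehyde
#'
#' Counts the molar amount of input chemicals sourced from the pumps:
#' benzaldehyde, internal standard and feed-A solvent; acetone and feed-B
#' solvent (scaling with `equiv_acetone`); NaOH and feed-C solvent
#' (scaling with `equiv_naoh`).  Strictly linear in each equivalence
#' variable.  Vectorised over rows of `conditions`.
#'
#' @param conditions data.frame (or single named vector) of reaction
#'   conditions
#' @param lab lab fixture block
#' @param economics list with `prices` (currency per mol, by species)
#' @return numeric vector of costs, currency per mol benzaldehyde
#' @export
compute_cost <- function(conditions, lab, economics) {
  if (is.null(dim(conditions))) conditions <- as.data.frame(as.list(conditions))
  p <- economics$prices
  feeds <- lab$feeds
  need <- unique(c("benzaldehyde", feeds$A$internal_standard, feeds$A$solvent,
                   feeds$B$species, feeds$B$solvent, feeds$C$species, feeds$C$solvent))
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing price for species: ", paste(miss, collapse = ", "))
  cA <- feeds$A$conc * feeds$A$purity
  cB <- feeds$B$conc * feeds$B$purity
  cC <- feeds$C$conc * feeds$C$purity
  # litres of each feed per mole benzaldehyde
  vA <- 1 / cA
  vB <- conditions$equiv_acetone / cB
  vC <- conditions$equiv_naoh / cC
  base <- p[["benzaldehyde"]] +
    vA * (feeds$A$is_conc * p[[feeds$A$internal_standard]] +
          feeds$A$solvent_conc * p[[feeds$A$solvent]])
  per_ea <- p[[feeds$B$species]] + (feeds$B$solvent_conc / cB) * p[[feeds$B$solvent]]
  per_en <- p[[feeds$C$species]] + (feeds$C$solvent_conc / cC) * p[[feeds$C$solvent]]
  unname(base + conditions$equiv_acetone * per_ea + conditions$equiv_naoh * per_en)
}

#' E-factor and space-time yield for one analysed run
#'
#' E-factor = (total input mass - product mass) / product mass using the
#' dispensed feed masses; STY = product mass / (reactor volume x residence
#' time) in g/L/h after scaling the run to the standard 5 mL benzaldehyde
#' injection volume.
#'
#' @param yield percent yield of the run
#' @param condition named condition vector
#' @param lab lab fixture block
#' @param sty_injection_volume standard benzaldehyde injection volume for
#'   STY scaling, mL
#' @return list `e_factor` (NA when product mass is zero) and `sty`
#' @export
compute_efactor_sty <- function(yield, condition, lab, sty_injection_volume = 5) {
  mm <- species_molar_mass()
  fl <- condition_to_flows(condition, lab)
  inj <- lab$rig$injection_volume
  disp <- fl$Q * (inj / fl$Q[["A"]])            # mL dispensed per pump
  mass_in <- sum(disp * vapply(lab$feeds, function(f) f$density, numeric(1)))  # g
  n_b <- lab$feeds$A$conc * lab$feeds$A$purity * inj / 1000   # mol benzaldehyde per run
  mass_p <- (yield / 100) * n_b * mm[["benzylideneacetone"]]  # g
  e_factor <- if (mass_p > 0) (mass_in - mass_p) / mass_p else NA_real_
  scale <- sty_injection_volume / inj
  mass_p_std <- mass_p * scale
  vol_L <- lab$rig$reactor_volume / 1000
  tau_h <- condition[["residence_time"]] / 60
  sty <- if (mass_p_std > 0) mass_p_std / (vol_L * tau_h) else 0
  list(e_factor = e_factor, sty = sty)
}

#' Flag abnormal performance indicators
#'
#' A run is abnormal when its computed yield exceeds the configured
#' superphysical threshold or the internal-standard quantification
#' failed.  Zero-percent yields are normal data and stay in history.
#'
#' @param yield percent yield (NA on internal-standard failure)
#' @param is_failure logical from [compute_yield()]
#' @param method a `quant_method`
#' @return logical abnormal flag
#' @export
flag_abnormal <- function(yield, is_failure, method) {
  isTRUE(is_failure) || (is.finite(yield) && yield > method$abnormal_yield_threshold)
}

#' Full post-processing of one chromatogram into performance indicators
#'
#' @param chrom chromatogram
#' @param condition named condition vector
#' @param lab lab fixture block
#' @param economics economics block
#' @param method optional `quant_method` (built from `lab` if NULL)
#' @return list: yield, cost, e_factor, sty, abnormal_flag, is_failure
#' @export
postprocess_run <- function(chrom, condition, lab, economics, method = NULL) {
  if (is.null(method)) method <- quant_method(lab)
  assigned <- assign_peaks(chrom, method)
  yr <- compute_yield(assigned, method)
  abnormal <- flag_abnormal(yr$yield, yr$is_failure, method)
  cost <- compute_cost(condition, lab, economics)
  es <- if (!is.na(yr$yield) && !abnormal) {
    compute_efactor_sty(yr$yield, condition, lab)
  } else list(e_factor = NA_real_, sty = NA_real_)
  list(yield = yr$yield, cost = cost, e_factor = es$e_factor, sty = es$sty,
       abnormal_flag = abnormal, is_failure = yr$is_failure)
}
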