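# Campaign configuration: default fixtures and validation.
#
# The default config emulates two flow-chemistry rigs ("cambridge",
# "singapore") running the base-catalysed aldol condensation of
# benzaldehyde (1) + acetone (2) -> benzylideneacetone (4), side product
# dibenzylideneacetone (5).  Feed stocks follow the published platform
# descriptions: 0.5 M benzaldehyde in acetonitrile with an internal
# standard, 6.73 M acetone (50% v/v in acetonitrile), and 0.1 M NaOH in
# ethanol.  Reactor volumes, pump limits, kinetic constants, prices and
# HPLC response factors are declared desk-scale fixtures, not measured
# values.

cond_vars <- c("equiv_acetone", "equiv_naoh", "residence_time", "temperature")

#' Molar masses (g/mol) of the species handled by the simulator
#' @return named numeric vector
#' @export
species_molar_mass <- function() {
  c(benzaldehyde = 106.12, acetone = 58.08, naoh = 40.00,
    benzylideneacetone = 146.19, dibenzylideneacetone = 234.29,
    biphenyl = 154.21, naphthalene = 128.17,
    acetonitrile = 41.05, ethanol = 46.07)
}

default_hplc <- function(which) {
  if (which == "cambridge") {
    list(
      method_runtime = 17,
      internal_standard = "biphenyl",
      retention_time = c(acetone = 2.2, benzaldehyde = 5.1,
                         benzylideneacetone = 8.7, biphenyl = 11.5,
                         dibenzylideneacetone = 14.2),
      retention_windows = list(
        acetone = c(2.0, 2.4), benzaldehyde = c(4.9, 5.4),
        benzylideneacetone = c(8.4, 9.0), biphenyl = c(11.2, 11.8),
        dibenzylideneacetone = c(13.9, 14.5)),
      response_factors = c(acetone = 800, benzaldehyde = 9000,
                           benzylideneacetone = 15000, biphenyl = 12000,
                           dibenzylideneacetone = 22000)
    )
  } else {
    list(
      method_runtime = 8,
      internal_standard = "naphthalene",
      retention_time = c(acetone = 1.5, benzaldehyde = 3.2,
                         benzylideneacetone = 4.8, naphthalene = 6.1,
                         dibenzylideneacetone = 7.2),
      retention_windows = list(
        acetone = c(1.3, 1.7), benzaldehyde = c(3.0, 3.4),
        benzylideneacetone = c(4.6, 5.0), naphthalene = c(5.9, 6.3),
        dibenzylideneacetone = c(7.0, 7.4)),
      response_factors = c(acetone = 700, benzaldehyde = 8000,
                           benzylideneacetone = 13000, naphthalene = 10000,
                           dibenzylideneacetone = 19000)
    )
  }
}

default_lab <- function(which) {
  is_species <- if (which == "cambridge") "biphenyl" else "naphthalene"
  is_conc <- if (which == "cambridge") 0.06 else 0.05
  list(
    name = which,
    rig = list(
      reactor_volume = 10,               # mL
      temperature_range = c(20, 80),     # degC
      residence_time_range = c(0.5, 20), # min
      pump_flow_range = c(0.02, 10),     # mL/min, all pumps
      injection_volume = 2               # mL benzaldehyde feed per run
    ),
    feeds = list(
      A = list(species = "benzaldehyde", conc = 0.5,
               internal_standard = is_species, is_conc = is_conc,
               solvent = "acetonitrile", solvent_conc = 18.9,
               purity = 0.99, fill_level = 500, density = 0.79),
      B = list(species = "acetone", conc = 6.73,
               solvent = "acetonitrile", solvent_conc = 9.4,
               purity = 0.99, fill_level = 1000, density = 0.78),
      C = list(species = "naoh", conc = 0.1,
               solvent = "ethanol", solvent_conc = 17.1,
               purity = 0.97, fill_level = 1000, density = 0.79)
    ),
    hplc = default_hplc(which)
  )
}

#' Default two-lab campaign configuration
#'
#' Mirrors the published two-lab cost-yield campaign: 65-experiment
#' allowance, two labs, yield maximised with a 90% goal threshold and run
#' material cost minimised.  All hardware/kinetics/price numbers are
#' desk-scale fixtures.
#'
#' @param seed master seed; fully determines campaign randomness
#' @return nested list, the campaign configuration
#' @export
default_campaign_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    goal_request = list(
      objectives = list(
        list(objective = "yield", direction = "maximise", threshold = 90),
        list(objective = "run_material_cost", direction = "minimise", threshold = 3.0)
      ),
      search_space = list(
        equiv_acetone = c(5, 50),
        equiv_naoh = c(0.05, 0.5),
        residence_time = c(2, 10),
        temperature = c(30, 70)
      ),
      labs = c("cambridge", "singapore"),
      cycle_allowance = 65L,
      deadline_ticks = 100000L
    ),
    labs = list(cambridge = default_lab("cambridge"),
                singapore = default_lab("singapore")),
    kinetics = default_kinetics(),
    economics = list(
      prices = c(benzaldehyde = 0.80, acetone = 0.05, naoh = 0.02,
                 biphenyl = 1.50, naphthalene = 0.90,
                 acetonitrile = 0.04, ethanol = 0.03)  # currency per mol
    ),
    optimiser = list(
      n_init = 8L, spectral_features = 500L,
      nsga_pop = 100L, nsga_gen = 100L,
      gp_restarts = 1L, ref_margin = 0.1
    ),
    noise = list(area_sd = 0.01, rt_jitter_sd = 0.02, detection_limit = 1e-4),
    faults = list(),
    control = list(
      conditions = list(
        c(equiv_acetone = 15, equiv_naoh = 0.2, residence_time = 5, temperature = 50),
        c(equiv_acetone = 30, equiv_naoh = 0.3, residence_time = 8, temperature = 60)
      ),
      tolerance = 0.05  # relative, vs cross-lab mean yield
    )
  )
}

#' Validate a campaign configuration
#'
#' @param config nested list as returned by [default_campaign_config()]
#' @return `config`, invisibly; stops with an informative message when invalid
#' @export
validate_config <- function(config) {
  missing <- setdiff(c("seed", "goal_request", "labs", "kinetics",
                       "economics", "optimiser", "noise", "control"),
                     names(config))
  if (length(missing)) stop("config is missing blocks: ", paste(missing, collapse = ", "))
  gr <- config$goal_request
  gmiss <- setdiff(c("objectives", "search_space", "labs", "cycle_allowance", "deadline_ticks"),
                   names(gr))
  if (length(gmiss)) stop("goal request is missing fields: ", paste(gmiss, collapse = ", "))
  if (length(gr$labs) < 1L) stop("goal request must name at least one lab")
  unknown <- setdiff(gr$labs, names(config$labs))
  if (length(unknown)) stop("unknown lab in goal request: ", paste(unknown, collapse = ", "))
  ssmiss <- setdiff(cond_vars, names(gr$search_space))
  if (length(ssmiss)) stop("search space is missing bounds for: ", paste(ssmiss, collapse = ", "))
  for (v in cond_vars) {
    b <- gr$search_space[[v]]
    if (length(b) != 2L || !is.finite(b[1]) || !is.finite(b[2]) || b[1] >= b[2])
      stop("search-space bounds for ", v, " must satisfy lower < upper")
  }
  if (length(gr$objectives) < 1L) stop("goal request needs at least one objective")
  for (ob in gr$objectives) {
    if (!all(c("objective", "direction", "threshold") %in% names(ob)))
      stop("each objective needs fields objective, direction, threshold")
    if (!is.finite(ob$threshold)) stop("objective threshold must be finite")
  }
  if (gr$cycle_allowance < 0L) stop("cycle_allowance must be >= 0")
  if (gr$deadline_ticks <= 0L) stop("deadline_ticks must be > 0")
  invisible(config)
}

# JSON keeps objects and arrays only; named atomic vectors (prices,
# response factors, control conditions) must travel as objects or their
# names are lost.  prep converts them to lists on the way out; restore
# rebuilds the in-memory shapes on the way in.
config_prep_json <- function(x) {
  if (is.list(x)) return(lapply(x, config_prep_json))
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

#' Read a campaign configuration from a JSON file
#' @param path JSON file
#' @return validated config list
#' @export
read_campaign_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(cfg$goal_request$objectives))
    cfg$goal_request$objectives <- lapply(seq_len(nrow(cfg$goal_request$objectives)),
                                          function(i) as.list(cfg$goal_request$objectives[i, ]))
  if (is.data.frame(cfg$control$conditions)) {
    cfg$control$conditions <- lapply(seq_len(nrow(cfg$control$conditions)),
                                     function(i) unlist(cfg$control$conditions[i, ]))
  } else if (is.list(cfg$control$conditions)) {
    cfg$control$conditions <- lapply(cfg$control$conditions, unlist)
  }
  cfg$economics$prices <- unlist(cfg$economics$prices)
  for (nm in names(cfg$labs)) {
    h <- cfg$labs[[nm]]$hplc
    h$retention_time <- unlist(h$retention_time)
    h$response_factors <- unlist(h$response_factors)
    h$retention_windows <- lapply(h$retention_windows, as.numeric)
    cfg$labs[[nm]]$hplc <- h
    cfg$labs[[nm]]$rig <- lapply(cfg$labs[[nm]]$rig, unlist)
  }
  cfg$goal_request$search_space <- lapply(cfg$goal_request$search_space, as.numeric)
  if (length(cfg$faults)) {
    if (is.data.frame(cfg$faults))
      cfg$faults <- lapply(seq_len(nrow(cfg$faults)), function(i) as.list(cfg$faults[i, ]))
  }
  validate_config(cfg)
}

#' Write a campaign configuration to JSON
#' @param config config list
#' @param path output path
#' @return `path`, invisibly
#' @export
write_campaign_config <- function(config, path) {
  jsonlite::write_json(config_prep_json(config), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
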