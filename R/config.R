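#' Load and validate a run configuration
#'
#' Reads a YAML (`.yml`/`.yaml`) or JSON (`.json`) configuration for the
#' simulation pipeline and validates it in one pass, reporting *all*
#' problems at once. Recognised keys:
#' \describe{
#'   \item{`preset`}{one of `"table1-verbatim"`, `"halflife-consistent"`,
#'     `"updated-k0"` (default `"table1-verbatim"`). See [pk_preset()].}
#'   \item{`decay_unit`}{`"1/day"` (default) or `"1/h"` — unit assigned to
#'     the absorption attenuation constants.}
#'   \item{`params`}{optional inline parameter override: a mapping with
#'     entries `NGMN` and/or `EE`, each holding [drug_params()] fields
#'     (`k_o`, `Cl`, `t_half`, `k_elim`, `V_d`, `decay_const`,
#'     `decay_unit`, `conc_unit`, `therapeutic_low`, `therapeutic_high`).
#'     Fields not given fall back to the preset.}
#'   \item{`scenario`}{mapping with `kind` in `"standard_cycle"`,
#'     `"delayed_replacement"` (alias `"missed_replacement"`),
#'     `"detachment"`, plus the kind-specific fields `delay_days`,
#'     `detach_time`, `area_fraction`, `duration`, `reattach_as_new`.}
#'   \item{`grid`}{mapping with `dt` (h, default 0.1) and optional
#'     `horizon` (h, default: the scenario regimen's horizon).}
#'   \item{`seed`}{integer seed for any stochastic stage (default 1).}
#'   \item{`outdir`}{default output directory for [run_pipeline()].}
#' }
#' Unknown keys (at the top level or inside `scenario`/`grid`) are
#' rejected by name.
#'
#' @param path path to the configuration file.
#' @return An object of class `run_config`: the validated configuration
#'   with defaults filled in.
#' @seealso [run_pipeline()], [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(raw)
}

#' @rdname load_config
#' @param config a configuration list (as from [load_config()]).
#' @export
save_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname load_config
#' @param raw a raw configuration list, as parsed from YAML/JSON; useful
#'   for building configurations programmatically without a file. Defaults
#'   are filled in and every problem is reported in a single error.
#' @export
validate_config <- function(raw) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))

  if (!is.list(raw)) {
    stop("configuration must be a mapping", call. = FALSE)
  }
  known <- c("preset", "decay_unit", "params", "scenario", "grid",
             "seed", "outdir")
  for (k in setdiff(names(raw), known)) {
    note("unknown key `", k, "` (known: ", paste(known, collapse = ", "), ")")
  }

  preset <- raw$preset %||% "table1-verbatim"
  if (!preset %in% c("table1-verbatim", "halflife-consistent",
                     "updated-k0")) {
    note("unknown preset `", preset, "`")
  }
  decay_unit <- raw$decay_unit %||% "1/day"
  if (!decay_unit %in% c("1/day", "1/h")) {
    note("`decay_unit` must be \"1/day\" or \"1/h\", got `", decay_unit, "`")
  }

  # an absent params block can round-trip as NULL or an empty mapping
  if (length(raw$params) == 0L) raw$params <- NULL
  if (!is.null(raw$params)) {
    bad <- setdiff(names(raw$params), c("NGMN", "EE"))
    for (k in bad) note("unknown hormone `", k, "` under `params`")
    pfields <- c("k_o", "Cl", "t_half", "k_elim", "V_d", "decay_const",
                 "decay_unit", "conc_unit", "therapeutic_low",
                 "therapeutic_high")
    for (h in intersect(names(raw$params), c("NGMN", "EE"))) {
      for (k in setdiff(names(raw$params[[h]]), pfields)) {
        note("unknown field `", k, "` under `params$", h, "`")
      }
    }
  }

  scen <- raw$scenario %||% list(kind = "standard_cycle")
  kind <- scen$kind %||% "standard_cycle"
  if (identical(kind, "missed_replacement")) kind <- "delayed_replacement"
  scen_fields <- list(
    standard_cycle = character(0),
    delayed_replacement = "delay_days",
    detachment = c("detach_time", "area_fraction", "duration",
                   "reattach_as_new")
  )
  if (!kind %in% names(scen_fields)) {
    note("unknown scenario kind `", kind, "`")
  } else {
    for (k in setdiff(names(scen), c("kind", scen_fields[[kind]]))) {
      note("unknown key `", k, "` for scenario `", kind, "`")
    }
    if (kind == "delayed_replacement") {
      dd <- scen$delay_days %||% 3
      if (!is.numeric(dd) || dd < 0) note("`delay_days` must be >= 0")
      scen$delay_days <- as.numeric(dd)
    }
    if (kind == "detachment") {
      af <- scen$area_fraction %||% 0.5
      if (!is.numeric(af) || af < 0 || af > 1) {
        note("`area_fraction` must lie in [0, 1], got ", af)
      }
      scen$area_fraction <- as.numeric(af)
      scen$detach_time <- as.numeric(scen$detach_time %||% 72)
      scen$duration <- as.numeric(scen$duration %||% 24)
      scen$reattach_as_new <- isTRUE(scen$reattach_as_new)
    }
  }
  scen$kind <- kind

  grid <- raw$grid %||% list()
  for (k in setdiff(names(grid), c("dt", "horizon"))) {
    note("unknown key `", k, "` under `grid`")
  }
  dt <- grid$dt %||% 0.1
  if (!is.numeric(dt) || dt <= 0 || dt > 1) {
    note("`grid$dt` must satisfy 0 < dt <= 1, got ", dt)
  }
  # an absent horizon may come back as NULL (YAML `~`) or an empty
  # mapping (JSON) after a round trip; normalise both to NULL
  horizon <- grid$horizon
  if (length(horizon) == 0L) horizon <- NULL else horizon <- as.numeric(horizon)

  seed <- raw$seed %||% 1L
  if (!is.numeric(seed) || seed != round(seed)) {
    note("`seed` must be an integer")
  }

  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }

  structure(
    list(preset = preset, decay_unit = decay_unit,
         params = raw$params, scenario = scen,
         grid = list(dt = as.numeric(dt), horizon = horizon),
         seed = as.integer(seed),
         outdir = raw$outdir %||% "patchpk-run"),
    class = "run_config"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# materialise drug_params, regimen and grid from a validated config
resolve_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pars <- pk_preset(config$preset, decay_unit = config$decay_unit)
  for (h in intersect(names(config$params), c("NGMN", "EE"))) {
    ov <- config$params[[h]]
    base <- pars[[h]]
    args <- list(
      name = h,
      k_o = ov$k_o %||% base$k_o,
      Cl = ov$Cl %||% base$Cl,
      t_half = ov$t_half %||% base$t_half,
      k_elim = ov$k_elim %||% base$k_elim,
      V_d = ov$V_d %||% base$V_d,
      decay_const = ov$decay_const %||% base$decay_const,
      decay_unit = ov$decay_unit %||% base$decay_unit,
      conc_unit = ov$conc_unit %||% base$conc_unit,
      therapeutic_low = ov$therapeutic_low %||% base$therapeutic_low,
      therapeutic_high = ov$therapeutic_high %||% base$therapeutic_high
    )
    pars[[h]] <- do.call(drug_params, args)
  }

  scen <- config$scenario
  reg <- switch(scen$kind,
    standard_cycle = standard_cycle(),
    delayed_replacement = delayed_replacement(scen$delay_days),
    detachment = detachment(scen$detach_time, scen$area_fraction,
                            scen$duration, scen$reattach_as_new)
  )
  horizon <- config$grid$horizon %||% reg$horizon
  list(params = pars, regimen = reg,
       grid = sim_grid(config$grid$dt, horizon),
       seed = config$seed, outdir = config$outdir)
}
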