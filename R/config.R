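## Configuration file I/O and validation.
##
## A run is fully described by a nested list (see default_config()); on
## disk it is a YAML (or JSON) file whose keys mirror the parameter
## constructors.  Missing keys fall back to the baseline defaults, so an
## empty file is a valid configuration of the healthy model.

#' Load and validate a run configuration
#'
#' Reads a YAML/JSON file of parameter overrides, merges it over the
#' baseline defaults and validates the result.  Scalar parameters use the
#' clinical units of the file schema: mmHg s/mL for resistances, mL/mmHg
#' for compliances, mL for volumes, ms for times, degrees for angles.
#'
#' @param path file path; \code{NULL} returns the validated defaults.
#' @return \code{lv_config}.
#' @export
load_validate_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (length(raw)) cfg <- merge_config(cfg, raw)
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(cfg, raw) {
  errs <- character()
  grab <- function(block, builder, unit = identity) {
    if (is.null(raw[[block]])) return(invisible())
    vals <- raw[[block]]
    tryCatch({
      cfg[[block]] <<- do.call(builder, vals)
    }, error = function(e) {
      errs <<- c(errs, paste0(block, ": ", conditionMessage(e)))
    })
  }
  if (!is.null(raw$geometry))
    cfg$geometry <- tryCatch(do.call(lv_geometry, raw$geometry),
                             error = function(e) {
                               errs <- c(errs, conditionMessage(e))
                               cfg$geometry })
  grab("fiber_rule", fiber_rule)
  grab("sarcomere", xb_params)
  grab("calcium", calcium_params)
  grab("remodeling", reorientation_params)
  grab("perturbation", perturbation_spec)
  if (!is.null(raw$resolution)) cfg$resolution <- raw$resolution
  if (!is.null(raw$protocol))
    cfg$protocol <- modifyList(cfg$protocol, raw$protocol)
  if (!is.null(raw$circulation)) {
    cc <- raw$circulation
    tryCatch({
      cfg$circulation <- circulation_params(
        resistances = unlist(cc$resistances_mmhg_s_ml) *
          lv_units$mmHg / lv_units$mL,
        compliances = unlist(cc$compliances_ml_mmhg) *
          lv_units$mL / lv_units$mmHg,
        slack_volumes = unlist(cc$slack_volumes_ml) * lv_units$mL,
        total_volume = cc$total_volume_ml * lv_units$mL)
    }, error = function(e)
      errs <<- c(errs, paste0("circulation: ", conditionMessage(e))))
  }
  if (length(errs))
    stop("configuration errors:\n  ", paste(errs, collapse = "\n  "))
  cfg
}

#' Validate a configuration
#'
#' Checks cross-field invariants (dt divides the cycle period, the run is
#' at least one cycle, required blocks present) and reports all failures
#' at once.
#'
#' @param cfg \code{lv_config}.
#' @return invisibly TRUE; stops with the list of offending keys otherwise.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  need <- c("geometry", "fiber_rule", "materials", "circulation",
            "sarcomere", "calcium", "remodeling", "perturbation",
            "protocol")
  miss <- need[!need %in% names(cfg)]
  if (length(miss))
    errs <- c(errs, paste("missing blocks:", paste(miss, collapse = ", ")))
  p <- cfg$protocol
  if (!is.null(p)) {
    k <- p$period_ms / p$dt_ms
    if (abs(k - round(k)) > 1e-9)
      errs <- c(errs, "protocol: dt_ms must divide period_ms")
    if (p$n_cycles < 1)
      errs <- c(errs, "protocol: n_cycles must be >= 1")
    if (p$dt_ms <= 0) errs <- c(errs, "protocol: dt_ms must be > 0")
  }
  if (length(errs))
    stop("configuration errors:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

#' Save a configuration's scalar overrides to YAML
#'
#' Writes the file-schema representation (clinical units) of the blocks
#' that differ from plain defaults; loading it back reproduces the
#' configuration.
#'
#' @param cfg \code{lv_config}.
#' @param path output YAML path.
#' @return invisibly \code{path}.
#' @export
save_config <- function(cfg, path) {
  out <- list(
    resolution = cfg$resolution,
    geometry = cfg$geometry[c("length_cm", "outer_diameter_cm",
                              "wall_thickness_cm", "apical_thickness_cm")],
    fiber_rule = cfg$fiber_rule[c("endo_deg", "epi_deg", "transverse_deg")],
    sarcomere = unclass(cfg$sarcomere),
    calcium = unclass(cfg$calcium),
    remodeling = unclass(cfg$remodeling),
    perturbation = unclass(cfg$perturbation),
    protocol = cfg$protocol,
    circulation = list(
      resistances_mmhg_s_ml = as.list(cfg$circulation$resistances /
                                        lv_units$mmHg * lv_units$mL),
      compliances_ml_mmhg = as.list(cfg$circulation$compliances *
                                      lv_units$mmHg / lv_units$mL),
      slack_volumes_ml = as.list(cfg$circulation$slack_volumes /
                                   lv_units$mL),
      total_volume_ml = cfg$circulation$total_volume / lv_units$mL))
  yaml::write_yaml(out, path)
  invisible(path)
}
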