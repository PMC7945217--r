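#' 60-pair mixed-width MLC template (Varian Millennium MLC-120 geometry)
#'
#' Two banks of 60 leaves: the outer 10 pairs on each side project to 10 mm at
#' isocenter and the inner 40 pairs to 5 mm, giving a 40 cm field in the leaf
#' direction. Overtravel across the central axis is 15.0 cm.
#'
#' @return An [MLCModel-class] with 60 pairs, width pattern
#'   10x1.0 / 40x0.5 / 10x1.0 cm, boundaries symmetric about 0.
#' @examples
#' m <- millennium120()
#' sum(leafWidths(m)) # 40 cm field
#' @export
millennium120 <- function() {
  mlcModel("millennium120",
    leafWidths = c(rep(1.0, 10), rep(0.5, 40), rep(1.0, 10)),
    overtravel = 15.0
  )
}

#' 40-pair uniform MLC template (Elekta MLCi geometry)
#'
#' 40 leaf pairs, each projecting to 10 mm at isocenter; leaves may overtravel
#' the central axis by 12.5 cm.
#'
#' @return An [MLCModel-class] with 40 pairs of 1.0 cm width.
#' @examples
#' overtravel(elektaMLCi())
#' @export
elektaMLCi <- function() {
  mlcModel("elektaMLCi", leafWidths = rep(1.0, 40), overtravel = 12.5)
}

#' Default delivery constraints for the two modeled system types
#'
#' The continuous type models a system with continuously variable dose rate;
#' the binned type models one whose dose rate is restricted to a geometric
#' ladder of bins (each half the previous). All numeric limits are documented
#' assumptions (see the shipped \code{machines.yaml} config); they are
#' configuration, not vendor claims.
#'
#' @param systemLabel \code{"continuous-type"} or \code{"binned-type"}.
#' @return A [MachineConstraints-class].
#' @examples
#' defaultConstraints("binned-type")
#' @export
defaultConstraints <- function(systemLabel) {
  switch(systemLabel,
    "continuous-type" = machineConstraints(
      maxGantrySpeed = 4.8, maxDoseRate = 600,
      doseRateMode = "continuous", maxLeafSpeed = 2.5
    ),
    "binned-type" = machineConstraints(
      maxGantrySpeed = 6.0, maxDoseRate = 600,
      doseRateMode = "binned",
      doseRateBins = 600 / 2^(0:4), maxLeafSpeed = 2.0
    ),
    stop("unknown system label '", systemLabel,
      "'; expected 'continuous-type' or 'binned-type'")
  )
}

#' Built-in machine registry
#'
#' @return Named list of the built-in [MLCModel-class] templates, used by
#'   [readRTPlan()] to match a plan's leaf-boundary table to a geometry.
#' @export
machineRegistry <- function() {
  list(millennium120 = millennium120(), elektaMLCi = elektaMLCi())
}

#' Read machine templates from a YAML config
#'
#' Users can add machines without code changes: each entry carries a name,
#' leaf widths (cm), overtravel (cm) and optionally constraints.
#'
#' @param path YAML file as written by [writeMachineConfig()].
#' @return Named list with elements \code{machines} (list of
#'   [MLCModel-class]) and \code{constraints} (list of
#'   [MachineConstraints-class], possibly empty).
#' @export
readMachineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  machines <- lapply(cfg$machines, function(m) {
    mlcModel(m$name, as.numeric(m$leaf_widths_cm),
      overtravel = m$overtravel_cm,
      minGap = if (is.null(m$min_gap_cm)) 0 else m$min_gap_cm)
  })
  names(machines) <- vapply(machines, function(m) m@name, character(1))
  constraints <- lapply(cfg$constraints, function(k) {
    machineConstraints(
      maxGantrySpeed = k$max_gantry_speed_deg_s,
      maxDoseRate = k$max_dose_rate_mu_min,
      doseRateMode = k$dose_rate_mode,
      doseRateBins = k$dose_rate_bins_mu_min,
      maxLeafSpeed = k$max_leaf_speed_cm_s
    )
  })
  list(machines = machines, constraints = constraints)
}

#' Write machine templates to a YAML config
#'
#' @param machines list of [MLCModel-class].
#' @param path output file.
#' @param constraints optional named list of [MachineConstraints-class].
#' @return \code{path}, invisibly.
#' @export
writeMachineConfig <- function(machines, path, constraints = list()) {
  if (is(machines, "MLCModel")) machines <- list(machines)
  cfg <- list(
    machines = lapply(machines, function(m) {
      list(name = m@name, leaf_widths_cm = m@leafWidths,
        overtravel_cm = m@overtravel, min_gap_cm = m@minGap)
    }),
    constraints = lapply(constraints, function(k) {
      list(max_gantry_speed_deg_s = k@maxGantrySpeed,
        max_dose_rate_mu_min = k@maxDoseRate,
        dose_rate_mode = k@doseRateMode,
        dose_rate_bins_mu_min = k@doseRateBins,
        max_leaf_speed_cm_s = k@maxLeafSpeed)
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
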