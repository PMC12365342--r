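#' Nearest-neighbor thermodynamic parameter set
#'
#' Holds the dinucleotide-stack enthalpy/entropy table, duplex initiation
#' terms, and reaction conditions (monovalent salt, total oligo
#' concentration) used for melting-temperature and dimer-energy
#' calculations. Construct with [thermoParameters()].
#'
#' @slot stacks data.frame with columns `stack` (the 10 unique
#'   dinucleotide stacks, top strand 5'->3'), `dH` (kcal/mol) and `dS`
#'   (cal/(mol K)).
#' @slot initGC,initAT numeric length-2 `(dH, dS)` duplex initiation terms
#'   for a terminal G-C / A-T pair.
#' @slot saltM monovalent cation concentration, mol/L.
#' @slot oligoM total oligonucleotide strand concentration, mol/L.
#' @slot dimerMinStretch minimum contiguous complementary run (bp) scored
#'   as a dimer.
#' @slot dgTempK temperature (Kelvin) at which stack free energies are
#'   evaluated for dimer screening.
#' @seealso [meltingTemperature()], [crossDimerEnergy()]
#' @exportClass ThermoParameters
setClass("ThermoParameters",
  representation(
    stacks = "data.frame",
    initGC = "numeric",
    initAT = "numeric",
    saltM = "numeric",
    oligoM = "numeric",
    dimerMinStretch = "integer",
    dgTempK = "numeric"
  )
)

setValidity("ThermoParameters", function(object) {
  msg <- character()
  need <- c("AA", "AT", "TA", "CA", "GT", "CT", "GA", "CG", "GC", "GG")
  if (!all(c("stack", "dH", "dS") %in% names(object@stacks))) {
    msg <- c(msg, "stacks must have columns stack, dH, dS")
  } else if (!all(need %in% object@stacks$stack)) {
    msg <- c(msg, paste(
      "stacks must contain all 10 unique dinucleotide stacks; missing:",
      paste(setdiff(need, object@stacks$stack), collapse = ", ")
    ))
  }
  if (length(object@initGC) != 2L || length(object@initAT) != 2L) {
    msg <- c(msg, "initiation terms must be length-2 (dH, dS)")
  }
  if (!.isScalarNumber(object@saltM) || object@saltM <= 0) {
    msg <- c(msg, "saltM must be a positive number")
  }
  if (!.isScalarNumber(object@oligoM) || object@oligoM <= 0) {
    msg <- c(msg, "oligoM must be a positive number")
  }
  if (length(object@dimerMinStretch) != 1L || object@dimerMinStretch < 1L) {
    msg <- c(msg, "dimerMinStretch must be a positive integer")
  }
  if (!.isScalarNumber(object@dgTempK) || object@dgTempK <= 0) {
    msg <- c(msg, "dgTempK must be positive")
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Sliding-window nucleotide diversity profile
#'
#' Per-window nucleotide diversity (pi) over a multiple alignment, the
#' median window pi, the hotspot threshold (`hotspotFactor` times the
#' median), and the merged hotspot intervals. Construct with
#' [slidingPi()].
#'
#' @slot windows data.frame with columns `midpoint`, `start`, `end`,
#'   `pi`, `n_valid_sites` (1-based inclusive alignment columns).
#' @slot medianPi median of the per-window pi values.
#' @slot hotspotFactor multiplier applied to the median to form the
#'   hotspot threshold.
#' @slot threshold hotspot threshold (= hotspotFactor * medianPi).
#' @slot hotspots IRanges of merged alignment-column intervals whose
#'   windows exceed the threshold (strictly).
#' @slot alignmentLength number of alignment columns profiled.
#' @seealso [slidingPi()], [selectAmplicon()], [hotspots()]
#' @exportClass DiversityProfile
setClass("DiversityProfile",
  representation(
    windows = "data.frame",
    medianPi = "numeric",
    hotspotFactor = "numeric",
    threshold = "numeric",
    hotspots = "IRanges",
    alignmentLength = "integer"
  )
)

setValidity("DiversityProfile", function(object) {
  msg <- character()
  cols <- c("midpoint", "start", "end", "pi", "n_valid_sites")
  if (!all(cols %in% names(object@windows))) {
    msg <- c(msg, paste("windows must have columns:", paste(cols, collapse = ", ")))
  } else {
    if (any(object@windows$pi < 0 | object@windows$pi > 1)) {
      msg <- c(msg, "window pi values must lie in [0, 1]")
    }
  }
  if (!isTRUE(all.equal(object@threshold, object@hotspotFactor * object@medianPi))) {
    msg <- c(msg, "threshold must equal hotspotFactor * medianPi")
  }
  if (length(object@hotspots) > 1L) {
    s <- IRanges::start(object@hotspots)
    e <- IRanges::end(object@hotspots)
    if (is.unsorted(s) || any(s[-1L] <= e[-length(e)])) {
      msg <- c(msg, "hotspot intervals must be sorted and non-overlapping")
    }
  }
  if (length(msg) == 0L) TRUE else msg
})

#' Multiplex PCR panel
#'
#' The result of multiplex design over a primer panel: the panel table
#' with per-oligo thermodynamics, prefilter exclusions with reasons, the
#' pairwise conflict graph, and the multiplex set assignment. Construct
#' with [designMultiplex()].
#'
#' @slot panel data.frame of retained panel entries (id, kind, fwd_seq,
#'   rev_seq, per-oligo tm and self-dimer energies, set_id).
#' @slot excluded data.frame of prefiltered entries with a `reason` column.
#' @slot conflicts data.frame of conflict edges (a, b, reason, value).
#' @slot sets data.frame of per-set summaries (set_id, size, tm_span).
#' @slot parameters named list of the thresholds used (cross-dimer cut,
#'   self-dimer cut, Tm floor, Tm window, maximum set size).
#' @seealso [designMultiplex()], [partitionMultiplex()], [multiplexSets()]
#' @exportClass MultiplexPanel
setClass("MultiplexPanel",
  representation(
    panel = "data.frame",
    excluded = "data.frame",
    conflicts = "data.frame",
    sets = "data.frame",
    parameters = "list"
  )
)

setValidity("MultiplexPanel", function(object) {
  msg <- character()
  if (!all(c("id", "set_id") %in% names(object@panel))) {
    msg <- c(msg, "panel must have columns id and set_id")
  } else if (anyDuplicated(object@panel$id)) {
    msg <- c(msg, "panel ids must be unique")
  }
  if (nrow(object@conflicts) > 0L &&
      !all(c("a", "b", "reason") %in% names(object@conflicts))) {
    msg <- c(msg, "conflicts must have columns a, b, reason")
  }
  if (length(msg) == 0L) TRUE else msg
})
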