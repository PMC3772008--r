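#' @import methods
NULL

HORIZONS <- c("A", "B", "C")
ACTIVITY_CATEGORIES <- c("high", "medium", "low", "none")

#' CalibrationCurve: a linear LBB calibration against KMnO4 standards
#'
#' Holds the least-squares line relating absorbance at 620 nm to KMnO4
#' concentration (uM), fitted from standards with [fitCalibration()].
#'
#' @slot slope absorbance units per uM KMnO4; must be positive.
#' @slot intercept absorbance at zero concentration.
#' @slot rSquared coefficient of determination in [0, 1].
#' @slot throughOrigin logical; TRUE if the intercept was constrained to 0.
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  representation(slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", throughOrigin = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@slope) != 1L || !is.finite(object@slope) ||
        object@slope <= 0)
      msg <- c(msg, "slope must be a single positive finite number")
    if (length(object@rSquared) != 1L || is.na(object@rSquared) ||
        object@rSquared < 0 || object@rSquared > 1 + 1e-12)
      msg <- c(msg, "rSquared must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' ActivityTable: horizon-by-category contingency table of isolate activities
#'
#' Cross-tabulation of Mn(II)-oxidizing activity categories (high, medium,
#' low, none) across soil horizons (A, B, C), as produced by
#' [tabulateActivity()]. Percentage summaries are computed on demand by
#' [columnPercentages()] and [withinCategoryPercentages()].
#'
#' @slot counts integer matrix, rows = horizons present, columns = the four
#'   activity categories.
#' @exportClass ActivityTable
setClass("ActivityTable",
  representation(counts = "matrix"),
  validity = function(object) {
    cts <- object@counts
    msg <- character()
    if (!is.numeric(cts) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "counts must be non-negative integers")
    if (!identical(colnames(cts), ACTIVITY_CATEGORIES))
      msg <- c(msg, "columns must be the four activity categories")
    if (length(msg)) msg else TRUE
  })

#' RestrictionEnzyme: a recognition site and cut position
#'
#' @slot name enzyme name, e.g. "HaeIII".
#' @slot site recognition sequence over A/C/G/T (uppercase).
#' @slot cutOffset 0-based position within the site where the cut falls
#'   (0 = immediately before the site's first base).
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character",
                 cutOffset = "integer"),
  validity = function(object) {
    msg <- character()
    if (!grepl("^[ACGT]+$", object@site))
      msg <- c(msg, "site must contain only A, C, G, T")
    if (object@cutOffset < 0L || object@cutOffset > nchar(object@site))
      msg <- c(msg, "cutOffset must lie within [0, nchar(site)]")
    if (length(msg)) msg else TRUE
  })

#' FragmentPattern: restriction-fragment lengths of one digested amplicon
#'
#' @slot enzymeName name of the enzyme used.
#' @slot fragmentLengths positive fragment lengths (bp), sorted descending.
#' @slot sequenceLength length of the digested sequence; fragment lengths
#'   always sum to it.
#' @exportClass FragmentPattern
setClass("FragmentPattern",
  representation(enzymeName = "character", fragmentLengths = "integer",
                 sequenceLength = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@fragmentLengths <= 0L))
      msg <- c(msg, "fragment lengths must be positive")
    if (sum(object@fragmentLengths) != object@sequenceLength)
      msg <- c(msg, "fragment lengths must sum to the sequence length")
    if (is.unsorted(rev(object@fragmentLengths)))
      msg <- c(msg, "fragment lengths must be sorted descending")
    if (length(msg)) msg else TRUE
  })

#' ArdraGrouping: two-stage HaeIII/Sau3AI pattern grouping of isolates
#'
#' @slot assignments named character vector, isolate id -> group id.
#' @slot representatives named character vector, group id -> the isolate
#'   chosen to represent (be sequenced for) that group.
#' @exportClass ArdraGrouping
setClass("ArdraGrouping",
  representation(assignments = "character", representatives = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@assignments)) ||
        anyDuplicated(names(object@assignments)))
      msg <- c(msg, "assignments must be uniquely named by isolate id")
    reps <- object@representatives
    if (!all(reps %in% names(object@assignments)) ||
        !all(object@assignments[reps] == names(reps)))
      msg <- c(msg, "each representative must belong to its group")
    if (length(msg)) msg else TRUE
  })

#' LaneProfile: a 1-D densitometric trace along a gel lane
#'
#' @slot laneId lane identifier.
#' @slot positions strictly increasing migration coordinates, normalized
#'   to [0, 1].
#' @slot intensities non-negative signal values, one per position.
#' @exportClass LaneProfile
setClass("LaneProfile",
  representation(laneId = "character", positions = "numeric",
                 intensities = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@positions) < 2L)
      msg <- c(msg, "a profile needs at least 2 samples")
    if (length(object@positions) != length(object@intensities))
      msg <- c(msg, "positions and intensities must have equal length")
    if (any(diff(object@positions) <= 0))
      msg <- c(msg, "positions must be strictly increasing")
    if (any(object@intensities < 0))
      msg <- c(msg, "intensities must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' BandSet: bands called from one lane, with significant probabilities
#'
#' Bands retained after the 1% relative-peak-height rule; each band carries
#' its migration position, peak height n_i, and significant probability
#' P_i = n_i / N where N is the summed peak height of retained bands.
#'
#' @slot laneId lane identifier.
#' @slot bands data.frame with columns `position`, `height`, `prob`,
#'   sorted by position.
#' @slot totalHeight N, the sum of retained peak heights.
#' @exportClass BandSet
setClass("BandSet",
  representation(laneId = "character", bands = "data.frame",
                 totalHeight = "numeric"),
  validity = function(object) {
    b <- object@bands
    msg <- character()
    if (!all(c("position", "height", "prob") %in% names(b)))
      msg <- c(msg, "bands must have columns position, height, prob")
    if (nrow(b)) {
      if (any(b$height <= 0)) msg <- c(msg, "peak heights must be positive")
      if (abs(sum(b$prob) - 1) > 1e-9)
        msg <- c(msg, "band probabilities must sum to 1")
      if (is.unsorted(b$position))
        msg <- c(msg, "bands must be sorted by position")
    }
    if (length(msg)) msg else TRUE
  })

#' LaneDistanceMatrix: symmetric pairwise band-pattern distances
#'
#' @slot laneIds ordered lane identifiers.
#' @slot values symmetric non-negative matrix with zero diagonal.
#' @exportClass LaneDistanceMatrix
setClass("LaneDistanceMatrix",
  representation(laneIds = "character", values = "matrix"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != length(object@laneIds) || ncol(v) != nrow(v))
      msg <- c(msg, "values must be square with one row per lane")
    else {
      if (any(abs(v - t(v)) > 1e-12)) msg <- c(msg, "matrix must be symmetric")
      if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
      if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
    }
    if (anyDuplicated(object@laneIds))
      msg <- c(msg, "lane ids must be unique")
    if (length(msg)) msg else TRUE
  })

#' OrdinationResult: low-dimensional embedding of a lane-distance matrix
#'
#' @slot laneIds ordered lane identifiers.
#' @slot points n-by-k matrix of coordinates, column-centered.
#' @slot stress Kruskal stress-1 (non-metric MDS) or NA (classical).
#' @slot eigenvalues eigenvalues sorted descending (classical) or numeric(0).
#' @slot method "classical" or "nonmetric".
#' @slot converged logical convergence flag (non-metric only; TRUE otherwise).
#' @exportClass OrdinationResult
setClass("OrdinationResult",
  representation(laneIds = "character", points = "matrix", stress = "numeric",
                 eigenvalues = "numeric", method = "character",
                 converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@points) != length(object@laneIds))
      msg <- c(msg, "one coordinate row per lane required")
    if (nrow(object@points) > 0 &&
        any(abs(colMeans(object@points)) > 1e-9))
      msg <- c(msg, "coordinates must be column-centered")
    if (!is.na(object@stress) && object@stress < 0)
      msg <- c(msg, "stress must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' DnaAlignment: equal-length aligned sequences over A, C, G, T, -, N
#'
#' @slot mat character matrix of single characters; rownames are the unique
#'   sequence ids, columns are alignment sites.
#' @exportClass DnaAlignment
setClass("DnaAlignment",
  representation(mat = "matrix"),
  validity = function(object) {
    m <- object@mat
    msg <- character()
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      msg <- c(msg, "rows must be uniquely named by sequence id")
    bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N"))
    if (length(bad))
      msg <- c(msg, paste0("invalid alignment characters: ",
                           paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' PhylotypeAssignment: sequence-to-phylotype clustering at a divergence cut
#'
#' @slot assignments named integer vector, sequence id -> phylotype index.
#' @slot threshold divergence threshold (fraction); within a phylotype every
#'   pairwise distance is strictly below it.
#' @exportClass PhylotypeAssignment
setClass("PhylotypeAssignment",
  representation(assignments = "integer", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@assignments)) ||
        anyDuplicated(names(object@assignments)))
      msg <- c(msg, "assignments must be uniquely named")
    if (object@threshold <= 0 || object@threshold >= 1)
      msg <- c(msg, "threshold must lie in (0, 1)")
    if (length(msg)) msg else TRUE
  })
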