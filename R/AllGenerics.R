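#' Accessors for SoilMnOx classes
#'
#' Small accessor generics so that user code never touches slots directly.
#'
#' @param object a SoilMnOx S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("laneId", function(object) standardGeneric("laneId"))

#' @rdname accessors
#' @export
setGeneric("laneIds", function(object) standardGeneric("laneIds"))

#' @rdname accessors
#' @export
setGeneric("bands", function(object) standardGeneric("bands"))

#' @rdname accessors
#' @export
setGeneric("nBands", function(object) standardGeneric("nBands"))

#' @rdname accessors
#' @export
setGeneric("fragmentLengths", function(object)
  standardGeneric("fragmentLengths"))

#' @rdname accessors
#' @export
setGeneric("groupAssignments", function(object)
  standardGeneric("groupAssignments"))

#' @rdname accessors
#' @export
setGeneric("groupRepresentatives", function(object)
  standardGeneric("groupRepresentatives"))

#' @rdname accessors
#' @export
setGeneric("activityCounts", function(object)
  standardGeneric("activityCounts"))

#' @rdname accessors
#' @export
setGeneric("distValues", function(object) standardGeneric("distValues"))

#' @rdname accessors
#' @export
setGeneric("ordPoints", function(object) standardGeneric("ordPoints"))

#' @rdname accessors
#' @export
setGeneric("ordStress", function(object) standardGeneric("ordStress"))

#' @rdname accessors
#' @export
setGeneric("alignmentIds", function(object) standardGeneric("alignmentIds"))

#' @rdname accessors
#' @export
setGeneric("alignmentMatrix", function(object)
  standardGeneric("alignmentMatrix"))

#' @rdname accessors
#' @export
setGeneric("phylotypes", function(object) standardGeneric("phylotypes"))

setMethod("laneId", "LaneProfile", function(object) object@laneId)
setMethod("laneId", "BandSet", function(object) object@laneId)
setMethod("laneIds", "LaneDistanceMatrix", function(object) object@laneIds)
setMethod("laneIds", "OrdinationResult", function(object) object@laneIds)
setMethod("bands", "BandSet", function(object) object@bands)
setMethod("nBands", "BandSet", function(object) nrow(object@bands))
setMethod("fragmentLengths", "FragmentPattern",
          function(object) object@fragmentLengths)
setMethod("groupAssignments", "ArdraGrouping",
          function(object) object@assignments)
setMethod("groupRepresentatives", "ArdraGrouping",
          function(object) object@representatives)
setMethod("activityCounts", "ActivityTable", function(object) object@counts)
setMethod("distValues", "LaneDistanceMatrix", function(object) {
  v <- object@values
  dimnames(v) <- list(object@laneIds, object@laneIds)
  v
})
setMethod("ordPoints", "OrdinationResult", function(object) {
  p <- object@points
  rownames(p) <- object@laneIds
  p
})
setMethod("ordStress", "OrdinationResult", function(object) object@stress)
setMethod("alignmentIds", "DnaAlignment",
          function(object) rownames(object@mat))
setMethod("alignmentMatrix", "DnaAlignment", function(object) object@mat)
setMethod("phylotypes", "PhylotypeAssignment",
          function(object) object@assignments)

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve (absorbance 620 nm vs uM KMnO4)\n")
  cat(sprintf("  slope %.6g, intercept %.6g, R^2 %.4f%s\n", object@slope,
              object@intercept, object@rSquared,
              if (object@throughOrigin) " (through origin)" else ""))
})

setMethod("show", "ActivityTable", function(object) {
  cat("ActivityTable: horizon x activity-category counts\n")
  cts <- object@counts
  tot <- rbind(cts, Compiled = colSums(cts))
  tot <- cbind(tot, Total = rowSums(tot))
  print(tot)
})

setMethod("show", "RestrictionEnzyme", function(object) {
  site <- object@site
  cat(sprintf("RestrictionEnzyme %s: %s^%s\n", object@name,
              substr(site, 1, object@cutOffset),
              substr(site, object@cutOffset + 1, nchar(site))))
})

setMethod("show", "FragmentPattern", function(object) {
  cat(sprintf("FragmentPattern (%s): %d fragment(s) from %d bp\n  [%s]\n",
              object@enzymeName, length(object@fragmentLengths),
              object@sequenceLength,
              paste(object@fragmentLengths, collapse = ", ")))
})

setMethod("show", "ArdraGrouping", function(object) {
  cat(sprintf("ArdraGrouping: %d isolate(s) in %d group(s)\n",
              length(object@assignments), length(object@representatives)))
  cat("  representatives:",
      paste(object@representatives, collapse = ", "), "\n")
})

setMethod("show", "LaneProfile", function(object) {
  cat(sprintf("LaneProfile '%s': %d samples on [%.3f, %.3f]\n",
              object@laneId, length(object@positions),
              min(object@positions), max(object@positions)))
})

setMethod("show", "BandSet", function(object) {
  cat(sprintf("BandSet '%s': %d band(s), total peak height %.4g\n",
              object@laneId, nrow(object@bands), object@totalHeight))
  if (nrow(object@bands)) print(round(object@bands, 4))
})

setMethod("show", "LaneDistanceMatrix", function(object) {
  cat(sprintf("LaneDistanceMatrix over %d lane(s)\n",
              length(object@laneIds)))
  print(round(distValues(object), 4))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult (%s MDS): %d lane(s) in %d dimension(s)\n",
              object@method, nrow(object@points), ncol(object@points)))
  if (!is.na(object@stress))
    cat(sprintf("  Kruskal stress-1 = %.4g (converged: %s)\n",
                object@stress, object@converged))
})

setMethod("show", "DnaAlignment", function(object) {
  cat(sprintf("DnaAlignment: %d sequence(s) x %d site(s)\n",
              nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "PhylotypeAssignment", function(object) {
  cat(sprintf("PhylotypeAssignment: %d sequence(s) in %d phylotype(s) at <%g%% divergence\n",
              length(object@assignments), length(unique(object@assignments)),
              100 * object@threshold))
})
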