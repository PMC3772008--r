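#' Construct a densitometric lane profile
#'
#' @param laneId lane identifier.
#' @param positions strictly increasing migration coordinates in [0, 1].
#' @param intensities non-negative intensities, one per position.
#' @return a [LaneProfile-class].
#' @export
laneProfile <- function(laneId, positions, intensities) {
  new("LaneProfile", laneId = as.character(laneId),
      positions = as.numeric(positions),
      intensities = as.numeric(intensities))
}

# moving average with equal weights; edges use the partial window
.movingAverage <- function(y, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(y)
  n <- length(y)
  h <- window %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.rollingMin <- function(y, window) {
  window <- max(1L, as.integer(window))
  if (window == 1L) return(y)
  n <- length(y)
  h <- window %/% 2L
  vapply(seq_len(n),
         function(i) min(y[max(1L, i - h):min(n, i + h)]), numeric(1))
}

# indices of strict local maxima; plateaus contribute their middle sample.
# values are compared on a coarse relative grid so that float jitter from
# the smoothing arithmetic cannot fabricate peaks on flat stretches
.localMaxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  scale <- max(abs(y), 1e-300)
  r <- rle(round(y / scale, 9))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (j in seq_len(k)) {
    if (j == 1L || j == k) next      # edge runs are not interior maxima
    if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L])
      out <- c(out, (starts[j] + ends[j]) %/% 2L)
  }
  out
}

# topographic prominence of peak i: height minus the higher of the two key
# saddles (minimum between the peak and the nearest higher ground each side;
# the profile edge acts as ground level on an open side)
.prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    higherL <- which(y[seq_len(p - 1L)] > y[p])
    baseL <- if (length(higherL)) min(y[(max(higherL)):p]) else
      min(y[1L:p])
    idxR <- if (p < length(y)) (p + 1L):length(y) else integer(0)
    higherR <- idxR[y[idxR] > y[p]]
    baseR <- if (length(higherR)) min(y[p:min(higherR)]) else
      min(y[p:length(y)])
    y[p] - max(baseL, baseR)
  }, numeric(1))
}

#' Call bands from a densitometric lane profile
#'
#' The trace is smoothed by a moving average, the baseline (a rolling
#' minimum) is subtracted, and interior local maxima with topographic
#' prominence of at least `minProminenceFraction` of the maximum intensity
#' become candidate bands. Candidates whose relative peak height (peak
#' height over summed candidate peak height) is not greater than 1% are
#' discarded, and the significant probabilities P_i = n_i / N are
#' renormalized over the retained bands.
#'
#' @param profile a [LaneProfile-class].
#' @param smoothingWindow moving-average window, samples (default 5).
#' @param minProminenceFraction prominence threshold as a fraction of the
#'   maximum smoothed intensity (default 0.02).
#' @param baselineWindow rolling-minimum window, samples (default 51).
#' @param minRelativeHeight the band-detection rule: candidates with
#'   relative peak height <= this fraction are dropped (default 0.01).
#' @return a [BandSet-class]; a flat or monotone profile yields an empty
#'   band set with a warning.
#' @export
detectBands <- function(profile, smoothingWindow = 5L,
                        minProminenceFraction = 0.02,
                        baselineWindow = 51L, minRelativeHeight = 0.01) {
  stopifnot(is(profile, "LaneProfile"))
  y <- .movingAverage(profile@intensities, smoothingWindow)
  y <- pmax(y - .rollingMin(y, baselineWindow), 0)
  peaks <- .localMaxima(y)
  if (length(peaks)) {
    prom <- .prominence(y, peaks)
    peaks <- peaks[prom >= minProminenceFraction * max(y)]
  }
  if (!length(peaks)) {
    warning("no bands detected in lane '", profile@laneId, "'")
    return(new("BandSet", laneId = profile@laneId,
               bands = data.frame(position = numeric(0), height = numeric(0),
                                  prob = numeric(0)),
               totalHeight = 0))
  }
  heights <- y[peaks]
  keep <- heights / sum(heights) > minRelativeHeight
  heights <- heights[keep]
  peaks <- peaks[keep]
  bandSet(profile@laneId, profile@positions[peaks], heights)
}

#' Build a BandSet directly from band positions and peak heights
#'
#' @param laneId lane identifier.
#' @param positions band positions in [0, 1].
#' @param heights positive peak heights (the n_i).
#' @return a [BandSet-class] with P_i = n_i / N.
#' @export
bandSet <- function(laneId, positions, heights) {
  stopifnot(length(positions) == length(heights), all(heights > 0))
  ord <- order(positions)
  positions <- positions[ord]
  heights <- heights[ord]
  new("BandSet", laneId = as.character(laneId),
      bands = data.frame(position = positions, height = heights,
                         prob = heights / sum(heights)),
      totalHeight = sum(heights))
}

#' Shannon diversity index of a lane's band pattern
#'
#' H = -sum_i P_i log(P_i) over the lane's bands, where P_i is band i's
#' significant probability (peak height over total peak height). Natural
#' logarithm by default.
#'
#' @param bands a [BandSet-class] with at least one band.
#' @param base logarithm base (default `exp(1)`, nats).
#' @return H, non-negative.
#' @examples
#' shannonIndex(bandSet("L1", c(.2, .4, .6, .8), c(1, 1, 1, 1)))  # log(4)
#' @export
shannonIndex <- function(bands, base = exp(1)) {
  stopifnot(is(bands, "BandSet"))
  p <- bands@bands$prob
  if (!length(p)) stop("Shannon index is undefined for an empty band set")
  -sum(p * log(p, base = base))
}

#' Match bands between two lanes by migration position
#'
#' Greedy nearest-pair matching: repeatedly pair the two unmatched bands
#' (one per lane) at smallest position difference within `positionTolerance`;
#' each band is used at most once. The number of pairs c is the count of
#' bands common to the two lanes, and P = n_A + n_B - c is the number of
#' distinct band positions across both.
#'
#' @param a,b [BandSet-class] objects from comparably normalized lanes.
#' @param positionTolerance maximum position difference for two bands to be
#'   the same band (normalized units, default 0.01).
#' @return list with `pairs` (2-column index matrix), `nA`, `nB`, `c`, `P`.
#' @export
matchBands <- function(a, b, positionTolerance = 0.01) {
  stopifnot(is(a, "BandSet"), is(b, "BandSet"))
  if (positionTolerance < 0) stop("positionTolerance must be >= 0")
  pa <- a@bands$position
  pb <- b@bands$position
  nA <- length(pa)
  nB <- length(pb)
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  if (nA && nB) {
    d <- abs(outer(pa, pb, "-"))
    repeat {
      m <- which.min(d)
      if (!length(m) || d[m] > positionTolerance || !is.finite(d[m])) break
      i <- (m - 1L) %% nA + 1L
      j <- (m - 1L) %/% nA + 1L
      pairs <- rbind(pairs, c(i, j))
      d[i, ] <- Inf
      d[, j] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  cc <- nrow(pairs)
  list(pairs = pairs, nA = nA, nB = nB, c = cc, P = nA + nB - cc)
}

#' Band-pattern distance between two lanes
#'
#' D = sum over the P union band positions of |A_i - B_i| / P, where A_i and
#' B_i are the significant probabilities of the band at that position in
#' lanes A and B, a lane lacking the band contributing 0, and
#' P = n_A + n_B - c. D is 0 iff the lanes share identical positions and
#' probabilities, and lies in [0, 1] because each lane's probabilities sum
#' to 1. The alternative presence/absence strategy `"dice"` gives
#' 1 - 2c/(n_A + n_B).
#'
#' @inheritParams matchBands
#' @param strategy `"probability"` (default) or `"dice"`.
#' @return distance in [0, 1]; two empty lanes give 0 with a warning.
#' @export
laneDistance <- function(a, b, positionTolerance = 0.01,
                         strategy = c("probability", "dice")) {
  strategy <- match.arg(strategy)
  m <- matchBands(a, b, positionTolerance)
  if (m$P == 0L) {
    warning("both lanes are empty; distance set to 0")
    return(0)
  }
  if (strategy == "dice") return(1 - 2 * m$c / (m$nA + m$nB))
  pa <- a@bands$prob
  pb <- b@bands$prob
  matchedA <- m$pairs[, 1L]
  matchedB <- m$pairs[, 2L]
  s <- sum(abs(pa[matchedA] - pb[matchedB]))
  s <- s + sum(pa[setdiff(seq_len(m$nA), matchedA)])
  s <- s + sum(pb[setdiff(seq_len(m$nB), matchedB)])
  s / m$P
}

#' Pairwise lane-distance matrix
#'
#' @param lanes list of [BandSet-class] objects with unique lane ids.
#' @inheritParams laneDistance
#' @return a [LaneDistanceMatrix-class].
#' @export
laneDistanceMatrix <- function(lanes, positionTolerance = 0.01,
                               strategy = c("probability", "dice")) {
  strategy <- match.arg(strategy)
  stopifnot(length(lanes) >= 2L,
            all(vapply(lanes, is, logical(1), "BandSet")))
  ids <- vapply(lanes, laneId, character(1))
  if (anyDuplicated(ids)) stop("duplicate lane ids")
  n <- length(lanes)
  v <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      v[i, j] <- v[j, i] <-
        laneDistance(lanes[[i]], lanes[[j]], positionTolerance, strategy)
  new("LaneDistanceMatrix", laneIds = ids, values = v)
}

#' Read lane profiles from CSV / write band tables and distance matrices
#'
#' `readLaneProfilesCSV` accepts a long CSV (`lane_id,position,intensity`)
#' or a wide CSV (`position` plus one intensity column per lane).
#'
#' @param path file path.
#' @param lanes list of [BandSet-class] objects.
#' @param d a [LaneDistanceMatrix-class].
#' @return `readLaneProfilesCSV`: named list of [LaneProfile-class];
#'   writers return the path invisibly.
#' @export
readLaneProfilesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("lane_id", "position", "intensity") %in% names(df))) {
    out <- lapply(split(df, df$lane_id), function(g)
      laneProfile(g$lane_id[1], g$position, g$intensity))
  } else if ("position" %in% names(df)) {
    laneCols <- setdiff(names(df), "position")
    out <- lapply(laneCols, function(id)
      laneProfile(id, df$position, df[[id]]))
    names(out) <- laneCols
  } else {
    stop("CSV must be long (lane_id,position,intensity) or wide (position + lane columns)")
  }
  out[order(names(out))]
}

#' @rdname readLaneProfilesCSV
#' @export
writeBandTable <- function(lanes, path) {
  rows <- lapply(lanes, function(bs)
    cbind(lane_id = laneId(bs), bands(bs)))
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname readLaneProfilesCSV
#' @export
writeDistanceMatrix <- function(d, path) {
  stopifnot(is(d, "LaneDistanceMatrix"))
  v <- distValues(d)
  utils::write.csv(data.frame(lane_id = rownames(v), v,
                              check.names = FALSE, row.names = NULL),
                   path, row.names = FALSE)
  invisible(path)
}
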