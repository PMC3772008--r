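#' Built-in restriction enzymes and the enzyme constructor
#'
#' ARDRA of 16S amplicons here uses the two tetracutter-class enzymes
#' HaeIII (GG^CC, blunt) and Sau3AI (^GATC). `restrictionEnzyme()` builds
#' further enzymes from a recognition site and a 0-based cut offset.
#'
#' @param name enzyme name.
#' @param site recognition sequence, A/C/G/T only.
#' @param cutOffset 0-based cut position within the site.
#' @return a [RestrictionEnzyme-class].
#' @examples
#' HaeIII()
#' restrictionEnzyme("EcoRI", "GAATTC", 1L)
#' @export
restrictionEnzyme <- function(name, site, cutOffset) {
  new("RestrictionEnzyme", name = name, site = toupper(site),
      cutOffset = as.integer(cutOffset))
}

#' @rdname restrictionEnzyme
#' @export
HaeIII <- function() restrictionEnzyme("HaeIII", "GGCC", 2L)

#' @rdname restrictionEnzyme
#' @export
Sau3AI <- function() restrictionEnzyme("Sau3AI", "GATC", 0L)

.checkDnaString <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A, C, G, T, N}")
  sequence
}

#' Digest a sequence in silico with a restriction enzyme
#'
#' Scans the (linear) sequence left to right for every occurrence of the
#' recognition site, including overlapping ones, and cuts at each
#' occurrence's cut offset; the fragments are the inter-cut intervals with
#' zero-length pieces dropped. The ambiguity code N never matches a site
#' position. Site matching is done with [Biostrings::matchPattern()].
#'
#' @param sequence DNA string (or a length-1 [Biostrings::DNAStringSet]
#'   element); lowercase accepted, N allowed.
#' @param enzyme a [RestrictionEnzyme-class].
#' @return a [FragmentPattern-class] of fragment lengths sorted descending.
#' @examples
#' digestSequence("AAGGCCTT", HaeIII())   # fragments 4, 4
#' digestSequence("GATCGATC", Sau3AI())   # fragments 4, 4
#' @export
digestSequence <- function(sequence, enzyme) {
  stopifnot(is(enzyme, "RestrictionEnzyme"))
  sequence <- .checkDnaString(sequence)
  n <- nchar(sequence)
  subject <- Biostrings::DNAString(sequence)
  # fixed = TRUE: N in the subject matches nothing
  hits <- Biostrings::matchPattern(enzyme@site, subject, fixed = TRUE)
  cuts <- sort(unique(Biostrings::start(hits) - 1L + enzyme@cutOffset))
  bounds <- c(0L, cuts, n)
  lens <- diff(bounds)
  lens <- lens[lens > 0L]
  new("FragmentPattern", enzymeName = enzyme@name,
      fragmentLengths = as.integer(sort(lens, decreasing = TRUE)),
      sequenceLength = n)
}

#' Compare two restriction-fragment patterns at gel resolution
#'
#' Two patterns are equal when, after discarding fragments shorter than
#' `minDetectableBp` from both, they have the same number of fragments and
#' each pair of sorted lengths differs by at most `toleranceFraction` of the
#' longer one. Tolerance 0 is exact multiset equality (pure in-silico mode);
#' `ardraGelMode()` gives a preset emulating agarose resolution.
#'
#' @param p,q [FragmentPattern-class] objects from the same enzyme.
#' @param toleranceFraction relative length tolerance, >= 0.
#' @param minDetectableBp fragments below this length are invisible.
#' @return logical.
#' @export
patternEqual <- function(p, q, toleranceFraction = 0, minDetectableBp = 0L) {
  stopifnot(is(p, "FragmentPattern"), is(q, "FragmentPattern"))
  if (p@enzymeName != q@enzymeName)
    stop("patterns come from different enzymes")
  if (toleranceFraction < 0) stop("toleranceFraction must be >= 0")
  a <- p@fragmentLengths[p@fragmentLengths >= minDetectableBp]
  b <- q@fragmentLengths[q@fragmentLengths >= minDetectableBp]
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0L) return(TRUE)
  all(abs(a - b) <= toleranceFraction * pmax(a, b))
}

#' @rdname patternEqual
#' @export
ardraGelMode <- function() list(toleranceFraction = 0.05, minDetectableBp = 50L)

# Partition pattern indices into equivalence groups. Under tolerance 0 the
# pattern relation is a true equivalence; under tolerance > 0 it is only
# reflexive/symmetric, so groups are its single-linkage transitive closure.
.partitionByPattern <- function(patterns, toleranceFraction, minDetectableBp) {
  n <- length(patterns)
  group <- integer(n)
  ng <- 0L
  for (i in seq_len(n)) {
    if (group[i] > 0L) next
    ng <- ng + 1L
    queue <- i
    group[i] <- ng
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (j in seq_len(n)) {
        if (group[j] == 0L &&
            patternEqual(patterns[[cur]], patterns[[j]],
                         toleranceFraction, minDetectableBp)) {
          group[j] <- ng
          queue <- c(queue, j)
        }
      }
    }
  }
  group
}

#' Two-stage ARDRA grouping of isolates
#'
#' Stage 1 partitions isolates by their HaeIII fragment patterns; isolates
#' sharing a stage-1 pattern are digested again and re-partitioned by their
#' Sau3AI patterns. The final groups are the stage-2 cells; one
#' representative per group (the lexicographically smallest isolate id) is
#' flagged as the isolate to sequence.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet] of
#'   amplicon sequences, names = isolate ids.
#' @param toleranceFraction,minDetectableBp pattern-comparison settings, see
#'   [patternEqual()]; the defaults are exact in-silico lengths.
#' @param enzymes list of two [RestrictionEnzyme-class] objects applied in
#'   order (default HaeIII then Sau3AI).
#' @return an [ArdraGrouping-class]. Group ids are `G1`, `G2`, ... ordered
#'   by their representatives' ids, so the grouping does not depend on the
#'   input order (exactly so at tolerance 0).
#' @export
groupByArdra <- function(sequences, toleranceFraction = 0,
                         minDetectableBp = 0L,
                         enzymes = list(HaeIII(), Sau3AI())) {
  if (is(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  if (length(sequences) == 0L) stop("no sequences supplied")
  ids <- names(sequences)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must be uniquely named by isolate id")
  stopifnot(length(enzymes) == 2L)

  pat1 <- lapply(sequences, digestSequence, enzyme = enzymes[[1L]])
  stage1 <- .partitionByPattern(pat1, toleranceFraction, minDetectableBp)

  assignments <- character(length(ids))
  names(assignments) <- ids
  cellReps <- character(0)
  for (g in unique(stage1)) {
    members <- which(stage1 == g)
    pat2 <- lapply(sequences[members], digestSequence, enzyme = enzymes[[2L]])
    stage2 <- .partitionByPattern(pat2, toleranceFraction, minDetectableBp)
    for (h in unique(stage2)) {
      cell <- ids[members[stage2 == h]]
      rep <- min(cell)
      cellReps <- c(cellReps, rep)
      assignments[cell] <- rep   # temporary key: the representative id
    }
  }
  cellReps <- sort(cellReps)
  groupIds <- paste0("G", seq_along(cellReps))
  names(groupIds) <- cellReps
  assignments <- groupIds[assignments]
  names(assignments) <- ids
  representatives <- cellReps
  names(representatives) <- groupIds
  new("ArdraGrouping", assignments = assignments,
      representatives = representatives)
}

#' Read amplicon FASTA / write an ARDRA grouping as CSV
#'
#' @param path file path.
#' @param grouping an [ArdraGrouping-class].
#' @return `readAmpliconFasta`: named uppercase character vector of
#'   sequences; `writeArdraGrouping`: the path, invisibly.
#' @export
readAmpliconFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' @rdname readAmpliconFasta
#' @export
writeArdraGrouping <- function(grouping, path) {
  stopifnot(is(grouping, "ArdraGrouping"))
  asg <- groupAssignments(grouping)
  reps <- groupRepresentatives(grouping)
  df <- data.frame(isolate_id = names(asg), group_id = unname(asg),
                   representative = names(asg) %in% reps)
  utils::write.csv(df[order(df$group_id, df$isolate_id), ], path,
                   row.names = FALSE)
  invisible(path)
}
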