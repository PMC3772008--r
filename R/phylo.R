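#' Build a DnaAlignment from sequences or an aligned FASTA file
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (characters A, C, G, T, -, N; lowercase accepted), or a
#'   [Biostrings::DNAStringSet].
#' @param path path to an aligned FASTA file.
#' @return a [DnaAlignment-class].
#' @export
dnaAlignment <- function(seqs) {
  if (is(seqs, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(seqs))
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    ids <- names(seqs)
    seqs <- toupper(as.character(seqs))
    if (length(unique(nchar(seqs))) != 1L)
      stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- ids
  }
  new("DnaAlignment", mat = m)
}

#' @rdname dnaAlignment
#' @export
readAlignedFasta <- function(path) {
  dnaAlignment(Biostrings::readDNAStringSet(path))
}

#' @rdname dnaAlignment
#' @param aln a [DnaAlignment-class].
#' @export
writeAlignedFasta <- function(aln, path) {
  stopifnot(is(aln, "DnaAlignment"))
  seqs <- apply(alignmentMatrix(aln), 1L, paste0, collapse = "")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

.BASES <- c("A", "C", "G", "T")
.PURINES <- c("A", "G")

# comparable sites under pairwise deletion: both characters unambiguous bases
.comparable <- function(a, b) a %in% .BASES & b %in% .BASES

#' Uncorrected p-distance between two aligned rows
#'
#' Mismatching comparable sites over comparable sites, where a site is
#' comparable iff both characters are unambiguous bases (pairwise deletion
#' of gaps and N).
#'
#' @param a,b equal-length character vectors (or strings) of aligned bases.
#' @return fraction of differing comparable sites.
#' @export
pDistance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("aligned rows must have equal length")
  ok <- .comparable(a, b)
  if (!any(ok)) stop("no comparable sites between the two sequences")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Kimura two-parameter distance between two aligned rows
#'
#' With P the transition fraction (A<->G, C<->T) and Q the transversion
#' fraction over comparable sites,
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q) substitutions per site.
#' Saturated pairs where a logarithm argument is non-positive are undefined
#' and returned as NA.
#'
#' @inheritParams pDistance
#' @return substitutions per site, or NA if the correction is undefined.
#' @examples
#' # 100 sites, 10 transitions, 5 transversions: -log(0.75)/2 - log(0.9)/4
#' @export
k2pDistance <- function(a, b) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1L]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1L]]
  if (length(a) != length(b)) stop("aligned rows must have equal length")
  ok <- .comparable(a, b)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites between the two sequences")
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  transition <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1) - 0.25 * log(arg2)
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln a [DnaAlignment-class].
#' @param model `"p"` (uncorrected) or `"k2p"`.
#' @param gapHandling `"pairwise"` deletion (default) removes
#'   gap/ambiguous sites per pair; `"complete"` removes every column
#'   containing a gap or N before any comparison.
#' @return symmetric numeric matrix with zero diagonal; undefined
#'   (saturated) K2P entries are NA.
#' @export
pairwiseDistances <- function(aln, model = c("p", "k2p"),
                              gapHandling = c("pairwise", "complete")) {
  stopifnot(is(aln, "DnaAlignment"))
  model <- match.arg(model)
  gapHandling <- match.arg(gapHandling)
  m <- alignmentMatrix(aln)
  if (gapHandling == "complete") {
    keep <- apply(m, 2L, function(col) all(col %in% .BASES))
    if (!any(keep)) stop("complete deletion removed every column")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  f <- if (model == "p") pDistance else k2pDistance
  v <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        v[i, j] <- v[j, i] <- f(m[i, ], m[j, ])
  v
}

#' Cluster sequences into phylotypes at a divergence threshold
#'
#' Agglomerative clustering (complete linkage by default, via
#' [stats::hclust()]) on the pairwise distance matrix, cut so that every
#' within-phylotype pair differs by strictly less than `threshold`. With
#' complete linkage the "< threshold" guarantee holds for every pair inside
#' a phylotype; single or average linkage relax it to the linkage criterion.
#'
#' @param aln a [DnaAlignment-class].
#' @param threshold divergence cut as a fraction (default 0.03, the
#'   conventional species-level 16S phylotype cut).
#' @param model distance model, `"p"` (default, standard for OTU-style
#'   grouping) or `"k2p"`.
#' @param linkage `"complete"` (default), `"single"` or `"average"`.
#' @return a [PhylotypeAssignment-class]; phylotype indices are numbered by
#'   the lexicographic order of each phylotype's smallest member id, so the
#'   result does not depend on input order.
#' @export
clusterPhylotypes <- function(aln, threshold = 0.03, model = c("p", "k2p"),
                              linkage = c("complete", "single", "average")) {
  linkage <- match.arg(linkage)
  v <- pairwiseDistances(aln, model = match.arg(model))
  if (any(is.na(v))) {
    bad <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop("undefined distance between '", rownames(v)[bad[1L]], "' and '",
         rownames(v)[bad[2L]], "'")
  }
  ids <- rownames(v)
  if (length(ids) == 1L) {
    memb <- stats::setNames(1L, ids)
  } else {
    hc <- stats::hclust(stats::as.dist(v), method = linkage)
    memb <- stats::cutree(hc, h = threshold - 1e-9)
  }
  # renumber by lexicographic order of each cluster's smallest member
  firsts <- vapply(split(names(memb), memb), min, character(1))
  relabel <- integer(length(firsts))
  relabel[order(firsts)] <- seq_along(firsts)
  out <- relabel[memb]
  names(out) <- names(memb)
  new("PhylotypeAssignment", assignments = as.integer(out) |>
        stats::setNames(names(memb)), threshold = threshold)
}

#' @rdname clusterPhylotypes
#' @param assignment a [PhylotypeAssignment-class].
#' @param path CSV path (columns `id`, `phylotype`).
#' @export
writePhylotypes <- function(assignment, path) {
  stopifnot(is(assignment, "PhylotypeAssignment"))
  a <- phylotypes(assignment)
  utils::write.csv(data.frame(id = names(a), phylotype = unname(a)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively join the pair (i, j) minimizing
#' Q_ij = (n - 2) d_ij - sum_k d_ik - sum_k d_jk, with branch lengths
#' v_i = d_ij / 2 + (r_i - r_j) / (2(n - 2)) and v_j = d_ij - v_i, reducing
#' the matrix by d_(ij)k = (d_ik + d_jk - d_ij) / 2, until three nodes
#' remain and are joined on a central node in closed form. Ties in Q are
#' broken by the smallest (i, j) index pair. On an additive matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param d symmetric distance matrix with unique row/col names (taxon
#'   labels) and zero diagonal; no NA entries.
#' @param clampNegative if TRUE, negative branch lengths (possible on
#'   non-additive input) are clamped to zero; default FALSE retains them.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighborJoining <- function(d, clampNegative = FALSE) {
  d <- .asDistMatrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  if (any(is.na(d))) stop("distance matrix contains undefined entries")
  labels <- rownames(d)
  if (anyDuplicated(labels)) stop("duplicate taxon labels")
  bl <- function(x) {
    if (clampNegative) x <- max(x, 0)
    sprintf("%.12g", x)
  }
  nodes <- labels
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]
    j <- best[1L, 2L]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    merged <- sprintf("(%s:%s,%s:%s)", nodes[i], bl(vi), nodes[j], bl(vj))
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    nodes <- c(nodes[keep], merged)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- d[1, 2] - v1
  v3 <- d[1, 3] - v1
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1L], bl(v1),
                    nodes[2L], bl(v2), nodes[3L], bl(v3))
  ape::read.tree(text = newick)
}

# canonical keys for the non-trivial bipartitions of an unrooted tree:
# for each internal node below the root, the set of tips on its side,
# represented by whichever side excludes the reference (first sorted) tip
.bipartitionKeys <- function(tree) {
  ntip <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1L]
  all <- sort(tree$tip.label)
  root <- ntip + 1L
  desc <- .descendantTips(tree)
  keys <- character(0)
  nodeOf <- integer(0)
  for (node in setdiff(seq_len(tree$Nnode) + ntip, root)) {
    tips <- desc[[node]]
    if (length(tips) <= 1L || length(tips) >= ntip - 1L) next  # trivial
    side <- sort(tips)
    if (ref %in% side) side <- setdiff(all, side)
    keys <- c(keys, paste(side, collapse = "|"))
    nodeOf <- c(nodeOf, node)
  }
  stats::setNames(keys, nodeOf)
}

# tip labels descending from each node (tips included), by reverse edge order
.descendantTips <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  edges <- tree$edge[order(tree$edge[, 1L], decreasing = TRUE), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]
    c <- edges[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `replicates` times, rebuilds the NJ tree per replicate, and
#' scores each non-trivial bipartition of the full-data tree by the
#' percentage of replicate trees containing it. Replicates in which any
#' pairwise distance is undefined (K2P saturation) are skipped and counted;
#' supports are percentages of the valid replicates.
#'
#' @param aln a [DnaAlignment-class] with at least 4 sequences.
#' @param model distance model, `"k2p"` (default) or `"p"`.
#' @param replicates number of bootstrap replicates (>= 1); 1,000 is the
#'   conventional choice for publication trees.
#' @param seed integer seed; the resampling is deterministic given it.
#' @param clampNegative passed to [neighborJoining()].
#' @return the full-data `phylo` tree with integer supports in [0, 100] as
#'   `node.label` on internal nodes (empty for the root and trivial
#'   bipartitions), plus attribute `skippedReplicates`.
#' @export
bootstrapSupport <- function(aln, model = c("k2p", "p"), replicates = 1000L,
                             seed = 1L, clampNegative = FALSE) {
  stopifnot(is(aln, "DnaAlignment"))
  model <- match.arg(model)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("replicates must be >= 1")
  m <- alignmentMatrix(aln)
  if (nrow(m) < 4L) stop("bootstrap supports need at least 4 sequences")
  full <- neighborJoining(pairwiseDistances(aln, model), clampNegative)
  keys <- .bipartitionKeys(full)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  valid <- 0L
  skipped <- 0L
  set.seed(as.integer(seed))
  L <- ncol(m)
  for (rep in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    v <- pairwiseDistances(dnaAlignment(m[, cols, drop = FALSE]), model)
    if (any(is.na(v))) {
      skipped <- skipped + 1L
      next
    }
    valid <- valid + 1L
    repKeys <- .bipartitionKeys(neighborJoining(v, clampNegative))
    hit <- keys %in% repKeys
    counts[hit] <- counts[hit] + 1L
  }
  if (valid == 0L) stop("every bootstrap replicate had undefined distances")
  support <- as.integer(round(100 * counts / valid))
  ntip <- length(full$tip.label)
  labs <- rep("", full$Nnode)
  labs[as.integer(names(keys)) - ntip] <- as.character(support)
  full$node.label <- labs
  attr(full, "skippedReplicates") <- skipped
  full
}

#' Newick round-trip helpers
#'
#' Thin wrappers over [ape::write.tree()] and [ape::read.tree()] so the
#' pipeline's tree I/O goes through one place. Branch lengths survive the
#' round trip to well beyond 6 decimals; bootstrap supports ride along as
#' internal node labels.
#'
#' @param tree a `phylo` object.
#' @param path optional file path; omitted, the Newick string is returned.
#' @param text Newick string (or use `path`).
#' @return `writeNewickTree`: the Newick string (invisibly if written to a
#'   file); `readNewickTree`: a `phylo` object.
#' @export
writeNewickTree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(text = NULL, path = NULL) {
  tr <- if (is.null(path)) ape::read.tree(text = text) else
    ape::read.tree(path)
  if (is.null(tr)) stop("malformed Newick input")
  tr
}
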