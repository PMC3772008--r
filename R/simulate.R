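#' Simulate a random tree (Yule topology, exponential branch lengths)
#'
#' Grows a pure-birth topology by splitting a uniformly chosen pending
#' lineage until `nTaxa` tips exist, then draws every branch length
#' independently from an exponential distribution. Deterministic given the
#' seed.
#'
#' @param nTaxa number of tips, >= 2.
#' @param seed integer seed.
#' @param meanBranchLength mean of the exponential branch lengths,
#'   substitutions per site (default 0.05).
#' @return a rooted `phylo` tree with tips `t1` ... `tn`.
#' @export
simulateTree <- function(nTaxa, seed = 1L, meanBranchLength = 0.05) {
  nTaxa <- as.integer(nTaxa)
  if (nTaxa < 2L) stop("nTaxa must be >= 2")
  set.seed(as.integer(seed))
  # grow the topology by splitting a uniformly chosen existing tip
  newick <- "(t1,t2)"
  for (k in seq_len(nTaxa)[-(1:2)]) {
    target <- sprintf("t%d", sample.int(k - 1L, 1L))
    newick <- sub(sprintf("\\b%s\\b", target),
                  sprintf("(%s,t%d)", target, k), newick)
  }
  tr <- ape::read.tree(text = paste0(newick, ";"))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / meanBranchLength)
  tr
}

# K2P per-branch substitution probabilities for branch length t (expected
# substitutions/site) and transition/transversion rate ratio kappa.
# With rates alpha (transition) and beta (each transversion) normalized so
# alpha + 2 beta = 1, the standard closed forms are
#   P(same)          = 1/4 + 1/4 e^{-4 beta t} + 1/2 e^{-2(alpha+beta) t}
#   P(transition)    = 1/4 + 1/4 e^{-4 beta t} - 1/2 e^{-2(alpha+beta) t}
#   P(transversion)  = 2 * (1/4 - 1/4 e^{-4 beta t})
.k2pBranchProbs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    transition = 0.25 + 0.25 * e1 - 0.5 * e2,
    transversionEach = 0.25 - 0.25 * e1)
}

.TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
.TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))

# evolve a character vector of bases along one branch
.evolveBranch <- function(bases, t, kappa) {
  if (t <= 0) return(bases)
  pr <- .k2pBranchProbs(t, kappa)
  n <- length(bases)
  u <- stats::runif(n)
  out <- bases
  toTransition <- u >= pr["same"] & u < pr["same"] + pr["transition"]
  out[toTransition] <- .TRANSITION_OF[bases[toTransition]]
  tv1 <- u >= pr["same"] + pr["transition"] &
    u < pr["same"] + pr["transition"] + pr["transversionEach"]
  tv2 <- u >= pr["same"] + pr["transition"] + pr["transversionEach"]
  for (bs in .BASES) {
    sel <- tv1 & bases == bs
    out[sel] <- .TRANSVERSIONS_OF[[bs]][1L]
    sel <- tv2 & bases == bs
    out[sel] <- .TRANSVERSIONS_OF[[bs]][2L]
  }
  out
}

#' Simulate an alignment on a tree under the K2P substitution model
#'
#' Draws the root sequence uniformly over A/C/G/T and evolves it down every
#' branch using the closed-form K2P site transition probabilities for that
#' branch's length (no event-by-event stepping), with transition/transversion
#' rate ratio `kappa`. Branch lengths are expected substitutions per site;
#' non-positive lengths are treated as zero. Deterministic given the seed.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param length number of sites, >= 1.
#' @param kappa transition/transversion rate ratio, > 0 (default 2).
#' @param seed integer seed.
#' @return a [DnaAlignment-class] over the tree's tip labels.
#' @export
simulateAlignment <- function(tree, length, kappa = 2, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  length <- as.integer(length)
  if (length < 1L) stop("alignment length must be >= 1")
  if (kappa <= 0) stop("kappa must be > 0")
  set.seed(as.integer(seed))
  ntip <- base::length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  seqs <- vector("list", nn)
  seqs[[root]] <- sample(.BASES, length, replace = TRUE)
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]  # preorder
  el <- tree$edge.length[order(tree$edge[, 1L])]
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1L]
    ch <- edges[k, 2L]
    seqs[[ch]] <- .evolveBranch(seqs[[p]], max(el[k], 0), kappa)
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  dnaAlignment(m)
}

#' Specify and simulate a densitometric gel lane
#'
#' `laneSpec()` describes a lane as a mixture of Gaussian bands on a flat
#' baseline; `simulateLane()` renders it on an even grid with additive
#' Gaussian noise (clipped at zero):
#' intensity(x) = baseline + sum_j h_j exp(-(x - p_j)^2 / (2 sigma^2)) + noise.
#'
#' @param positions band positions in (0, 1).
#' @param intensities positive band heights.
#' @param sigma Gaussian band width, normalized units (default 0.004).
#' @param baseline flat baseline level (default 0.02).
#' @param noiseSd standard deviation of the additive noise (default 0.01).
#' @param samples samples per lane (default 2000).
#' @return `laneSpec`: a list spec; `simulateLane`: a [LaneProfile-class].
#' @export
laneSpec <- function(positions, intensities, sigma = 0.004, baseline = 0.02,
                     noiseSd = 0.01, samples = 2000L) {
  stopifnot(length(positions) == length(intensities),
            all(positions > 0 & positions < 1),
            all(intensities > 0), sigma > 0, noiseSd >= 0, samples >= 2L)
  list(positions = positions, intensities = intensities, sigma = sigma,
       baseline = baseline, noiseSd = noiseSd, samples = as.integer(samples))
}

#' @rdname laneSpec
#' @param spec a spec from `laneSpec()`.
#' @param laneId lane identifier.
#' @param seed integer seed.
#' @export
simulateLane <- function(spec, laneId = "lane", seed = 1L) {
  set.seed(as.integer(seed))
  x <- seq(0, 1, length.out = spec$samples)
  y <- rep(spec$baseline, spec$samples)
  for (j in seq_along(spec$positions))
    y <- y + spec$intensities[j] *
      exp(-(x - spec$positions[j])^2 / (2 * spec$sigma^2))
  if (spec$noiseSd > 0)
    y <- y + stats::rnorm(spec$samples, sd = spec$noiseSd)
  laneProfile(laneId, x, pmax(y, 0))
}

#' Simulate a stratified-horizon community as a set of gel lanes
#'
#' Emulates the structure of DGGE gels from stratified soils: a shared pool
#' of band positions (distinct community members), from which each horizon's
#' lane draws a subset whose size is that horizon's richness — surface soil
#' richer than subsoil richer than substratum by default (20/12/8). Band
#' intensities are lognormal, giving moderately uneven communities.
#'
#' @param richness named integer vector of bands per lane (default
#'   `c(A = 20, B = 12, C = 8)`).
#' @param poolSize number of distinct band positions available (default 30).
#' @param seed integer seed.
#' @param intensitySdLog lognormal sdlog of band intensities (default 0.35).
#' @param ... further arguments to [laneSpec()] (sigma, baseline, noiseSd,
#'   samples).
#' @return named list of [LaneProfile-class], one per horizon.
#' @export
simulateCommunityLanes <- function(richness = c(A = 20L, B = 12L, C = 8L),
                                   poolSize = 30L, seed = 1L,
                                   intensitySdLog = 0.35, ...) {
  stopifnot(all(richness >= 1L), poolSize >= max(richness))
  set.seed(as.integer(seed))
  pool <- seq(0.05, 0.95, length.out = poolSize)
  lanes <- vector("list", length(richness))
  names(lanes) <- names(richness)
  for (i in seq_along(richness)) {
    pos <- sort(sample(pool, richness[i]))
    h <- stats::rlnorm(richness[i], meanlog = 0, sdlog = intensitySdLog)
    spec <- laneSpec(pos, h, ...)
    lanes[[i]] <- simulateLane(spec, laneId = names(richness)[i],
                               seed = sample.int(.Machine$integer.max, 1L))
  }
  lanes
}

#' Simulate per-isolate activity records with prescribed Table counts
#'
#' Emits one record per requested horizon x category cell, drawing the
#' MnO2-equivalent value uniformly inside the category's interval: high in
#' [50, 240] (the upper end matching the observed activity range), medium in
#' [10, 50), low in [1, 10), none in [0, 1). [tabulateActivity()] on the
#' output reproduces the requested counts exactly, and every record's
#' category round-trips through [categorizeActivity()].
#'
#' @param perHorizonCounts named list, horizon -> integer vector of counts
#'   for categories (high, medium, low, none); e.g.
#'   `list(A = c(8, 32, 143, 9), ...)`.
#' @param seed integer seed.
#' @return data.frame of records (`isolate_id`, `horizon`, `mno2_uM`,
#'   `category`).
#' @export
simulateActivityTable <- function(perHorizonCounts, seed = 1L) {
  if (length(perHorizonCounts) == 0L) stop("empty specification")
  if (!all(names(perHorizonCounts) %in% HORIZONS))
    stop("horizons must be among A, B, C")
  set.seed(as.integer(seed))
  lims <- list(high = c(50, 240), medium = c(10, 50), low = c(1, 10),
               none = c(0, 1))
  rows <- list()
  for (hz in names(perHorizonCounts)) {
    cts <- perHorizonCounts[[hz]]
    stopifnot(length(cts) == 4L, all(cts >= 0))
    for (ci in seq_along(ACTIVITY_CATEGORIES)) {
      nc <- cts[ci]
      if (nc == 0L) next
      lim <- lims[[ACTIVITY_CATEGORIES[ci]]]
      # upper bounds of medium/low/none are exclusive; runif never hits them
      vals <- stats::runif(nc, lim[1L], lim[2L])
      rows[[length(rows) + 1L]] <- data.frame(
        horizon = hz, mno2_uM = vals,
        category = ACTIVITY_CATEGORIES[ci])
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(isolate_id = sprintf("%s%03d", out$horizon,
                                    stats::ave(seq_len(nrow(out)),
                                               out$horizon, FUN = seq_along)),
               out)
  rownames(out) <- NULL
  out
}

#' Simulate a set of 16S-like amplicons with known ARDRA structure
#'
#' Generates `nGroups` random amplicon sequences (uniform bases) and, for
#' each, `copies` exact duplicates, so the two-enzyme ARDRA grouping has a
#' known expected answer. Purely a convenience for demonstrations and tests.
#'
#' @param nGroups number of distinct amplicons.
#' @param copies copies per amplicon (default 1).
#' @param length amplicon length in bp (default 1500).
#' @param seed integer seed.
#' @return named character vector of sequences.
#' @export
simulateAmplicons <- function(nGroups, copies = 1L, length = 1500L,
                              seed = 1L) {
  set.seed(as.integer(seed))
  out <- character(0)
  for (g in seq_len(nGroups)) {
    s <- paste0(sample(.BASES, length, replace = TRUE), collapse = "")
    for (cpy in seq_len(copies))
      out[sprintf("iso%02d_%d", g, cpy)] <- s
  }
  out
}
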