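# shared fixture builders and independent oracles

randomDna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force restriction digestion: scan every index for a literal site
# match (N matches nothing), cut at start - 1 + offset, drop empty pieces
bruteForceDigest <- function(sequence, site, cutOffset) {
  s <- strsplit(toupper(sequence), "")[[1L]]
  p <- strsplit(site, "")[[1L]]
  n <- length(s)
  L <- length(p)
  if (n < L) return(n)
  hit <- rep(TRUE, n - L + 1L)
  for (k in seq_len(L))
    hit <- hit & s[seq_len(n - L + 1L) + k - 1L] == p[k]
  cuts <- which(hit) - 1L + cutOffset
  lens <- diff(c(0L, sort(unique(cuts)), n))
  sort(lens[lens > 0L], decreasing = TRUE)
}

# additive distance matrix of a tree by path-length sums
additiveMatrix <- function(tree) ape::cophenetic.phylo(tree)

# Procrustes root-mean-square distance after optimal translation/rotation/
# reflection (no scaling): closed-form orthogonal Procrustes via SVD
procrustesRMSD <- function(x, y) {
  x <- scale(as.matrix(x), scale = FALSE)
  y <- scale(as.matrix(y), scale = FALSE)
  s <- svd(crossprod(y, x))
  rot <- s$u %*% t(s$v)
  sqrt(max(sum((y %*% rot - x)^2), 0) / nrow(x))
}

# unrooted topology equality
sameTopology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

table1Counts <- list(A = c(8L, 32L, 143L, 9L),
                     B = c(22L, 17L, 54L, 67L),
                     C = c(20L, 29L, 19L, 83L))
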