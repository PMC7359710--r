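# Shared small fixtures, built once per test run.

fixGrid <- function(lo = 900, hi = 1800, by = 2) seq(lo, hi, by = by)

# memoized small phantoms keyed by arguments
.phantomCache <- new.env(parent = emptyenv())
cachedPhantom <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.phantomCache[[key]]))
    .phantomCache[[key]] <- makePhantom(...)
  .phantomCache[[key]]
}

# L2-normalize rows, for scale-free spectral comparisons
l2rows <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-12)

# median per-pixel RMS between row-normalized matrices
medianRms <- function(A, B) {
  stats::median(sqrt(rowMeans((l2rows(A) - l2rows(B))^2)))
}

# adjusted Rand index (mclust is the independent implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# cosine-similarity matching of recovered vs true component spectra:
# returns the minimum matched cosine under greedy row-wise argmax matching
minMatchedCosine <- function(Strue, Shat) {
  k <- nrow(Strue)
  cosm <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cosm[i, j] <- sum(Strue[i, ] * Shat[j, ]) /
      sqrt(sum(Strue[i, ]^2) * sum(Shat[j, ]^2))
  perm <- apply(cosm, 1, which.max)
  min(cosm[cbind(seq_len(k), perm)])
}
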