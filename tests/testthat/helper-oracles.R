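# Independent oracles and small fixture builders used across the suite.

# Naive O(n^3) average-neighbour agglomeration: clusters merge while the
# smallest mean of all cross-pair distances (computed from the original
# matrix each round) is <= cutoff. Ties: lowest cluster-index pair.
naiveAverageNeighbor <- function(dm, cutoff) {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) < 2) break
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-15) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    if (best_d > cutoff + 1e-9) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# Canonical form of a partition for set-wise comparison.
partitionSets <- function(groups) {
  s <- unname(lapply(groups, function(g) sort(as.integer(g))))
  s[order(vapply(s, min, integer(1)))]
}

membershipToSets <- function(memb) {
  partitionSets(split(seq_along(memb), memb))
}

randomDistanceMatrix <- function(n, max_d = 0.5) {
  m <- matrix(0, n, n)
  v <- runif(n * (n - 1) / 2, 0, max_d)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  dimnames(m) <- list(sprintf("x%02d", 1:n), sprintf("x%02d", 1:n))
  m
}

# Variant table from sequences and a count vector/matrix.
makeVC <- function(seqs, counts, sample = "s1") {
  variantCounts(seqs, counts, sample = sample)
}

# Plant exactly n_sub substitutions into seq at the given 1-based sites.
substituteAt <- function(seq, sites, to = NULL) {
  ch <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(sites)) {
    s <- sites[k]
    ch[s] <- if (is.null(to)) setdiff(bases, ch[s])[1] else to[k]
  }
  paste(ch, collapse = "")
}

# A fixed ACGT-repeat template: no homopolymers, passes every filter.
repeatTemplate <- function(len) {
  paste(rep_len(c("A", "C", "G", "T"), len), collapse = "")
}

# Deterministic non-periodic template. Used wherever exact Hamming
# distances must survive global alignment: with a high-entropy template and
# scattered substitution sites the optimal alignment is gapless, so the
# planted substitution counts are recovered exactly.
oracleTemplate <- function(len) {
  withr::with_seed(1234 + len, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
}

# Equidistant variant set: k sequences over length L whose pairwise
# uncorrected distances all equal 2*s/L (disjoint, scattered s-site
# substitution sets), so every average-linkage merge happens exactly at
# that height.
equidistantVariants <- function(k, s, L) {
  stopifnot(k * s * 2 <= L)
  base <- oracleTemplate(L)
  lapply(seq_len(k), function(i) {
    sites <- i + (seq_len(s) - 1) * 2 * k # spacing 2k keeps subs isolated
    substituteAt(base, sites)
  }) |> unlist()
}

# Three sequences over a given base with exact pairwise Hamming distances
# n12, n13, n23 (must satisfy triangle parity: n12+n13-n23 even, >= 0).
# Substitution sites are scattered (stride 4, interleaved pools) so the
# distances survive global alignment.
tripletVariants <- function(base, n12, n13, n23) {
  L <- nchar(base)
  k <- (n12 + n13 - n23) / 2 # sites where v3 copies v2's substitution
  stopifnot(k == round(k), k >= 0, k <= min(n12, n13))
  m <- n13 - k
  stopifnot(1 + 4 * max(n12 - 1, 0) <= L, 3 + 4 * max(m - 1, 0) <= L)
  sites12 <- seq(1, by = 4, length.out = n12)
  sitesM <- seq(3, by = 4, length.out = m)
  ch <- strsplit(base, "")[[1]]
  bases <- c("A", "C", "G", "T")
  v2 <- ch
  for (s in sites12) v2[s] <- setdiff(bases, ch[s])[1]
  v3 <- ch
  if (k > 0) for (s in sites12[seq_len(k)]) v3[s] <- v2[s]
  for (s in sitesM) v3[s] <- setdiff(bases, ch[s])[2]
  c(base, paste(v2, collapse = ""), paste(v3, collapse = ""))
}
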