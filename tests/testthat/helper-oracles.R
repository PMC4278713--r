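# Independent oracles, deliberately naive, used to validate the package's
# implementations on small instances.

# O(n^2) all-pairs Kendall tau-b: explicit concordance/discordance counting
# with tie corrections tallied directly.
tauOracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    s <- sign(dx) * sign(dy)
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NA_real_)
  (C - D) / den
}

# Brute-force agglomerative average linkage: at every step recompute every
# inter-cluster mean dissimilarity from the original matrix (no
# Lance-Williams updates), same tie-break rule (lexicographically smallest
# pair of smallest original member indices).
upgmaOracle <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dv <- mean(d[clusters[[i]], clusters[[j]]])
      key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || dv < best$d ||
          (dv == best$d && (key[1] < best$key[1] ||
                            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dv, key = key)
      }
    }
    a <- best$i; b <- best$j
    if (min(clusters[[a]]) > min(clusters[[b]])) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(node[a], node[b])
    height[step] <- best$d
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    node[a] <- step
    clusters[[b]] <- NULL
    node <- node[-b]
  }
  list(merge = merge, height = height)
}

# nearest integer, half away from zero (independent of the package's helper)
.roundHalfAwayOracle <- function(x) sign(x) * floor(abs(x) + 0.5)

# all vectors of length n over an alphabet, as rows
allVectors <- function(n, alphabet) {
  as.matrix(do.call(expand.grid, rep(list(alphabet), n)))
}

# small cohort straight from a score matrix
cohortFromScores <- function(sc) GBMCohort(sc, defaultMarkerRegistry())

# score matrix with all tumors at baseline for the given markers
baselineMatrix <- function(markers, ids) {
  reg <- defaultMarkerRegistry()
  reg <- reg[match(markers, reg$name), ]
  base <- vapply(reg$scheme, function(s)
    switch(s, basal_1to2 = 1, proliferation_fraction = 0.15, 0), numeric(1))
  matrix(rep(base, length(ids)), nrow = length(markers),
         dimnames = list(markers, ids))
}
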