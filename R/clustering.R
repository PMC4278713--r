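# Kendall tau-b biclustering: similarity, average linkage, cluster labelling
# and the sequential marker-pruning procedure.

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation, suited to the heavily tied ordinal
#' scores produced by semi-quantitative IHC evaluation:
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' with \eqn{C}/\eqn{D} the concordant/discordant pair counts,
#' \eqn{n_0 = n(n-1)/2} and \eqn{n_1}, \eqn{n_2} the within-tie pair counts
#' of the two vectors. Computed from the joint contingency table. Returns
#' \code{NA} when either vector is constant (the denominator vanishes);
#' constant items are expected to be pruned before clustering.
#'
#' @param x,y numeric vectors of equal length >= 2. Pairs with an NA in
#'   either vector are dropped.
#' @return tau-b in [-1, 1], or NA for degenerate input.
#' @examples
#' kendallTauB(0:3, 0:3)        #  1
#' kendallTauB(0:3, 3:0)        # -1
#' @export
kendallTauB <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 complete observations")
  xl <- sort(unique(x)); yl <- sort(unique(y))
  if (length(xl) < 2 || length(yl) < 2) return(NA_real_)
  M <- table(factor(x, levels = xl), factor(y, levels = yl))
  r <- nrow(M); c <- ncol(M)
  C <- 0; D <- 0
  for (i in seq_len(r)) for (j in seq_len(c)) {
    nij <- M[i, j]
    if (nij == 0) next
    if (i < r) {
      blk <- M[(i + 1):r, , drop = FALSE]
      if (j < c) C <- C + nij * sum(blk[, (j + 1):c])
      if (j > 1) D <- D + nij * sum(blk[, 1:(j - 1)])
    }
  }
  n0 <- n * (n - 1) / 2
  n1 <- sum(choose(rowSums(M), 2))
  n2 <- sum(choose(colSums(M), 2))
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

#' Pairwise tau-b similarity along one axis of the score matrix
#'
#' @param mat standardized score matrix, markers x tumors.
#' @param axis \code{"tumors"} (similarity between columns) or
#'   \code{"markers"} (between rows).
#' @return symmetric similarity matrix; diagonal is 1 for items with nonzero
#'   score variance and NA otherwise.
#' @export
buildSimilarity <- function(mat, axis = c("tumors", "markers")) {
  axis <- match.arg(axis)
  v <- if (axis == "tumors") t(mat) else mat   # items in rows
  n <- nrow(v)
  if (n < 2) stop("need at least 2 items along axis ", axis)
  if (ncol(v) < 2) stop("need at least 2 observations per item")
  sim <- matrix(NA_real_, n, n, dimnames = list(rownames(v), rownames(v)))
  varying <- apply(v, 1, function(z) length(unique(z[!is.na(z)])) > 1)
  diag(sim) <- ifelse(varying, 1, NA_real_)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    t <- kendallTauB(v[i, ], v[j, ])
    sim[i, j] <- t
    sim[j, i] <- t
  }
  attr(sim, "axis") <- axis
  sim
}

# UPGMA (unweighted average linkage) on a dissimilarity matrix with
# deterministic tie-breaking: among minimal pairs pick the one whose sorted
# pair of smallest original item indices is lexicographically least.
.upgma <- function(d, labels) {
  n <- nrow(d)
  stopifnot(n >= 2)
  D <- d
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  rep_idx <- seq_len(n)           # smallest original index in each cluster
  node <- -seq_len(n)             # hclust merge coding
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    mn <- min(sub)
    hits <- which(sub == mn, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    keys <- cbind(pmin(rep_idx[idx[hits[, 1]]], rep_idx[idx[hits[, 2]]]),
                  pmax(rep_idx[idx[hits[, 1]]], rep_idx[idx[hits[, 2]]]))
    pick <- order(keys[, 1], keys[, 2])[1]
    a <- idx[hits[pick, 1]]; b <- idx[hits[pick, 2]]
    if (rep_idx[a] > rep_idx[b]) { tmp <- a; a <- b; b <- tmp }
    merge[step, ] <- c(node[a], node[b])
    height[step] <- mn
    # Lance-Williams update for unweighted average linkage
    for (k in idx) {
      if (k == a || k == b) next
      D[a, k] <- D[k, a] <-
        (size[a] * D[a, k] + size[b] * D[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    node[a] <- step
    active[b] <- FALSE
  }
  ord <- .leafOrder(merge, height, labels)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "average",
                 call = match.call(), dist.method = "(1 - tau)/2"),
            class = "hclust")
}

# Leaf ordering: tighter (lower-height) subtree first; ties broken by the
# lexicographically smallest leaf label, so heatmap output is reproducible.
.leafOrder <- function(merge, height, labels) {
  rec <- function(i) {
    if (i < 0) return(-i)
    l <- merge[i, 1]; r <- merge[i, 2]
    hl <- if (l < 0) 0 else height[l]
    hr <- if (r < 0) 0 else height[r]
    lo <- rec(l); ro <- rec(r)
    first <- hl < hr ||
      (hl == hr && min(labels[lo]) <= min(labels[ro]))
    if (first) c(lo, ro) else c(ro, lo)
  }
  rec(nrow(merge))
}

#' Average-linkage clustering of a tau similarity matrix
#'
#' Transforms similarity to dissimilarity via \eqn{d = (1 - \tau)/2} (tau 1
#' maps to 0, tau -1 to 1) and runs unweighted average linkage (UPGMA).
#' Tie-breaking is deterministic (smallest lexicographic pair of original
#' item indices), so results are reproducible. Merge heights are
#' non-decreasing.
#'
#' @param similarity symmetric tau matrix from [buildSimilarity()]. Missing
#'   entries (degenerate constant items) abort with the offending pairs
#'   listed.
#' @return an object of class \code{hclust}.
#' @export
averageLinkage <- function(similarity) {
  stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity),
            nrow(similarity) >= 2)
  labels <- rownames(similarity)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(similarity)))
  off <- similarity
  diag(off) <- 1
  if (any(is.na(off))) {
    bad <- which(is.na(off) & upper.tri(off), arr.ind = TRUE)
    pairs <- apply(bad, 1, function(r)
      paste(labels[r[1]], labels[r[2]], sep = "/"))
    stop("similarity undefined for pair(s): ",
         paste(utils::head(pairs, 5), collapse = ", "),
         if (length(pairs) > 5) " ..." else "")
  }
  d <- (1 - off) / 2
  diag(d) <- 0
  .upgma(d, labels)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k-1 merges; every item is assigned to exactly one cluster.
#'
#' @param dendrogram an \code{hclust} object.
#' @param k number of clusters, 1 <= k <= number of items.
#' @return named integer vector of cluster ids.
#' @export
cutClusters <- function(dendrogram, k) {
  n <- length(dendrogram$labels)
  if (k < 1 || k > n) stop("k must lie in 1..", n)
  cutree(dendrogram, k = k)
}

#' Label tumor clusters by subclass-marker enrichment
#'
#' For each cluster and candidate subclass, enrichment is the mean
#' standardized score of that subclass's designated markers inside the
#' cluster minus the mean outside. A cluster is labelled with the
#' argmax-enrichment subclass when the enrichment exceeds \code{threshold},
#' and \code{UNLABELED} otherwise.
#'
#' @param assignment named cluster vector from [cutClusters()].
#' @param stdMat standardized matrix (retained markers x tumors).
#' @param registry marker registry.
#' @param threshold minimum enrichment for a label (default 0.25).
#' @param subclasses candidate subclasses.
#' @return data frame: cluster, n, label, enrichment, and one
#'   \code{enrichment_<subclass>} column per candidate.
#' @export
labelClusters <- function(assignment, stdMat, registry, threshold = 0.25,
                          subclasses = c("PN", "CLAS", "MES")) {
  clusters <- sort(unique(assignment))
  des <- setNames(registry$designated_subclass, registry$name)
  out <- data.frame(cluster = clusters, n = NA_integer_,
                    label = NA_character_, enrichment = NA_real_,
                    stringsAsFactors = FALSE)
  enr <- matrix(NA_real_, length(clusters), length(subclasses),
                dimnames = list(NULL, subclasses))
  for (ci in seq_along(clusters)) {
    inside <- names(assignment)[assignment == clusters[ci]]
    if (!length(inside)) stop("cluster ", clusters[ci], " has no members")
    outside <- setdiff(colnames(stdMat), inside)
    out$n[ci] <- length(inside)
    for (sc in subclasses) {
      mk <- rownames(stdMat)[des[rownames(stdMat)] == sc]
      if (!length(mk)) { enr[ci, sc] <- NA_real_; next }
      mIn <- mean(stdMat[mk, inside, drop = FALSE], na.rm = TRUE)
      mOut <- if (length(outside))
        mean(stdMat[mk, outside, drop = FALSE], na.rm = TRUE) else 0
      enr[ci, sc] <- mIn - mOut
    }
    best <- which.max(enr[ci, ])
    if (length(best) && is.finite(enr[ci, best]) && enr[ci, best] > threshold) {
      out$label[ci] <- subclasses[best]
      out$enrichment[ci] <- enr[ci, best]
    } else {
      out$label[ci] <- "UNLABELED"
      out$enrichment[ci] <- if (length(best)) enr[ci, best] else NA_real_
    }
  }
  colnames(enr) <- paste0("enrichment_", subclasses)
  cbind(out, as.data.frame(enr))
}

#' Sequential marker pruning before clustering
#'
#' Reproduces the step-wise removal of markers without discriminating power,
#' recording the stage and reason per marker:
#' \enumerate{
#'   \item differential-staining filter: markers whose minor-category
#'     frequency (share of tumors off the modal score) is below
#'     \code{minMinorFreq} are removed - effectively constant stains;
#'   \item designation-concordance filter: the remaining markers are
#'     clustered (tau-b, average linkage) and cut into \code{markerK} groups;
#'     a marker whose co-members do not include any marker sharing its
#'     designated subclass (singletons included) is removed;
#'   \item high-expression-group filter: tumors are clustered into
#'     \code{tumorK} preliminary clusters; a marker is removed when no
#'     cluster's mean standardized score exceeds the outside mean by at
#'     least \code{margin}.
#' }
#' Filters (2) and (3) are iterated to a fixed point, mirroring repeated
#' clustering attempts on the shrinking panel. Markers flagged
#' \code{is_genetic} are exempt from filters (2) and (3): alteration calls
#' are retained on biological grounds even when they end up as the lone
#' representative of their subclass (they remain subject to filter (1),
#' since a constant marker breaks the similarity computation).
#'
#' @param stdMat standardized matrix from [standardizeMatrix()].
#' @param registry marker registry.
#' @param minMinorFreq filter-1 threshold (default 0.02).
#' @param markerK marker-dendrogram cut for filter 2 (default 4).
#' @param tumorK preliminary tumor clusters for filter 3 (default 3).
#' @param margin filter-3 enrichment margin (default 0.1).
#' @return list with \code{retained} (marker names), \code{report}
#'   (data frame marker/stage/detail) and \code{markerDendrogram} (of the
#'   retained panel; NULL when fewer than 2 markers survive).
#' @export
pruneMarkers <- function(stdMat, registry, minMinorFreq = 0.02,
                         markerK = 4, tumorK = 3, margin = 0.1) {
  report <- data.frame(marker = character(0), stage = character(0),
                       detail = character(0), stringsAsFactors = FALSE)
  note <- function(marker, stage, detail)
    rbind(report, data.frame(marker = marker, stage = stage, detail = detail,
                             stringsAsFactors = FALSE))
  des <- setNames(registry$designated_subclass, registry$name)
  genetic <- registry$name[registry$is_genetic]
  keep <- rownames(stdMat)

  # (1) differential staining
  for (m in keep) {
    v <- stdMat[m, ]
    v <- v[!is.na(v)]
    minor <- 1 - max(table(v)) / length(v)
    if (minor < minMinorFreq)
      report <- note(m, "low_variability",
                     sprintf("minor-category frequency %.3f < %.3f",
                             minor, minMinorFreq))
  }
  keep <- setdiff(keep, report$marker)

  markerDend <- NULL
  repeat {
    changed <- FALSE
    # (2) designation concordance on the marker dendrogram
    if (length(keep) >= 3) {
      sim <- buildSimilarity(stdMat[keep, , drop = FALSE], "markers")
      markerDend <- averageLinkage(sim)
      cl <- cutClusters(markerDend, min(markerK, length(keep)))
      for (m in setdiff(keep, genetic)) {
        mates <- setdiff(names(cl)[cl == cl[m]], m)
        if (!length(mates) || !any(des[mates] == des[m])) {
          report <- note(m, "designation_discordant",
                         if (length(mates))
                           paste0("clusters with ",
                                  paste(mates, collapse = ","),
                                  " (designated ",
                                  paste(unique(des[mates]), collapse = ","),
                                  ") not ", des[m])
                         else "singleton in marker dendrogram")
          changed <- TRUE
        }
      }
      keep <- setdiff(keep, report$marker)
    }
    # (3) high-expression group
    if (length(keep) >= 2 && ncol(stdMat) > tumorK) {
      simT <- buildSimilarity(stdMat[keep, , drop = FALSE], "tumors")
      ht <- averageLinkage(simT)
      cl <- cutClusters(ht, tumorK)
      for (m in setdiff(keep, genetic)) {
        best <- -Inf
        for (cc in unique(cl)) {
          inside <- mean(stdMat[m, names(cl)[cl == cc]], na.rm = TRUE)
          outside <- mean(stdMat[m, names(cl)[cl != cc]], na.rm = TRUE)
          best <- max(best, inside - outside)
        }
        if (best < margin) {
          report <- note(m, "no_high_expression_group",
                         sprintf("max cluster enrichment %.3f < %.3f",
                                 best, margin))
          changed <- TRUE
        }
      }
      keep <- setdiff(keep, report$marker)
    }
    if (!changed) break
  }
  if (length(keep) >= 2) {
    sim <- buildSimilarity(stdMat[keep, , drop = FALSE], "markers")
    markerDend <- averageLinkage(sim)
  }
  list(retained = keep, report = report, markerDendrogram = markerDend)
}

#' Bicluster a scored cohort
#'
#' End-to-end unsupervised analysis: standardize by scheme range, prune
#' uninformative markers, build tau-b average-linkage dendrograms over both
#' markers and tumors, cut the tumor dendrogram into \code{k} clusters and
#' label the clusters by subclass-marker enrichment.
#'
#' @param cohort a [GBMCohort-class].
#' @param k number of tumor clusters (default 3).
#' @param threshold labelling enrichment threshold (default 0.25).
#' @param minMinorFreq,markerK,tumorK,margin pruning parameters, see
#'   [pruneMarkers()].
#' @return a [BiclusterResult-class].
#' @export
clusterCohort <- function(cohort, k = 3, threshold = 0.25,
                          minMinorFreq = 0.02, markerK = 4, tumorK = 3,
                          margin = 0.1) {
  registry <- markerRegistry(cohort)
  std <- standardizeMatrix(cohort)
  excl <- registry[registry$excluded, "name"]
  pr <- pruneMarkers(std, registry, minMinorFreq = minMinorFreq,
                     markerK = markerK, tumorK = tumorK, margin = margin)
  report <- pr$report
  if (length(excl))
    report <- rbind(data.frame(marker = excl, stage = "registry_excluded",
                               detail = "excluded = TRUE in registry",
                               stringsAsFactors = FALSE), report)
  if (length(pr$retained) < 2)
    stop("fewer than 2 markers retained after pruning")
  mat <- std[pr$retained, , drop = FALSE]
  simT <- buildSimilarity(mat, "tumors")
  hT <- averageLinkage(simT)
  cl <- cutClusters(hT, k)
  labs <- labelClusters(cl, mat, registry, threshold = threshold)
  new("BiclusterResult", standardized = mat, tumorDendrogram = hT,
      markerDendrogram = pr$markerDendrogram, tumorClusters = cl,
      clusterLabels = labs, prunedMarkers = report)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights.
#'
#' @param dendrogram an \code{hclust} object.
#' @param file optional path; when given the tree is also written there.
#' @return Newick string.
#' @export
dendrogramToNewick <- function(dendrogram, file = NULL) {
  phy <- ape::as.phylo(dendrogram)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) writeLines(txt, file)
  txt
}
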