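# Kendall tau-b, average linkage, cluster cutting/labelling, pruning.

test_that("tau-b handles perfect concordance, discordance and degeneracy", {
  expect_equal(kendallTauB(0:3, 0:3), 1)
  expect_equal(kendallTauB(0:3, 3:0), -1)
  expect_true(is.na(kendallTauB(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(kendallTauB(c(1, 1), c(2, 2))))
  expect_error(kendallTauB(1:3, 1:4), "length mismatch")
  # example with ties, against the all-pairs oracle
  x <- c(0, 0, 1, 2); y <- c(1, 0, 1, 1)
  expect_equal(kendallTauB(x, y), tauOracle(x, y))
})

test_that("tau-b matches the pair-count oracle and stats::cor on random vectors", {
  set.seed(21)
  for (r in 1:200) {
    n <- sample(3:15, 1)
    x <- sample(0:3, n, replace = TRUE)
    y <- sample(0:3, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    t <- kendallTauB(x, y)
    expect_equal(t, tauOracle(x, y), tolerance = 1e-12)
    expect_equal(t, suppressWarnings(cor(x, y, method = "kendall")),
                 tolerance = 1e-12)
    expect_gte(t, -1); expect_lte(t, 1)
  }
})

test_that("tau-b is symmetric and invariant under strictly monotone relabeling", {
  set.seed(22)
  for (r in 1:50) {
    x <- sample(0:2, 8, replace = TRUE)
    y <- sample(0:2, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendallTauB(x, y), kendallTauB(y, x))
    # strictly increasing maps preserve all pair orderings
    expect_equal(kendallTauB(x, y), kendallTauB(x^2 + 3 * x, 10 * y - 4))
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(23)
  m <- matrix(sample(0:3, 30, replace = TRUE), 5, 6,
              dimnames = list(paste0("M", 1:5), paste0("T", 1:6)))
  simT <- buildSimilarity(m, "tumors")
  expect_equal(dim(simT), c(6, 6))
  expect_identical(simT, t(simT))
  simM <- buildSimilarity(m, "markers")
  expect_equal(dim(simM), c(5, 5))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(simM[i, j], kendallTauB(m[i, ], m[j, ]))
  # two identical tumors have similarity 1
  m2 <- cbind(T1 = c(0, 1, 2), T2 = c(0, 1, 2))
  rownames(m2) <- paste0("M", 1:3)
  expect_equal(buildSimilarity(m2, "tumors")["T1", "T2"], 1)
  # constant item: unit diagonal only where variance is nonzero
  m3 <- rbind(M1 = c(1, 1, 1), M2 = c(0, 1, 2), M3 = c(2, 1, 0))
  colnames(m3) <- paste0("T", 1:3)
  simC <- buildSimilarity(m3, "markers")
  expect_true(is.na(simC["M1", "M1"]))
  expect_equal(simC["M2", "M2"], 1)
  expect_error(averageLinkage(simC), "undefined for pair")
})

test_that("average linkage agrees with hand agglomeration on 3 items", {
  # d(A,B)=0.1, d(A,C)=0.5, d(B,C)=0.5: merge (A,B) at 0.1, then C at 0.5
  d <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  sim <- 1 - 2 * d
  h <- averageLinkage(sim)
  expect_equal(h$height, c(0.1, 0.5))
  expect_equal(h$merge, rbind(c(-1L, -2L), c(1L, -3L)))
  cl <- cutClusters(h, 2)
  expect_equal(unname(cl[c("A", "B")]), c(1, 1))
  expect_equal(unname(cl["C"]), 2)
  expect_equal(length(unique(cutClusters(h, 3))), 3)
  expect_equal(length(unique(cutClusters(h, 1))), 1)
  expect_error(cutClusters(h, 4), "k must lie")
  # 2 items merge once at their dissimilarity
  d2 <- matrix(c(0, .3, .3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(averageLinkage(1 - 2 * d2)$height, 0.3)
})

test_that("average linkage matches the brute-force agglomerator and hclust", {
  set.seed(31)
  for (r in 1:60) {
    n <- sample(4:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("I", 1:n), paste0("I", 1:n))
    h <- averageLinkage(1 - 2 * d)
    o <- upgmaOracle(d)
    expect_identical(h$merge, o$merge)
    expect_equal(h$height, o$height, tolerance = 1e-12)
    # reference implementation agrees on heights
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(h$height), sort(hc$height), tolerance = 1e-9)
    # ultrametric property: non-decreasing heights
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("clustering is invariant under input permutation up to leaf order", {
  set.seed(32)
  n <- 7
  d <- matrix(0, n, n); d[upper.tri(d)] <- runif(n * (n - 1) / 2); d <- d + t(d)
  ids <- paste0("I", 1:n)
  dimnames(d) <- list(ids, ids)
  h1 <- averageLinkage(1 - 2 * d)
  p <- sample(n)
  h2 <- averageLinkage((1 - 2 * d)[p, p])
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-12)
  for (k in 2:4) {
    c1 <- cutClusters(h1, k)
    c2 <- cutClusters(h2, k)[ids]
    # same partition: co-membership matrices identical
    expect_identical(outer(c1, c1, "=="), outer(c2, c2, "=="))
  }
})

test_that("cluster labelling scores subclass enrichment", {
  reg <- defaultMarkerRegistry()
  m <- rbind(EGFR = c(1, 1, 0, 0), EGFRvIII = c(1, 1, 0, 0),
             VIM = c(0, 0, 1, 1), PTEN = c(0, 0, 1, 1))
  colnames(m) <- paste0("T", 1:4)
  cl <- setNames(c(1, 1, 2, 2), colnames(m))
  lab <- labelClusters(cl, m, reg)
  expect_equal(lab$label, c("CLAS", "MES"))
  expect_equal(lab$enrichment, c(1, 1))
  # uniform matrix: zero enrichment everywhere, no labels
  lab0 <- labelClusters(cl, matrix(0.5, 4, 4, dimnames = dimnames(m)), reg)
  expect_true(all(lab0$label == "UNLABELED"))
})

test_that("marker pruning removes constant, discordant and unassociated markers", {
  reg <- defaultMarkerRegistry()
  ids <- sprintf("T%02d", 1:12)
  A <- 1:4; B <- 5:8; C <- 9:12
  blk <- function(hot) { v <- rep(0, 12); v[hot] <- 1; v }
  m <- rbind(VIM = blk(A), CD44 = blk(A), GFAP = blk(A),
             OLIG2 = blk(A),                       # PN marker in a MES clade
             IDH1_R132H = blk(B), p53 = blk(B),
             EGFR = blk(C), EGFRvIII = blk(C),
             MET = blk(c(1, 2, 5, 6, 9, 10)),      # no cluster association
             NEFL = rep(0.5, 12))                  # constant
  colnames(m) <- ids
  pr <- pruneMarkers(m, reg, markerK = 3, tumorK = 3)
  expect_setequal(pr$retained,
                  c("VIM", "CD44", "GFAP", "IDH1_R132H", "p53",
                    "EGFR", "EGFRvIII"))
  rep <- pr$report
  expect_equal(rep$stage[rep$marker == "NEFL"], "low_variability")
  expect_equal(rep$stage[rep$marker == "OLIG2"], "designation_discordant")
  expect_equal(rep$stage[rep$marker == "MET"], "no_high_expression_group")
})

test_that("dendrograms export to parseable Newick", {
  v <- validationCohortFixture()
  bic <- clusterCohort(v, k = 3)
  txt <- dendrogramToNewick(bic@tumorDendrogram)
  phy <- ape::read.tree(text = txt)
  expect_equal(sort(phy$tip.label), sort(colnames(v)))
})
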