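# Delta-Ct normalization, expression ratios, and the metagene score.

.ctTable <- function(sample, genes, means, reps = 3, jitter = 0) {
  do.call(rbind, lapply(seq_along(genes), function(i)
    data.frame(sample_id = sample, gene = genes[i], replicate = seq_len(reps),
               ct = means[i] + jitter * seq_len(reps))))
}

test_that("delta-Ct subtracts the replicate-averaged reference", {
  ct <- .ctTable("S1", c("ASCL1", "RPS27"), c(25, 20))
  expect_equal(deltaCt(ct)$delta_ct, 5)
  # replicate averaging
  ct <- rbind(
    data.frame(sample_id = "S1", gene = "ASCL1", replicate = 1:3,
               ct = c(24.9, 25.0, 25.1)),
    data.frame(sample_id = "S1", gene = "RPS27", replicate = 1:3,
               ct = c(20, 20, 20)))
  expect_equal(deltaCt(ct)$delta_ct, 5)
  # full 9-gene sample: 8 delta-Cts, reference excluded
  sig <- defaultQpcrSignature()
  genes <- c(sig$PN, sig$MES, sig$reference)
  dct <- deltaCt(.ctTable("S1", genes, c(rep(26, 8), 20)))
  expect_equal(nrow(dct), 8)
  expect_false(sig$reference %in% dct$gene)
  # missing reference errors; short replicates flagged
  expect_error(deltaCt(.ctTable("S1", "ASCL1", 25)), "reference")
  ct <- rbind(.ctTable("S1", "RPS27", 20),
              .ctTable("S1", "ASCL1", 25, reps = 2))
  expect_equal(deltaCt(ct)$flag, "LOW_REPLICATES")
})

test_that("delta-Ct is invariant under replicate permutation and global Ct shifts", {
  set.seed(61)
  sig <- defaultQpcrSignature()
  genes <- c(sig$PN, sig$MES, sig$reference)
  ct <- .ctTable("S1", genes, runif(9, 18, 30), jitter = 0.01)
  d1 <- deltaCt(ct)
  ct2 <- ct[sample(nrow(ct)), ]
  d2 <- deltaCt(ct2)
  expect_equal(d1$delta_ct, d2$delta_ct[match(d1$gene, d2$gene)])
  ct3 <- ct; ct3$ct <- ct3$ct + 1.7   # uniform shift cancels via reference
  expect_equal(deltaCt(ct3)$delta_ct, d1$delta_ct)
})

test_that("group expression ratios follow delta-delta-Ct exponentiation", {
  dct <- data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                    gene = "ASCL1", delta_ct = c(4, 4, 4, 4))
  r <- groupExpressionRatio(dct, c("A1", "A2"), c("B1", "B2"), "ASCL1")
  expect_equal(r$ratio, 1)
  dct$delta_ct <- c(5, 5, 4, 4)     # B one cycle lower -> double expression
  r <- groupExpressionRatio(dct, c("A1", "A2"), c("B1", "B2"), "ASCL1")
  expect_equal(r$ratio, 2)
  expect_error(groupExpressionRatio(dct, character(0), "B1", "ASCL1"),
               "empty group")
})

test_that("programmed group separation is recovered from the generator", {
  ct <- generateQpcr(n_pn = 8, n_mes = 8, separation = log2(3) * 1,
                     replicate_sd = 0.1, seed = 9)
  labels <- attr(ct, "labels")
  dct <- deltaCt(ct)
  pnIds <- names(labels)[labels == "PN"]
  mesIds <- names(labels)[labels == "MES"]
  for (g in defaultQpcrSignature()$PN) {
    r <- groupExpressionRatio(dct, mesIds, pnIds, g)   # PN gene, PN vs MES
    expect_equal(r$ratio, 3, tolerance = 0.15)
    expect_lt(r$p_value, 0.01)
  }
})

test_that("metagene is Z-corrected, antisymmetric and sign-faithful", {
  sig <- defaultQpcrSignature()
  genes <- c(sig$PN, sig$MES, sig$reference)
  # two mirror-image samples: equal magnitude, opposite sign
  ct <- rbind(.ctTable("P", genes, c(rep(24, 4), rep(28, 4), 20)),
              .ctTable("M", genes, c(rep(28, 4), rep(24, 4), 20)))
  mg <- metageneScores(deltaCt(ct))
  expect_equal(sum(mg$metagene), 0)
  expect_equal(abs(mg$metagene[1]), abs(mg$metagene[2]))
  expect_equal(mg$sample_id[1], "M")  # MES-like first, positive metagene
  expect_gt(mg$metagene[1], 0)
  # swapping the PN and MES gene sets negates the metagene
  swapped <- list(PN = sig$MES, MES = sig$PN, reference = sig$reference)
  mg2 <- metageneScores(deltaCt(ct), signature = swapped)
  expect_equal(sort(mg2$metagene), sort(-mg$metagene))
  # Z columns are exact
  ct <- generateQpcr(seed = 2)
  mg <- metageneScores(deltaCt(ct), ihcLabels = attr(ct, "labels"))
  expect_lt(abs(mean(mg$pn_z)), 1e-9)
  expect_lt(abs(sd(mg$pn_z) - 1), 1e-9)
  expect_lt(abs(mean(mg$mes_z)), 1e-9)
  expect_lt(abs(sd(mg$mes_z) - 1), 1e-9)
  # labels carried through and signs match generation
  expect_true(all(mg$ihc_label[mg$metagene > 0] == "MES"))
  expect_true(all(mg$ihc_label[mg$metagene < 0] == "PN"))
  # degenerate input
  expect_error(metageneScores(deltaCt(.ctTable("S1", genes, c(1:8, 20) + 20))),
               "at least 2 samples")
})

test_that("a programmed discordant sample crosses the metagene zero line", {
  # 10 PN-like and 10 MES-like samples, then overwrite one "PN" sample with
  # a MES-like transcriptional profile: its metagene must come out positive
  ct <- generateQpcr(n_pn = 10, n_mes = 10, separation = 2,
                     replicate_sd = 0.2, seed = 15)
  sig <- defaultQpcrSignature()
  rogue <- ct$sample_id == "PN_05"
  own <- ct$gene %in% sig$PN & rogue
  opp <- ct$gene %in% sig$MES & rogue
  ct$ct[own] <- ct$ct[own] + 2   # PN genes down-expressed
  ct$ct[opp] <- ct$ct[opp] - 2   # MES genes over-expressed
  mg <- metageneScores(deltaCt(ct), ihcLabels = attr(ct, "labels"))
  expect_gt(mg$metagene[mg$sample_id == "PN_05"], 0)
  others <- mg$sample_id != "PN_05"
  expect_true(all(sign(mg$metagene[others]) ==
                  ifelse(mg$ihc_label[others] == "MES", 1, -1)))
})

test_that("reciprocal and per-gene variants stay ordered consistently", {
  ct <- generateQpcr(seed = 4)
  labels <- attr(ct, "labels")
  dct <- deltaCt(ct)
  mgG <- metageneScores(dct, ihcLabels = labels, zMode = "per_gene")
  expect_true(all(sign(mgG$metagene) == ifelse(mgG$ihc_label == "MES", 1, -1)))
  mgR <- metageneScores(dct, ihcLabels = labels, inverse = "reciprocal")
  expect_true(all(sign(mgR$metagene) == ifelse(mgR$ihc_label == "MES", 1, -1)))
})
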