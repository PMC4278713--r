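# Domain types, registry, and the tabular readers/writers.

test_that("default registry encodes the panel's scheme system", {
  reg <- defaultMarkerRegistry()
  expect_equal(nrow(reg), 24)
  expect_setequal(reg$name[reg$is_genetic],
                  c("IDH1_R132H", "EGFR", "EGFRvIII", "EGFR_FISH"))
  expect_equal(reg$name[reg$excluded], "DLL3")
  expect_true(all(reg$scheme %in% schemeNames()))
  # binary alteration markers aggregate by single consensus
  bin <- reg$scheme == "binary_alteration"
  aggr <- vapply(reg$scheme, function(s) schemeInfo(s)$aggregation, "")
  expect_true(all(aggr[bin] == "single_consensus"))
  # allowed values strictly increasing and scheme-appropriate
  expect_equal(schemeInfo("triad_0to2")$values, 0:2)
  expect_equal(schemeInfo("basal_1to2")$values, c(1, 2))
  expect_null(schemeInfo("proliferation_fraction")$values)
  expect_error(schemeInfo("not_a_scheme"), "unknown")
})

test_that("core-score parsing validates rows and names offenders", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c("tumor_id\tcore_id\tmarker\tvalue", "T1\t1\tVIM\t2"), tmp)
  cs <- readCoreScores(tmp)
  expect_equal(nrow(cs), 1)
  expect_equal(cs$value, 2)

  writeLines(c("tumor_id\tcore_id\tmarker\tvalue", "T1\t1\tYKL40\t0"), tmp)
  expect_error(readCoreScores(tmp), "basal_1to2.*line 2")

  writeLines(c("tumor_id\tcore_id\tmarker\tvalue", "T1\t1\tNOPE\t1"), tmp)
  expect_error(readCoreScores(tmp), "unknown marker 'NOPE' at line 2")

  writeLines(c("tumor_id\tcore_id\tmarker\tvalue",
               "T1\t1\tVIM\t2", "T1\t1\tVIM\t1"), tmp)
  expect_error(readCoreScores(tmp), "duplicate.*line 3")

  writeLines(c("tumor_id\tcore_id\tmarker\tvalue", "T1\t5\tVIM\t2"), tmp)
  expect_error(readCoreScores(tmp), "core_id")

  # missing values are permitted
  writeLines(c("tumor_id\tcore_id\tmarker\tvalue",
               "T1\t1\tVIM\t2", "T1\t2\tVIM\t."), tmp)
  expect_equal(sum(is.na(readCoreScores(tmp)$value)), 1)
})

test_that("a full cohort-sized core file parses to the expected row count", {
  markers10 <- c("IDH1_R132H", "EGFR", "EGFRvIII", "EGFR_FISH", "p53",
                 "PTEN", "VIM", "YKL40", "CD44", "GFAP")
  cfg <- cohortConfig(123, core_noise = 0.05, seed = 11, markers = markers10)
  gen <- generateCohort(cfg)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write.table(gen$cores, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- readCoreScores(tmp)
  expect_equal(nrow(cs), 123 * 4 * 10)
  expect_equal(cs$value, gen$cores$value)  # row order preserved
})

test_that("profile serialization round-trips scores and flags bit-exactly", {
  # irrational-looking means and a consensus inconsistency flag
  cores <- data.frame(
    tumor_id = rep(c("T1", "T2"), each = 8),
    core_id = rep(1:4, 4),
    marker = rep(rep(c("VIM", "IDH1_R132H"), each = 4), 2),
    value = c(2, 2, 1, 0,  1, 1, 0, 1,   1, 0, 0, 0,  0, 0, 0, 0))
  coh <- aggregateCohort(cores)
  expect_match(tumorFlags(coh)[["T1"]], "IDH1_R132H:INCONSISTENT_CONSENSUS")
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeProfiles(coh, tmp)
  back <- readProfiles(tmp)
  expect_identical(scoreMatrix(back), scoreMatrix(coh))
  expect_identical(tumorFlags(back), tumorFlags(coh))

  # 44-tumor fixture with ground truth round-trips too
  v <- validationCohortFixture()
  writeProfiles(v, tmp)
  back <- readProfiles(tmp)
  expect_identical(scoreMatrix(back), scoreMatrix(v))
  expect_identical(groundTruth(back), groundTruth(v))
})

test_that("GBMCohort validity rejects malformed cohorts", {
  sc <- baselineMatrix(c("VIM", "YKL40"), c("T1", "T2"))
  expect_s4_class(cohortFromScores(sc), "GBMCohort")
  bad <- sc; bad["VIM", 1] <- 7
  expect_error(cohortFromScores(bad), "outside")
  bad <- sc; bad["YKL40", 1] <- 0          # below the basal scheme floor
  expect_error(cohortFromScores(bad), "outside")
  sc2 <- sc; rownames(sc2) <- c("VIM", "NOT_A_MARKER")
  expect_error(cohortFromScores(sc2), "not in registry")
  sc3 <- sc; colnames(sc3) <- c("T1", "T1")
  expect_error(cohortFromScores(sc3), "unique")
  # consensus markers must hold exact allowed values
  sc4 <- baselineMatrix(c("EGFR", "VIM"), "T1")
  sc4["EGFR", 1] <- 0.5
  expect_error(cohortFromScores(sc4), "consensus")
})

test_that("FISH and proliferation tables validate on read", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(c("tumor_id\tcore_id\tegfr_signals\tcep7_signals",
               "T1\t1\t40\t20"), tmp)
  expect_equal(nrow(readFishCounts(tmp)), 1)
  writeLines(c("tumor_id\tcore_id\tegfr_signals\tcep7_signals",
               "T1\t1\t-3\t20"), tmp)
  expect_error(readFishCounts(tmp), "non-negative")
  writeLines(c("tumor_id\tcore_id\tmarker\tpositive_cells\ttotal_cells",
               "T1\t1\tKi67\t50\t100"), tmp)
  expect_equal(readProliferationCounts(tmp)$positive_cells, 50)
  writeLines(c("tumor_id\tcore_id\tmarker\tpositive_cells\ttotal_cells",
               "T1\t1\tKi67\t150\t100"), tmp)
  expect_error(readProliferationCounts(tmp), "positive_cells")
})
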