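# Per-core score aggregation, proliferation indices, FISH calling, and
# scheme-range standardization of the score matrix.

#' Aggregate per-core scores for one marker of one tumor
#'
#' Aggregation follows the marker's scheme: \code{mean_of_cores} and
#' \code{fraction} take the arithmetic mean over available cores;
#' \code{single_consensus} returns the common value when all cores agree and
#' otherwise the majority value with an \code{INCONSISTENT_CONSENSUS} flag
#' (exact ties resolve toward the altered/positive state, never silently).
#' Fewer than two usable cores adds a \code{LOW_CORE_COUNT} flag.
#'
#' @param values numeric vector of raw core scores (NAs are dropped).
#' @param scheme scheme identifier.
#' @return list with \code{score}, \code{n_cores} and \code{flags}.
#' @examples
#' aggregateMarker(c(2, 2, 1, 1), "triad_0to2")$score       # 1.5
#' aggregateMarker(c(1, 1, 0, 1), "binary_alteration")      # majority + flag
#' @export
aggregateMarker <- function(values, scheme) {
  info <- schemeInfo(scheme)
  values <- values[!is.na(values)]
  if (!length(values)) stop("no core scores supplied")
  if (!is.null(info$values)) {
    if (!all(values %in% info$values))
      stop("core score outside scheme ", scheme, " allowed values")
  } else if (any(values < info$min | values > info$max)) {
    stop("core score outside [", info$min, ", ", info$max, "]")
  }
  flags <- character(0)
  if (length(values) < 2L) flags <- c(flags, "LOW_CORE_COUNT")
  if (info$aggregation == "single_consensus") {
    if (length(unique(values)) > 1L) {
      flags <- c(flags, "INCONSISTENT_CONSENSUS")
      tab <- table(values)
      top <- as.numeric(names(tab)[tab == max(tab)])
      score <- max(top)  # tie -> positive/altered state
    } else {
      score <- values[[1L]]
    }
  } else {
    score <- mean(values)
  }
  list(score = score, n_cores = length(values), flags = flags)
}

#' Aggregate a per-core score table into a GBMCohort
#'
#' Applies [aggregateMarker()] to every (tumor, marker) group of a validated
#' core-score table (see [readCoreScores()]). Tumor order follows first
#' appearance; markers are emitted in registry order. Per-tumor flags are
#' recorded as \code{"marker:FLAG"} entries joined by \code{";"}.
#'
#' @param coreScores data frame with columns \code{tumor_id}, \code{core_id},
#'   \code{marker}, \code{value}.
#' @param registry marker registry.
#' @param groundTruth optional named (by tumor id) or ordered vector of
#'   generating subclass labels.
#' @return a [GBMCohort-class].
#' @export
aggregateCohort <- function(coreScores, registry = defaultMarkerRegistry(),
                            groundTruth = NULL) {
  tumors <- unique(coreScores$tumor_id)
  markers <- intersect(registry$name, unique(coreScores$marker))
  sc <- matrix(NA_real_, length(markers), length(tumors),
               dimnames = list(markers, tumors))
  flags <- setNames(rep("", length(tumors)), tumors)
  sch <- setNames(registry$scheme, registry$name)
  grp <- split(seq_len(nrow(coreScores)),
               list(factor(coreScores$marker, markers),
                    factor(coreScores$tumor_id, tumors)), drop = TRUE)
  for (g in grp) {
    m <- coreScores$marker[g[1L]]
    t <- coreScores$tumor_id[g[1L]]
    v <- coreScores$value[g]
    if (all(is.na(v))) next
    agg <- aggregateMarker(v, sch[[m]])
    sc[m, t] <- agg$score
    if (length(agg$flags)) {
      entry <- paste0(m, ":", agg$flags, collapse = ";")
      flags[t] <- if (nzchar(flags[t])) paste(flags[t], entry, sep = ";") else entry
    }
  }
  if (!is.null(groundTruth) && !is.null(names(groundTruth)))
    groundTruth <- unname(groundTruth[tumors])
  GBMCohort(sc, registry, flags = unname(flags), groundTruth = groundTruth)
}

#' Proliferation index of one tumor for one marker
#'
#' Per-core positive fraction (positive / total tumor cells counted in a
#' field of at least 100 cells), averaged over cores.
#'
#' @param positive_cells,total_cells integer vectors, one entry per core.
#' @return fraction in [0, 1].
#' @examples
#' proliferationIndex(c(0, 100), c(200, 100))  # 0.5
#' @export
proliferationIndex <- function(positive_cells, total_cells) {
  stopifnot(length(positive_cells) == length(total_cells),
            length(total_cells) >= 1)
  small <- which(total_cells < 100)
  if (length(small))
    stop("core ", small[1], " has fewer than 100 tumor cells (",
         total_cells[small[1]], ")")
  if (any(positive_cells < 0 | positive_cells > total_cells))
    stop("positive_cells must lie in [0, total_cells]")
  mean(positive_cells / total_cells)
}

#' Call EGFR amplification status from FISH signal counts
#'
#' Signals are pooled over all cores of a tumor; the tumor-level ratio is
#' total EGFR signals / total CEP7 signals and the call is positive when the
#' ratio is >= 2 (boundary inclusive).
#'
#' @param fishCounts data frame with columns \code{tumor_id},
#'   \code{egfr_signals}, \code{cep7_signals} (see [readFishCounts()]).
#' @return data frame: \code{tumor_id}, \code{egfr_total}, \code{cep7_total},
#'   \code{ratio}, \code{positive}.
#' @examples
#' callEgfrFish(data.frame(tumor_id = "T1", core_id = 1:2,
#'                         egfr_signals = c(25, 15), cep7_signals = c(12, 8)))
#' @export
callEgfrFish <- function(fishCounts) {
  stopifnot(all(c("tumor_id", "egfr_signals", "cep7_signals") %in%
                colnames(fishCounts)))
  tumors <- unique(fishCounts$tumor_id)
  out <- data.frame(tumor_id = tumors,
                    egfr_total = NA_real_, cep7_total = NA_real_,
                    ratio = NA_real_, positive = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(tumors)) {
    rows <- fishCounts$tumor_id == tumors[i]
    e <- sum(fishCounts$egfr_signals[rows])
    c7 <- sum(fishCounts$cep7_signals[rows])
    if (c7 <= 0)
      stop("tumor ", tumors[i],
           ": zero CEP7 signals, hybridization uninterpretable")
    out$egfr_total[i] <- e
    out$cep7_total[i] <- c7
    out$ratio[i] <- e / c7
    out$positive[i] <- (e / c7) >= 2
  }
  out
}

#' Standardize the score matrix for clustering
#'
#' Min-max scales every non-genetic marker by its scheme's theoretical range
#' (not the observed range), so values are comparable across schemes and
#' cohorts; markers flagged \code{is_genetic} (0/1 alteration calls) pass
#' through unchanged. Registry-excluded markers are dropped by default.
#'
#' @param cohort a [GBMCohort-class].
#' @param dropExcluded drop markers with \code{excluded = TRUE} (default TRUE).
#' @return numeric matrix (markers x tumors) with all values in [0, 1].
#' @export
standardizeMatrix <- function(cohort, dropExcluded = TRUE) {
  reg <- markerRegistry(cohort)
  sc <- scoreMatrix(cohort)
  if (dropExcluded) {
    keep <- !reg$excluded
    reg <- reg[keep, , drop = FALSE]
    sc <- sc[keep, , drop = FALSE]
  }
  out <- sc
  for (i in seq_len(nrow(sc))) {
    if (reg$is_genetic[i]) next
    r <- schemeRange(reg$scheme[i])
    out[i, ] <- (sc[i, ] - r[1]) / (r[2] - r[1])
  }
  out
}
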