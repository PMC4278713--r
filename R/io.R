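# Tabular readers/writers. Dialect: UTF-8, tab-separated, mandatory header,
# "." for missing values. Score serialization uses %.17g so numeric round
# trips are bit-exact.

.fmtNum <- function(x) ifelse(is.na(x), ".", sprintf("%.17g", x))

.readTsv <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", na.strings = ".",
                   stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Read per-core marker scores
#'
#' Reads a tab-separated file of raw per-core scores (columns
#' \code{tumor_id}, \code{core_id}, \code{marker}, \code{value}) and validates
#' every row against the marker's scoring scheme. Row order is preserved;
#' duplicate (tumor, core, marker) triples, unknown markers and out-of-scheme
#' values are rejected with the offending file row named. Missing values
#' (\code{"."}) are allowed and represent failed/lost cores.
#'
#' @param path file path.
#' @param registry marker registry (default: shipped panel).
#' @return data frame with the validated rows.
#' @export
readCoreScores <- function(path, registry = defaultMarkerRegistry()) {
  df <- .readTsv(path, c("tumor_id", "core_id", "marker", "value"))
  rowno <- seq_len(nrow(df)) + 1L  # file line numbers (header = line 1)
  unknown <- !(df$marker %in% registry$name)
  if (any(unknown))
    stop("unknown marker '", df$marker[which(unknown)[1]], "' at line ",
         rowno[which(unknown)[1]])
  if (any(!is.finite(df$core_id) | df$core_id < 1 | df$core_id > 4 |
          df$core_id != round(df$core_id)))
    stop("core_id must be an integer in 1..4 (line ",
         rowno[which(!(df$core_id %in% 1:4))[1]], ")")
  key <- paste(df$tumor_id, df$core_id, df$marker, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (tumor, core, marker) triple at line ",
         rowno[which(duplicated(key))[1]])
  df$value <- as.numeric(df$value)
  sch <- registry$scheme[match(df$marker, registry$name)]
  for (i in seq_len(nrow(df))) {
    v <- df$value[i]
    if (is.na(v)) next
    info <- schemeInfo(sch[i])
    ok <- if (is.null(info$values)) v >= info$min && v <= info$max
          else v %in% info$values
    if (!ok)
      stop("value ", v, " not allowed for scheme ", sch[i],
           " (marker ", df$marker[i], ", line ", rowno[i], ")")
  }
  df
}

#' Write aggregated tumor profiles
#'
#' Serializes a [GBMCohort-class] to a tab-separated file: \code{tumor_id},
#' one column per marker, a \code{flags} column (";"-joined quality flags) and,
#' when present, \code{ground_truth}. Scores round-trip bit-exactly through
#' [readProfiles()].
#'
#' @param cohort a \code{GBMCohort}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeProfiles <- function(cohort, path) {
  stopifnot(is(cohort, "GBMCohort"), ncol(cohort) > 0)
  sc <- scoreMatrix(cohort)
  out <- data.frame(tumor_id = colnames(sc), stringsAsFactors = FALSE)
  for (m in rownames(sc)) out[[m]] <- .fmtNum(sc[m, ])
  fl <- tumorFlags(cohort)
  out$flags <- ifelse(nzchar(fl), fl, ".")
  gt <- groundTruth(cohort)
  if (!is.null(gt)) out$ground_truth <- gt
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aggregated tumor profiles
#'
#' Inverse of [writeProfiles()].
#'
#' @param path file path.
#' @param registry marker registry.
#' @return a [GBMCohort-class].
#' @export
readProfiles <- function(path, registry = defaultMarkerRegistry()) {
  df <- .readTsv(path, "tumor_id")
  if (anyDuplicated(df$tumor_id)) stop("duplicate tumor ids in ", path)
  markers <- intersect(colnames(df), registry$name)
  if (!length(markers)) stop("no registered marker columns in ", path)
  sc <- t(as.matrix(df[, markers, drop = FALSE]))
  mode(sc) <- "numeric"
  colnames(sc) <- df$tumor_id
  flags <- if ("flags" %in% colnames(df)) {
    f <- as.character(df$flags); f[is.na(f)] <- ""; f
  } else NULL
  gt <- if ("ground_truth" %in% colnames(df)) as.character(df$ground_truth) else NULL
  GBMCohort(sc, registry, flags = flags, groundTruth = gt)
}

#' Read EGFR/CEP7 FISH signal counts
#'
#' Columns: \code{tumor_id}, \code{core_id}, \code{egfr_signals},
#' \code{cep7_signals} (non-negative counts).
#'
#' @param path file path.
#' @return validated data frame.
#' @export
readFishCounts <- function(path) {
  df <- .readTsv(path, c("tumor_id", "core_id", "egfr_signals", "cep7_signals"))
  for (col in c("egfr_signals", "cep7_signals")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad))
      stop(col, " must be a non-negative count (line ", bad[1] + 1L, ")")
  }
  df
}

#' Read proliferation cell counts
#'
#' Columns: \code{tumor_id}, \code{core_id}, \code{marker} (Ki67 or TOP2A),
#' \code{positive_cells}, \code{total_cells}.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
readProliferationCounts <- function(path) {
  df <- .readTsv(path, c("tumor_id", "core_id", "marker",
                         "positive_cells", "total_cells"))
  bad <- which(!(df$marker %in% c("Ki67", "TOP2A")))
  if (length(bad))
    stop("proliferation marker must be Ki67 or TOP2A (line ", bad[1] + 1L, ")")
  bad <- which(df$positive_cells < 0 | df$positive_cells > df$total_cells)
  if (length(bad))
    stop("positive_cells must lie in [0, total_cells] (line ", bad[1] + 1L, ")")
  df
}

#' Read a qRT-PCR Ct table
#'
#' Comma-separated with columns \code{sample_id}, \code{gene},
#' \code{replicate}, \code{ct}.
#'
#' @param path file path.
#' @return validated data frame.
#' @export
readQpcrCt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "gene", "replicate", "ct")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad)) stop("ct must be positive (line ", bad[1] + 1L, ")")
  df
}
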