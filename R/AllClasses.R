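#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom stats cutree rnorm runif sd setNames wilcox.test
#' @importFrom utils read.delim write.table read.csv
NULL

#' GBMCohort: a scored tumor cohort
#'
#' A container for a cohort of glioblastomas with one aggregated
#' semi-quantitative score per marker and tumor. It extends
#' \linkS4class{SummarizedExperiment}: rows are markers, columns are tumors,
#' and the single assay \code{"scores"} holds the aggregated scores (mean of
#' cores, consensus call, or positive-cell fraction depending on the marker's
#' scoring scheme). \code{rowData} carries the marker registry (scheme,
#' designated subclass, genetic flag, exclusion flag); \code{colData} carries
#' per-tumor quality flags and, for synthetic cohorts, the generating
#' ground-truth subclass.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso [GBMCohort()] for construction, [scoreMatrix()],
#'   [markerRegistry()], [tumorFlags()], [groundTruth()] for access.
#' @export
setClass("GBMCohort", contains = "SummarizedExperiment")

setValidity("GBMCohort", function(object) {
  msg <- character(0)
  if (!"scores" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'scores' is required")
  rd <- SummarizedExperiment::rowData(object)
  need <- c("scheme", "designated_subclass", "is_genetic", "excluded")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "tumor ids (colnames) must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "marker names (rownames) must be unique")
  if (!length(msg) && "scores" %in% SummarizedExperiment::assayNames(object)) {
    sc <- SummarizedExperiment::assay(object, "scores")
    for (i in seq_len(nrow(sc))) {
      info <- schemeInfo(rd$scheme[i])
      v <- sc[i, ]
      v <- v[!is.na(v)]
      if (length(v) && (any(v < info$min) || any(v > info$max)))
        msg <- c(msg, sprintf("marker %s has scores outside [%g, %g]",
                              rownames(sc)[i], info$min, info$max))
      if (length(v) && info$aggregation == "single_consensus" &&
          !all(v %in% info$values))
        msg <- c(msg, sprintf("consensus marker %s has non-consensus values",
                              rownames(sc)[i]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GBMCohort
#'
#' @param scores numeric matrix, markers in rows (rownames = marker names),
#'   tumors in columns (colnames = tumor ids).
#' @param registry marker registry data frame (see [defaultMarkerRegistry()]);
#'   every row of \code{scores} must name a registered marker.
#' @param flags optional character vector of per-tumor quality flags, entries
#'   like \code{"IDH1_R132H:INCONSISTENT_CONSENSUS"} joined by \code{";"}
#'   (\code{""} for none).
#' @param groundTruth optional character vector of generating subclass labels
#'   (synthetic cohorts only).
#' @return a [GBMCohort-class] object.
#' @examples
#' coh <- validationCohortFixture()
#' coh
#' @export
GBMCohort <- function(scores, registry = defaultMarkerRegistry(),
                      flags = NULL, groundTruth = NULL) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)), !is.null(colnames(scores)))
  unknown <- setdiff(rownames(scores), registry$name)
  if (length(unknown))
    stop("markers not in registry: ", paste(unknown, collapse = ", "))
  reg <- registry[match(rownames(scores), registry$name), , drop = FALSE]
  rd <- S4Vectors::DataFrame(reg[, c("scheme", "designated_subclass",
                                     "is_genetic", "excluded")],
                             row.names = rownames(scores))
  n <- ncol(scores)
  if (is.null(flags)) flags <- rep("", n)
  stopifnot(length(flags) == n)
  cd <- S4Vectors::DataFrame(flags = flags, row.names = colnames(scores))
  if (!is.null(groundTruth)) {
    stopifnot(length(groundTruth) == n)
    cd$ground_truth <- groundTruth
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scores = scores), rowData = rd, colData = cd)
  new("GBMCohort", se)
}

#' @describeIn GBMCohort-class matrix of aggregated scores (markers x tumors).
#' @param x a \code{GBMCohort}.
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @export
setMethod("scoreMatrix", "GBMCohort", function(x)
  SummarizedExperiment::assay(x, "scores"))

#' @describeIn GBMCohort-class marker registry as a plain data frame.
#' @export
setGeneric("markerRegistry", function(x) standardGeneric("markerRegistry"))

#' @export
setMethod("markerRegistry", "GBMCohort", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(name = rownames(x),
             scheme = rd$scheme,
             designated_subclass = rd$designated_subclass,
             is_genetic = rd$is_genetic,
             excluded = rd$excluded,
             stringsAsFactors = FALSE)
})

#' @describeIn GBMCohort-class per-tumor quality flag strings.
#' @export
setGeneric("tumorFlags", function(x) standardGeneric("tumorFlags"))

#' @export
setMethod("tumorFlags", "GBMCohort", function(x)
  setNames(SummarizedExperiment::colData(x)$flags, colnames(x)))

#' @describeIn GBMCohort-class generating subclass labels, or NULL.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @export
setMethod("groundTruth", "GBMCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"ground_truth" %in% colnames(cd)) return(NULL)
  setNames(cd$ground_truth, colnames(x))
})

setMethod("show", "GBMCohort", function(object) {
  reg <- markerRegistry(object)
  cat("GBMCohort:", ncol(object), "tumors x", nrow(object), "markers\n")
  cat("  schemes:", paste(sort(unique(reg$scheme)), collapse = ", "), "\n")
  gt <- groundTruth(object)
  if (!is.null(gt))
    cat("  ground truth:",
        paste(sprintf("%s=%d", names(table(gt)), as.integer(table(gt))),
              collapse = " "), "\n")
  nf <- sum(nzchar(SummarizedExperiment::colData(object)$flags))
  if (nf) cat("  tumors with quality flags:", nf, "\n")
})

#' BiclusterResult: two-way clustering of a scored cohort
#'
#' Result of [clusterCohort()]: the standardized marker x tumor matrix after
#' pruning, average-linkage dendrograms for tumors and markers (as
#' \code{hclust} objects), the tumor cluster assignment at the requested cut,
#' cluster-to-subclass labels with enrichment scores, and the per-marker
#' pruning report.
#'
#' @slot standardized standardized score matrix (retained markers x tumors).
#' @slot tumorDendrogram,markerDendrogram \code{hclust} objects.
#' @slot tumorClusters named integer vector, tumor id -> cluster id.
#' @slot clusterLabels data frame: cluster, n, label, enrichment plus one
#'   enrichment column per candidate subclass.
#' @slot prunedMarkers data frame: marker, stage, detail for every pruned
#'   marker.
#' @export
setClass("BiclusterResult",
         representation(standardized = "matrix",
                        tumorDendrogram = "ANY",
                        markerDendrogram = "ANY",
                        tumorClusters = "integer",
                        clusterLabels = "data.frame",
                        prunedMarkers = "data.frame"))

#' @describeIn BiclusterResult-class tumor -> cluster assignment.
#' @param x a \code{BiclusterResult}.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))

#' @export
setMethod("clusterAssignments", "BiclusterResult", function(x) x@tumorClusters)

#' @describeIn BiclusterResult-class cluster label table.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @export
setMethod("clusterLabels", "BiclusterResult", function(x) x@clusterLabels)

#' @describeIn BiclusterResult-class pruning report.
#' @export
setGeneric("prunedMarkers", function(x) standardGeneric("prunedMarkers"))

#' @export
setMethod("prunedMarkers", "BiclusterResult", function(x) x@prunedMarkers)

setMethod("show", "BiclusterResult", function(object) {
  cat("BiclusterResult:", length(object@tumorClusters), "tumors,",
      nrow(object@standardized), "retained markers,",
      length(unique(object@tumorClusters)), "clusters\n")
  lab <- object@clusterLabels
  for (i in seq_len(nrow(lab)))
    cat(sprintf("  cluster %d (n=%d): %s (enrichment %.3f)\n",
                lab$cluster[i], lab$n[i], lab$label[i], lab$enrichment[i]))
  if (nrow(object@prunedMarkers))
    cat("  pruned markers:",
        paste(object@prunedMarkers$marker, collapse = ", "), "\n")
})
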