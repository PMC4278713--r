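# End-to-end orchestration: score -> cluster -> index -> assign (-> metagene),
# writing every intermediate artifact plus a machine-readable summary and the
# full effective parameter set, so that each reported number is recomputable
# from the emitted files.

#' Run the subclassification pipeline
#'
#' Stages, in order: aggregate per-core scores (when a core-score table is
#' given), bicluster the standardized matrix, compute the PN/MES index, and
#' apply the three-step assignment scheme; optionally score a qRT-PCR Ct
#' table against the assigned labels. Artifacts written to \code{outDir}:
#' \code{profiles.tsv}, \code{clusters.tsv}, \code{tumor_dendrogram.nwk},
#' \code{marker_dendrogram.nwk}, \code{pruned_markers.tsv}, \code{index.tsv},
#' \code{calls.tsv}, optionally \code{metagene.tsv}, and \code{summary.json}
#' (assignment rates, cluster labels, index class counts and all effective
#' parameters). Deterministic stages are byte-identical across reruns.
#'
#' @param input a [GBMCohort-class], a profiles TSV path, or a core-score
#'   TSV path (\code{inputType} disambiguates files).
#' @param outDir output directory (created if needed).
#' @param inputType \code{"cohort"}, \code{"profiles"} or \code{"cores"}.
#' @param registry marker registry.
#' @param k tumor clusters (default 3).
#' @param threshold cluster-labelling enrichment threshold (default 0.25).
#' @param mesThreshold MES-high threshold for assignment (default 0.75).
#' @param lower,upper PN/MES index class thresholds (defaults -1, +1).
#' @param ctPath optional qRT-PCR Ct CSV for the metagene stage.
#' @param cluster set FALSE to skip the clustering stage.
#' @return invisibly, a list with the cohort, bicluster result, index table,
#'   calls, summary list and the summary.json path.
#' @export
runPipeline <- function(input, outDir,
                        inputType = c("cohort", "profiles", "cores"),
                        registry = defaultMarkerRegistry(),
                        k = 3, threshold = 0.25, mesThreshold = 0.75,
                        lower = -1, upper = 1, ctPath = NULL,
                        cluster = TRUE) {
  inputType <- match.arg(inputType)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("score", switch(inputType,
    cohort = {
      if (!is(input, "GBMCohort")) stop("expected a GBMCohort")
      input
    },
    profiles = readProfiles(input, registry),
    cores = aggregateCohort(readCoreScores(input, registry), registry)))
  writeProfiles(cohort, file.path(outDir, "profiles.tsv"))

  bic <- NULL
  if (cluster) {
    bic <- stage("cluster", clusterCohort(cohort, k = k, threshold = threshold))
    cl <- clusterAssignments(bic)
    write.table(data.frame(tumor_id = names(cl), cluster = cl),
                file.path(outDir, "clusters.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(prunedMarkers(bic), file.path(outDir, "pruned_markers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    dendrogramToNewick(bic@tumorDendrogram,
                       file.path(outDir, "tumor_dendrogram.nwk"))
    dendrogramToNewick(bic@markerDendrogram,
                       file.path(outDir, "marker_dendrogram.nwk"))
  }

  idx <- stage("index", indexDistributionReport(cohort, lower, upper))
  write.table(idx, file.path(outDir, "index.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- stage("assign", assignSubclass(cohort, mesThreshold = mesThreshold))
  write.table(calls, file.path(outDir, "calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarizeAssignments(calls)

  meta <- NULL
  if (!is.null(ctPath)) {
    meta <- stage("metagene", {
      dct <- deltaCt(readQpcrCt(ctPath))
      metageneScores(dct,
                     ihcLabels = setNames(calls$subclass, calls$tumor_id))
    })
    write.table(meta, file.path(outDir, "metagene.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  summary <- list(
    n_tumors = summ$n_total,
    assignment_counts = as.list(summ$counts),
    assignment_percentages = as.list(summ$percentages),
    index_class_counts = as.list(setNames(
      as.integer(attr(idx, "class_counts")),
      names(attr(idx, "class_counts")))),
    cluster_labels = if (!is.null(bic))
      setNames(as.list(clusterLabels(bic)$label),
               paste0("cluster_", clusterLabels(bic)$cluster)) else NULL,
    pruned_markers = if (!is.null(bic)) prunedMarkers(bic)$marker else NULL,
    parameters = list(k = k, enrichment_threshold = threshold,
                      mes_high_threshold = mesThreshold,
                      index_lower = lower, index_upper = upper))
  jsonPath <- file.path(outDir, "summary.json")
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(list(cohort = cohort, bicluster = bic, index = idx,
                 calls = calls, summary = summary, summary_path = jsonPath))
}
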