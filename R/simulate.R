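# Synthetic cohort and qPCR generators. All generators are pure functions of
# (config, seed); each tumor/sample draws from its own seeded substream, so
# the first n tumors of a larger cohort equal a smaller cohort generated with
# the same seed.

.substream <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + i * 7919
  as.integer(s %% 2147483646 + 1)
}

#' Default per-subclass marker emission distributions
#'
#' Categorical distributions over raw scheme values (named probability
#' vectors) for every marker and generating subclass, plus uniform ranges
#' \code{c(min, max)} for the continuous proliferation fractions. Defining
#' markers are emitted deterministically at their characteristic category
#' (IDH1 R132H for PN, EGFR for CLAS, VIM and YKL40 for MES), so noise-free
#' cohorts are perfectly separable - a deliberate idealization for recovery
#' testing. PN tumors emit no EGFR features and no high MES scores (mutual
#' exclusivity); CLAS tumors emit high MES markers with appreciable
#' probability, since MES co-expression in CLAS tumors is common.
#'
#' @return nested list: subclass -> marker -> distribution.
#' @export
defaultEmissions <- function() {
  list(
    PN = list(
      IDH1_R132H = c("1" = 1),
      EGFR = c("0" = 1), EGFRvIII = c("0" = 1), EGFR_FISH = c("0" = 1),
      p53 = c("1" = 0.15, "2" = 0.85),
      OLIG2 = c("1" = 0.1, "2" = 0.3, "3" = 0.6),
      PDGFRA = c("1" = 0.5, "2" = 0.5),
      DLL3 = c("1" = 1),
      PTEN = c("0" = 1), VIM = c("0" = 1), YKL40 = c("1" = 1),
      CD44 = c("0" = 0.7, "1" = 0.3), FN1 = c("0" = 0.8, "1" = 0.2),
      MET = c("0" = 0.8, "1" = 0.2),
      NES = c("1" = 0.8, "2" = 0.2), NF1 = c("1" = 0.8, "2" = 0.2),
      STAT3 = c("1" = 0.8, "2" = 0.2), GFAP = c("1" = 0.5, "2" = 0.5),
      CHGA = c("0" = 0.5, "1" = 0.3, "2" = 0.2),
      NeuN = c("0" = 0.4, "1" = 0.3, "2" = 0.3),
      NEFL = c("0" = 0.5, "1" = 0.3, "2" = 0.2),
      SYP = c("0" = 0.4, "1" = 0.4, "2" = 0.2),
      Ki67 = c(min = 0.05, max = 0.30), TOP2A = c(min = 0.02, max = 0.25)),
    CLAS = list(
      IDH1_R132H = c("0" = 1),
      EGFR = c("1" = 1),
      EGFRvIII = c("0" = 0.54, "1" = 0.46),
      EGFR_FISH = c("0" = 0.17, "1" = 0.83),
      p53 = c("0" = 0.35, "1" = 0.55, "2" = 0.1),
      OLIG2 = c("0" = 0.5, "1" = 0.4, "2" = 0.1),
      PDGFRA = c("1" = 0.85, "2" = 0.15),
      DLL3 = c("1" = 1),
      PTEN = c("0" = 0.3, "1" = 0.4, "2" = 0.3),
      VIM = c("0" = 0.25, "1" = 0.4, "2" = 0.35),
      YKL40 = c("1" = 0.7, "2" = 0.3),
      CD44 = c("0" = 0.3, "1" = 0.4, "2" = 0.2, "3" = 0.1),
      FN1 = c("0" = 0.5, "1" = 0.4, "2" = 0.1),
      MET = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
      NES = c("1" = 0.6, "2" = 0.4), NF1 = c("1" = 0.7, "2" = 0.3),
      STAT3 = c("1" = 0.7, "2" = 0.3), GFAP = c("1" = 0.6, "2" = 0.4),
      CHGA = c("0" = 0.7, "1" = 0.3),
      NeuN = c("0" = 0.6, "1" = 0.4),
      NEFL = c("0" = 0.7, "1" = 0.3),
      SYP = c("0" = 0.5, "1" = 0.4, "2" = 0.1),
      Ki67 = c(min = 0.10, max = 0.50), TOP2A = c(min = 0.05, max = 0.40)),
    MES = list(
      IDH1_R132H = c("0" = 1),
      EGFR = c("0" = 1), EGFRvIII = c("0" = 1), EGFR_FISH = c("0" = 1),
      p53 = c("0" = 0.5, "1" = 0.4, "2" = 0.1),
      OLIG2 = c("0" = 0.6, "1" = 0.4),
      PDGFRA = c("1" = 0.8, "2" = 0.2),
      DLL3 = c("1" = 1),
      PTEN = c("1" = 0.2, "2" = 0.8),
      VIM = c("2" = 1), YKL40 = c("2" = 1),
      CD44 = c("2" = 0.2, "3" = 0.8), FN1 = c("1" = 0.3, "2" = 0.7),
      MET = c("1" = 0.3, "2" = 0.7),
      NES = c("1" = 0.3, "2" = 0.7), NF1 = c("1" = 0.4, "2" = 0.6),
      STAT3 = c("1" = 0.4, "2" = 0.6), GFAP = c("1" = 0.2, "2" = 0.8),
      CHGA = c("0" = 0.8, "1" = 0.2),
      NeuN = c("0" = 0.8, "1" = 0.2),
      NEFL = c("0" = 0.8, "1" = 0.2),
      SYP = c("0" = 0.7, "1" = 0.3),
      Ki67 = c(min = 0.10, max = 0.60), TOP2A = c(min = 0.05, max = 0.50)),
    OTHER = list(
      IDH1_R132H = c("0" = 1),
      EGFR = c("0" = 1), EGFRvIII = c("0" = 1), EGFR_FISH = c("0" = 1),
      p53 = c("0" = 0.5, "1" = 0.4, "2" = 0.1),
      OLIG2 = c("0" = 0.4, "1" = 0.4, "2" = 0.2),
      PDGFRA = c("1" = 0.8, "2" = 0.2),
      DLL3 = c("1" = 1),
      PTEN = c("0" = 0.55, "1" = 0.35, "2" = 0.10),
      VIM = c("0" = 0.5, "1" = 0.4, "2" = 0.1),
      YKL40 = c("1" = 0.9, "2" = 0.1),
      CD44 = c("0" = 0.4, "1" = 0.4, "2" = 0.2),
      FN1 = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
      MET = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
      NES = c("1" = 0.7, "2" = 0.3), NF1 = c("1" = 0.7, "2" = 0.3),
      STAT3 = c("1" = 0.7, "2" = 0.3), GFAP = c("1" = 0.5, "2" = 0.5),
      CHGA = c("0" = 0.5, "1" = 0.3, "2" = 0.2),
      NeuN = c("0" = 0.5, "1" = 0.3, "2" = 0.2),
      NEFL = c("0" = 0.6, "1" = 0.3, "2" = 0.1),
      SYP = c("0" = 0.5, "1" = 0.3, "2" = 0.2),
      Ki67 = c(min = 0.05, max = 0.45), TOP2A = c(min = 0.02, max = 0.40))
  )
}

#' Build a cohort generator configuration
#'
#' @param n_tumors number of tumors.
#' @param proportions subclass probabilities (must sum to 1); the default
#'   mirrors the observed training assignment rates.
#' @param emissions per-subclass emission distributions
#'   (default [defaultEmissions()]).
#' @param core_noise probability that an individual core's score deviates by
#'   one category (default 0.05).
#' @param cores_per_tumor biopsies per tumor (default 4).
#' @param seed RNG seed.
#' @param markers optional subset of markers to emit (default: full panel).
#' @param registry marker registry.
#' @return validated config list for [generateCohort()].
#' @export
cohortConfig <- function(n_tumors,
                         proportions = c(PN = 0.05, CLAS = 0.42,
                                         MES = 0.15, OTHER = 0.38),
                         emissions = defaultEmissions(),
                         core_noise = 0.05, cores_per_tumor = 4,
                         seed = 1, markers = NULL,
                         registry = defaultMarkerRegistry()) {
  stopifnot(n_tumors >= 1, cores_per_tumor >= 1)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("subclass proportions must be non-negative and sum to 1")
  if (core_noise < 0 || core_noise > 1)
    stop("core_noise must be a probability")
  for (sc in names(proportions)) {
    if (proportions[sc] > 0 && is.null(emissions[[sc]]))
      stop("no emission distributions for subclass ", sc)
    for (m in names(emissions[[sc]])) {
      p <- emissions[[sc]][[m]]
      if (!all(c("min", "max") %in% names(p)) &&
          abs(sum(p) - 1) > 1e-8)
        stop("emission for ", sc, "/", m, " does not sum to 1")
    }
  }
  if (is.null(markers)) markers <- registry$name
  list(n_tumors = n_tumors, proportions = proportions, emissions = emissions,
       core_noise = core_noise, cores_per_tumor = cores_per_tumor,
       seed = seed, markers = markers, registry = registry)
}

# one-category noise step within a scheme: move +/-1 level (inward at the
# boundary); fractions get a +/-0.05 nudge clamped to [0, 1]
.perturbCore <- function(v, info) {
  if (is.null(info$values)) {
    return(min(info$max, max(info$min, v + sample(c(-0.05, 0.05), 1))))
  }
  lv <- info$values
  i <- match(v, lv)
  j <- i + sample(c(-1L, 1L), 1)
  if (j < 1L) j <- 2L
  if (j > length(lv)) j <- length(lv) - 1L
  lv[j]
}

#' Generate a synthetic scored cohort
#'
#' Draws each tumor's subclass from \code{proportions}, then per-core raw
#' scores from that subclass's emission distributions. Consensus (binary
#' alteration) markers are drawn once per tumor and emitted identically
#' across cores; \code{core_noise} independently perturbs each core by one
#' category, which is what creates inconsistent consensus calls and
#' fractional means downstream. Reproducible given the seed, and stable
#' under subsetting (tumor i is identical in any cohort with the same seed).
#'
#' @param config from [cohortConfig()].
#' @return list with \code{cores} (per-core score table), \code{truth}
#'   (data frame tumor_id/subclass) and \code{cohort} (the aggregated
#'   [GBMCohort-class] with ground truth attached).
#' @export
generateCohort <- function(config) {
  reg <- config$registry
  markers <- config$markers
  sch <- setNames(reg$scheme, reg$name)
  unknown <- setdiff(markers, reg$name)
  if (length(unknown)) stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  nc <- config$cores_per_tumor
  rows <- vector("list", config$n_tumors)
  truth <- character(config$n_tumors)
  ids <- sprintf("SIM%04d", seq_len(config$n_tumors))
  for (i in seq_len(config$n_tumors)) {
    set.seed(.substream(config$seed, i))
    sc <- sample(names(config$proportions), 1, prob = config$proportions)
    truth[i] <- sc
    em <- config$emissions[[sc]]
    vals <- matrix(NA_real_, length(markers), nc)
    for (mi in seq_along(markers)) {
      m <- markers[mi]
      p <- em[[m]]
      if (is.null(p)) stop("no emission for ", sc, "/", m)
      info <- schemeInfo(sch[[m]])
      if (all(c("min", "max") %in% names(p))) {
        base <- runif(1, p[["min"]], p[["max"]])
        core <- rep(base, nc)
      } else if (info$aggregation == "single_consensus") {
        core <- rep(as.numeric(sample(names(p), 1, prob = p)), nc)
      } else {
        core <- as.numeric(sample(names(p), nc, replace = TRUE, prob = p))
      }
      if (config$core_noise > 0) {
        flip <- runif(nc) < config$core_noise
        for (k in which(flip)) core[k] <- .perturbCore(core[k], info)
      }
      vals[mi, ] <- core
    }
    rows[[i]] <- data.frame(
      tumor_id = ids[i],
      core_id = rep(seq_len(nc), each = length(markers)),
      marker = rep(markers, nc),
      value = as.vector(vals),
      stringsAsFactors = FALSE)
  }
  cores <- do.call(rbind, rows)
  truthDf <- data.frame(tumor_id = ids, subclass = truth,
                        stringsAsFactors = FALSE)
  cohort <- aggregateCohort(cores, reg, groundTruth = setNames(truth, ids))
  list(cores = cores, truth = truthDf, cohort = cohort)
}

#' Generate a synthetic qRT-PCR Ct table
#'
#' Emulates the 9-gene PN/MES fingerprint experiment: a reference gene with
#' constant baseline Ct, and signature genes whose Ct is shifted down by
#' \code{separation}/2 cycles in samples of the matching subclass and up by
#' the same amount in the opposite subclass (group difference =
#' \code{separation} cycles). Triplicates carry independent Gaussian noise.
#' Sample substreams make the table stable under changing group sizes.
#'
#' @param n_pn,n_mes samples per group (default 10 each).
#' @param separation group delta-Ct difference in cycles (default 2).
#' @param replicate_sd replicate noise sd in cycles (default 0.2).
#' @param seed RNG seed.
#' @param base_ct baseline Ct of signature genes (default 26).
#' @param reference_ct reference gene Ct (default 20).
#' @param signature gene signature map.
#' @return Ct table (sample_id, gene, replicate, ct) with a
#'   \code{labels} attribute mapping sample id to generating subclass.
#' @export
generateQpcr <- function(n_pn = 10, n_mes = 10, separation = 2,
                         replicate_sd = 0.2, seed = 1,
                         base_ct = 26, reference_ct = 20,
                         signature = defaultQpcrSignature()) {
  stopifnot(n_pn >= 1, n_mes >= 1, replicate_sd >= 0)
  ids <- c(sprintf("PN_%02d", seq_len(n_pn)),
           sprintf("MES_%02d", seq_len(n_mes)))
  labels <- setNames(rep(c("PN", "MES"), c(n_pn, n_mes)), ids)
  genes <- c(signature$PN, signature$MES, signature$reference)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    set.seed(.substream(seed, i))
    lab <- labels[[i]]
    mu <- vapply(genes, function(g) {
      if (g == signature$reference) return(reference_ct)
      own <- (g %in% signature$PN && lab == "PN") ||
             (g %in% signature$MES && lab == "MES")
      base_ct + if (own) -separation / 2 else separation / 2
    }, numeric(1))
    ct <- rep(mu, each = 3) + rnorm(3 * length(genes), 0, replicate_sd)
    rows[[i]] <- data.frame(sample_id = ids[i],
                            gene = rep(genes, each = 3),
                            replicate = rep(1:3, length(genes)),
                            ct = ct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}
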