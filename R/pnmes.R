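# The PN/MES index: recoding of the five index markers, totals, and the
# strict +/-1 classification thresholds.
#
# Recoding maps are linear rescalings of each scheme's full range onto the
# stated target ranges (PN markers onto 0-1.5, MES markers onto 0-1), applied
# to per-core mean scores so fractional inputs recode continuously. Both
# totals attain a maximum of exactly 3.

#' Recode the PN index markers
#'
#' IDH1 R132H (consensus 0/1) maps to \{0, 1.5\}; p53 (triad mean in [0, 2])
#' maps linearly onto [0, 1.5].
#'
#' @param idh1 consensus alteration call(s), 0 or 1.
#' @param p53 aggregated triad score(s) in [0, 2].
#' @return matrix with columns \code{IDH1_R132H} and \code{p53}.
#' @examples
#' recodePn(1, 2)      # 1.5, 1.5 - the attainable maximum, total 3
#' recodePn(0, 1.25)   # 0, 0.9375
#' @export
recodePn <- function(idh1, p53) {
  if (any(!(idh1 %in% c(0, 1)))) stop("idh1 must be a 0/1 consensus call")
  if (any(p53 < 0 | p53 > 2)) stop("p53 must lie in [0, 2]")
  cbind(IDH1_R132H = 1.5 * idh1, p53 = 0.75 * p53)
}

#' Recode the MES index markers
#'
#' PTEN and VIM (triad means in [0, 2]) map onto [0, 1] by halving; YKL40
#' (basal scheme mean in [1, 2]) maps onto [0, 1] by subtracting the basal
#' level.
#'
#' @param pten,vim aggregated triad scores in [0, 2].
#' @param ykl40 aggregated basal-scheme scores in [1, 2].
#' @return matrix with columns \code{PTEN}, \code{VIM}, \code{YKL40}.
#' @examples
#' recodeMes(2, 2, 2)          # 1, 1, 1 - the attainable maximum, total 3
#' recodeMes(1.5, 1, 1.75)     # 0.75, 0.5, 0.75
#' @export
recodeMes <- function(pten, vim, ykl40) {
  if (any(pten < 0 | pten > 2)) stop("pten must lie in [0, 2]")
  if (any(vim < 0 | vim > 2)) stop("vim must lie in [0, 2]")
  if (any(ykl40 < 1 | ykl40 > 2)) stop("ykl40 must lie in [1, 2]")
  cbind(PTEN = pten / 2, VIM = vim / 2, YKL40 = ykl40 - 1)
}

.indexClass <- function(index, lower = -1, upper = 1) {
  ifelse(index > upper, "PN", ifelse(index < lower, "MES", "UNASSIGNED"))
}

#' PN/MES index of a scored cohort
#'
#' The index is the PN total (recoded IDH1 R132H + p53, each in [0, 1.5])
#' minus the MES total (recoded PTEN + VIM + YKL40, each in [0, 1]); both
#' totals have maximum 3, so the index lies in [-3, 3]. Classification uses
#' strict thresholds: PN when index > \code{upper}, MES when index <
#' \code{lower}, otherwise UNASSIGNED.
#'
#' @param cohort a [GBMCohort-class] containing the five index markers.
#' @param lower,upper classification thresholds (defaults -1 and +1, strict).
#' @return data frame with recoded components, totals, \code{index} and
#'   \code{index_class} per tumor.
#' @export
pnmesIndex <- function(cohort, lower = -1, upper = 1) {
  sc <- scoreMatrix(cohort)
  need <- c("IDH1_R132H", "p53", "PTEN", "VIM", "YKL40")
  miss <- setdiff(need, rownames(sc))
  if (length(miss))
    stop("cohort lacks index marker(s): ", paste(miss, collapse = ", "))
  bad <- need[apply(is.na(sc[need, , drop = FALSE]), 1, any)]
  if (length(bad))
    stop("missing scores for index marker(s): ", paste(bad, collapse = ", "))
  pn <- recodePn(sc["IDH1_R132H", ], sc["p53", ])
  mes <- recodeMes(sc["PTEN", ], sc["VIM", ], sc["YKL40", ])
  pn_total <- rowSums(pn)
  mes_total <- rowSums(mes)
  index <- pn_total - mes_total
  data.frame(tumor_id = colnames(sc),
             pn_idh1 = pn[, "IDH1_R132H"], pn_p53 = pn[, "p53"],
             mes_pten = mes[, "PTEN"], mes_vim = mes[, "VIM"],
             mes_ykl40 = mes[, "YKL40"],
             pn_total = pn_total, mes_total = mes_total,
             index = index,
             index_class = .indexClass(index, lower, upper),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Index distribution report with aligned CLAS-feature flags
#'
#' Orders tumors by descending PN/MES index and aligns the Classical-subtype
#' features (high EGFR expression, EGFR amplification by FISH, EGFRvIII)
#' under the index, the layout used to inspect where CLAS tumors fall along
#' the PN-MES axis. Every tumor appears exactly once; the per-class counts
#' (attribute \code{class_counts}) sum to the cohort size.
#'
#' @param cohort a [GBMCohort-class].
#' @param lower,upper index thresholds passed to [pnmesIndex()].
#' @return data frame sorted by descending index with logical columns
#'   \code{egfr_high}, \code{egfr_amplified}, \code{egfrviii}; class counts
#'   in \code{attr(, "class_counts")}.
#' @export
indexDistributionReport <- function(cohort, lower = -1, upper = 1) {
  idx <- pnmesIndex(cohort, lower, upper)
  sc <- scoreMatrix(cohort)
  flag <- function(m) if (m %in% rownames(sc))
    as.logical(sc[m, idx$tumor_id] == 1) else rep(NA, nrow(idx))
  idx$egfr_high <- flag("EGFR")
  idx$egfr_amplified <- flag("EGFR_FISH")
  idx$egfrviii <- flag("EGFRvIII")
  ord <- order(-idx$index, idx$tumor_id)
  idx <- idx[ord, , drop = FALSE]
  rownames(idx) <- NULL
  counts <- table(factor(idx$index_class, c("PN", "UNASSIGNED", "MES")))
  stopifnot(sum(counts) == nrow(idx))
  attr(idx, "class_counts") <- counts
  idx
}
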