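# The ordered three-step subclass assignment scheme and cohort summaries.
#
# Canonical order: (1) IDH1 R132H positive -> PN; (2) high EGFR expression
# -> CLAS; (3) two or more of PTEN/VIM/YKL40 highly expressed -> MES;
# otherwise UNCLASSIFIED. The order matters: PN features are mutually
# exclusive with CLAS and MES markers, while MES markers co-occur in CLAS
# tumors, so evaluating MES before CLAS would flip those tumors.

.MES_INDEX_MARKERS <- c("PTEN", "VIM", "YKL40")

.recodeMesOne <- function(marker, score) {
  switch(marker,
         PTEN = recodeMes(score, 0, 1)[, "PTEN"],
         VIM = recodeMes(0, score, 1)[, "VIM"],
         YKL40 = recodeMes(0, 0, score)[, "YKL40"],
         stop("not a MES index marker: ", marker))
}

#' Is a MES index marker highly expressed?
#'
#' "High" means the recoded score (PTEN, VIM: score/2; YKL40: score - 1)
#' reaches \code{threshold}; the default 0.75 demands a core majority at the
#' top scoring category. Boundary inclusive.
#'
#' @param marker one of PTEN, VIM, YKL40.
#' @param score aggregated raw score(s) within the marker's scheme range.
#' @param threshold recoded-scale threshold (default 0.75).
#' @return logical.
#' @examples
#' isMesHigh("PTEN", 2)     # TRUE
#' isMesHigh("YKL40", 1)    # FALSE (basal level)
#' isMesHigh("VIM", 1.5)    # TRUE, boundary inclusive
#' @export
isMesHigh <- function(marker, score, threshold = 0.75) {
  .recodeMesOne(marker, score) >= threshold
}

#' Assign subclasses by the ordered three-step scheme
#'
#' Evaluates the three rules strictly in \code{order} and stops at the first
#' that fires. Exactly one rule (possibly none) fires per tumor.
#'
#' @param cohort a [GBMCohort-class] containing IDH1_R132H, EGFR and the
#'   three MES index markers; a missing marker or score is an error naming
#'   it.
#' @param order permutation of \code{c("PN", "CLAS", "MES")}; the canonical
#'   order is the default.
#' @param mesThreshold recoded-scale MES-high threshold (default 0.75).
#' @return data frame: \code{tumor_id}, \code{subclass} (PN, CLAS, MES or
#'   UNCLASSIFIED), \code{rule_fired} (IDH1_POSITIVE, EGFR_HIGH,
#'   MES_TWO_OF_THREE or NONE) and \code{mes_high_markers} (comma-joined).
#' @export
assignSubclass <- function(cohort, order = c("PN", "CLAS", "MES"),
                           mesThreshold = 0.75) {
  if (length(order) != 3 || !setequal(order, c("PN", "CLAS", "MES")))
    stop("order must be a permutation of PN, CLAS, MES")
  sc <- scoreMatrix(cohort)
  need <- c("IDH1_R132H", "EGFR", .MES_INDEX_MARKERS)
  miss <- setdiff(need, rownames(sc))
  if (length(miss))
    stop("cohort lacks required marker(s): ", paste(miss, collapse = ", "))
  bad <- need[apply(is.na(sc[need, , drop = FALSE]), 1, any)]
  if (length(bad))
    stop("missing scores for required marker(s): ", paste(bad, collapse = ", "))
  mesHigh <- vapply(.MES_INDEX_MARKERS, function(m)
    isMesHigh(m, sc[m, ], mesThreshold), logical(ncol(sc)))
  if (ncol(sc) == 1) mesHigh <- matrix(mesHigh, nrow = 1,
                                       dimnames = list(NULL, .MES_INDEX_MARKERS))
  n <- ncol(sc)
  subclass <- rep("UNCLASSIFIED", n)
  rule <- rep("NONE", n)
  undecided <- rep(TRUE, n)
  for (step in order) {
    fires <- switch(step,
                    PN = sc["IDH1_R132H", ] == 1,
                    CLAS = sc["EGFR", ] == 1,
                    MES = rowSums(mesHigh) >= 2)
    hit <- undecided & fires
    subclass[hit] <- step
    rule[hit] <- switch(step, PN = "IDH1_POSITIVE", CLAS = "EGFR_HIGH",
                        MES = "MES_TWO_OF_THREE")
    undecided <- undecided & !hit
  }
  data.frame(tumor_id = colnames(sc), subclass = subclass, rule_fired = rule,
             mes_high_markers = apply(mesHigh, 1, function(z)
               paste(.MES_INDEX_MARKERS[z], collapse = ",")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# nearest integer, half away from zero
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize subclass calls
#'
#' @param calls data frame from [assignSubclass()].
#' @return list with \code{n_total}, integer \code{counts} and nearest-integer
#'   \code{percentages} (half rounded away from zero) per subclass; counts
#'   sum to \code{n_total}.
#' @examples
#' coh <- validationCohortFixture()
#' summarizeAssignments(assignSubclass(coh))
#' @export
summarizeAssignments <- function(calls) {
  stopifnot(nrow(calls) > 0)
  lev <- c("PN", "CLAS", "MES", "UNCLASSIFIED")
  counts <- table(factor(calls$subclass, lev))
  n <- nrow(calls)
  stopifnot(sum(counts) == n)
  pct <- .roundHalfAway(100 * as.numeric(counts) / n)
  list(n_total = n,
       counts = setNames(as.integer(counts), lev),
       percentages = setNames(as.numeric(pct), lev))
}

#' Sensitivity of calls to the assignment order
#'
#' Re-runs the scheme under an alternative step order and reports which
#' tumors change subclass. With MES evaluated before CLAS, exactly the
#' EGFR-high tumors with two or more high MES markers flip CLAS -> MES.
#'
#' @param cohort a [GBMCohort-class].
#' @param order alternative permutation of \code{c("PN", "CLAS", "MES")}.
#' @param mesThreshold MES-high threshold.
#' @return list with \code{canonical} and \code{alternative} call tables and
#'   \code{changed}, the tumor ids whose subclass differs.
#' @export
orderSensitivity <- function(cohort, order, mesThreshold = 0.75) {
  canonical <- assignSubclass(cohort, mesThreshold = mesThreshold)
  alternative <- assignSubclass(cohort, order = order,
                                mesThreshold = mesThreshold)
  changed <- canonical$tumor_id[canonical$subclass != alternative$subclass]
  list(canonical = canonical, alternative = alternative, changed = changed)
}
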