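# The 9-gene qRT-PCR PN/MES fingerprint: delta-Ct normalization, group
# expression ratios, and the Z-corrected metagene score.

#' Default 9-gene PN/MES signature
#'
#' @return list with \code{PN} genes (ASCL1, DLL3, NCAM1, OLIG2), \code{MES}
#'   genes (CHI3L1, SERPINE1, TGFB1, TIMP1) and the \code{reference} gene
#'   (RPS27).
#' @export
defaultQpcrSignature <- function() {
  list(PN = c("ASCL1", "DLL3", "NCAM1", "OLIG2"),
       MES = c("CHI3L1", "SERPINE1", "TGFB1", "TIMP1"),
       reference = "RPS27")
}

#' Delta-Ct normalization
#'
#' Per sample, each gene's replicate-mean Ct minus the reference gene's
#' replicate-mean Ct. Lower delta-Ct means higher expression. The reference
#' gene is excluded from the output. Samples with fewer than
#' \code{minReplicates} replicates for a gene are flagged
#' \code{LOW_REPLICATES}, not dropped.
#'
#' @param ct Ct table: \code{sample_id}, \code{gene}, \code{replicate},
#'   \code{ct} (see [readQpcrCt()]).
#' @param reference reference gene name (default RPS27).
#' @param minReplicates expected replicates per sample/gene (default 3).
#' @return data frame: \code{sample_id}, \code{gene}, \code{n_replicates},
#'   \code{delta_ct}, \code{flag}.
#' @examples
#' ct <- data.frame(sample_id = "S1", gene = c("ASCL1", "RPS27"),
#'                  replicate = 1, ct = c(25, 20))
#' deltaCt(ct)$delta_ct   # 5
#' @export
deltaCt <- function(ct, reference = "RPS27", minReplicates = 3) {
  stopifnot(all(c("sample_id", "gene", "ct") %in% colnames(ct)))
  out <- list()
  for (s in unique(ct$sample_id)) {
    sub <- ct[ct$sample_id == s, , drop = FALSE]
    refCt <- sub$ct[sub$gene == reference]
    if (!length(refCt))
      stop("sample ", s, ": reference gene ", reference, " missing")
    refMean <- mean(refCt)
    genes <- setdiff(unique(sub$gene), reference)
    for (g in genes) {
      v <- sub$ct[sub$gene == g]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, gene = g, n_replicates = length(v),
        delta_ct = mean(v) - refMean,
        flag = if (length(v) < minReplicates) "LOW_REPLICATES" else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Wide sample x gene delta-Ct matrix
#'
#' @param dct long table from [deltaCt()].
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
deltaCtMatrix <- function(dct) {
  samples <- unique(dct$sample_id)
  genes <- unique(dct$gene)
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  m[cbind(match(dct$sample_id, samples), match(dct$gene, genes))] <- dct$delta_ct
  m
}

#' Fold expression ratio of group B relative to group A
#'
#' Standard delta-delta-Ct exponentiation (100% efficiency assumed):
#' \eqn{2^{\bar{\Delta Ct}_A - \bar{\Delta Ct}_B}}, with group A as the unit
#' reference. A rank-based two-group comparison (Wilcoxon/Mann-Whitney) is
#' reported alongside.
#'
#' @param dct long delta-Ct table from [deltaCt()].
#' @param samplesA,samplesB sample ids of the two groups (A is the unit
#'   reference).
#' @param gene gene to compare.
#' @return list with \code{gene}, \code{ratio} and \code{p_value}.
#' @export
groupExpressionRatio <- function(dct, samplesA, samplesB, gene) {
  a <- dct$delta_ct[dct$gene == gene & dct$sample_id %in% samplesA]
  b <- dct$delta_ct[dct$gene == gene & dct$sample_id %in% samplesB]
  if (!length(a) || !length(b)) stop("empty group for gene ", gene)
  p <- if (length(a) > 1 && length(b) > 1)
    suppressWarnings(wilcox.test(a, b)$p.value) else NA_real_
  list(gene = gene, ratio = 2^(mean(a) - mean(b)), p_value = p)
}

.zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("zero variance across samples; Z-score undefined")
  (x - mean(x)) / s
}

#' Metagene scores from delta-Ct values
#'
#' Per sample, the inverse delta-Ct (negation by default: monotone in log2
#' expression and stable near zero; set \code{inverse = "reciprocal"} for the
#' literal reciprocal reading) is averaged over the PN genes and over the MES
#' genes; each signature mean is Z-corrected across samples (mean 0, sd 1);
#' the metagene is the MES Z-score minus the PN Z-score, so positive values
#' are MES-like. \code{zMode = "per_gene"} Z-scores each gene column before
#' averaging instead.
#'
#' @param dct long delta-Ct table from [deltaCt()] covering all 8 signature
#'   genes for at least 2 samples.
#' @param signature gene signature map (default [defaultQpcrSignature()]).
#' @param ihcLabels optional named vector of IHC/FISH-based subclass labels
#'   carried through for comparison.
#' @param inverse \code{"negate"} (default) or \code{"reciprocal"}.
#' @param zMode \code{"signature"} (default) or \code{"per_gene"}.
#' @return data frame ordered by decreasing metagene (MES-most first):
#'   \code{sample_id}, \code{pn_raw}, \code{mes_raw}, \code{pn_z},
#'   \code{mes_z}, \code{metagene}, \code{ihc_label}.
#' @export
metageneScores <- function(dct, signature = defaultQpcrSignature(),
                           ihcLabels = NULL,
                           inverse = c("negate", "reciprocal"),
                           zMode = c("signature", "per_gene")) {
  inverse <- match.arg(inverse)
  zMode <- match.arg(zMode)
  m <- deltaCtMatrix(dct)
  genes <- c(signature$PN, signature$MES)
  miss <- setdiff(genes, colnames(m))
  if (length(miss))
    stop("delta-Ct table lacks signature gene(s): ", paste(miss, collapse = ", "))
  if (nrow(m) < 2) stop("metagene Z-correction needs at least 2 samples")
  if (anyNA(m[, genes]))
    stop("missing delta-Ct values for signature genes")
  inv <- if (inverse == "negate") -m[, genes, drop = FALSE]
         else 1 / m[, genes, drop = FALSE]
  if (zMode == "per_gene")
    inv <- apply(inv, 2, .zscore)
  pn_raw <- rowMeans(inv[, signature$PN, drop = FALSE])
  mes_raw <- rowMeans(inv[, signature$MES, drop = FALSE])
  pn_z <- .zscore(pn_raw)
  mes_z <- .zscore(mes_raw)
  out <- data.frame(sample_id = rownames(m),
                    pn_raw = pn_raw, mes_raw = mes_raw,
                    pn_z = pn_z, mes_z = mes_z,
                    metagene = mes_z - pn_z,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$ihc_label <- if (!is.null(ihcLabels))
    unname(ihcLabels[out$sample_id]) else NA_character_
  out[order(-out$metagene, out$sample_id), , drop = FALSE]
}
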