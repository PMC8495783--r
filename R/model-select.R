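# Likelihood-ratio tests between the general and the nested alternative
# model, FDR correction across genes, best-fit selection.
#
# Terminology follows the workflow's convention: the *alternative* model is
# the restricted one, nested within the *general* model (the reverse of the
# usual statistical naming). The LRT asks whether the extra parameters of
# the general model are justified.

#' Likelihood-ratio test between two nested fits
#'
#' Computes `stat = max(0, 2 * (lnL_general - lnL_alternative))` with
#' `df = np_general - np_alternative` degrees of freedom and the upper-tail
#' chi-square p-value. A negative raw difference (the restricted model
#' apparently beating the general one — a local-optimum symptom) is clamped
#' to 0 and flagged rather than silently rerun.
#'
#' @param general the general (parameter-rich) [ModelFit-class].
#' @param alternative the alternative (restricted, nested) [ModelFit-class].
#' @return one-row data.frame: `gene_id`, `lnl_general`, `lnl_alternative`,
#'   `stat`, `df`, `pvalue`, `negative_stat_flag`.
#' @export
lrtTest <- function(general, alternative) {
  stopifnot(is(general, "ModelFit"), is(alternative, "ModelFit"))
  if (alternative@np >= general@np)
    stop("models are not nested as required: alternative np (", alternative@np,
         ") must be smaller than general np (", general@np, ")")
  raw <- 2 * (lnL(general) - lnL(alternative))
  df <- general@np - alternative@np
  stat <- max(0, raw)
  data.frame(gene_id = geneId(general),
             lnl_general = lnL(general), lnl_alternative = lnL(alternative),
             stat = stat, df = df,
             pvalue = pchisq(stat, df, lower.tail = FALSE),
             negative_stat_flag = raw < 0,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues numeric vector of p-values in \[0,1\].
#' @return q-values, order-aligned with the input.
#' @export
fdrAdjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH")
}

#' Pick the best-fit model for a gene
#'
#' The restricted (alternative) model is preferred unless the FDR-adjusted
#' LRT rejects it: general iff `qvalue < alpha` (strict inequality).
#'
#' @param qvalue FDR-adjusted p-value.
#' @param alpha significance level (default 0.05).
#' @return `"general"` or `"alternative"`.
#' @export
selectBest <- function(qvalue, alpha = 0.05) {
  ifelse(qvalue < alpha, "general", "alternative")
}

#' Summarize LRT results across genes
#'
#' Applies the FDR correction across all genes' p-values and the best-model
#' rule, returning one row per gene. Failed genes are simply absent (they
#' live in the exclusion log).
#'
#' @param lrtRows data.frame of [lrtTest()] rows (one per gene).
#' @param alpha significance level for [selectBest()].
#' @return data.frame: `gene_id`, `lnl_general`, `lnl_alternative`, `stat`,
#'   `df`, `pvalue`, `qvalue`, `best_model`, `negative_stat_flag`, sorted by
#'   `gene_id`.
#' @export
summaryTable <- function(lrtRows, alpha = 0.05) {
  stopifnot(is.data.frame(lrtRows), nrow(lrtRows) >= 1L)
  out <- lrtRows[order(lrtRows$gene_id), , drop = FALSE]
  out$qvalue <- fdrAdjust(out$pvalue)
  out$best_model <- selectBest(out$qvalue, alpha)
  rownames(out) <- NULL
  out[, c("gene_id", "lnl_general", "lnl_alternative", "stat", "df",
          "pvalue", "qvalue", "best_model", "negative_stat_flag")]
}
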