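#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, used for differential-expression
#' tables that lack a pre-computed `padj` column. Thin, validated wrapper
#' around [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]` (NA allowed).
#' @return Numeric vector of adjusted p-values.
#' @export
adjust_pvalues <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Select differentially expressed genes
#'
#' Keeps genes with `|log2FoldChange| > lfc_cutoff` (strict; default
#' `log2(1.5)`) and adjusted p-value `< alpha` (strict; default 0.05). A
#' supplied `padj` column (DESeq2 results dialect) is used verbatim;
#' Benjamini-Hochberg adjustment of the raw p-values is applied only when it
#' is absent. Genes with missing `padj` (e.g. removed by DESeq2 independent
#' filtering) are excluded and counted.
#'
#' @param de Data frame with columns `gene`, `log2FoldChange`, `pvalue` and
#'   optionally `padj` (names configurable via `col_*`).
#' @param lfc_cutoff Strict absolute log2 fold-change threshold.
#' @param alpha Strict adjusted-p threshold.
#' @param col_gene,col_lfc,col_pvalue,col_padj Column names.
#' @return A list of class `deg_result`: `up` and `down` gene sets, an
#'   `evidence` element (`evidence_set`, provenance `"DEG"`, members
#'   `up` + `down`), thresholds, and the count of NA-padj genes skipped.
#' @export
select_degs <- function(de, lfc_cutoff = log2(1.5), alpha = 0.05,
                        col_gene = "gene", col_lfc = "log2FoldChange",
                        col_pvalue = "pvalue", col_padj = "padj") {
  missing <- setdiff(c(col_gene, col_lfc), names(de))
  if (length(missing) > 0) {
    abort(paste0("DE table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  gene <- canonicalize_protein(de[[col_gene]])
  lfc <- de[[col_lfc]]
  if (col_padj %in% names(de)) {
    padj <- de[[col_padj]]
  } else if (col_pvalue %in% names(de)) {
    padj <- adjust_pvalues(de[[col_pvalue]])
  } else {
    abort("DE table needs a padj or a pvalue column")
  }
  n_na <- sum(is.na(padj))
  usable <- !is.na(padj) & !is.na(lfc)
  sig <- usable & padj < alpha
  up <- unique(gene[sig & lfc > lfc_cutoff])
  down <- unique(gene[sig & lfc < -lfc_cutoff])
  ev <- evidence_set(
    c(up, down), provenance = "DEG", name = "DEGs",
    params = sprintf("|log2FC| > %.4f, adjusted p < %s", lfc_cutoff,
                     format(alpha))
  )
  structure(
    list(up = up, down = down, evidence = ev,
         lfc_cutoff = lfc_cutoff, alpha = alpha, n_na_padj = n_na),
    class = "deg_result"
  )
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf(
    "<deg_result> %d up, %d down (|log2FC| > %.3f, padj < %s; %d NA-padj gene(s) skipped)\n",
    length(x$up), length(x$down), x$lfc_cutoff, format(x$alpha), x$n_na_padj
  ))
  invisible(x)
}

#' @export
tidy.deg_result <- function(x, ...) {
  tibble(
    gene = c(x$up, x$down),
    direction = rep(c("up", "down"), c(length(x$up), length(x$down)))
  )
}

#' @export
glance.deg_result <- function(x, ...) {
  tibble(n_up = length(x$up), n_down = length(x$down),
         lfc_cutoff = x$lfc_cutoff, alpha = x$alpha, n_na_padj = x$n_na_padj)
}
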