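#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' `padj_(i) = min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' original order. Delegates to [stats::p.adjust()] after input validation.
#'
#' @param pvalues numeric vector of p-values, all in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues))
    stop_chemoflux("pvalues must be numeric", "chemoflux_deg_error")
  bad <- is.finite(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad | !is.finite(pvalues)))
    stop_chemoflux("p-values must lie in [0, 1]", "chemoflux_deg_error")
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify differentially expressed genes
#'
#' A gene is called upregulated when its adjusted p-value is below `alpha`
#' (strict inequality) and its log2 fold change is at least `lfc_up`
#' (inclusive), downregulated when padj < alpha and log2FC <= `lfc_down`
#' (inclusive), and unchanged otherwise. If the table has no `padj` column it
#' is computed from `pvalue` with [bh_adjust()].
#'
#' @param table data frame with columns `gene_id`, `log2fc`, and `padj` or
#'   `pvalue`
#' @param lfc_up,lfc_down inclusive log2 fold-change thresholds (defaults
#'   +1 / -1: at least doubled or halved expression)
#' @param alpha adjusted-p threshold (default 0.05, strict)
#' @return the table with added columns `padj` (if computed) and `class`
#'   (factor up/down/none), plus a `counts` attribute
#'   (named vector up/down/none)
#' @export
classify_degs <- function(table, lfc_up = 1, lfc_down = -1, alpha = 0.05) {
  required <- c("gene_id", "log2fc")
  missing <- setdiff(required, names(table))
  if (length(missing) || !("padj" %in% names(table) || "pvalue" %in% names(table)))
    stop_chemoflux(paste("gene table lacks columns:",
                         paste(c(missing, "padj|pvalue"), collapse = ", ")),
                   "chemoflux_schema_error")
  if (!"padj" %in% names(table)) table$padj <- bh_adjust(table$pvalue)
  cls <- rep("none", nrow(table))
  cls[table$padj < alpha & table$log2fc >= lfc_up] <- "up"
  cls[table$padj < alpha & table$log2fc <= lfc_down] <- "down"
  table$class <- factor(cls, levels = c("up", "down", "none"))
  counts <- c(up = sum(cls == "up"), down = sum(cls == "down"),
              none = sum(cls == "none"))
  attr(table, "counts") <- counts
  table
}

#' @rdname classify_degs
#' @param classified output of `classify_degs()`
#' @return `deg_counts()`: named vector `up`, `down`, `none`, `total`
#' @export
deg_counts <- function(classified) {
  counts <- attr(classified, "counts") %||%
    c(up = sum(classified$class == "up"), down = sum(classified$class == "down"),
      none = sum(classified$class == "none"))
  c(counts, total = unname(counts[["up"]] + counts[["down"]]))
}

#' Tally differentially expressed genes by arCOG class
#'
#' Counts up- and downregulated genes per archaeal-COG functional class
#' letter. Genes without a mapping are tallied under `"unknown"`. Row order of
#' the input never affects the result.
#'
#' @param classified output of [classify_degs()]
#' @param mapping optional named character vector gene_id -> arCOG letter;
#'   if `NULL`, an `arcog` column of the table is used
#' @return tibble with columns `arcog`, `up`, `down`, sorted by class letter
#' @export
tally_arcog <- function(classified, mapping = NULL) {
  arcog <- if (!is.null(mapping)) unname(mapping[classified$gene_id])
           else if ("arcog" %in% names(classified)) classified$arcog
           else rep(NA_character_, nrow(classified))
  arcog[is.na(arcog) | !nzchar(arcog)] <- "unknown"
  deg <- classified$class %in% c("up", "down")
  lv <- sort(unique(arcog[deg]))
  n_up <- unname(vapply(lv, function(a) sum(arcog == a & classified$class == "up"), 0L))
  n_down <- unname(vapply(lv, function(a) sum(arcog == a & classified$class == "down"), 0L))
  tibble::tibble(arcog = lv, up = n_up, down = n_down)
}

#' Read a per-gene statistics table
#'
#' CSV with columns `gene_id, log2fc, pvalue[, padj, arcog]`.
#'
#' @param path CSV file
#' @return tibble
#' @export
read_gene_stats <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("gene_id", "log2fc", "pvalue"), names(df))
  if (length(missing))
    stop_chemoflux(paste("gene stats table lacks columns:", paste(missing, collapse = ", ")),
                   "chemoflux_schema_error")
  tibble::as_tibble(df)
}
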