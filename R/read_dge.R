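#' Read a differential gene-expression table
#'
#' Loads per-gene differential-expression results (e.g. a DESeq2 results
#' table exported as TSV/CSV) down to the three fields used for
#' methylation-expression integration: gene id, log2 fold change and
#' adjusted P value. Blank or `NA` adjusted P values are preserved as
#' missing (DESeq2 reports `NA` for independently filtered genes).
#'
#' @param path Path to a delimited text file with a header. Tab, comma and
#'   semicolon delimiters are auto-detected.
#' @param column_map Optional named character vector mapping canonical
#'   names (`gene_id`, `log2fc`, `padj`) to actual header names; defaults
#'   cover DESeq2 (`log2FoldChange`/`padj`), edgeR (`logFC`/`FDR`) and
#'   limma (`logFC`/`adj.P.Val`) dialects.
#' @return Tibble with columns `gene_id`, `gene_key` (version-stripped),
#'   `log2fc`, `padj`.
#' @export
read_dge <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(";", first)) ";" else if (grepl(",", first)) "," else ""
  raw <- read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "\"")
  # DESeq2 CSVs often carry gene ids as an unnamed first (rownames) column
  if (!is.null(names(raw)) && names(raw)[1] %in% c("", "X")) names(raw)[1] <- "gene_id"

  aliases <- list(
    gene_id = c("gene_id", "gene", "ensembl_gene_id", "id", "row"),
    log2fc  = c("log2fc", "log2FoldChange", "logFC", "log2_fold_change"),
    padj    = c("padj", "adj.P.Val", "FDR", "qvalue", "q_value", "adjusted_pvalue")
  )
  header <- names(raw)
  actual <- vapply(names(aliases), function(canon) {
    resolve_column(canon, header, aliases[[canon]], column_map)
  }, character(1))
  if (anyNA(actual)) {
    stop("missing required column(s): ",
         paste(names(actual)[is.na(actual)], collapse = ", "), call. = FALSE)
  }
  df <- raw[actual]
  names(df) <- names(aliases)
  df$gene_id <- as.character(df$gene_id)
  suppressWarnings({
    df$log2fc <- as.numeric(df$log2fc)
    df$padj <- as.numeric(df$padj)
  })
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    stop("duplicate gene_id(s) in DGE table: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  }
  bad <- !is.na(df$padj) & (df$padj < 0 | df$padj > 1)
  if (any(bad)) stop("padj outside [0,1] for ", sum(bad), " gene(s)", call. = FALSE)
  tibble::tibble(
    gene_id = df$gene_id,
    gene_key = strip_tx_version(df$gene_id),
    log2fc = df$log2fc,
    padj = df$padj
  )
}
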