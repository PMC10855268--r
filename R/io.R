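#' Read a design table written as TSV
#'
#' @param path Path to a design TSV (columns `sample_id`, `fish_id`, `day`,
#'   `group`, `time`, `site`).
#' @return Design data frame.
#' @export
read_design_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sample_id", "fish_id", "day", "group", "time", "site")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("design table missing column(s): ", paste(missing, collapse = ", "))
  d$day <- as.integer(d$day)
  d
}

#' Read an omics feature table written as TSV
#'
#' Expects rows = samples with the first column `sample_id` and remaining
#' columns features.
#'
#' @param path Path to the TSV.
#' @param block_name Block label; defaults to the file name stem.
#' @return An [omics_block()].
#' @export
read_block_tsv <- function(path, block_name = NULL) {
  if (is.null(block_name))
    block_name <- sub("^block_", "", sub("\\.tsv$", "", basename(path)))
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  if (names(d)[1] != "sample_id")
    stop("feature table must have 'sample_id' as its first column")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$sample_id
  omics_block(block_name, m)
}

#' Read an OTU count table written as TSV
#'
#' Expects rows = taxa with the first column `taxon` (taxonomy label) and
#' remaining columns samples.
#'
#' @param path Path to the TSV.
#' @return An `otu_table`.
#' @export
read_otu_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  if (names(d)[1] != "taxon")
    stop("OTU table must have 'taxon' as its first column")
  m <- as.matrix(d[, -1, drop = FALSE])
  if (any(m < 0) || any(m != round(m)))
    stop("OTU counts must be non-negative integers")
  storage.mode(m) <- "integer"
  rownames(m) <- d$taxon
  structure(list(counts = m, taxonomy = d$taxon,
                 library_size = colSums(m)),
            class = "otu_table")
}

#' Write a data frame as a TSV with a provenance header comment
#'
#' @param df Data frame.
#' @param path Output path (directories created).
#' @param comment Optional provenance line written as a leading `#` comment.
#' @return Invisibly, `path`.
#' @export
write_tsv_report <- function(df, path, comment = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
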