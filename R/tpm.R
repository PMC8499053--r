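#' Transcript-level TPM table with gene annotation
#'
#' @param tpm transcripts x cells non-negative matrix of TPM values, row
#'   names transcript ids, column names cell ids.
#' @param tx2gene data.frame with columns `transcript_id`, `gene_id`.
#' @param gene_type named character vector gene_id -> gene type (GENCODE
#'   `gene_type` attribute); genes absent default to `NA`.
#' @return list of class `odegr_tpm` with elements `tpm`, `tx2gene`,
#'   `gene_type`. Transcripts with no gene mapping are dropped with a
#'   warning.
#' @export
tpm_table <- function(tpm, tx2gene, gene_type = character()) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  if (is.null(rownames(tpm))) stop("tpm needs transcript ids as row names")
  if (is.null(colnames(tpm))) stop("tpm needs cell ids as column names")
  known <- rownames(tpm) %in% tx2gene$transcript_id
  if (!all(known)) {
    warning(sprintf("%d transcripts without gene mapping dropped (e.g. %s)",
                    sum(!known), rownames(tpm)[!known][1]))
    tpm <- tpm[known, , drop = FALSE]
  }
  map <- setNames(tx2gene$gene_id, tx2gene$transcript_id)
  structure(list(tpm = tpm,
                 tx2gene = data.frame(
                   transcript_id = rownames(tpm),
                   gene_id = unname(map[rownames(tpm)]),
                   stringsAsFactors = FALSE),
                 gene_type = gene_type),
            class = "odegr_tpm")
}

#' Read a transcript x cell TPM matrix from TSV
#'
#' First column = transcript_id, remaining columns = cells.
#'
#' @param path TSV file.
#' @param tx2gene,gene_type as in [tpm_table()] (typically from
#'   [read_gtf_genes()]).
#' @return an `odegr_tpm`.
#' @export
read_tpm <- function(path, tx2gene, gene_type = character()) {
  if (!file.exists(path)) stop(sprintf("TPM file not found: %s", path))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  tpm_table(m, tx2gene, gene_type)
}

#' Select expressed transcripts
#'
#' Keeps transcripts whose mean over cells of `log10(TPM + 1)` is strictly
#' greater than `threshold`. Raising the threshold never enlarges the set.
#'
#' @param table an `odegr_tpm`.
#' @param threshold mean log-expression cutoff (default 0.5).
#' @return character vector of transcript ids.
#' @export
select_transcripts <- function(table, threshold = 0.5) {
  m <- rowMeans(log10(table$tpm + 1))
  rownames(table$tpm)[m > threshold]
}

#' Protein-coding genes owning at least one selected transcript
#'
#' @param selected transcript ids (from [select_transcripts()]).
#' @param table an `odegr_tpm`.
#' @return unique gene ids with `gene_type == "protein_coding"` and >= 1
#'   selected transcript, in first-appearance order.
#' @export
genes_from_transcripts <- function(selected, table) {
  map <- setNames(table$tx2gene$gene_id, table$tx2gene$transcript_id)
  known <- selected %in% names(map)
  if (!all(known)) {
    warning(sprintf("%d selected transcripts with unknown gene skipped",
                    sum(!known)))
    selected <- selected[known]
  }
  genes <- unique(unname(map[selected]))
  genes[!is.na(genes) &
          genes %in% names(table$gene_type)[table$gene_type == "protein_coding"]]
}

#' Log-transformed TPM rows of one gene's selected transcripts
#'
#' @param table an `odegr_tpm`.
#' @param gene_id gene to extract.
#' @param selected transcript ids passing the expression filter; only the
#'   gene's transcripts inside this set are returned.
#' @return matrix of `log10(TPM + 1)`, transcripts x cells (possibly 0
#'   rows).
#' @export
gene_tpm_rows <- function(table, gene_id, selected = rownames(table$tpm)) {
  tx <- table$tx2gene$transcript_id[table$tx2gene$gene_id == gene_id]
  tx <- intersect(tx, selected)
  log10(table$tpm[tx, , drop = FALSE] + 1)
}
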