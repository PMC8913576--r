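#' Construct a circRNA sequence record
#'
#' One mature circular RNA sequence, written linearly from an arbitrary
#' rotation (circBase convention: the first base follows the back-splice
#' junction). The sequence is uppercased and `U` is mapped to `T` on
#' construction.
#'
#' @param circ_id Non-empty accession, e.g. `"hsa_circ_0000725"`.
#' @param sequence Nucleotide string over `A,C,G,T,N` (lowercase and `U`
#'   accepted and normalized).
#' @param host_gene,transcript,genomic_position Optional annotation strings.
#'   `genomic_position` is treated as an opaque 1-based-inclusive label and
#'   never used for arithmetic.
#' @return An object of class `circ_record` with fields `circ_id`, `sequence`,
#'   `length_nt`, `host_gene`, `transcript`, `genomic_position`.
#' @export
circ_record <- function(circ_id, sequence, host_gene = "", transcript = "",
                        genomic_position = "") {
  if (!is.character(circ_id) || length(circ_id) != 1L || !nzchar(circ_id))
    stop("circ_id must be a non-empty string")
  sequence <- .normalize_nt(sequence, circ_id)
  structure(
    list(circ_id = circ_id, sequence = sequence, length_nt = nchar(sequence),
         host_gene = host_gene, transcript = transcript,
         genomic_position = genomic_position),
    class = "circ_record"
  )
}

#' Construct a host-gene protein record
#'
#' @param protein_id Non-empty identifier.
#' @param sequence Amino-acid string over the 20 standard letters plus `X`;
#'   internal stop characters are rejected.
#' @param gene Host gene symbol (used to pair proteins with circRNAs).
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(protein_id, sequence, gene = "") {
  if (!is.character(protein_id) || length(protein_id) != 1L ||
      !nzchar(protein_id))
    stop("protein_id must be a non-empty string")
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty protein sequence for ", protein_id)
  bad <- .first_illegal(sequence, .AA_ALPHABET)
  if (!is.na(bad))
    stop(sprintf("record '%s': illegal amino-acid character '%s' at offset %d",
                 protein_id, substr(sequence, bad, bad), bad))
  structure(list(protein_id = protein_id, gene = gene, sequence = sequence),
            class = "protein_record")
}

#' @export
print.circ_record <- function(x, ...) {
  cat(sprintf("<circ_record> %s (%d nt)%s\n", x$circ_id, x$length_nt,
              if (nzchar(x$host_gene)) paste0(" host=", x$host_gene) else ""))
  invisible(x)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)%s\n", x$protein_id,
              nchar(x$sequence),
              if (nzchar(x$gene)) paste0(" gene=", x$gene) else ""))
  invisible(x)
}

.normalize_nt <- function(sequence, id) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("record '", id, "': empty or invalid sequence")
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  bad <- .first_illegal(sequence, .NT_ALPHABET)
  if (!is.na(bad))
    stop(sprintf("record '%s': illegal nucleotide character '%s' at offset %d",
                 id, substr(sequence, bad, bad), bad))
  sequence
}

# 1-based offset of the first character outside `alphabet`, or NA.
.first_illegal <- function(sequence, alphabet) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(!(ch %in% alphabet))
  if (length(hit)) hit[1L] else NA_integer_
}

#' Read a FASTA file of circRNA sequences or host proteins
#'
#' Parsing is delegated to Biostrings; validation, uppercasing and the
#' RNA-to-DNA (`U` to `T`) normalization happen on ingest. Record order is
#' preserved and duplicate ids within one file are rejected.
#'
#' @param path FASTA file path.
#' @param alphabet `"nucleotide"` (returns [circ_record()]s) or `"protein"`
#'   (returns [protein_record()]s).
#' @return A named list of records, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  recs <- if (alphabet == "nucleotide") {
    Map(circ_record, ids, seqs)
  } else {
    Map(protein_record, ids, seqs)
  }
  names(recs) <- ids
  recs
}

#' Write records to FASTA (60-character line wrap)
#'
#' @param records List of [circ_record()] or [protein_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  ids <- vapply(records, function(r) r$circ_id %||% r$protein_id, character(1))
  seqs <- vapply(records, `[[`, character(1), "sequence")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.ANNOT_COLS <- c("circ_id", "log2fc", "adj_p", "host_gene", "transcript",
                 "genomic_position", "db_coding_flag")

#' Read a circRNA annotation table
#'
#' Tab-separated with header; required columns `circ_id` (or `id`) and
#' `log2fc`. Optional columns `adj_p`, `host_gene`, `transcript`,
#' `genomic_position`, `db_coding_flag`; missing ones come back as `NA`.
#' A missing `adj_p` marks a row as pre-filtered upstream (tables of already
#' gated candidates print only the fold change).
#'
#' @param path TSV path.
#' @return A data frame with the canonical columns, one row per circRNA.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  names(df)[names(df) == "id"] <- "circ_id"
  for (col in c("circ_id", "log2fc"))
    if (!col %in% names(df)) stop("annotation table missing required column: ", col)
  if (nrow(df) == 0L) {
    warning("annotation table has a header but no rows: ", path)
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.ANNOT_COLS)), .ANNOT_COLS))
    out$log2fc <- numeric(0); out$adj_p <- numeric(0)
    out$db_coding_flag <- logical(0)
    return(out)
  }
  if (!is.numeric(df$log2fc)) {
    suppressWarnings(lfc <- as.numeric(df$log2fc))
    if (anyNA(lfc) && !all(is.na(df$log2fc[is.na(lfc)])))
      stop("non-numeric log2fc value(s) in ", path)
    df$log2fc <- lfc
  }
  if (anyDuplicated(df$circ_id))
    stop("duplicate circ_id in annotation table: ",
         paste(unique(df$circ_id[duplicated(df$circ_id)]), collapse = ", "))
  for (col in setdiff(.ANNOT_COLS, names(df)))
    df[[col]] <- if (col == "adj_p") NA_real_
                 else if (col == "db_coding_flag") NA else NA_character_
  if (!is.logical(df$db_coding_flag))
    df$db_coding_flag <- as.logical(df$db_coding_flag)
  if (!is.numeric(df$adj_p)) df$adj_p <- as.numeric(df$adj_p)
  bad_p <- !is.na(df$adj_p) & (df$adj_p < 0 | df$adj_p > 1)
  if (any(bad_p)) stop("adj_p outside [0, 1] for: ",
                       paste(df$circ_id[bad_p], collapse = ", "))
  df[, .ANNOT_COLS]
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]; `log2fc` is printed to 2 decimals
#' (the precision of published candidate tables).
#'
#' @param df Annotation data frame.
#' @param path Output TSV path.
#' @export
write_annotation_table <- function(df, path) {
  out <- df[, intersect(.ANNOT_COLS, names(df)), drop = FALSE]
  out$log2fc <- formatC(out$log2fc, format = "f", digits = 2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write candidate rows to TSV or JSON
#'
#' Output is deterministic: rows sorted by descending `log2fc` then
#' `circ_id`, fixed column order, so repeated exports are byte-identical.
#'
#' @param rows Candidate data frame (as produced by [run_scan()]).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_candidates <- function(rows, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rows <- sort_candidates(rows)
  if (format == "tsv") {
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_candidates
#' @export
sort_candidates <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  rows[order(-rows$log2fc, rows$circ_id), , drop = FALSE]
}
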