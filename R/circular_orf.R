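#' ORF-scan parameters
#'
#' Defaults encode the candidate-filter thresholds of the scanning strategy:
#' the coded peptide must have more than 50 aa (`min_pep_aa = 51`), base
#' reuse must stay under 50 bp (`max_overlay_bp = 49`), and the ORF must
#' span the back-splice junction (`require_junction = TRUE`).
#'
#' @param min_pep_aa Minimum peptide length kept by [filter_orfs()]
#'   (strictly-more-than-50 rule, so the default is 51).
#' @param max_overlay_bp Maximum base reuse kept by [filter_orfs()]
#'   (strictly-fewer-than-50 rule, so the default is 49).
#' @param max_cycles Reading bound in circle lengths. Three cycles are
#'   exhaustive: when the circle length is not a multiple of 3 the frame
#'   shifts each lap and returns to its start after exactly 3 laps; when it
#'   is a multiple of 3 a single lap already decides termination.
#' @param require_junction Keep only junction-spanning ORFs in
#'   [filter_orfs()].
#' @param start_codons Start codon set; `ATG` by default.
#' @return A list of class `orf_params`.
#' @export
orf_params <- function(min_pep_aa = 51L, max_overlay_bp = 49L,
                       max_cycles = 3L, require_junction = TRUE,
                       start_codons = "ATG") {
  stopifnot(min_pep_aa >= 1L, max_cycles >= 1L, max_overlay_bp >= 0L,
            length(start_codons) >= 1L, all(nchar(start_codons) == 3L))
  structure(list(min_pep_aa = as.integer(min_pep_aa),
                 max_overlay_bp = as.integer(max_overlay_bp),
                 max_cycles = as.integer(max_cycles),
                 require_junction = isTRUE(require_junction),
                 start_codons = toupper(start_codons)),
            class = "orf_params")
}

#' Translate a codon string (standard genetic code)
#'
#' Translates everything it is given, including stops (as `*`); termination
#' is the caller's concern. Any codon containing a base other than A/C/G/T
#' translates to `X`; a stop is only ever called on an exact stop codon.
#'
#' @param codon_string Nucleotide string, length a multiple of 3.
#' @return Amino-acid string of length `nchar(codon_string)/3`.
#' @export
translate_nt <- function(codon_string) {
  n <- nchar(codon_string)
  if (n %% 3L != 0L)
    stop("codon string length (", n, ") is not a multiple of 3")
  if (n == 0L) return("")
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(codon_string, starts, starts + 2L)
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Find ORFs on a circular sequence
#'
#' Scans every position of the circle for a start codon and reads codons
#' forward with wraparound until the first in-frame stop, up to
#' `max_cycles` circle lengths. A reading that meets no stop within that
#' bound can never terminate (see [orf_params()]) and is flagged infinite;
#' infinite ORFs are dropped from the result unless `include_infinite`.
#'
#' Every distinct start position is reported, including nested starts
#' sharing a stop. Coordinates are 0-based; `start_nt` is the offset of the
#' start codon on the supplied rotation, `orf_len_nt` counts start through
#' stop codon inclusive, and the translated `peptide` excludes the stop.
#' The back-splice junction sits between the last and first base of the
#' supplied rotation, so `spans_junction` is `start_nt + orf_len_nt > L`
#' and `overlay_bp` (bases read more than once) is
#' `max(0, orf_len_nt - L)`.
#'
#' @param rec A [circ_record()].
#' @param params An [orf_params()] object.
#' @param include_infinite Also return rows for infinite readings
#'   (`is_infinite = TRUE`, no peptide).
#' @return A data frame, one row per ORF, sorted by descending `pep_len_aa`
#'   then ascending `start_nt`, with columns `circ_id`, `start_nt`, `frame`,
#'   `orf_len_nt`, `pep_len_aa`, `spans_junction`, `overlay_bp`,
#'   `is_complete`, `is_infinite`, `peptide`.
#' @export
find_circular_orfs <- function(rec, params = orf_params(),
                               include_infinite = FALSE) {
  stopifnot(inherits(rec, "circ_record"))
  seq <- rec$sequence
  L <- rec$length_nt
  if (L < 3L) stop("circle '", rec$circ_id, "' shorter than one codon (L = ", L, ")")
  # The extended string makes wraparound reads plain substring extractions:
  # a read of at most max_cycles*L nt starting anywhere in the first copy
  # stays inside max_cycles + 1 copies.
  ext <- strrep(seq, params$max_cycles + 1L)
  first <- substring(ext, 1:L, 3:(L + 2L))
  starts0 <- which(first %in% params$start_codons) - 1L
  max_nt <- params$max_cycles * L
  n_codons <- max_nt %/% 3L

  rows <- lapply(starts0, function(s) {
    cod_at <- s + 3L * (seq_len(n_codons) - 1L) + 1L
    cods <- substring(ext, cod_at, cod_at + 2L)
    hit <- which(cods %in% .STOP_CODONS)
    if (length(hit)) {
      k <- hit[1L]                       # stop is the k-th codon
      orf_len <- 3L * k
      pep <- if (k > 1L) {
        aa <- .CODON_TABLE[cods[seq_len(k - 1L)]]
        aa[is.na(aa)] <- "X"
        paste(aa, collapse = "")
      } else ""
      list(start_nt = s, frame = s %% 3L, orf_len_nt = orf_len,
           pep_len_aa = k - 1L, spans_junction = s + orf_len > L,
           overlay_bp = max(0L, orf_len - L), is_complete = TRUE,
           is_infinite = FALSE, peptide = pep)
    } else {
      list(start_nt = s, frame = s %% 3L, orf_len_nt = NA_integer_,
           pep_len_aa = NA_integer_, spans_junction = NA,
           overlay_bp = NA_integer_, is_complete = FALSE,
           is_infinite = TRUE, peptide = "")
    }
  })

  out <- .orf_rows_to_df(rec$circ_id, rows)
  if (!include_infinite) out <- out[!out$is_infinite, , drop = FALSE]
  ord <- order(-ifelse(is.na(out$pep_len_aa), -1L, out$pep_len_aa), out$start_nt)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.ORF_COLS <- c("circ_id", "start_nt", "frame", "orf_len_nt", "pep_len_aa",
               "spans_junction", "overlay_bp", "is_complete", "is_infinite",
               "peptide")

.orf_rows_to_df <- function(circ_id, rows) {
  if (length(rows) == 0L) {
    return(data.frame(circ_id = character(0), start_nt = integer(0),
                      frame = integer(0), orf_len_nt = integer(0),
                      pep_len_aa = integer(0), spans_junction = logical(0),
                      overlay_bp = integer(0), is_complete = logical(0),
                      is_infinite = logical(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  df <- cbind(circ_id = circ_id, df, stringsAsFactors = FALSE)
  df[, .ORF_COLS]
}

#' Apply the candidate ORF rules
#'
#' Keeps ORFs that (1) span the back-splice junction (when
#' `params$require_junction`), (2) encode strictly more than
#' `params$min_pep_aa - 1` amino acids, and (3) reuse at most
#' `params$max_overlay_bp` bases. All three inequalities are strict at the
#' published thresholds: a 50-aa peptide and a 50-bp overlay are both
#' rejected. Rejected rows, each annotated with the first rule that fired
#' (`junction`, `pep_len`, `overlay`), are attached as
#' `attr(result, "rejections")`.
#'
#' @param orfs Data frame from [find_circular_orfs()] (complete ORFs).
#' @param params An [orf_params()] object.
#' @return The kept subset, same columns and ordering.
#' @export
filter_orfs <- function(orfs, params = orf_params()) {
  orfs <- orfs[orfs$is_complete & !orfs$is_infinite, , drop = FALSE]
  rule <- rep(NA_character_, nrow(orfs))
  if (params$require_junction)
    rule[!orfs$spans_junction] <- "junction"
  rule[is.na(rule) & orfs$pep_len_aa < params$min_pep_aa] <- "pep_len"
  rule[is.na(rule) & orfs$overlay_bp > params$max_overlay_bp] <- "overlay"
  kept <- orfs[is.na(rule), , drop = FALSE]
  rej <- orfs[!is.na(rule), , drop = FALSE]
  rej$rule <- rule[!is.na(rule)]
  rownames(kept) <- NULL
  rownames(rej) <- NULL
  attr(kept, "rejections") <- rej
  kept
}

#' Headline ORF for a circRNA
#'
#' Promotes one ORF per circRNA: the longest peptide, ties broken by the
#' smallest start position.
#'
#' @param orfs Data frame of qualifying ORFs for one circRNA.
#' @return A one-row data frame, or `NULL` when `orfs` is empty.
#' @export
best_orf <- function(orfs) {
  if (is.null(orfs) || nrow(orfs) == 0L) return(NULL)
  orfs[order(-orfs$pep_len_aa, orfs$start_nt)[1L], , drop = FALSE]
}

#' Write a per-ORF TSV
#'
#' @param orfs ORF data frame (possibly several circRNAs row-bound).
#' @param path Output path.
#' @export
write_orf_table <- function(orfs, path) {
  utils::write.table(orfs[, .ORF_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
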