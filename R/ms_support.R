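#' In-silico digestion parameters
#'
#' Conventional bottom-up proteomics search settings.
#'
#' @param max_missed_cleavages Missed cleavages allowed, 0-5.
#' @param min_len,max_len Fragment length bounds (aa) applied after
#'   digestion.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 2L, min_len = 7L,
                          max_len = 35L) {
  stopifnot(max_missed_cleavages >= 0L, max_missed_cleavages <= 5L,
            min_len >= 1L, min_len <= max_len)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_params")
}

#' Tryptic digestion of a peptide
#'
#' Trypsin cleaves C-terminal to lysine or arginine except when the next
#' residue is proline (the standard `KR|not-P` rule; set
#' `strict_kr = TRUE` to drop the proline exception). Fragments with 0 to
#' `max_missed_cleavages` missed cleavages are emitted, then the length
#' bounds are applied. Zero-missed fragments partition the peptide exactly.
#'
#' @param peptide Non-empty amino-acid string.
#' @param params A [digest_params()] object.
#' @param strict_kr Cleave after every K/R regardless of proline.
#' @return A data frame with `fragment`, `start`, `end` (0-based half-open
#'   on the peptide), `missed_cleavages`; masses are filled later by
#'   [select_evidence_peptides()] or [peptide_mass()].
#' @export
tryptic_digest <- function(peptide, params = digest_params(),
                           strict_kr = FALSE) {
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  ch <- strsplit(peptide, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cut_after <- which(ch %in% c("K", "R"))
  if (!strict_kr)
    cut_after <- cut_after[cut_after == n | ch[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after[cut_after < n], n)   # half-open fragment bounds
  nfrag <- length(bounds) - 1L
  rows <- list()
  for (m in 0:min(params$max_missed_cleavages, nfrag - 1L)) {
    for (i in seq_len(nfrag - m)) {
      s <- bounds[i]; e <- bounds[i + m + 1L]
      rows[[length(rows) + 1L]] <-
        data.frame(fragment = substr(peptide, s + 1L, e),
                   start = s, end = e, missed_cleavages = m,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  len <- out$end - out$start
  out <- out[len >= params$min_len & len <= params$max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neutral peptide mass
#'
#' Residue-mass sum plus one water; `mono` uses monoisotopic residue
#' masses, `avg` average masses. No modifications.
#'
#' @param fragment Amino-acid string over the 20 standard residues
#'   (`X` and stops rejected).
#' @param kind `"mono"` or `"avg"`.
#' @return Mass in Da.
#' @export
peptide_mass <- function(fragment, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  if (!nzchar(fragment)) stop("fragment must be non-empty")
  ch <- strsplit(fragment, "", fixed = TRUE)[[1L]]
  tab <- if (kind == "mono") .MONO_RESIDUE_MASS else .AVG_RESIDUE_MASS
  masses <- tab[ch]
  if (anyNA(masses))
    stop("non-standard residue(s) in fragment: ",
         paste(unique(ch[is.na(masses)]), collapse = ", "))
  sum(masses) + if (kind == "mono") .WATER_MONO else .WATER_AVG
}

#' Select MS evidence peptides covering the unique region
#'
#' Keeps tryptic fragments that overlap at least one unique (uncovered)
#' residue of the circRNA peptide — the fragments whose detection in
#' LC-MS/MS cannot be explained by the linear host protein — and fills in
#' monoisotopic and average masses.
#'
#' @param digest Output of [tryptic_digest()] on the circRNA peptide.
#' @param report [uniqueness_report()] computed on the same peptide.
#' @return A data frame sorted by descending `unique_aa_overlap` then
#'   ascending `start`, with columns of `digest` plus `covers_unique`,
#'   `unique_aa_overlap`, `mono_mass_da`, `avg_mass_da`, and the report's
#'   `circ_id`.
#' @export
select_evidence_peptides <- function(digest, report) {
  if (length(report$covered_mask) > 0L && nrow(digest) > 0L) {
    maxend <- max(digest$end)
    if (maxend > length(report$covered_mask))
      stop("digest and uniqueness report disagree on peptide length")
  }
  uncov <- !report$covered_mask
  overlap <- vapply(seq_len(nrow(digest)), function(i) {
    s <- digest$start[i]; e <- digest$end[i]
    sum(uncov[(s + 1L):e])
  }, integer(1))
  if (nrow(digest) == 0L) overlap <- integer(0)
  out <- digest
  out$covers_unique <- overlap >= 1L
  out$unique_aa_overlap <- overlap
  out <- out[out$covers_unique, , drop = FALSE]
  if (nrow(out)) {
    out$mono_mass_da <- vapply(out$fragment, peptide_mass, numeric(1),
                               kind = "mono", USE.NAMES = FALSE)
    out$avg_mass_da <- vapply(out$fragment, peptide_mass, numeric(1),
                              kind = "avg", USE.NAMES = FALSE)
  } else {
    out$mono_mass_da <- numeric(0)
    out$avg_mass_da <- numeric(0)
  }
  out <- out[order(-out$unique_aa_overlap, out$start), , drop = FALSE]
  out <- cbind(circ_id = rep(report$circ_id, nrow(out)), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Export an MS search database (protein FASTA)
#'
#' One record per candidate peptide with header
#' `circ_id|orf_start|pep_len`; ordering follows the supplied candidate
#' order, so repeated export of the same input is byte-identical.
#' Duplicate peptides from different circRNAs are all kept under their
#' distinct headers.
#'
#' @param candidates Data frame with columns `circ_id`, `orf_start_nt`,
#'   `pep_len_aa`, `peptide` (as produced by [run_scan()]).
#' @param path Output FASTA path.
#' @export
export_search_db <- function(candidates, path) {
  keep <- nzchar(candidates$peptide) & !is.na(candidates$peptide)
  candidates <- candidates[keep, , drop = FALSE]
  recs <- lapply(seq_len(nrow(candidates)), function(i) {
    protein_record(
      sprintf("%s|%d|%d", candidates$circ_id[i],
              candidates$orf_start_nt[i], candidates$pep_len_aa[i]),
      candidates$peptide[i])
  })
  write_fasta(recs, path)
}
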