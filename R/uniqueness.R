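#' Uniqueness-comparison parameters
#'
#' @param min_match Minimum exact-match length (aa) for a host substring to
#'   "cover" residues of the circRNA peptide. Default 7, the shortest
#'   peptide length routinely accepted as MS evidence.
#' @param threshold Minimum count of unique residues, strict: a peptide
#'   passes with *more than* `threshold` unique aa. Default 2, per the
#'   more-than-two-unique-aa rule for LC-MS/MS identifiability.
#' @param il_equivalent Treat isoleucine and leucine as the same letter
#'   (mass spectrometry cannot distinguish them). Off by default: the
#'   uniqueness rule is sequence-based.
#' @return A list of class `uniqueness_params`.
#' @export
uniqueness_params <- function(min_match = 7L, threshold = 2L,
                              il_equivalent = FALSE) {
  stopifnot(min_match >= 1L, threshold >= 0L)
  structure(list(min_match = as.integer(min_match),
                 threshold = as.integer(threshold),
                 il_equivalent = isTRUE(il_equivalent)),
            class = "uniqueness_params")
}

#' Longest exact common substring of two amino-acid strings
#'
#' Classic dynamic program over common-suffix lengths. Ties are broken by
#' the smallest position in `a`, then the smallest position in `b`.
#'
#' @param a,b Non-empty strings.
#' @return A list with `length`, `pos_a`, `pos_b` (0-based start offsets;
#'   positions are `NA` when `length` is 0).
#' @export
longest_common_substring <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("both inputs must be non-empty")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  best <- 0L; pa <- NA_integer_; pb <- NA_integer_
  prev <- integer(m)
  for (i in seq_len(n)) {
    shifted <- c(0L, prev[-m])
    cur <- ifelse(av[i] == bv, shifted + 1L, 0L)
    j <- which.max(cur)
    if (cur[j] > best) {      # strict: earlier rows win ties (smaller pos_a)
      best <- cur[j]
      pa <- i - best
      pb <- j - best
    }
    prev <- cur
  }
  list(length = best, pos_a = pa, pos_b = pb)
}

#' Compare a circRNA peptide against host linear protein(s)
#'
#' A peptide position is *covered* when it lies inside an exact match of
#' length at least `min_match` against any host protein; equivalently, when
#' some `min_match`-length window containing it occurs verbatim in a host.
#' Unique residues are the uncovered positions — the part of the peptide
#' that cannot come from the linear host transcript and therefore
#' identifies the circRNA in LC-MS/MS.
#'
#' @param peptide Non-empty amino-acid string.
#' @param hosts List of [protein_record()]s; may be empty (everything is
#'   then unique).
#' @param params A [uniqueness_params()] object.
#' @param circ_id Identifier carried into the report.
#' @return An object of class `uniqueness_report`: `circ_id`, `host_ids`,
#'   `common_area_aa` (longest exact common substring with any host),
#'   `covered_mask` (logical per peptide position), `unique_aa_count`,
#'   `unique_segments` (data frame of 0-based half-open intervals), and
#'   `passes` (`unique_aa_count > threshold`, strict).
#' @export
uniqueness_report <- function(peptide, hosts = list(),
                              params = uniqueness_params(),
                              circ_id = NA_character_) {
  if (!nzchar(peptide)) stop("peptide must be non-empty")
  pep_cmp <- if (params$il_equivalent) chartr("I", "L", peptide) else peptide
  n <- nchar(peptide)
  mm <- params$min_match
  covered <- rep(FALSE, n)
  common <- 0L
  host_ids <- vapply(hosts, `[[`, character(1), "protein_id")
  for (h in hosts) {
    hseq <- if (params$il_equivalent) chartr("I", "L", h$sequence) else h$sequence
    common <- max(common, longest_common_substring(pep_cmp, hseq)$length)
    if (nchar(hseq) < mm || n < mm) next
    host_kmers <- unique(substring(hseq, 1:(nchar(hseq) - mm + 1L),
                                   mm:nchar(hseq)))
    pep_starts <- 1:(n - mm + 1L)
    pep_kmers <- substring(pep_cmp, pep_starts, pep_starts + mm - 1L)
    for (s in pep_starts[pep_kmers %in% host_kmers])
      covered[s:(s + mm - 1L)] <- TRUE
  }
  segs <- .mask_runs(!covered)
  uniq <- sum(!covered)
  structure(
    list(circ_id = circ_id, host_ids = host_ids,
         common_area_aa = as.integer(common), covered_mask = covered,
         unique_aa_count = as.integer(uniq), unique_segments = segs,
         passes = uniq > params$threshold,
         min_match = mm, threshold = params$threshold),
    class = "uniqueness_report"
  )
}

# Maximal TRUE runs of a logical mask as 0-based half-open intervals.
.mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf(
    "<uniqueness_report>%s common_area=%d aa, unique=%d aa in %d segment(s), %s\n",
    if (is.na(x$circ_id)) "" else paste0(" ", x$circ_id),
    x$common_area_aa, x$unique_aa_count, nrow(x$unique_segments),
    if (x$passes) "PASS" else "FAIL"))
  invisible(x)
}

#' Strict uniqueness gate
#'
#' @param report A [uniqueness_report()].
#' @param threshold Minimum unique-residue count, strict.
#' @return `TRUE` iff `unique_aa_count > threshold`.
#' @export
passes_uniqueness <- function(report, threshold = 2L) {
  report$unique_aa_count > threshold
}

#' Write a uniqueness TSV for a set of reports
#'
#' @param reports List of [uniqueness_report()]s.
#' @param path Output path.
#' @export
write_uniqueness_table <- function(reports, path) {
  df <- do.call(rbind, lapply(reports, function(r) {
    segs <- paste(sprintf("%d-%d", r$unique_segments$start,
                          r$unique_segments$end), collapse = ",")
    data.frame(circ_id = r$circ_id, common_area_aa = r$common_area_aa,
               unique_aa_count = r$unique_aa_count, unique_segments = segs,
               passes = r$passes, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
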