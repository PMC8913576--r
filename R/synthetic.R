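# Synthetic fixtures with planted ground truth. Stand-ins for the real
# inputs (public microarray series and circBase sequences), built so the
# truth of every pipeline stage is known by construction.

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# 12-nt background motif: a stop codon in every reading frame when tiled
# (TAA at offset 0, TGA at 4, TAG at 8) and no ATG in any frame, so
# background regions can never host a qualifying ORF or a start codon.
.BG_MOTIF <- c("T", "A", "A", "C", "T", "G", "A", "A", "T", "A", "G", "A")

.codons_matching <- function(pattern) {
  # pattern: length-3 character vector, NA = free position
  all_codons <- names(.CODON_TABLE)
  keep <- rep(TRUE, 64L)
  for (k in 1:3) {
    if (!is.na(pattern[k]))
      keep <- keep & substr(all_codons, k, k) == pattern[k]
  }
  all_codons[keep]
}

#' Generate a circular sequence with one planted ORF
#'
#' Builds a circle whose only start codon is the planted one, whose
#' background frames hit a stop at least every 12 nt (so no accidental
#' qualifying ORF can exist), and whose planted ATG-to-stop reading has
#' exactly the requested geometry — including rolling-circle overlay,
#' where the reading constrains some circle positions on several laps.
#' The construction is rejection-sampled and then verified with the
#' package's own scanner; the returned truth is exact.
#'
#' @param L Circle length (nt).
#' @param orf_aa_len Planted peptide length; the ORF occupies
#'   `3 * (orf_aa_len + 1)` nt including its stop.
#' @param start_nt 0-based start-codon offset on the returned rotation.
#' @param want_junction Must the ORF span the back-splice junction
#'   (`start_nt + orf_len > L`)?
#' @param want_overlay_bp Required base reuse; must equal
#'   `max(0, orf_len - L)`, otherwise the geometry is infeasible.
#' @param seed Integer seed; the same seed reproduces the same circle.
#' @param circ_id Identifier for the record.
#' @return A list with `record` ([circ_record()]) and `truth` (planted
#'   start/frame/length/peptide/junction/overlay).
#' @export
make_circ_with_orf <- function(L, orf_aa_len, start_nt, want_junction,
                               want_overlay_bp = 0L, seed = 1L,
                               circ_id = sprintf("syn_circ_%04d", seed)) {
  orf_nt <- 3L * (as.integer(orf_aa_len) + 1L)
  L <- as.integer(L); start_nt <- as.integer(start_nt)
  if (start_nt < 0L || start_nt >= L) stop("start_nt must lie in [0, L)")
  if (max(0L, orf_nt - L) != want_overlay_bp)
    stop(sprintf(
      "infeasible geometry: overlay is determined as max(0, %d - %d) = %d, not %d",
      orf_nt, L, max(0L, orf_nt - L), want_overlay_bp))
  if ((start_nt + orf_nt > L) != isTRUE(want_junction))
    stop("infeasible geometry: junction spanning is determined by start and length")

  .with_seed(seed, {
    # Overlaid constructions force every second-lap codon from first-lap
    # choices, so only a small fraction of attempts satisfies all
    # constraints; the attempt bound is sized for overlay near 50 bp.
    for (attempt in 1:5000) {
      circ <- .plant_orf_attempt(L, orf_nt, start_nt)
      if (is.null(circ)) next
      seq <- paste(circ, collapse = "")
      # Pre-check: exactly one circular ATG occurrence, at the planted start.
      ext2 <- paste0(seq, substr(seq, 1L, 2L))
      atg <- as.integer(gregexpr("(?=ATG)", ext2, perl = TRUE)[[1L]]) - 1L
      atg <- atg[atg >= 0L & atg < L]
      if (!identical(atg, start_nt)) next
      rec <- circ_record(circ_id, seq)
      scan <- find_circular_orfs(rec, orf_params(), include_infinite = TRUE)
      if (nrow(scan) != 1L || scan$start_nt != start_nt ||
          !scan$is_complete || scan$orf_len_nt != orf_nt) next
      truth <- list(circ_id = circ_id, start_nt = start_nt,
                    frame = start_nt %% 3L, orf_len_nt = orf_nt,
                    pep_len_aa = as.integer(orf_aa_len),
                    peptide = scan$peptide,
                    spans_junction = scan$spans_junction,
                    overlay_bp = scan$overlay_bp, seed = seed)
      return(list(record = rec, truth = truth))
    }
    stop("could not satisfy the planted-ORF constraints after 5000 attempts")
  })
}

# One construction attempt; NULL when a constraint clashes.
.plant_orf_attempt <- function(L, orf_nt, start_nt) {
  circ <- rep(NA_character_, L)
  n_cod <- orf_nt %/% 3L
  for (j in seq_len(n_cod) - 1L) {
    pos <- (start_nt + 3L * j + 0:2) %% L + 1L
    pattern <- circ[pos]
    choices <- .codons_matching(pattern)
    if (j == 0L) {
      choices <- intersect(choices, "ATG")
    } else if (j == n_cod - 1L) {
      choices <- intersect(choices, .STOP_CODONS)
    } else {
      # interior: no premature stop, no nested start
      choices <- setdiff(choices, c(.STOP_CODONS, "ATG"))
    }
    if (length(choices) == 0L) return(NULL)
    codon <- if (length(choices) == 1L) choices else sample(choices, 1L)
    circ[pos] <- strsplit(codon, "", fixed = TRUE)[[1L]]
  }
  free <- which(is.na(circ))
  if (length(free))
    circ[free] <- .BG_MOTIF[(seq_along(free) - 1L) %% length(.BG_MOTIF) + 1L]
  circ
}

#' Generate a host protein sharing a controlled region with a circ-peptide
#'
#' The host carries `substr(circ_peptide, 1, shared_prefix_len)` verbatim
#' at its start, followed by residues rejection-sampled so that no other
#' exact match of length >= `min_match` exists between host and peptide —
#' the relationship of a circRNA peptide to its host linear protein, with
#' the common-area length known by construction.
#'
#' @param circ_peptide Amino-acid string.
#' @param shared_prefix_len Planted common-area length `k`
#'   (0 <= k <= min(|peptide|, total_len)).
#' @param total_len Host protein length.
#' @param seed Integer seed.
#' @param min_match Match length the construction must avoid elsewhere
#'   (keep equal to the [uniqueness_params()] used downstream).
#' @param protein_id,gene Identifiers for the record.
#' @return A [protein_record()].
#' @export
make_host_protein <- function(circ_peptide, shared_prefix_len, total_len,
                              seed = 1L, min_match = 7L,
                              protein_id = "syn_host", gene = "SYNHOST") {
  k <- as.integer(shared_prefix_len)
  if (k > min(nchar(circ_peptide), total_len))
    stop("shared_prefix_len exceeds peptide or host length")
  aa20 <- setdiff(.AA_ALPHABET, "X")
  prefix <- substr(circ_peptide, 1L, k)
  .with_seed(seed, {
    for (attempt in 1:500) {
      tail_len <- total_len - k
      host <- paste0(prefix,
                     paste(sample(aa20, tail_len, replace = TRUE),
                           collapse = ""))
      rep <- uniqueness_report(circ_peptide,
                               list(structure(list(protein_id = protein_id,
                                                   gene = gene,
                                                   sequence = host),
                                              class = "protein_record")),
                               uniqueness_params(min_match = min_match))
      expected_cov <- rep(FALSE, nchar(circ_peptide))
      if (k >= min_match) expected_cov[seq_len(k)] <- TRUE
      ok_cov <- identical(rep$covered_mask, expected_cov)
      ok_common <- k < min_match || rep$common_area_aa == k
      if (ok_cov && ok_common)
        return(protein_record(protein_id, host, gene = gene))
    }
    stop("could not build a host protein without stray matches after 500 attempts")
  })
}

#' Generate a two-group expression matrix with planted DE rows
#'
#' Gaussian log2 intensities around per-circRNA baselines; the first
#' `n_de` rows get a +/-`lfc` shift (random sign) in the tumor group.
#'
#' @param n_circ Number of circRNAs (rows).
#' @param n_per_group Samples per group (>= 3).
#' @param n_de Number of planted differential rows.
#' @param lfc Planted log2 fold change magnitude.
#' @param sigma Per-sample Gaussian noise SD on the log2 scale.
#' @param seed Integer seed.
#' @return A list: `values` (matrix, rownames are circ ids), `groups`
#'   (per-column `"normal"`/`"tumor"`), `truth` (data frame `circ_id`,
#'   `is_de`, `direction`).
#' @export
make_expression_matrix <- function(n_circ, n_per_group, n_de, lfc, sigma,
                                   seed = 1L) {
  stopifnot(n_de <= n_circ, n_per_group >= 3L)
  .with_seed(seed, {
    ids <- sprintf("syn_circ_%05d", seq_len(n_circ))
    baseline <- stats::runif(n_circ, 6, 12)
    n_s <- 2L * n_per_group
    values <- matrix(stats::rnorm(n_circ * n_s, sd = sigma),
                     nrow = n_circ) + baseline
    groups <- rep(c("normal", "tumor"), each = n_per_group)
    sign_de <- if (n_de > 0L) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
    if (n_de > 0L)
      values[seq_len(n_de), groups == "tumor"] <-
        values[seq_len(n_de), groups == "tumor"] + sign_de * lfc
    dimnames(values) <- list(ids, sprintf("%s_%02d", groups,
                                          c(seq_len(n_per_group),
                                            seq_len(n_per_group))))
    truth <- data.frame(
      circ_id = ids,
      is_de = seq_len(n_circ) <= n_de,
      direction = c(ifelse(sign_de > 0, "up", "down"),
                    rep(NA_character_, n_circ - n_de)),
      stringsAsFactors = FALSE)
    list(values = values, groups = groups, truth = truth)
  })
}
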