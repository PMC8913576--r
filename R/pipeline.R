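#' Pipeline configuration
#'
#' Bundles the per-stage parameters and stage toggles of the scanning
#' strategy. Stage order is fixed — differential expression, then the
#' three ORF rules (junction spanning, peptide length, overlay), then the
#' database coding flag, then host-protein uniqueness — but every stage
#' can be disabled for inputs that lack the corresponding evidence.
#'
#' @param orf An [orf_params()] object.
#' @param uniq A [uniqueness_params()] object.
#' @param digest A [digest_params()] object.
#' @param lfc_cut,q_cut Differential-expression cuts (strict).
#' @param stages Named logical vector toggling `de`, `orf`, `db`,
#'   `uniqueness`.
#' @param pre_filtered Declare the annotation table already DE-gated
#'   upstream: the DE stage then passes every row and only the up/down
#'   direction is recorded.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(orf = orf_params(), uniq = uniqueness_params(),
                            digest = digest_params(), lfc_cut = 1,
                            q_cut = 0.05,
                            stages = c(de = TRUE, orf = TRUE, db = TRUE,
                                       uniqueness = TRUE),
                            pre_filtered = FALSE) {
  full <- c(de = TRUE, orf = TRUE, db = TRUE, uniqueness = TRUE)
  full[names(stages)] <- stages
  if (!any(full)) stop("at least one stage must be enabled")
  structure(list(orf = orf, uniq = uniq, digest = digest,
                 lfc_cut = lfc_cut, q_cut = q_cut, stages = full,
                 pre_filtered = isTRUE(pre_filtered)),
            class = "pipeline_config")
}

.STAGE_NAMES <- c("de", "orf_junction", "pep_len", "overlay", "db",
                  "uniqueness")

#' Run the full candidate scan
#'
#' Applies the scanning strategy stage by stage to every annotated
#' circRNA, with per-stage provenance: each candidate row carries a
#' `pass`/`fail`/`skipped` flag per stage, and a candidate failing a stage
#' keeps `skipped` flags downstream rather than being dropped. A stage is
#' `skipped` when it is disabled, when its evidence is absent (no database
#' flag, no host protein), or when an upstream stage already failed.
#'
#' @param records Named list of [circ_record()]s (names are circ_ids), or
#'   `NULL` when the ORF stage is disabled.
#' @param annotations Annotation data frame (see
#'   [read_annotation_table()]).
#' @param hosts List of [protein_record()]s; matched to candidates by
#'   `gene` (falling back to `protein_id`) against the annotation's
#'   `host_gene`.
#' @param config A [pipeline_config()].
#' @return A data frame of candidate rows sorted by descending `log2fc`
#'   then `circ_id`: annotation columns, `input_ok`, best-ORF columns
#'   (`orf_start_nt`, `orf_len_nt`, `pep_len_aa`, `spans_junction`,
#'   `overlay_bp`, `peptide`), uniqueness columns (`common_area_aa`,
#'   `unique_aa_count`), `stage_<name>` flags and `final_pass`.
#' @export
run_scan <- function(records, annotations, hosts = list(),
                     config = pipeline_config()) {
  if (anyDuplicated(annotations$circ_id))
    stop("conflicting duplicate annotations for: ",
         paste(unique(annotations$circ_id[duplicated(annotations$circ_id)]),
               collapse = ", "))
  host_keys <- vapply(hosts, function(h)
    if (nzchar(h$gene)) h$gene else h$protein_id, character(1))
  rows <- lapply(seq_len(nrow(annotations)), function(i)
    .scan_one(annotations[i, ], records, hosts, host_keys, config))
  out <- do.call(rbind, rows)
  out <- out[order(-out$log2fc, out$circ_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.scan_one <- function(ann, records, hosts, host_keys, config) {
  flags <- stats::setNames(rep("skipped", length(.STAGE_NAMES)), .STAGE_NAMES)
  input_ok <- TRUE
  orf_row <- NULL
  uniq <- list(common_area_aa = NA_integer_, unique_aa_count = NA_integer_)
  failed <- FALSE

  if (config$stages[["de"]] && !failed) {
    if (config$pre_filtered) {
      flags[["de"]] <- "pass"            # gate already applied upstream
    } else {
      ok <- abs(ann$log2fc) > config$lfc_cut &&
        (is.na(ann$adj_p) || ann$adj_p < config$q_cut)
      flags[["de"]] <- if (isTRUE(ok)) "pass" else "fail"
      failed <- !isTRUE(ok)
    }
  }

  if (config$stages[["orf"]] && !failed) {
    rec <- records[[ann$circ_id]]
    if (is.null(rec)) {
      warning("no sequence for annotated circRNA '", ann$circ_id,
              "'; row marked failed at input")
      input_ok <- FALSE
      failed <- TRUE
    } else {
      orfs <- find_circular_orfs(rec, config$orf)
      s1 <- if (config$orf$require_junction)
        orfs[orfs$spans_junction, , drop = FALSE] else orfs
      if (nrow(s1) == 0L) {
        flags[["orf_junction"]] <- "fail"; failed <- TRUE
      } else {
        flags[["orf_junction"]] <- "pass"
        s2 <- s1[s1$pep_len_aa >= config$orf$min_pep_aa, , drop = FALSE]
        if (nrow(s2) == 0L) {
          flags[["pep_len"]] <- "fail"; failed <- TRUE
        } else {
          flags[["pep_len"]] <- "pass"
          s3 <- s2[s2$overlay_bp <= config$orf$max_overlay_bp, , drop = FALSE]
          if (nrow(s3) == 0L) {
            flags[["overlay"]] <- "fail"; failed <- TRUE
          } else {
            flags[["overlay"]] <- "pass"
            orf_row <- best_orf(s3)
          }
        }
      }
    }
  }

  if (config$stages[["db"]] && !failed) {
    flag <- ann$db_coding_flag
    if (is.na(flag)) {
      flags[["db"]] <- "skipped"          # no database evidence supplied
    } else {
      flags[["db"]] <- if (isTRUE(flag)) "pass" else "fail"
      failed <- !isTRUE(flag)
    }
  }

  if (config$stages[["uniqueness"]] && !failed && !is.null(orf_row)) {
    cand_hosts <- hosts[host_keys == ann$host_gene & nzchar(ann$host_gene)]
    if (length(cand_hosts) == 0L) {
      flags[["uniqueness"]] <- "skipped"  # no host protein available
    } else {
      rep <- uniqueness_report(orf_row$peptide, cand_hosts, config$uniq,
                               circ_id = ann$circ_id)
      uniq <- rep
      flags[["uniqueness"]] <- if (rep$passes) "pass" else "fail"
      failed <- !rep$passes
    }
  }

  final_pass <- input_ok && all(flags != "fail")
  if (config$stages[["orf"]]) final_pass <- final_pass && !is.null(orf_row)

  out <- data.frame(
    circ_id = ann$circ_id, log2fc = ann$log2fc, adj_p = ann$adj_p,
    host_gene = ann$host_gene, transcript = ann$transcript,
    genomic_position = ann$genomic_position,
    db_coding_flag = ann$db_coding_flag, input_ok = input_ok,
    orf_start_nt = if (is.null(orf_row)) NA_integer_ else orf_row$start_nt,
    orf_len_nt = if (is.null(orf_row)) NA_integer_ else orf_row$orf_len_nt,
    pep_len_aa = if (is.null(orf_row)) NA_integer_ else orf_row$pep_len_aa,
    spans_junction = if (is.null(orf_row)) NA else orf_row$spans_junction,
    overlay_bp = if (is.null(orf_row)) NA_integer_ else orf_row$overlay_bp,
    peptide = if (is.null(orf_row)) NA_character_ else orf_row$peptide,
    common_area_aa = uniq$common_area_aa,
    unique_aa_count = uniq$unique_aa_count,
    stringsAsFactors = FALSE)
  for (s in .STAGE_NAMES) out[[paste0("stage_", s)]] <- flags[[s]]
  out$final_pass <- final_pass
  out
}

#' Summarize a candidate table
#'
#' Per-stage survivor counts along the fixed stage order, the final
#' candidate count, and the up/down partition of final candidates by sign
#' of `log2fc`.
#'
#' @param rows Candidate data frame from [run_scan()].
#' @return A list: `n_input`, `stage_counts` (named integer vector of
#'   rows not failed at or before each stage), `n_final`, `n_up`,
#'   `n_down`.
#' @export
summarize_candidates <- function(rows) {
  if (nrow(rows) == 0L) {
    return(list(n_input = 0L,
                stage_counts = stats::setNames(rep(0L, length(.STAGE_NAMES)),
                                               .STAGE_NAMES),
                n_final = 0L, n_up = 0L, n_down = 0L))
  }
  alive <- rep(TRUE, nrow(rows)) & rows$input_ok
  counts <- integer(0)
  for (s in .STAGE_NAMES) {
    alive <- alive & rows[[paste0("stage_", s)]] != "fail"
    counts[s] <- sum(alive)
  }
  final <- rows[rows$final_pass, , drop = FALSE]
  list(n_input = nrow(rows), stage_counts = counts,
       n_final = nrow(final),
       n_up = sum(final$log2fc > 0), n_down = sum(final$log2fc < 0))
}
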