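#' Two-sided Welch t-test p-value
#'
#' Stand-in for moderated microarray statistics: an unequal-variance t on
#' log2 intensities. Degenerate inputs (zero variance in both groups) give
#' p = 1 when the means are equal and p = 0 otherwise, so constant planted
#' shifts are never discarded.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return Two-sided p-value.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / length(a) + vb / length(b)
  if (se2 == 0) return(if (mean(a) == mean(b)) 1 else 0)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1L) +
                 (vb / length(b))^2 / (length(b) - 1L))
  2 * stats::pt(-abs(t), df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure with monotonicity enforcement; input order
#' is preserved.
#'
#' @param pvals Numeric vector in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvals[o]))[ro]
}

#' Row-wise differential expression on a two-group matrix
#'
#' Welch t per row plus BH adjustment; fold change is tumor mean minus
#' normal mean on the log2 scale.
#'
#' @param values Numeric matrix, circRNAs in rows, samples in columns,
#'   log2 intensities.
#' @param groups Character/factor per column, levels `"normal"` and
#'   `"tumor"`, each with >= 2 samples.
#' @return A data frame: `circ_id`, `log2fc`, `p`, `adj_p`, `direction`
#'   (`up` iff `log2fc > 0`).
#' @export
de_results <- function(values, groups) {
  groups <- as.character(groups)
  if (!all(groups %in% c("normal", "tumor")))
    stop("groups must be 'normal' or 'tumor'")
  it <- groups == "tumor"; inl <- !it
  if (sum(it) < 2L || sum(inl) < 2L)
    stop("each group needs at least 2 samples")
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("circ_%05d", seq_len(nrow(values)))
  nt <- sum(it); nn <- sum(inl)
  mt <- rowMeans(values[, it, drop = FALSE])
  mn <- rowMeans(values[, inl, drop = FALSE])
  vt <- apply(values[, it, drop = FALSE], 1L, stats::var)
  vn <- apply(values[, inl, drop = FALSE], 1L, stats::var)
  se2 <- vt / nt + vn / nn
  tstat <- (mt - mn) / sqrt(se2)
  df <- se2^2 / ((vt / nt)^2 / (nt - 1L) + (vn / nn)^2 / (nn - 1L))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se2 == 0] <- ifelse(mt[se2 == 0] == mn[se2 == 0], 1, 0)
  data.frame(circ_id = ids, log2fc = mt - mn, p = p, adj_p = bh_adjust(p),
             direction = ifelse(mt - mn > 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the differential-expression gate
#'
#' Keeps rows with `|log2fc| > lfc_cut` and `adj_p < q_cut`, both strict:
#' a row at exactly the fold-change cut is rejected. With
#' `pre_filtered = TRUE` the input is declared already gated upstream
#' (e.g. a published candidate table printing only fold changes); all rows
#' are kept and only the up/down direction is computed.
#'
#' @param df Data frame with `log2fc` and (unless pre-filtered) `adj_p`.
#' @param lfc_cut,q_cut Strict cuts; defaults `1` and `0.05`.
#' @param pre_filtered Declare the table already gated.
#' @return The kept rows with a `direction` column.
#' @export
apply_de_gate <- function(df, lfc_cut = 1, q_cut = 0.05,
                          pre_filtered = FALSE) {
  if (!pre_filtered) {
    if (!"adj_p" %in% names(df) || anyNA(df$adj_p))
      stop("adj_p missing; pass pre_filtered = TRUE for already-gated tables")
    keep <- abs(df$log2fc) > lfc_cut & df$adj_p < q_cut
    df <- df[keep, , drop = FALSE]
  }
  df$direction <- ifelse(df$log2fc > 0, "up", "down")
  rownames(df) <- NULL
  df
}

#' Merge differential-expression lists from several datasets
#'
#' Union by `circ_id`, keeping the entry with the largest absolute fold
#' change when a circRNA appears in more than one list.
#'
#' @param ... Data frames with `circ_id` and `log2fc`.
#' @return One merged data frame.
#' @export
merge_de_lists <- function(...) {
  all <- do.call(rbind, lapply(list(...), function(d) d))
  all <- all[order(-abs(all$log2fc)), , drop = FALSE]
  out <- all[!duplicated(all$circ_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
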