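# Independent brute-force oracles. Deliberately naive: explicit modular
# indexing on character vectors, translation via Biostrings::GENETIC_CODE,
# substring enumeration for common substrings. These stay independent of
# the package's extended-string scanner and DP implementations.

oracle_orfs <- function(seq, max_cycles = 3L, include_infinite = FALSE) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(ch)
  gc_tab <- Biostrings::GENETIC_CODE
  stops <- names(gc_tab)[gc_tab == "*"]
  rows <- list()
  for (s in 0:(L - 1L)) {
    first <- paste0(ch[s %% L + 1L], ch[(s + 1L) %% L + 1L],
                    ch[(s + 2L) %% L + 1L])
    if (first != "ATG") next
    k <- 0L
    pep <- character(0)
    complete <- FALSE
    while (3L * (k + 1L) <= max_cycles * L) {
      codon <- paste0(ch[(s + 3L * k) %% L + 1L],
                      ch[(s + 3L * k + 1L) %% L + 1L],
                      ch[(s + 3L * k + 2L) %% L + 1L])
      if (codon %in% stops) {
        complete <- TRUE
        break
      }
      aa <- unname(gc_tab[codon])
      pep <- c(pep, if (is.na(aa)) "X" else aa)
      k <- k + 1L
    }
    if (complete) {
      orf_len <- 3L * (k + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        start_nt = s, orf_len_nt = orf_len, pep_len_aa = k,
        spans_junction = s + orf_len > L,
        overlay_bp = max(0L, orf_len - L), is_complete = TRUE,
        is_infinite = FALSE, peptide = paste(pep, collapse = ""),
        stringsAsFactors = FALSE)
    } else if (include_infinite) {
      rows[[length(rows) + 1L]] <- data.frame(
        start_nt = s, orf_len_nt = NA_integer_, pep_len_aa = NA_integer_,
        spans_junction = NA, overlay_bp = NA_integer_, is_complete = FALSE,
        is_infinite = TRUE, peptide = "", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start_nt = integer(0), orf_len_nt = integer(0),
                      pep_len_aa = integer(0), spans_junction = logical(0),
                      overlay_bp = integer(0), is_complete = logical(0),
                      is_infinite = logical(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df[order(df$start_nt), , drop = FALSE]
}

# Canonical form for comparing scanner output against the oracle.
canon_orfs <- function(df) {
  df <- df[order(df$start_nt),
           c("start_nt", "orf_len_nt", "pep_len_aa", "spans_junction",
             "overlay_bp", "is_complete", "is_infinite", "peptide"),
           drop = FALSE]
  rownames(df) <- NULL
  df
}

random_circle <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# O(n^2 m) longest-common-substring oracle: try lengths descending,
# starts ascending, locate in b with fixed-string matching.
oracle_lcs <- function(a, b) {
  n <- nchar(a)
  for (len in min(n, nchar(b)):1) {
    for (i in 1:(n - len + 1L)) {
      sub <- substr(a, i, i + len - 1L)
      j <- regexpr(sub, b, fixed = TRUE)[1L]
      if (j > 0L)
        return(list(length = len, pos_a = i - 1L, pos_b = j - 1L))
    }
  }
  list(length = 0L, pos_a = NA_integer_, pos_b = NA_integer_)
}

random_peptide <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], n,
               replace = TRUE), collapse = "")
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
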