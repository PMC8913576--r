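test_that("translation follows the standard code with N -> X", {
  expect_identical(translate_nt("ATGAAAGGG"), "MKG")
  expect_identical(translate_nt("ATGNNN"), "MX")
  expect_identical(translate_nt("TAATAGTGA"), "***")
  expect_error(translate_nt("ATGA"), "multiple of 3")

  set.seed(41)
  nt <- random_circle(900)   # 300 codons
  gc_tab <- Biostrings::GENETIC_CODE
  starts <- seq(1, 900, 3)
  expected <- paste(unname(gc_tab[substring(nt, starts, starts + 2)]),
                    collapse = "")
  expect_identical(translate_nt(nt), expected)
})

test_that("hand-traced circles: linear, junction-wrapping and infinite ORFs", {
  lin <- find_circular_orfs(circ_record("lin", "ATGAAAGGGTAG"))
  expect_identical(nrow(lin), 1L)
  expect_identical(lin$start_nt, 0L)
  expect_identical(lin$orf_len_nt, 12L)
  expect_identical(lin$peptide, "MKG")
  expect_false(lin$spans_junction)
  expect_identical(lin$overlay_bp, 0L)

  # same codons rotated so the ORF wraps the back-splice junction
  wrap <- find_circular_orfs(circ_record("wrap", "AAGGGTAGATGA"))
  expect_identical(nrow(wrap), 1L)
  expect_identical(wrap$start_nt, 8L)
  expect_identical(wrap$orf_len_nt, 12L)
  expect_identical(wrap$peptide, "MKG")
  expect_true(wrap$spans_junction)
  expect_identical(wrap$overlay_bp, 0L)

  # L multiple of 3, single ATG, no stop in its frame: infinite, excluded
  inf <- find_circular_orfs(circ_record("inf", "ATGAAAAAA"))
  expect_identical(nrow(inf), 0L)
  diag <- find_circular_orfs(circ_record("inf", "ATGAAAAAA"),
                             include_infinite = TRUE)
  expect_identical(nrow(diag), 1L)
  expect_true(diag$is_infinite)
  expect_false(diag$is_complete)

  expect_error(find_circular_orfs(circ_record("tiny", "AT")),
               "shorter than one codon")
})

test_that("scanner matches the brute-force oracle on random circles", {
  set.seed(101)
  for (i in 1:400) {
    L <- sample(3:15, 1)
    s <- random_circle(L)
    expect_identical(
      canon_orfs(find_circular_orfs(circ_record("x", s),
                                    include_infinite = TRUE)),
      canon_orfs(oracle_orfs(s, include_infinite = TRUE)),
      info = s)
  }
  for (i in 1:100) {
    s <- random_circle(sample(16:60, 1))
    expect_identical(
      canon_orfs(find_circular_orfs(circ_record("x", s),
                                    include_infinite = TRUE)),
      canon_orfs(oracle_orfs(s, include_infinite = TRUE)),
      info = s)
  }
})

test_that("rotation covariance: peptide multiset is rotation-invariant", {
  set.seed(19)
  for (i in 1:40) {
    L <- sample(12:60, 1)
    s <- random_circle(L)
    r <- sample(L - 1, 1)
    rot <- paste0(substr(s, r + 1, L), substr(s, 1, r))
    a <- find_circular_orfs(circ_record("a", s))
    b <- find_circular_orfs(circ_record("b", rot))
    key <- function(d) sort(paste(d$peptide, d$orf_len_nt, d$is_complete))
    expect_identical(key(a), key(b))
    # starts shift by -r mod L
    expect_setequal(b$start_nt, (a$start_nt - r) %% L)
  }
})

test_that("linear consistency: non-wrapping ORFs match a linear scan", {
  set.seed(23)
  for (i in 1:40) {
    s <- random_circle(sample(30:90, 1))
    L <- nchar(s)
    circ <- find_circular_orfs(circ_record("x", s))
    lin <- circ[circ$start_nt + circ$orf_len_nt <= L, , drop = FALSE]
    for (j in seq_len(nrow(lin))) {
      orf_nt <- substr(s, lin$start_nt[j] + 1,
                       lin$start_nt[j] + lin$orf_len_nt[j])
      expect_identical(substr(orf_nt, 1, 3), "ATG")
      expect_identical(translate_nt(substr(orf_nt, 1, nchar(orf_nt) - 3)),
                       lin$peptide[j])
    }
  }
})

test_that("three cycles are exhaustive when L is not a multiple of 3", {
  set.seed(29)
  n <- 0
  while (n < 60) {
    L <- sample(4:60, 1)
    if (L %% 3 == 0) next
    n <- n + 1
    s <- random_circle(L)
    rec <- circ_record("x", s)
    a <- canon_orfs(find_circular_orfs(rec, orf_params(max_cycles = 3),
                                       include_infinite = TRUE))
    b <- canon_orfs(find_circular_orfs(rec, orf_params(max_cycles = 6),
                                       include_infinite = TRUE))
    expect_identical(a, b, info = s)
  }
})

test_that("overlay accounting holds for every emitted ORF", {
  set.seed(31)
  for (i in 1:60) {
    s <- random_circle(sample(5:50, 1))
    L <- nchar(s)
    orfs <- find_circular_orfs(circ_record("x", s))
    expect_identical(orfs$overlay_bp, pmax(0L, orfs$orf_len_nt - L))
    expect_identical(orfs$spans_junction, orfs$start_nt + orfs$orf_len_nt > L)
    expect_true(all(orfs$orf_len_nt %% 3L == 0L))
    expect_identical(orfs$pep_len_aa, orfs$orf_len_nt %/% 3L - 1L)
    expect_false(any(grepl("*", orfs$peptide, fixed = TRUE)))
  }
})

test_that("filter rules are strict at the published boundaries", {
  sim50 <- make_circ_with_orf(L = 240, orf_aa_len = 50, start_nt = 200,
                              want_junction = TRUE, want_overlay_bp = 0,
                              seed = 61)
  orfs <- find_circular_orfs(sim50$record)
  kept <- filter_orfs(orfs)
  expect_identical(nrow(kept), 0L)
  expect_identical(attr(kept, "rejections")$rule, "pep_len")

  kept51 <- filter_orfs(find_circular_orfs(
    make_circ_with_orf(L = 240, orf_aa_len = 51, start_nt = 200,
                       want_junction = TRUE, want_overlay_bp = 0,
                       seed = 62)$record))
  expect_identical(nrow(kept51), 1L)

  # overlay exactly 50 rejected, 49 kept (rule 3 strict)
  ov50 <- make_circ_with_orf(L = 253, orf_aa_len = 100, start_nt = 10,
                             want_junction = TRUE, want_overlay_bp = 50,
                             seed = 63)
  k50 <- filter_orfs(find_circular_orfs(ov50$record))
  expect_identical(nrow(k50), 0L)
  expect_identical(attr(k50, "rejections")$rule, "overlay")
  ov49 <- make_circ_with_orf(L = 254, orf_aa_len = 100, start_nt = 10,
                             want_junction = TRUE, want_overlay_bp = 49,
                             seed = 64)
  expect_identical(nrow(filter_orfs(find_circular_orfs(ov49$record))), 1L)

  # non-junction ORF rejected unless require_junction is off
  nj <- make_circ_with_orf(L = 300, orf_aa_len = 60, start_nt = 0,
                           want_junction = FALSE, want_overlay_bp = 0,
                           seed = 65)
  knj <- filter_orfs(find_circular_orfs(nj$record))
  expect_identical(nrow(knj), 0L)
  expect_identical(attr(knj, "rejections")$rule, "junction")
  expect_identical(
    nrow(filter_orfs(find_circular_orfs(nj$record),
                     orf_params(require_junction = FALSE))), 1L)
})

test_that("best_orf promotes the longest peptide, ties to smallest start", {
  orfs <- data.frame(circ_id = "c", start_nt = c(30L, 10L, 20L),
                     frame = 0L, orf_len_nt = c(183L, 183L, 150L),
                     pep_len_aa = c(60L, 60L, 49L), spans_junction = TRUE,
                     overlay_bp = 0L, is_complete = TRUE,
                     is_infinite = FALSE, peptide = "M",
                     stringsAsFactors = FALSE)
  expect_identical(best_orf(orfs)$start_nt, 10L)
  expect_null(best_orf(orfs[0, ]))
})
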