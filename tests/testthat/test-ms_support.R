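test_that("tryptic digestion applies the KR|not-P rule", {
  d <- tryptic_digest("MKRAPK", digest_params(0, 1, 100))
  expect_identical(d$fragment, c("MK", "R", "APK"))
  expect_identical(d$start, c(0L, 2L, 3L))
  expect_identical(d$end, c(2L, 3L, 6L))

  # K before P does not cleave
  expect_identical(tryptic_digest("AKPR", digest_params(0, 1, 100))$fragment,
                   "AKPR")
  # unless strict KR is requested
  expect_identical(tryptic_digest("AKPR", digest_params(0, 1, 100),
                                  strict_kr = TRUE)$fragment, c("AK", "PR"))
  expect_error(tryptic_digest(""), "non-empty")
})

test_that("0-missed fragments tile the peptide; missed counts match runs", {
  set.seed(89)
  for (i in 1:30) {
    pep <- random_peptide(sample(10:80, 1))
    d <- tryptic_digest(pep, digest_params(2, 1, 1000))
    d0 <- d[d$missed_cleavages == 0L, ]
    expect_identical(paste(d0$fragment, collapse = ""), pep)
    expect_identical(d0$start[1], 0L)
    expect_identical(d0$end[nrow(d0)], nchar(pep))
    expect_identical(d0$start[-1], d0$end[-nrow(d0)])
    for (m in 1:2) {
      dm <- d[d$missed_cleavages == m, ]
      expect_identical(nrow(dm), max(0L, nrow(d0) - m))
      # each m-missed fragment concatenates m+1 adjacent 0-missed ones
      for (j in seq_len(nrow(dm))) {
        expect_identical(dm$fragment[j],
                         substr(pep, dm$start[j] + 1, dm$end[j]))
      }
    }
  }
})

test_that("peptide masses: reference residues, additivity, mono < avg", {
  expect_equal(peptide_mass("G", "avg"), 75.0672, tolerance = 1e-4)
  expect_equal(peptide_mass("AG", "avg"), 146.146, tolerance = 1e-3)
  expect_error(peptide_mass(""), "non-empty")
  expect_error(peptide_mass("AXA"), "non-standard")

  set.seed(97)
  water <- c(mono = 18.0105646863, avg = 18.0153)
  for (i in 1:25) {
    f1 <- random_peptide(sample(2:20, 1))
    f2 <- random_peptide(sample(2:20, 1))
    for (kind in c("mono", "avg")) {
      expect_equal(peptide_mass(paste0(f1, f2), kind),
                   peptide_mass(f1, kind) + peptide_mass(f2, kind) -
                     water[[kind]],
                   tolerance = 1e-6)
    }
    expect_lt(peptide_mass(f1, "mono"), peptide_mass(f1, "avg"))
  }
})

test_that("evidence selection keeps exactly unique-overlapping fragments", {
  # peptide with a known unique segment (3, 7): host covers the rest
  pep <- "ABCDEFGHIJKLMNOPQRST"
  pep <- gsub("[BJOUXZ]", "S", pep)   # legal residues only
  report <- list(circ_id = "c1",
                 covered_mask = !(seq_len(nchar(pep)) %in% 4:7),
                 unique_aa_count = 4L)
  digest <- data.frame(
    fragment = c(substr(pep, 1, 2), substr(pep, 3, 6), substr(pep, 8, 20)),
    start = c(0L, 2L, 7L), end = c(2L, 6L, 20L), missed_cleavages = 0L,
    stringsAsFactors = FALSE)
  ev <- select_evidence_peptides(digest, report)
  expect_identical(ev$start, 2L)               # only (2,6) overlaps (3,7)
  expect_identical(ev$unique_aa_overlap, 3L)   # positions 3,4,5
  expect_true(all(ev$mono_mass_da < ev$avg_mass_da))

  # zero unique residues: nothing selected
  report0 <- list(circ_id = "c1", covered_mask = rep(TRUE, nchar(pep)))
  expect_identical(nrow(select_evidence_peptides(digest, report0)), 0L)

  # no hosts: everything unique, all fragments kept
  rep_all <- uniqueness_report(pep, circ_id = "c1")
  ev_all <- select_evidence_peptides(digest, rep_all)
  expect_identical(nrow(ev_all), nrow(digest))
  expect_identical(ev_all$unique_aa_overlap, ev_all$end - ev_all$start)

  # interval-overlap brute force on random masks
  set.seed(101)
  for (i in 1:20) {
    p <- random_peptide(40)
    mask <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    rep <- list(circ_id = "x", covered_mask = mask)
    d <- tryptic_digest(p, digest_params(1, 1, 100))
    ev <- select_evidence_peptides(d, rep)
    for (j in seq_len(nrow(d))) {
      want <- sum(!mask[(d$start[j] + 1):d$end[j]])
      sel <- ev[ev$start == d$start[j] & ev$end == d$end[j], ]
      if (want >= 1) expect_identical(sel$unique_aa_overlap[1], want)
      else expect_identical(nrow(sel), 0L)
    }
  }
})

test_that("search database export round-trips and is deterministic", {
  cands <- data.frame(circ_id = c("cA", "cB", "cC"),
                      orf_start_nt = c(10L, 20L, 30L),
                      pep_len_aa = c(3L, 3L, 5L),
                      peptide = c("MKG", "MKG", "MKGWS"),
                      stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".fa")
  p2 <- withr::local_tempfile(fileext = ".fa")
  export_search_db(cands, p1)
  export_search_db(cands, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_fasta(p1, "protein")
  expect_length(back, 3L)   # duplicate peptides kept under distinct headers
  expect_identical(names(back), c("cA|10|3", "cB|20|3", "cC|30|5"))
  expect_identical(back[["cA|10|3"]]$sequence, "MKG")
})
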