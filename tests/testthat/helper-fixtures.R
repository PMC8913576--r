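# A 10-circle fixture with mixed planted failure modes: four candidates
# that pass every stage, and one planted failure per stage of the funnel.
# Every circle carries a qualifying-geometry ORF unless its failure mode
# is an ORF rule; truth records which stage must trip.
make_mixed_fixture <- function(seed) {
  base <- (seed %% 1000000L) * 100L
  specs <- list(
    list(id = "pass1", L = 240L, aa = 60L, s = 150L, junc = TRUE, ov = 0L,
         lfc = 2.5, db = TRUE, shared = 30L, fail = NA),
    list(id = "pass2", L = 300L, aa = 75L, s = 280L, junc = TRUE, ov = 0L,
         lfc = 1.8, db = TRUE, shared = 50L, fail = NA),
    list(id = "pass3", L = 200L, aa = 70L, s = 50L, junc = TRUE, ov = 13L,
         lfc = -2.2, db = TRUE, shared = 20L, fail = NA),
    list(id = "pass4", L = 164L, aa = 70L, s = 5L, junc = TRUE, ov = 49L,
         lfc = 3.1, db = TRUE, shared = 0L, fail = NA),
    list(id = "fail_de", L = 240L, aa = 60L, s = 150L, junc = TRUE, ov = 0L,
         lfc = 0.5, db = TRUE, shared = 30L, fail = "de"),
    list(id = "fail_junction", L = 400L, aa = 70L, s = 0L, junc = FALSE,
         ov = 0L, lfc = 2.0, db = TRUE, shared = 30L, fail = "orf_junction"),
    list(id = "fail_peplen", L = 240L, aa = 50L, s = 200L, junc = TRUE,
         ov = 0L, lfc = 2.0, db = TRUE, shared = 30L, fail = "pep_len"),
    list(id = "fail_overlay", L = 163L, aa = 70L, s = 5L, junc = TRUE,
         ov = 50L, lfc = 2.0, db = TRUE, shared = 30L, fail = "overlay"),
    list(id = "fail_db", L = 240L, aa = 60L, s = 150L, junc = TRUE, ov = 0L,
         lfc = 2.0, db = FALSE, shared = 30L, fail = "db"),
    list(id = "fail_unique", L = 240L, aa = 60L, s = 150L, junc = TRUE,
         ov = 0L, lfc = 2.0, db = TRUE, shared = 60L, fail = "uniqueness"))
  records <- list(); hosts <- list(); ann <- list(); expected <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sim <- make_circ_with_orf(sp$L, sp$aa, sp$s, sp$junc, sp$ov,
                              seed = base + i, circ_id = sp$id)
    records[[sp$id]] <- sim$record
    gene <- paste0("HOST_", sp$id)
    shared <- min(sp$shared, nchar(sim$truth$peptide))
    hosts[[i]] <- make_host_protein(sim$truth$peptide, shared,
                                    max(100L, shared + 40L),
                                    seed = base + 50L + i,
                                    protein_id = paste0("prot_", sp$id),
                                    gene = gene)
    ann[[i]] <- data.frame(circ_id = sp$id, log2fc = sp$lfc, adj_p = 0.001,
                           host_gene = gene, transcript = NA_character_,
                           genomic_position = NA_character_,
                           db_coding_flag = sp$db, stringsAsFactors = FALSE)
    expected[[i]] <- data.frame(circ_id = sp$id,
                                final_pass = is.na(sp$fail),
                                fail_stage = if (is.na(sp$fail))
                                  NA_character_ else sp$fail,
                                stringsAsFactors = FALSE)
  }
  list(records = records, ann = do.call(rbind, ann), hosts = hosts,
       expected = do.call(rbind, expected))
}

check_mixed_run <- function(out, expected) {
  ok <- TRUE
  for (i in seq_len(nrow(expected))) {
    row <- out[out$circ_id == expected$circ_id[i], ]
    if (row$final_pass != expected$final_pass[i]) ok <- FALSE
    if (!is.na(expected$fail_stage[i])) {
      if (row[[paste0("stage_", expected$fail_stage[i])]] != "fail")
        ok <- FALSE
      # no other stage may fail: the planted defect is the only one
      other <- setdiff(c("de", "orf_junction", "pep_len", "overlay", "db",
                         "uniqueness"), expected$fail_stage[i])
      if (any(unlist(row[paste0("stage_", other)]) == "fail")) ok <- FALSE
    }
  }
  ok
}
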