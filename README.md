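# circpepscan

Scanning circular RNAs for peptide-coding potential.

Circular RNAs (circRNAs) are covalently closed transcripts made by
back-splicing. Some are translated, and a circRNA-derived peptide can be
distinguished from its host-gene protein only through the back-splice
junction: the open reading frame must cross the junction, and the
peptide must contain residues the linear host protein does not.
`circpepscan` is for computational biologists who want to nominate such
peptide-coding circRNA candidates from sequence and expression data and
prepare the evidence needed to verify them by LC-MS/MS.

The package implements a candidate funnel:

1. **Differential expression** — keep circRNAs with `|log2FC| > 1` and
   BH-adjusted `p < 0.05` (Welch *t* + Benjamini–Hochberg stand-in, or a
   precomputed DE table);
2. **Circular ORF scan** — for circle length *L* and start position
   *s*, codons are read at indices `(s + 3k + j) mod L` until the first
   in-frame stop, up to `3L` nt (three laps are provably exhaustive);
   stop-free "infinite" readings are excluded;
3. **Sequence rules** — ORF spans the junction
   (`start + orf_len > L`), peptide `> 50` aa, base reuse (overlay,
   `max(0, orf_len − L)`) `< 50` bp; all strict;
4. **Database flag** — optional boolean coding-potential annotation
   from external registries, consumed as input, never queried;
5. **Uniqueness** — more than 2 peptide residues not covered by any
   exact `≥ 7`-aa match to the host protein.

Survivors come with per-stage provenance, an in-silico tryptic digest
(KR|¬P rule) with monoisotopic/average masses, and a protein-FASTA
search database for MS engines. A synthetic-fixture generator plants
ORFs, host proteins and expression shifts with exact known truth, so
the whole funnel is testable without downloads.

## Worked example

Generate a circle with a planted junction-spanning 60-aa ORF, a host
protein sharing its first 30 residues, and run the scan:

```r
library(circpepscan)

sim  <- make_circ_with_orf(L = 240, orf_aa_len = 60, start_nt = 150,
                           want_junction = TRUE, want_overlay_bp = 0,
                           seed = 7, circ_id = "demo_circ")
host <- make_host_protein(sim$truth$peptide, shared_prefix_len = 30,
                          total_len = 120, seed = 8,
                          protein_id = "demo_host", gene = "DEMO")
ann  <- data.frame(circ_id = "demo_circ", log2fc = 2.1, adj_p = 0.003,
                   host_gene = "DEMO", transcript = NA,
                   genomic_position = NA, db_coding_flag = TRUE)

out <- run_scan(list(demo_circ = sim$record), ann, list(host),
                pipeline_config())
out[, c("circ_id", "pep_len_aa", "spans_junction", "overlay_bp",
        "unique_aa_count", "final_pass")]
#>    circ_id pep_len_aa spans_junction overlay_bp unique_aa_count final_pass
#> 1 demo_circ         60           TRUE          0              30       TRUE
```

The planted ORF starts at position 150 on a 240-nt circle, so its
183 nt (60 codons + stop) wrap the back-splice junction with no base
read twice; 30 of its 60 residues are not explainable by the host
protein, so the uniqueness gate (> 2 unique aa) passes and the row
survives every stage. Tryptic evidence peptides for the MS search:

```r
rep <- uniqueness_report(sim$truth$peptide, list(host),
                         circ_id = "demo_circ")
ev  <- select_evidence_peptides(
  tryptic_digest(sim$truth$peptide, digest_params()), rep)
ev[1, c("fragment", "missed_cleavages", "unique_aa_overlap",
        "mono_mass_da")]
#>             fragment missed_cleavages unique_aa_overlap mono_mass_da
#> 1 LNIRQNPRVTTDILSSST                2                18     2014.081
```

Each selected fragment overlaps at least one unique residue; its
neutral monoisotopic mass (residue sum + H2O) is what a search engine
would match against observed spectra.

The same pipeline is exposed as a CLI (`inst/cli/circpepscan.R`) with
subcommands `scan`, `orfs`, `unique`, `digest`, `defilter`, `simulate`.
A 57-row published candidate table ships in
`inst/extdata/table1_candidates.tsv`; loaded pre-filtered it partitions
into 46 up- and 11 down-regulated candidates.

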