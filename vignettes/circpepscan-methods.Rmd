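---
title: "Methods: scanning circular RNAs for peptide-coding potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning circular RNAs for peptide-coding potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circpepscan)
```

## The problem

Circular RNAs (circRNAs) are covalently closed, single-stranded
transcripts produced by back-splicing. They carry no 5' cap and no
poly-A tail, yet a growing number have been shown to be translated
through cap-independent initiation. Because the back-splice junction is
the only sequence feature a circRNA does not share with its linear host
transcript, a peptide can be attributed to the circle — rather than to
the host mRNA — only if its reading frame crosses that junction and if
it contains residues that the host protein does not.

`circpepscan` implements a candidate funnel for this attribution
problem. Starting from mature circRNA sequences, an annotation table
with expression statistics, and (optionally) host-gene protein
sequences, it applies in order:

1. a **differential-expression gate**: `|log2FC| > 1` and BH-adjusted
   `p < 0.05`, both strict;
2. **circular ORF detection** with junction wraparound and rolling-circle
   reading, excluding *infinite* ORFs (readings that never meet an
   in-frame stop);
3. the three **sequence rules**: the ORF spans the back-splice junction,
   the encoded peptide is longer than 50 aa, and fewer than 50 bases of
   the circle are read more than once (*overlay*);
4. an optional **database coding flag** consumed as a boolean annotation
   (external registries are never queried);
5. a **uniqueness gate**: the predicted peptide must contain more than
   two residues not explainable by the host linear protein.

Survivors are emitted as a candidate table with full per-stage
provenance, together with mass-spectrometry support: an in-silico
tryptic digest, selection of fragments overlapping the unique region,
monoisotopic/average masses, and a protein-FASTA search database.

## Circular ORF model

The circle of length $L$ is supplied linearly from an arbitrary
rotation; by convention the back-splice junction sits between the last
and first base of that rotation. For every position $s$ carrying a
start codon (ATG by default) the scanner reads codons at indices
$(s + 3k + j) \bmod L$ until the first exact in-frame stop, up to a
bound of $3L$ nucleotides from $s$.

**Why three cycles suffice.** If $L \equiv 0 \pmod 3$, the reading
frame is identical on every lap, so a lap without a stop can never
terminate: one cycle decides. If $L \not\equiv 0 \pmod 3$, each lap
shifts the frame by $L \bmod 3 \in \{1, 2\}$, and the reader returns to
its initial state after exactly 3 laps; a stop not met within 3 cycles
is never met. Readings that exhaust the bound are flagged *infinite*
(biologically, potential rolling-circle products) and excluded from
candidates, matching the strategy's exclusion step. This argument is
verified empirically in the test suite by comparing 3-cycle against
6-cycle scans on random circles.

**Bookkeeping.** `orf_len_nt` counts start through stop codon
inclusive; the peptide excludes the stop, so
`pep_len_aa = orf_len_nt/3 - 1`. `overlay_bp = max(0, orf_len_nt - L)`
counts bases read more than once, and
`spans_junction = start_nt + orf_len_nt > L`. Every distinct start is
reported (nested starts sharing a stop are all kept); the pipeline
promotes one headline ORF per circRNA — longest peptide, ties to the
smallest start. Codons containing `N` translate to `X`, and a stop is
only called on an exact stop codon: ambiguity never terminates a
reading.

The published worked examples report ORF/peptide pairs (963 nt /
306 aa, and 1,499 nt / 475 aa) that are not mutually consistent under
any single length convention ($306 \times 3 = 918$;
$475 \times 3 = 1425$; 1,499 is not a multiple of 3). This package
fixes the convention above — ATG-initiated, stop included in the
nucleotide length — and does not attempt to guess the convention behind
those printed numbers. Reproducing them would additionally require the
original circBase and RefSeq records, which are deliberately not
bundled; all shipped tests run on synthetic sequences or the published
candidate table.

**Start-codon choice.** Stop-to-stop ORF definitions (the default of
classic ORF finders) include translation-incompetent frames; since the
strategy's output is a *peptide* prediction, this package requires an
ATG start. The start set is configurable (`orf_params(start_codons=)`)
for users who want near-cognate starts.

## Uniqueness against the host protein

"Unique sequence" is operationalized as exact-substring non-coverage: a
peptide position is *covered* when it lies inside an exact match of
length at least `min_match` (default 7 aa, the shortest fragment
routinely accepted as MS evidence) against any supplied host protein.
This is computed by 7-mer window membership, which is equivalent to the
interval definition, and audited in tests by brute-force rescanning.
The gate passes when strictly more than 2 residues are uncovered.

Two readings of "more than two unique aa" are possible — total
uncovered residues, or the longest contiguous unique run. The total is
implemented; the report also lists the maximal unique segments so the
contiguous reading can be audited. The comparison set is whatever
protein FASTA the user supplies: the host protein alone reproduces the
strategy, a whole proteome makes the gate stricter. Isoleucine and
leucine are distinct by default (the rule is sequence-based);
`uniqueness_params(il_equivalent = TRUE)` collapses them for
MS-faithful matching, where the two are isobaric.

## Differential-expression stand-in

Full-scale analyses of the public microarray series behind this
strategy use batch correction and moderated statistics from dedicated
microarray packages. Those steps are out of scope here; the package substitutes a documented stand-in —
per-row Welch t on log2 intensities plus Benjamini–Hochberg — and also
accepts precomputed DE tables so users can run any upstream machinery.
A table without adjusted p-values can be declared `pre_filtered`, in
which case all rows are kept and only the up/down partition by the sign
of the fold change is computed; this is how published candidate tables
(which print only fold changes, including one row at exactly
log2FC = 1.00, already gated upstream) are consumed. Degenerate rows
with zero variance in both groups get `p = 1` when the means are equal
and `p = 0` otherwise, so a constant planted shift is never discarded.
When several dataset-level DE lists are merged, the entry with the
largest `|log2FC|` wins per circRNA; the original study's deduplication
rule is unstated, so this policy is a documented choice and no
headline count depends on it.

## Tryptic digestion and masses

Cleavage is C-terminal to K/R except before P (the convention of
mainstream search engines; `strict_kr = TRUE` disables the exception),
with up to 2 missed cleavages and 7–35 aa length bounds by default.
Masses are neutral peptide masses — residue sums plus one water — with
the standard monoisotopic and average residue tables embedded as
constants; no fixed or variable modifications are applied. The
whole-peptide average mass in kDa supports comparing predictions with
Western-blot band positions, but band positions are experimental
observations and no acceptance value is claimed for them.

## What the synthetic generator emulates

`make_circ_with_orf()` builds circles in which truth is unambiguous by
construction: the background is tiled with a 12-nt motif containing a
stop codon in every reading frame and no ATG in any frame, so start
codons and qualifying ORFs can only exist where planted. The planted
reading is constructed codon-by-codon under the circle's wraparound
constraints (with overlay, second-lap codons are partially forced by
first-lap choices; the construction rejection-samples until all
constraints hold, which is why near-50-bp overlays take more attempts).
Every accepted circle is re-verified with the package's own scanner,
and spot-checked against an independent brute-force walker in the
tests.

This emulates the *geometry* of real circRNAs — junction-wrapping ORFs,
rolling-circle overlay, host proteins sharing a controlled common
region — but not their statistics: real backgrounds contain many ATGs,
nested and competing ORFs, and repeat structure. A green planted-
recovery test therefore establishes that the funnel's bookkeeping and
gates are correct, not that the thresholds are biologically optimal.
`make_expression_matrix()` likewise plants clean Gaussian log2 shifts
(defaults: 10 samples per group, noise SD 0.5, effect |log2FC| = 2 —
sizes typical of the microarray series the strategy was built on) and
does not imitate probe-level noise or batch structure.

All generators draw from a seed-local RNG stream and restore the
caller's `.Random.seed`, so identical seeds give byte-identical
fixtures anywhere in a session.

## Numerical and design choices

* All thresholds are strict inequalities, exactly as published: a 50-aa
  peptide, a 50-bp overlay, `|log2FC| = 1.0` and 2 unique residues are
  all rejected.
* Stage order is fixed (DE, ORF rules, database, uniqueness); the
  database gate precedes uniqueness, following the narrated order of
  the original results. Both gates skip — rather than fail — when their
  evidence (flag, host protein) is absent, so the tool is runnable
  without database access; every stage can also be disabled explicitly.
* A candidate failing a stage keeps `skipped` flags downstream: the
  funnel never silently drops a row, and stage attribution is exact.
* Coordinates are 0-based half-open internally; genomic position
  strings are opaque labels (1-based inclusive, as printed in candidate
  tables) and never used for arithmetic — the supplied mature sequence
  is authoritative.
* Longest-common-substring ties resolve to the smallest position in the
  peptide, then in the host, making reports deterministic.
* The CLI accepts a JSON configuration file (`--config`), with explicit
  flags winning; YAML was avoided to keep the dependency footprint to
  packages available everywhere R is. The effective configuration is
  echoed into the output directory for provenance.

## Known limitations

* No IRES or m6A translation-initiation evidence, and no Kozak scoring:
  an ORF passing all gates is a *candidate*, not a demonstrated
  translation product.
* The uniqueness gate is exact-match based; homologous-but-diverged
  host regions (or other proteome members, unless supplied) can leave a
  peptide "unique" that a spectral search engine would still assign
  elsewhere.
* The DE stand-in has no empirical-Bayes shrinkage and no batch
  correction; with few samples per group its p-values are noisier than
  moderated alternatives.
* The strategy's full-scale funnel counts (965 differential circRNAs,
  362 after sequence rules, 225 after databases, 57 final) depend on
  full-size public datasets and 2020-era database snapshots and are not
  reproducible from this package's desk-scale inputs; the shipped
  candidate table reproduces only the final 46-up / 11-down partition.
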