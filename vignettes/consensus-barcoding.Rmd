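---
title: "Consensus barcoding from multiplexed nanopore amplicon pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus barcoding from multiplexed nanopore amplicon pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A single nanopore flow cell can sequence the pooled COI amplicons of
thousands of individually tagged specimens, but its reads carry 5--15%
errors: substitutions, insertions and deletions, with deletions enriched in
homopolymer runs. Recovering one accurate barcode per specimen from such a
pool requires (i) assigning each noisy read back to its specimen despite
errors inside the identifying tags, and (ii) collapsing each specimen's
read bin into a single sequence whose residual error rate is orders of
magnitude below the per-read rate. `nanobarcoder` implements both steps,
plus the surrounding machinery (barcode set comparison, rarefaction
analysis, a read simulator) needed to validate them end to end.

## Demultiplexing model

Amplicons are built by single-PCR tagging: each primer carries a 13-bp tag
at its 5' end, so a forward-oriented read is

```
[fwd tag][fwd primer][barcode][revcomp(rev primer)][revcomp(rev tag)]
```

and arrives on a uniformly random strand. Demultiplexing proceeds by:

1. **Length filter.** Reads shorter than the expected barcode length
   (default 658 bp) are dropped. Reads longer than 1.7x the tagged-amplicon
   length are treated as two ligated amplicons and cut at the midpoint; each
   half is processed independently. The 1.7x boundary is our own choice for
   "approximately twice the expected length": halves of a true double-read
   are ~1.0x long, and single reads with even extreme insertion noise stay
   below 1.3--1.4x, so the band between is processed whole rather than
   split.
2. **Primer localisation.** Both primers are searched on both strands by
   infix (semi-global) edit-distance alignment, restricted to a window at
   each read end (default: tag length + primer length + 2x tag-error
   budget + 10 bp slack). Up to 10 edits are tolerated; the primer hit only
   anchors position and orientation, so this generosity costs nothing.
   Orientation is chosen to minimise the summed edit distance of the two
   primer hits; both primers must be found, otherwise the read is
   `missing-primer`. Reported spans are 0-based, half-open.
3. **Tag matching.** The flanking region outside each primer is matched
   against the registered tags, accepting the unique tag within 2
   Levenshtein edits. Because every tag pair in a valid scheme is >= 5
   edits apart, the radius-2 balls around tags are disjoint (triangle
   inequality), so fuzzy matching cannot cross-assign a read. The flank
   window is taken a few bases wider than the tag and matched by infix
   distance: indel errors at the primer boundary shift the tag's exact
   position, and anchoring on a jittery boundary would otherwise burn the
   2-edit budget on alignment slip rather than true tag errors (we measured
   ~10% of reads lost to this effect with exact-width flanks, against the
   ~5% theoretically expected at a 5% error rate).
4. **Assignment.** The (fwd, rev) tag pair is looked up in the
   demultiplexing sheet; the read is reoriented, trimmed of tags and
   primers, and appended to its specimen's bin in arrival order. Each flank
   is matched independently; a read with one unmatched flank is unassigned
   rather than rescued by combination frequency. In the (provably
   impossible, for a valid scheme) event of a tag tie, the read is
   unassigned, never arbitrarily resolved.

Bins store plainly reoriented, trimmed sequences, so the per-specimen FASTA
files under `demultiplexed/` can be fed directly to other tools.

## Consensus model

Consensus calling runs in up to three phases per bin, with four QC
criteria. The per-column rule, shared by all phases: columns where more
than 70% of reads have a gap are deleted; for surviving columns, base
frequencies over A/C/G/T are computed **relative to all reads in the
column** (gaps and Ns stay in the denominator -- a documented, testable
choice; the alternative of renormalising over residues only would call
bases in heavily gapped columns from very few observations); the base is
emitted iff exactly one base reaches the frequency threshold (default
0.3), otherwise `N`.

* **Consensus by length.** For coverages 25, 50, 100, 200 (capped at the
  bin size and at 200), the reads closest to the expected length are
  aligned and called. The schedule is a geometric doubling from the 25x
  starting point; it balances speed (most bins resolve at 25x) against
  yield. The call is accepted once it is (1) translatable -- at least one
  forward frame free of stop codons under the invertebrate mitochondrial
  code (NCBI translation table 5), the appropriate default for arthropod
  COI; codons
  containing N never count as stops -- (2) of exactly the expected length,
  and (3) free of Ns. Reverse frames are not tested because demultiplexing
  fixes the orientation. If the 0.3-threshold call fails, the call is
  repeated across thresholds 0.2--0.5 (step 0.05) and accepted only when
  every QC-passing sweep call is identical ("all", not "any two": the
  stricter reading, since accepting two agreeing calls while a third
  passing threshold disagrees would hide genuine ambiguity). Otherwise the
  0.3 call is kept as the preliminary barcode, and the best preliminary
  across the schedule (fewest Ns, then closest length) moves on.
* **Fourth QC criterion.** After each phase, the accepted barcodes are
  aligned together; any barcode that induces a gap column (it holds the
  only residue where every other row has a gap) is demoted. This catches
  uncorrected indels that the per-bin criteria cannot see. It presumes the
  pool contains homologous barcodes of one marker and one length -- which
  is what an amplicon pool is.
* **Consensus by similarity.** Failed bins are re-called after discarding
  outlier reads: reads are ranked by global edit distance to the
  preliminary barcode and only the closest 100 within 10% divergence are
  kept. This removes co-amplified contaminants and chimera fragments.
* **Consensus by comparison.** Remaining preliminaries are aligned against
  their 20 nearest accepted barcodes. Columns where the preliminary holds
  the only residue are deleted (insertion fix); columns where it holds the
  only gap are filled with `N` (deletion fix); mismatches are never touched,
  so this step cannot import another specimen's bases. The fix count is
  recorded and capped at 5 for the filtered output class. We require *all*
  neighbours to agree (gap or residue) before fixing; a majority quorum
  would fix more but risks chasing neighbour noise.

Output classes: `QC_compliant` (all four criteria, no fixes), `Filtered`
(translatable, expected length, < 1% Ns, <= 5 fixes; includes the former,
and also barcodes that retain a few Ns without ever passing the strict
criteria), `Fixed_barcodes_1to5` / `_over5`, `Allbarcodes` (union), and
`Remaining` (untranslatable, wrong length, or no barcode -- the catch-all
completing the partition). Bins with fewer than 5 reads yield no barcode:
below that, a single contaminant read can dominate a "consensus".

## Barcode comparison

Two barcodes are `identical` (perfect match, no ambiguity codes),
`compatible` (differences explained by IUPAC codes: N matches anything, R
matches A/G, ... -- the natural generalisation beyond N), or `incorrect`
(>= 1 substitution or indel at unambiguous positions). Errors =
substitutions + indels. Sequences of clearly different lengths (< 0.8
length ratio, e.g. a 313-bp mini-barcode against 658 bp) are compared over
their best ends-free overlap so overhangs are not errors. The aggregate
identity is `1 - sum(errors) / sum(compared positions)`;
ambiguity-involving positions are excluded from the denominator (the raw
sums are reported so either convention can be recomputed).

## The simulator

The simulator provides ground truth for every claim above. It emulates:
dual-tagged amplicon structure; uniformly random strand; per-base
substitution/insertion/deletion errors with a 3x deletion multiplier
inside homopolymer runs >= 3 (the R9-style error profile); highly skewed
bin sizes (log-uniform by default); double-length chimeric reads
(concatenations of two amplicons); primer-free junk reads; and negative
controls receiving 0--3 stray tagged reads. Reference barcodes are a
homologous family: a random stop-free ancestor with codon-safe
substitutions per species (~12% from the ancestor, every pair >= 5%
apart), because the cross-barcode QC criterion -- like the real marker --
presumes homology; independently random sequences would be rejected by it
wholesale. Quality strings are constant dummies: no stage consumes
qualities.

What the simulator does **not** emulate: quality-score structure, PCR
chimera breakpoints inside amplicons (chimeras are clean concatenations),
adapter remnants, context-dependent miscall patterns, or abundance-biased
contamination. Passing tests on simulated pools therefore demonstrate the
algorithmic behaviour (assignment, error suppression, QC logic), not
performance on any particular flow-cell chemistry.

The `noisy_standard` preset fixes the standard study conditions: 50
specimens, 658 bp, 5% total read error (substitutions 2%, insertions
1.5%, deletions 1.5% -- an R10-like split of the 85--95% per-read
accuracy typical of nanopore basecalls), bin sizes log-uniform on
[5, 300], 2% chimeras, 5% junk, seed
42. Preset seeds are part of the preset definition so that bundles are
byte-identical everywhere.

## Numerical and engineering choices

* **Alignment engine.** MSAs are delegated to MAFFT behind an injected
  adapter; read-level alignments default to `--retree 2 --op 0 --ep 1`
  (zero gap-opening cost suits indel-dominated nanopore errors; with
  MAFFT's defaults we measured residual indel errors in 25x consensus
  calls that `--op 0 --ep 1` eliminates). Barcode-level alignments (gap
  filter, neighbour comparison) use engine defaults. A `key=value`
  parameter file overrides read-level arguments, since nanopore error
  profiles keep changing.
* **Edit distances.** Primer localisation uses semi-global alignment under
  a unit-cost IUPAC-aware scoring matrix (consistent code pairs cost 0);
  tag matching and read ranking use plain Levenshtein distance.
* **Tie-breaks.** Length-closest read selection breaks ties by arrival
  order; neighbour selection by specimen id; equal-frequency consensus
  columns emit `N` by the uniqueness rule. All stages iterate bins in
  specimen-id order, so outputs are byte-stable under any scheduling.
* **Degenerate inputs.** Empty FASTQ: zeroed statistics, empty bins, no
  error. Single-read "MSA": the read itself. Gap-filter sets of < 2:
  vacuous pass. Comparison pools of < 3: phase 3 skipped.
* **Problem sizes.** The bundled analyses run 50-specimen pools (~5000
  reads) and rarefaction at two coverage caps; these sizes exercise every
  code path (splitting, junk rejection, all three phases, fixes) while a
  full run stays in the minutes range on one core. Larger pools scale
  linearly in reads and bins.

## Known limitations

* Non-coding or length-variable markers (ITS, rRNA) are out of scope: two
  of four QC criteria (translation, fixed length) are meaningless there.
* Dual-PCR (two-round) tagging layouts and quality-aware demultiplexing
  are not supported.
* The comparison step can, in principle, disadvantage genuinely
  indel-bearing rare haplotypes; it only runs on bins that failed both
  earlier phases.
* Paper-scale validation against public sequencing runs requires
  downloading those runs; the package's self-contained evidence is
  simulation-based.
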