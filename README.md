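# nanobarcoder

Specimen DNA barcodes from massively multiplexed nanopore amplicon pools.

Thousands of COI amplicons, each PCR-tagged with a specimen-specific pair of
13-bp indices, can be sequenced together on one nanopore flow cell. The
reads come back at 5–15% error. `nanobarcoder` turns that single FASTQ plus
a tag-combination sheet into one quality-controlled barcode per specimen:

* **Demultiplexing** — primers are located by semi-global edit-distance
  alignment within a window at each read end (≤ 10 edits); the flanking
  tags are matched within ≤ 2 Levenshtein edits. Because all tags in a
  valid scheme are ≥ 5 edits apart, the 2-edit balls are disjoint and fuzzy
  matching cannot cross-assign a read. Double-length concatemer reads are
  split and each half demultiplexed on its own.
* **Consensus calling** — per bin, in up to three phases. *By length*:
  align the reads closest to the expected length at increasing coverage
  (25, 50, 100, 200×) and call each MSA column: drop columns with > 70%
  gaps, emit the base iff exactly one of A/C/G/T reaches 30% of the reads,
  else `N`; accept once the call is translatable (invertebrate
  mitochondrial code, any forward frame), exactly the expected length, and
  N-free, re-sweeping the threshold over 0.2–0.5 when 0.3 fails. *By
  similarity*: re-call after discarding reads > 10% divergent from the
  preliminary barcode. *By comparison*: align the preliminary against its
  20 nearest accepted barcodes; delete residues all neighbours gap, fill
  gaps all neighbours resolve with `N`, and count the fixes. A fourth,
  set-level QC rejects any barcode that forces gap columns into the MSA of
  accepted barcodes.
* **Classification** — `QC_compliant`, `Filtered` (translatable, full
  length, < 1% N, ≤ 5 fixes), `Fixed_barcodes_1to5`/`_over5`,
  `Allbarcodes`, `Remaining`.
* **Comparison** — two barcode sets are partitioned into *identical* /
  *compatible* (differences explained by IUPAC ambiguity codes) /
  *incorrect* (errors = substitutions + indels), with an aggregate identity.
* **Simulation** — a generator for ground-truth barcode families and
  nanopore-like tagged reads (skewed bins, chimeras, junk, negatives), so
  every stage is testable with no external data.

Multiple sequence alignments are delegated to [MAFFT](https://mafft.cbrc.jp)
(required on `PATH`), with nanopore-suited gap costs by default and a
`key=value` parameter file for overrides.

## Quick start

```r
library(nanobarcoder)

# a self-contained simulated pool: 50 specimens, 5% read error,
# log-uniform bin sizes 5-300, chimeras and junk included
fx <- make_fixture("noisy_standard", "sim_pool")

cfg <- run_config(fastq = fx$paths$fastq, sheet = fx$paths$sheet,
                  scheme = fx$scheme, outdir = "run_out")
res <- run_pipeline(cfg)
res$summary
#>                metric value
#> 1           raw_reads  4944
#> 2           too_short     0
#> 3         split_reads    86
#> 4            segments  5030
#> 5            assigned  4593
#> 6          unassigned   437
#> 7           specimens    50
#> 8           negatives     0
#> 9  class_QC_compliant    47
#> 10     class_Filtered    50
#> 11   class_Fixed_1to5     3
#> 12  class_Fixed_over5     0
#> 13  class_Allbarcodes    50
#> 14    class_Remaining     0
#> 15    no_barcode_bins     0
```

4944 raw reads become 5030 candidate segments (86 chimeras were split in
two); 4593 segments are assigned to bins, junk reads fail at the primer
stage. All 50 specimens yield a `Filtered` barcode; 47 pass all four QC
criteria untouched and 3 needed 1–5 indel fixes. Comparing against the
simulator's truth:

```r
filt <- vapply(res$records[res$sets$Filtered], `[[`, "", "sequence")
compare_sets(filt, fx$truth)
#> Barcode comparison: 50 shared (48 identical, 0 compatible, 2 incorrect), 0 only in A, 0 only in B
#> Errors: 4 over 32896 compared positions (identity 99.9878%)
```

48/50 barcodes match the truth byte for byte; the two barcodes that needed
indel fixes carry a handful of residual errors where the fix landed inside
a repeat, which is exactly why fixed barcodes are flagged as such.
Rarefaction by arrival order
(`rarefaction_curve(..., mode = "coverage")`) shows the filtered yield at
50× coverage already equals the yield at 200×.

A thin command-line front end ships in `inst/cli/nanobarcoder`
(subcommands `run`, `demux`, `rarefy`, `compare`, `simulate`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "nanobarcoder", load_package = "installed")'
```

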