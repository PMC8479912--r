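scheme <- small_scheme()
params <- demux_params(scheme)

test_that("length filtering keeps, drops and splits reads as designed", {
  truth <- generate_reference_barcodes(2, 658, seed = 12)
  tg <- unname(scheme$tags)
  amp1 <- build_amplicon(scheme, tg[1], tg[9], truth[[1]])
  amp2 <- build_amplicon(scheme, tg[2], tg[10], truth[[2]])

  reads <- c(short = strrep("ACGT", 75),            # 300 bp, dropped
             ok = paste0(strrep("A", 21), amp1),    # ~700 bp, single
             concat = paste0(amp1, amp2))           # ~1470 bp, split
  prep <- prepare_reads(reads, scheme, params)
  expect_equal(prep$stats$raw_reads, 3)
  expect_equal(prep$stats$too_short, 1)
  expect_equal(prep$stats$split_reads, 1)
  expect_equal(prep$stats$segments, 3)  # 1 single + 2 halves
  expect_setequal(prep$segments$seg_id, c("ok", "concat/1", "concat/2"))
})

test_that("a concatemer of two tagged amplicons yields one read per specimen", {
  truth <- generate_reference_barcodes(2, 658, seed = 12)
  tg <- unname(scheme$tags)
  df <- data.frame(specimen_id = c("spA", "spB"),
                   fwd_tag = tg[1:2], rev_tag = tg[9:10])
  spec <- structure(list(entries = df, negatives = character(0)),
                    class = "demux_spec")
  concat <- paste0(build_amplicon(scheme, tg[1], tg[9], truth[[1]]),
                   build_amplicon(scheme, tg[2], tg[10], truth[[2]]))
  dmx <- demultiplex(c(r1 = concat), spec, scheme, params)
  expect_equal(nrow(dmx$bins$spA), 1)
  expect_equal(nrow(dmx$bins$spB), 1)
  expect_equal(dmx$bins$spA$seq, unname(truth[1]))
  expect_equal(dmx$bins$spB$seq, unname(truth[2]))
})

test_that("primers are located on both strands; hopeless primers are no-hits", {
  pp <- scheme$primer_pair
  inner <- generate_reference_barcodes(1, 200, seed = 3)[[1]]

  seg <- paste0(strrep("T", 13), pp$fwd, inner)
  hit <- locate_primer(seg, pp, params)
  expect_true(hit$found)
  expect_equal(hit$primer, "fwd")
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$edits, 0)
  expect_equal(hit$start, 13)          # 0-based
  expect_equal(hit$end, 13 + nchar(pp$fwd))

  # reverse-complemented forward primer near the 3' end -> reverse strand
  seg_rc <- revcomp(seg)
  hit <- locate_primer(seg_rc, pp, params)
  expect_true(hit$found)
  expect_equal(hit$primer, "fwd")
  expect_equal(hit$orientation, "reverse")

  # mutate the embedded primer until no substring of the segment is within
  # 10 edits of either primer on either strand (brute-force infix check):
  # must be a no-hit
  set.seed(99)
  queries <- c(pp$fwd, pp$rev, revcomp(pp$fwd), revcomp(pp$rev))
  bg5 <- strrep("TC", 7); bg3 <- strrep("TC", 50)
  repeat {
    mut <- paste(sample(c("A", "C", "G", "T"), nchar(pp$fwd), replace = TRUE),
                 collapse = "")
    seg <- paste0(bg5, mut, bg3)
    if (all(utils::adist(queries, seg, partial = TRUE) >= 11)) break
  }
  expect_false(locate_primer(seg, pp, params)$found)
})

test_that("single-read assignment honours the 2-edit tag budget", {
  truth <- generate_reference_barcodes(1, 658, seed = 8)[[1]]
  tg <- unname(scheme$tags)
  df <- data.frame(specimen_id = "spX", fwd_tag = tg[1], rev_tag = tg[9])
  spec <- structure(list(entries = df, negatives = character(0)),
                    class = "demux_spec")

  # exact tags: assigned, trimmed to the inner amplicon
  seg <- build_amplicon(scheme, tg[1], tg[9], truth)
  r <- assign_read(seg, spec, scheme, params)
  expect_true(r$assigned)
  expect_equal(r$specimen_id, "spX")
  expect_equal(r$sequence, truth)

  # two substitutions in the forward tag: still uniquely assignable
  tag_mut <- tg[1]
  substr(tag_mut, 3, 3) <- if (substr(tag_mut, 3, 3) == "A") "C" else "A"
  substr(tag_mut, 7, 7) <- if (substr(tag_mut, 7, 7) == "G") "T" else "G"
  expect_equal(c(utils::adist(tag_mut, tg[1])), 2)
  seg <- build_amplicon(scheme, tag_mut, tg[9], truth)
  r <- assign_read(seg, spec, scheme, params)
  expect_true(r$assigned)
  expect_equal(r$specimen_id, "spX")

  # a fwd flank >= 3 edits from every tag is rejected
  set.seed(41)
  repeat {
    far <- paste(sample(c("A", "C", "G", "T"), 13, replace = TRUE),
                 collapse = "")
    if (all(utils::adist(far, tg) >= 5)) break
  }
  seg <- build_amplicon(scheme, far, tg[9], truth)
  r <- assign_read(seg, spec, scheme, params)
  expect_false(r$assigned)
  expect_equal(r$reason, "no-fwd-tag")
})

test_that("error-free pools demultiplex perfectly; bins preserve arrival order", {
  fx <- get_fixture("clean_small")
  dmx <- demultiplex(fx$paths$fastq, fx$sheet, fx$scheme)
  sizes <- vapply(dmx$bins, nrow, 0L)
  expect_true(all(sizes == 30))
  expect_equal(dmx$stats$assigned, 300)
  expect_equal(dmx$stats$unassigned_total, 0)
  # no cross-assignment against generator truth; arrival order kept
  lab <- read.csv(fx$paths$labels, stringsAsFactors = FALSE)
  rownames(lab) <- lab$read_id
  for (sp in names(dmx$bins)) {
    b <- dmx$bins[[sp]]
    expect_true(all(lab[b$read_id, "specimen_id"] == sp))
    expect_false(is.unsorted(b$arrival))
  }
})

test_that("noisy pools keep high assignment rates with zero cross-talk", {
  fx <- get_fixture("noisy_standard")
  dmx <- demultiplex(fx$paths$fastq, fx$sheet, fx$scheme)
  lab <- read.csv(fx$paths$labels, stringsAsFactors = FALSE)
  rownames(lab) <- lab$read_id

  assigned_of <- function(kind) {
    n_kind <- 0L; n_assigned <- 0L; n_correct <- 0L
    for (sp in names(dmx$bins)) {
      b <- dmx$bins[[sp]]
      base <- sub("/[12]$", "", b$read_id)
      k <- lab[base, "kind"] == kind
      n_assigned <- n_assigned + sum(k)
      if (kind == "amplicon") {
        n_correct <- n_correct + sum(k & lab[base, "specimen_id"] == sp)
      } else if (kind == "chimera") {
        n_correct <- n_correct +
          sum(k & (lab[base, "src1"] == sp | lab[base, "src2"] == sp))
      }
    }
    c(assigned = n_assigned, correct = n_correct)
  }
  amp <- assigned_of("amplicon")
  expect_gte(amp[["assigned"]] / sum(lab$kind == "amplicon"), 0.95)
  expect_equal(amp[["correct"]], amp[["assigned"]])  # zero cross-assignment
  chim <- assigned_of("chimera")
  expect_equal(chim[["correct"]], chim[["assigned"]])

  # junk reads never reach a bin; nearly all fail at the primer stage
  junk <- assigned_of("junk")
  expect_equal(junk[["assigned"]], 0)
  expect_gte(dmx$stats$unassigned[["missing-primer"]],
             0.9 * sum(lab$kind == "junk"))
})

test_that("segment accounting closes and demultiplexing is deterministic", {
  fx <- get_fixture("noisy_standard")
  dmx <- demultiplex(fx$paths$fastq, fx$sheet, fx$scheme)
  st <- dmx$stats
  expect_equal(st$assigned + st$unassigned_total, st$segments)
  expect_equal(st$segments, st$raw_reads - st$too_short + st$split_reads)

  dmx2 <- demultiplex(fx$paths$fastq, fx$sheet, fx$scheme)
  expect_identical(dmx$bins, dmx2$bins)
})

test_that("an empty read set yields empty bins and zeroed statistics", {
  fx <- get_fixture("clean_small")
  dmx <- demultiplex(character(0), fx$sheet, fx$scheme)
  expect_equal(dmx$stats$raw_reads, 0)
  expect_equal(dmx$stats$assigned, 0)
  expect_equal(dmx$stats$segments, 0)
  expect_true(all(vapply(dmx$bins, nrow, 0L) == 0))
})

test_that("no sequence within 2 edits of one tag is assignable to another", {
  # brute force over a generated valid set: single and double edits
  tags <- generate_tag_set(8, seed = 17)
  for (tg in tags) {
    variants <- tag_edit_neighbors(tg, 2)
    d <- utils::adist(variants, tags)
    within <- rowSums(d <= 2)
    expect_true(all(within == 1L))
  }
})
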