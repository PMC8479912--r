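params658 <- consensus_params(658)

test_that("the per-column consensus rule follows gap and frequency thresholds", {
  # unanimity
  expect_equal(call_consensus(matrix("A", 10, 1)), "A")
  # 8 gaps of 10 (80% > 70%): column deleted
  m <- matrix(c(rep("-", 8), "A", "C"), 10, 1)
  expect_equal(call_consensus(m), "")
  # A:4 G:3 C:3 of 10: three bases reach 0.3 -> N
  m <- matrix(c(rep("A", 4), rep("G", 3), rep("C", 3)), 10, 1)
  expect_equal(call_consensus(m), "N")
  # gaps count in the denominator: 3 A of 10 with 7 gaps -> gap fraction
  # 0.7 (not deleted), A at 0.3 -> called
  m <- matrix(c(rep("A", 3), rep("-", 7)), 10, 1)
  expect_equal(call_consensus(m), "A")
})

test_that("consensus calls match a brute-force per-column oracle", {
  set.seed(202)
  for (i in 1:200) {
    m <- random_msa(sample(2:12, 1), sample(1:40, 1))
    thr <- sample(seq(0.2, 0.5, 0.05), 1)
    expect_identical(call_consensus(m, thr, 0.7),
                     consensus_oracle(m, thr, 0.7))
  }
})

test_that("consensus of identical reads reproduces the read, at any threshold", {
  set.seed(7)
  seq <- generate_reference_barcodes(1, 120)[[1]]
  for (n in c(1, 3, 10)) {
    msa <- structure(list(seqs = rep(seq, n), width = nchar(seq)),
                     class = "msa")
    for (thr in c(0.2, 0.3, 0.5)) {
      expect_equal(call_consensus(msa, thr), seq)
    }
  }
})

test_that("QC evaluates translation, length and ambiguity independently", {
  seq <- generate_reference_barcodes(1, 658, seed = 21)[[1]]
  qc <- qc_evaluate(seq, params658)
  expect_true(qc$translatable && qc$length_ok && qc$n_free)

  qc <- qc_evaluate(paste0(seq, "A"), params658)
  expect_false(qc$length_ok)
  expect_true(qc$translatable)

  with_n <- seq
  substr(with_n, 11, 11) <- "N"
  qc <- qc_evaluate(with_n, params658)
  expect_false(qc$n_free)

  # stops planted in all three frames (positions 1, 5, 9) kill translation
  blocked <- seq
  substr(blocked, 1, 3) <- "TAA"
  substr(blocked, 5, 7) <- "TAA"
  substr(blocked, 9, 11) <- "TAA"
  expect_false(qc_evaluate(blocked, params658)$translatable)

  # N-containing codons are never counted as stops
  nn <- paste0("TNA", substr(seq, 4, nchar(seq)))
  expect_true(qc_evaluate(nn, params658)$translatable)
})

test_that("the cross-barcode gap filter rejects exactly the indel carrier", {
  barcodes <- generate_reference_barcodes(20, 300, seed = 31)
  expect_true(all(msa_gap_filter(barcodes)))

  # insert one base into one barcode: only that barcode fails
  broken <- barcodes
  s <- broken[[7]]
  broken[[7]] <- paste0(substr(s, 1, 150), "A", substr(s, 151, nchar(s)))
  gf <- msa_gap_filter(broken)
  expect_false(gf[["sp007"]])
  expect_true(all(gf[names(gf) != "sp007"]))

  # vacuous pass for sets of one
  expect_true(msa_gap_filter(barcodes[1]))
})

test_that("consensus by length recovers the template and respects min_reads", {
  set.seed(55)
  truth <- generate_reference_barcodes(1, 658)[[1]]
  em <- error_model(0.02, 0.015, 0.015)
  reads <- vapply(1:200, function(i) nanobarcoder:::mutate_seq(truth, em), "")
  bin <- data.frame(read_id = paste0("r", 1:200), seq = reads,
                    length_dev = abs(nchar(reads) - 658), arrival = 1:200)
  rec <- consensus_by_length(bin, params658, specimen_id = "spT")
  expect_equal(rec$status, "candidate")
  expect_equal(rec$phase, "length")
  expect_equal(rec$coverage_used, 25)
  expect_equal(rec$sequence, truth)

  # below the read floor: no barcode, with a reason
  rec <- consensus_by_length(bin[1:3, ], params658)
  expect_equal(rec$status, "none")
  expect_equal(rec$reason, "insufficient-reads")
})

test_that("a 20% co-amplified contaminant cannot override the 30% rule", {
  set.seed(56)
  truth <- generate_reference_barcodes(2, 658)
  contam <- truth[[2]]
  em <- error_model(0.02, 0.015, 0.015)
  reads <- c(vapply(1:20, function(i) nanobarcoder:::mutate_seq(truth[[1]], em), ""),
             vapply(1:5, function(i) nanobarcoder:::mutate_seq(contam, em), ""))
  bin <- data.frame(read_id = paste0("r", 1:25), seq = reads,
                    length_dev = abs(nchar(reads) - 658), arrival = 1:25)
  rec <- consensus_by_length(bin, params658)
  expect_equal(rec$sequence, truth[[1]])
})

test_that("consensus by similarity excludes divergent reads and rescues the call", {
  set.seed(57)
  truth <- generate_reference_barcodes(1, 658)[[1]]
  offtarget <- nanobarcoder:::mutate_template(truth, 0.4)
  em <- error_model(0.02, 0.015, 0.015)
  reads <- c(vapply(1:35, function(i) nanobarcoder:::mutate_seq(truth, em), ""),
             vapply(1:15, function(i) nanobarcoder:::mutate_seq(offtarget, em), ""))
  bin <- data.frame(read_id = paste0("r", 1:50), seq = reads,
                    length_dev = abs(nchar(reads) - 658), arrival = 1:50)
  # a preliminary with residual ambiguities, close to the truth
  prelim_seq <- truth
  substr(prelim_seq, 50, 50) <- "N"
  substr(prelim_seq, 400, 400) <- "N"
  prelim <- nanobarcoder:::new_record("spT", 50, sequence = prelim_seq,
                                      coverage_used = 50, phase = "length",
                                      status = "preliminary",
                                      qc = c(qc_evaluate(prelim_seq, params658),
                                             list(msa_gap_ok = NA)))
  rec <- consensus_by_similarity(bin, prelim, params658)
  expect_equal(rec$status, "candidate")
  expect_equal(rec$phase, "similarity")
  expect_equal(rec$sequence, truth)
  expect_lte(rec$coverage_used, 35)   # off-target reads were excluded

  # nothing within 10%: the preliminary passes through annotated
  far_bin <- bin[36:50, ]
  rec <- consensus_by_similarity(far_bin, prelim, params658)
  expect_equal(rec$sequence, prelim_seq)
  expect_equal(rec$note, "similarity-no-reads-retained")
})

test_that("comparison against accepted barcodes fixes indels and counts them", {
  # the neighbour pool emulates the "nearest accepted barcodes" situation:
  # close relatives a few percent divergent from the failing specimen
  set.seed(61)
  truth <- generate_reference_barcodes(1, 658)[[1]]
  pool <- vapply(1:20, function(i) {
    nanobarcoder:::mutate_template(truth, 0.04)
  }, "")
  names(pool) <- sprintf("nb%02d", 1:20)

  mk_prelim <- function(s) {
    nanobarcoder:::new_record("spQ", 10, sequence = s, coverage_used = 10,
                              phase = "length", status = "preliminary",
                              qc = c(qc_evaluate(s, params658),
                                     list(msa_gap_ok = NA)))
  }
  # one deletion: filled with N, length restored; the N-filled result is
  # compatible with the truth (the gap may legally sit anywhere inside an
  # ambiguous repeat, so positions are checked by alignment, not index)
  del1 <- paste0(substr(truth, 1, 99), substr(truth, 101, 658))
  rec <- consensus_by_comparison(mk_prelim(del1), pool, params658)
  expect_equal(rec$n_fixes, 1)
  expect_equal(nchar(rec$sequence), 658)
  expect_equal(rec$n_count, 1)
  chk <- classify_pair(rec$sequence, truth)
  expect_equal(chk$category, "compatible")
  expect_equal(chk$error_count, 0)

  # two insertions: both deleted at the right positions
  ins2 <- paste0(substr(truth, 1, 200), "A",
                 substr(truth, 201, 500), "G", substr(truth, 501, 658))
  rec <- consensus_by_comparison(mk_prelim(ins2), pool, params658)
  expect_equal(rec$n_fixes, 2)
  expect_equal(rec$sequence, truth)

  # a pool below the floor is skipped
  rec <- consensus_by_comparison(mk_prelim(del1), pool[1:2], params658)
  expect_equal(rec$sequence, del1)
  expect_equal(rec$note, "comparison-skipped")
})

test_that("output classification follows the published thresholds", {
  rec <- function(seq, n_fixes = 0, status = "candidate", gap_ok = TRUE) {
    nanobarcoder:::new_record("x", 50, sequence = seq, coverage_used = 25,
                              n_fixes = n_fixes, phase = "length",
                              status = status,
                              qc = c(qc_evaluate(seq, params658),
                                     list(msa_gap_ok = gap_ok)))
  }
  clean <- generate_reference_barcodes(3, 658, seed = 77)
  r1 <- rec(clean[[1]])                                  # perfect
  with_n <- clean[[2]]
  for (p in c(10, 100, 250, 400, 550)) substr(with_n, p, p) <- "N"
  r2 <- rec(with_n, n_fixes = 2, status = "fixed", gap_ok = NA)  # 5 N, 2 fixes
  r2$specimen_id <- "y"
  r3 <- rec(substr(clean[[3]], 1, 640), status = "preliminary", gap_ok = NA)
  r3$specimen_id <- "z"                                  # wrong length
  r6 <- rec(with_n, n_fixes = 6, status = "fixed", gap_ok = NA)
  r6$specimen_id <- "w"                                  # too many fixes

  cls <- classify_barcodes(list(r1, r2, r3, r6), params658)
  expect_setequal(cls$sets$QC_compliant, "x")
  expect_setequal(cls$sets$Filtered, c("x", "y"))        # 5/658 < 1%, 2 fixes
  expect_setequal(cls$sets$Fixed_1to5, "y")
  expect_setequal(cls$sets$Fixed_over5, "w")
  expect_setequal(cls$sets$Remaining, "z")
  expect_setequal(cls$sets$Allbarcodes, c("x", "y", "w"))
})

test_that("records accepted in phase 1 with full QC are never altered later", {
  res <- get_pipeline_result("clean_small")
  for (r in res$records) {
    expect_equal(r$phase, "length")
    expect_equal(r$status, "candidate")
    expect_equal(r$n_fixes, 0)
  }
})
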