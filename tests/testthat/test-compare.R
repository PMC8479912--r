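test_that("pair classification separates identical, compatible and incorrect", {
  r <- classify_pair("ACGTAC", "ACGTAC")
  expect_equal(r$category, "identical")
  expect_equal(r$error_count, 0)

  # an N explains the difference: compatible, no error
  r <- classify_pair("ACNTAC", "ACGTAC")
  expect_equal(r$category, "compatible")
  expect_equal(r$error_count, 0)

  # other ambiguity codes too (R is consistent with A)
  expect_equal(classify_pair("ACGTAR", "ACGTAA")$category, "compatible")
  # ...but inconsistent codes are errors (R cannot be C)
  expect_equal(classify_pair("ACGTAR", "ACGTAC")$category, "incorrect")

  r <- classify_pair("ACGTAC", "ACGAAC")
  expect_equal(r$category, "incorrect")
  expect_equal(r$error_count, 1)

  # an indel is one error
  r <- classify_pair("ACGTACGTACGTACGTACGT", "ACGTACGACGTACGTACGT")
  expect_equal(r$category, "incorrect")
  expect_equal(r$error_count, 1)
})

test_that("classification is symmetric and matches a brute-force edit script", {
  set.seed(404)
  for (i in 1:60) {
    n <- sample(12:30, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    # derive b from a by a few random edits so pairs stay globally alignable
    b <- a
    for (k in seq_len(sample(0:2, 1))) {
      p <- sample(nchar(b), 1)
      op <- sample(c("sub", "ins", "del"), 1)
      b <- switch(op,
        sub = { s <- b; substr(s, p, p) <- sample(c("A","C","G","T"), 1); s },
        ins = paste0(substr(b, 1, p), sample(c("A","C","G","T"), 1),
                     substr(b, p + 1, nchar(b))),
        del = paste0(substr(b, 1, p - 1), substr(b, p + 1, nchar(b)))
      )
    }
    ra <- classify_pair(a, b)
    rb <- classify_pair(b, a)
    expect_equal(ra$category, rb$category)
    expect_equal(ra$error_count, rb$error_count)
    expect_equal(ra$error_count, lev_oracle(a, b))
  }
})

test_that("a mini-barcode inside a full barcode compares over the overlap", {
  full <- generate_reference_barcodes(1, 658, seed = 15)[[1]]
  mini <- substr(full, 200, 512)   # 313 bp
  r <- classify_pair(mini, full)
  expect_equal(r$error_count, 0)
  expect_equal(r$category, "compatible")
  # a real substitution in the overlap still counts
  mini_err <- mini
  substr(mini_err, 100, 100) <- setdiff(c("A","C","G","T"),
                                        substr(mini, 100, 100))[1]
  expect_equal(classify_pair(mini_err, full)$error_count, 1)
})

test_that("set comparison partitions ids and aggregates identity correctly", {
  x <- generate_reference_barcodes(10, 300, seed = 88)

  # self-comparison: everything identical, aggregate identity exactly 1
  r <- compare_sets(x, x)
  expect_length(r$identical, 10)
  expect_equal(r$totals[["incorrect"]], 0)
  expect_identical(r$aggregate_identity, 1)

  # one planted substitution: 9 identical, 1 incorrect with 1 error
  y <- x
  s <- y[[4]]
  substr(s, 150, 150) <- setdiff(c("A","C","G","T"), substr(s, 150, 150))[1]
  y[[4]] <- s
  r <- compare_sets(x, y)
  expect_length(r$identical, 9)
  expect_equal(r$incorrect$specimen_id, "sp004")
  expect_equal(r$incorrect$error_count, 1)
  # identity recomputed the other way round
  expect_equal(r$aggregate_identity, 1 - r$total_errors / r$total_compared)
  expect_equal(r$total_errors, sum(r$incorrect$error_count))

  # asymmetric id sets
  r <- compare_sets(x[1:5], x[3:5])
  expect_equal(r$totals[["shared"]], 3)
  expect_setequal(r$only_in_A, c("sp001", "sp002"))
  expect_length(r$only_in_B, 0)

  # duplicate ids abort
  dup <- c(x[1], x[1])
  expect_error(compare_sets(dup, x), "duplicate")
})

test_that("comparison outputs partition into FASTA files on request", {
  x <- generate_reference_barcodes(6, 120, seed = 5)
  y <- x[1:4]
  s <- y[[2]]; substr(s, 10, 10) <- "N"; y[[2]] <- s
  out <- tempfile("cmp")
  r <- compare_sets(x, y, outdir = out)
  expect_true(file.exists(file.path(out, "identical.fasta")))
  expect_true(file.exists(file.path(out, "compatible.fasta")))
  expect_true(file.exists(file.path(out, "only_in_A.fasta")))
  got <- read_fasta(file.path(out, "identical.fasta"))
  expect_setequal(names(got), r$identical)
  summ <- read.csv(file.path(out, "comparison_summary.csv"))
  expect_equal(nrow(summ), 4)
})
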