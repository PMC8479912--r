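# Consensus barcode calling.
#
# One barcode is reconstructed per specimen bin in up to three phases:
#
#  1. Consensus by length: the reads closest to the expected barcode length
#     are aligned at increasing coverage; a per-column frequency rule calls
#     the consensus, and the call is accepted as soon as it is translatable,
#     of the expected length and free of ambiguous bases. If the default
#     frequency threshold fails, the call is repeated across a threshold
#     sweep and accepted only when every QC-passing sweep call agrees.
#  2. Consensus by similarity: outlier reads (more than 10% divergent from
#     the preliminary barcode) are removed and the call repeated.
#  3. Consensus by comparison: indel errors left in a preliminary barcode are
#     fixed against its nearest already-accepted barcodes: residues the
#     neighbours all gap are deleted, gaps the neighbours all fill become N.
#
# A fourth QC criterion operates across the whole barcode set: any barcode
# that forces gap columns into an alignment of the accepted barcodes is
# rejected (it almost certainly carries an uncorrected indel).

#' Consensus-calling parameters
#'
#' All thresholds of the calling algorithm in one place.
#'
#' @param expected_len expected barcode length (bp), without tags/primers.
#' @param freq_threshold default per-column base frequency required to call
#'   a base.
#' @param sweep_range,sweep_step frequency interval re-tried when the default
#'   threshold fails the first three QC criteria.
#' @param gap_majority columns with a gap fraction above this are deleted.
#' @param coverage_schedule increasing read coverages tried during consensus
#'   by length.
#' @param max_coverage_cbl cap on coverage used in consensus by length.
#' @param similarity_top_n maximum reads retained in consensus by similarity.
#' @param max_divergence reads more divergent than this from the preliminary
#'   barcode are discarded in consensus by similarity.
#' @param comparison_k number of nearest accepted barcodes used to fix a
#'   preliminary barcode.
#' @param max_fixes_filtered most indel fixes a "filtered" barcode may carry.
#' @param max_n_fraction_filtered most ambiguity a "filtered" barcode may
#'   carry (fraction of its length).
#' @param min_reads bins with fewer reads yield no barcode.
#' @param genetic_code NCBI translation table id; "5" is the invertebrate
#'   mitochondrial code appropriate for arthropod COI.
#' @return object of class `consensus_params`.
#' @export
consensus_params <- function(expected_len,
                             freq_threshold = 0.3,
                             sweep_range = c(0.2, 0.5),
                             sweep_step = 0.05,
                             gap_majority = 0.7,
                             coverage_schedule = c(25L, 50L, 100L, 200L),
                             max_coverage_cbl = 200L,
                             similarity_top_n = 100L,
                             max_divergence = 0.10,
                             comparison_k = 20L,
                             max_fixes_filtered = 5L,
                             max_n_fraction_filtered = 0.01,
                             min_reads = 5L,
                             genetic_code = "5") {
  stopifnot(freq_threshold > 0, freq_threshold <= 0.5,
            gap_majority > 0.5,
            all(diff(coverage_schedule) > 0),
            sweep_range[1] > 0, sweep_range[2] <= 0.5)
  structure(
    list(expected_len = as.integer(expected_len),
         freq_threshold = freq_threshold,
         sweep_range = sweep_range, sweep_step = sweep_step,
         gap_majority = gap_majority,
         coverage_schedule = as.integer(coverage_schedule),
         max_coverage_cbl = as.integer(max_coverage_cbl),
         similarity_top_n = as.integer(similarity_top_n),
         max_divergence = max_divergence,
         comparison_k = as.integer(comparison_k),
         max_fixes_filtered = as.integer(max_fixes_filtered),
         max_n_fraction_filtered = max_n_fraction_filtered,
         min_reads = as.integer(min_reads),
         genetic_code = genetic_code),
    class = "consensus_params"
  )
}

#' Call a consensus sequence from an MSA
#'
#' Columns where more than `gap_majority` of the reads have a gap are
#' deleted. For the remaining columns, base frequencies are computed over
#' {A,C,G,T} relative to the total number of reads (gaps and Ns stay in the
#' denominator); the column's base is emitted iff exactly one base reaches
#' `freq_threshold`, otherwise an N is emitted.
#'
#' @param msa an `msa` object, a character matrix (rows = reads) or a
#'   character vector of equal-length gapped sequences.
#' @param freq_threshold minimum base frequency.
#' @param gap_majority gap fraction above which a column is deleted.
#' @return consensus DNA string (possibly containing N).
#' @export
call_consensus <- function(msa, freq_threshold = 0.3, gap_majority = 0.7) {
  m <- if (inherits(msa, "msa")) as.matrix(msa)
       else if (is.matrix(msa)) msa
       else seq_matrix(msa)
  nr <- nrow(m)
  stopifnot(nr >= 1)
  gap_frac <- colSums(m == "-") / nr
  keep <- gap_frac <= gap_majority
  counts <- rbind(A = colSums(m == "A"), C = colSums(m == "C"),
                  G = colSums(m == "G"), T = colSums(m == "T"))
  freq <- counts / nr
  pass <- freq >= freq_threshold
  npass <- colSums(pass)
  top <- max.col(t(freq), ties.method = "first")
  base <- ifelse(npass == 1L, DNA_BASES[top], "N")
  paste(base[keep], collapse = "")
}

#' Evaluate the first three QC criteria on a barcode
#'
#' (1) translatable: at least one of the three forward reading frames is free
#' of stop codons under the configured genetic code (codons containing N are
#' never counted as stops); (2) exact expected length; (3) free of ambiguous
#' bases.
#'
#' @param seq barcode sequence.
#' @param params a [consensus_params()].
#' @return list with `translatable`, `length_ok`, `n_free`.
#' @export
qc_evaluate <- function(seq, params) {
  stopifnot(nzchar(seq))
  seq <- toupper(seq)
  list(translatable = is_translatable(seq, params$genetic_code),
       length_ok = nchar(seq) == params$expected_len,
       n_free = !grepl("N", seq, fixed = TRUE))
}

is_translatable <- function(seq, genetic_code = "5") {
  code <- Biostrings::getGeneticCode(genetic_code)
  stops <- names(code)[code == "*"]
  n <- nchar(seq)
  for (f in 0:2) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    if (length(starts) == 0) next
    codons <- substring(seq, starts, starts + 2L)
    if (!any(codons %in% stops)) return(TRUE)
  }
  FALSE
}

#' Cross-barcode gap filter (fourth QC criterion)
#'
#' Aligns a set of barcodes and fails every barcode that induces a gap
#' insertion: a column where the barcode holds a residue while all other
#' rows hold gaps. With fewer than two barcodes the test passes vacuously.
#'
#' @param barcodes named character vector of barcode sequences.
#' @param config an [aligner_config()].
#' @return named logical vector, `TRUE` = pass.
#' @export
msa_gap_filter <- function(barcodes, config = aligner_config()) {
  nm <- names(barcodes) %||% paste0("b", seq_along(barcodes))
  if (length(barcodes) < 2) {
    return(stats::setNames(rep(TRUE, length(barcodes)), nm))
  }
  aln <- align_bin(stats::setNames(barcodes, nm), config, mode = "barcodes")
  m <- as.matrix(aln)
  nr <- nrow(m)
  gaps <- m == "-"
  lone <- which(colSums(gaps) == nr - 1L)   # exactly one residue in column
  fail <- rep(FALSE, nr)
  for (j in lone) fail[which(!gaps[, j])] <- TRUE
  stats::setNames(!fail, nm)
}

# ---- barcode records -------------------------------------------------------

new_record <- function(specimen_id, bin_size,
                       sequence = NA_character_, coverage_used = NA_integer_,
                       n_fixes = 0L, phase = NA_character_,
                       status = "none", reason = NA_character_,
                       qc = NULL, note = NA_character_) {
  n_count <- if (is.na(sequence)) NA_integer_ else
    count_char(sequence, "N")
  structure(
    list(specimen_id = specimen_id, sequence = sequence,
         coverage_used = coverage_used, bin_size = bin_size,
         n_count = n_count, n_fixes = n_fixes, phase = phase,
         status = status, reason = reason,
         qc = qc %||% list(translatable = NA, length_ok = NA, n_free = NA,
                           msa_gap_ok = NA),
         out_class = NA_character_, note = note),
    class = "barcode_record"
  )
}

#' @export
print.barcode_record <- function(x, ...) {
  cat(sprintf("<barcode %s: %s, phase=%s, len=%s, N=%s, fixes=%d, class=%s>\n",
              x$specimen_id, x$status, x$phase %||% NA,
              if (is.na(x$sequence)) NA else nchar(x$sequence),
              x$n_count, x$n_fixes, x$out_class))
  invisible(x)
}

# consensus + QC at the default threshold, falling back to the threshold
# sweep; sweep calls are accepted only if every QC-passing call is identical
call_with_sweep <- function(msa, params) {
  cons <- call_consensus(msa, params$freq_threshold, params$gap_majority)
  if (!nzchar(cons)) return(list(sequence = cons, passed = FALSE, qc = NULL))
  qc <- qc_evaluate(cons, params)
  if (qc$translatable && qc$length_ok && qc$n_free) {
    return(list(sequence = cons, passed = TRUE, qc = qc))
  }
  thrs <- seq(params$sweep_range[1], params$sweep_range[2],
              by = params$sweep_step)
  calls <- vapply(thrs, function(t) {
    call_consensus(msa, t, params$gap_majority)
  }, "")
  ok <- vapply(calls, function(s) {
    if (!nzchar(s)) return(FALSE)
    q <- qc_evaluate(s, params)
    q$translatable && q$length_ok && q$n_free
  }, TRUE)
  if (any(ok) && length(unique(calls[ok])) == 1L) {
    s <- calls[ok][1]
    return(list(sequence = s, passed = TRUE, qc = qc_evaluate(s, params)))
  }
  list(sequence = cons, passed = FALSE, qc = qc)
}

#' Consensus by length for one read bin
#'
#' For each coverage in the schedule (capped at the bin size and
#' `max_coverage_cbl`), aligns the reads whose lengths are closest to the
#' expected barcode length (ties broken by arrival order) and calls the
#' consensus. Returns immediately once the first three QC criteria pass;
#' otherwise returns the best preliminary barcode (fewest Ns, then length
#' closest to expected).
#'
#' @param bin data.frame with columns `read_id`, `seq`, `length_dev`,
#'   `arrival` (a bin from [demultiplex()]).
#' @param params a [consensus_params()].
#' @param config an [aligner_config()].
#' @param specimen_id id stored on the returned record.
#' @return a `barcode_record` with status `"candidate"` (first three QC
#'   passed), `"preliminary"`, or `"none"` (bin below `min_reads`).
#' @export
consensus_by_length <- function(bin, params, config = aligner_config(),
                                specimen_id = "specimen") {
  n <- nrow(bin)
  if (n < params$min_reads) {
    return(new_record(specimen_id, n, status = "none",
                      reason = "insufficient-reads"))
  }
  covs <- sort(unique(pmin(params$coverage_schedule,
                           min(n, params$max_coverage_cbl))))
  ord <- order(bin$length_dev, bin$arrival)
  best <- NULL
  for (cv in covs) {
    sel <- bin[ord[seq_len(cv)], ]
    msa <- align_bin(stats::setNames(sel$seq, sel$read_id), config, "reads")
    res <- call_with_sweep(msa, params)
    if (res$passed) {
      return(new_record(specimen_id, n, sequence = res$sequence,
                        coverage_used = cv, phase = "length",
                        status = "candidate", qc = c(res$qc,
                                                     list(msa_gap_ok = NA))))
    }
    if (nzchar(res$sequence)) {
      cand <- list(seq = res$sequence, cov = cv,
                   n = count_char(res$sequence, "N"),
                   dev = abs(nchar(res$sequence) - params$expected_len))
      if (is.null(best) || cand$n < best$n ||
          (cand$n == best$n && cand$dev < best$dev)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(new_record(specimen_id, n, status = "none",
                      reason = "no-consensus"))
  }
  qc <- qc_evaluate(best$seq, params)
  new_record(specimen_id, n, sequence = best$seq, coverage_used = best$cov,
             phase = "length", status = "preliminary",
             qc = c(qc, list(msa_gap_ok = NA)))
}

#' Consensus by similarity for one read bin
#'
#' Ranks all bin reads by global edit distance to the preliminary barcode,
#' retains up to `similarity_top_n` reads within `max_divergence`, and
#' re-runs alignment, consensus and QC. Returns the improved record or the
#' unchanged preliminary.
#'
#' @param bin the read bin (as in [consensus_by_length()]).
#' @param preliminary the phase-1 `barcode_record`.
#' @param params a [consensus_params()].
#' @param config an [aligner_config()].
#' @return a `barcode_record`.
#' @export
consensus_by_similarity <- function(bin, preliminary, params,
                                    config = aligner_config()) {
  pseq <- preliminary$sequence
  if (is.na(pseq) || !nzchar(pseq) || nrow(bin) == 0) return(preliminary)
  d <- as.vector(utils::adist(pseq, bin$seq))
  keep <- d / nchar(pseq) < params$max_divergence
  if (!any(keep)) {
    preliminary$note <- "similarity-no-reads-retained"
    return(preliminary)
  }
  ord <- order(!keep, d, bin$arrival)   # retained reads first, closest first
  sel <- bin[ord[seq_len(min(sum(keep), params$similarity_top_n))], ]
  msa <- align_bin(stats::setNames(sel$seq, sel$read_id), config, "reads")
  res <- call_with_sweep(msa, params)
  if (!nzchar(res$sequence)) return(preliminary)
  if (res$passed) {
    return(new_record(preliminary$specimen_id, preliminary$bin_size,
                      sequence = res$sequence, coverage_used = nrow(sel),
                      phase = "similarity", status = "candidate",
                      qc = c(res$qc, list(msa_gap_ok = NA))))
  }
  new_n <- count_char(res$sequence, "N")
  new_dev <- abs(nchar(res$sequence) - params$expected_len)
  old_dev <- abs(nchar(pseq) - params$expected_len)
  if (new_n < preliminary$n_count ||
      (new_n == preliminary$n_count && new_dev < old_dev)) {
    return(new_record(preliminary$specimen_id, preliminary$bin_size,
                      sequence = res$sequence, coverage_used = nrow(sel),
                      phase = "similarity", status = "preliminary",
                      qc = c(res$qc, list(msa_gap_ok = NA))))
  }
  preliminary$note <- "similarity-no-improvement"
  preliminary
}

#' Fix a preliminary barcode by comparison with accepted barcodes
#'
#' Aligns the preliminary barcode with its `comparison_k` nearest
#' QC-compliant neighbours. Residues that all neighbours gap are deleted
#' (insertion fixes); gaps that all neighbours fill are replaced with N
#' (deletion fixes); mismatch columns are left untouched. The number of
#' fixes is recorded on the returned record.
#'
#' @param preliminary a `barcode_record` that failed full QC.
#' @param compliant_pool named character vector of QC-compliant barcode
#'   sequences (names = specimen ids).
#' @param params a [consensus_params()].
#' @param config an [aligner_config()].
#' @return a `barcode_record` with `n_fixes` set and QC re-evaluated. If the
#'   pool holds fewer than 3 barcodes the preliminary passes through
#'   unchanged.
#' @export
consensus_by_comparison <- function(preliminary, compliant_pool, params,
                                    config = aligner_config()) {
  pseq <- preliminary$sequence
  pool <- compliant_pool[names(compliant_pool) != preliminary$specimen_id]
  if (is.na(pseq) || !nzchar(pseq) || length(pool) < 3) {
    preliminary$note <- "comparison-skipped"
    return(preliminary)
  }
  d <- as.vector(utils::adist(pseq, pool))
  ord <- order(d, names(pool))           # ties broken by specimen id
  nb <- pool[ord[seq_len(min(params$comparison_k, length(pool)))]]
  aln <- align_bin(c(".query" = pseq, nb), config, mode = "barcodes")
  m <- as.matrix(aln)
  p <- m[1, ]
  others <- m[-1, , drop = FALSE]
  all_gap <- colSums(others == "-") == nrow(others)
  no_gap <- colSums(others == "-") == 0L
  ins_fix <- p != "-" & all_gap          # delete the inserted residue
  del_fix <- p == "-" & no_gap           # fill the deletion with N
  out <- p
  out[ins_fix] <- ""
  out[del_fix] <- "N"
  out[p == "-" & !del_fix] <- ""
  fixed <- paste(out, collapse = "")
  n_fixes <- sum(ins_fix) + sum(del_fix)
  if (n_fixes == 0L) {
    preliminary$note <- "comparison-no-fixes"
    return(preliminary)
  }
  qc <- qc_evaluate(fixed, params)
  new_record(preliminary$specimen_id, preliminary$bin_size,
             sequence = fixed, coverage_used = preliminary$coverage_used,
             n_fixes = preliminary$n_fixes + n_fixes, phase = "comparison",
             status = "fixed", qc = c(qc, list(msa_gap_ok = NA)))
}

#' Classify barcode records into the five output sets
#'
#' `QC_compliant`: all four QC criteria pass and no fixes were needed.
#' `Filtered`: translatable, expected length, under
#' `max_n_fraction_filtered` ambiguity and at most `max_fixes_filtered`
#' fixes (includes the QC-compliant set). `Fixed_1to5` / `Fixed_over5`:
#' barcodes with indel fixes, grouped by count. `Allbarcodes`: union of the
#' previous sets. `Remaining`: untranslatable, wrong length, or no barcode.
#'
#' @param records list of `barcode_record`s.
#' @param params a [consensus_params()].
#' @return list with `records` (out_class filled in) and `sets` (named list
#'   of specimen id vectors).
#' @export
classify_barcodes <- function(records, params) {
  ids <- vapply(records, function(r) r$specimen_id, "")
  in_set <- function(f) ids[vapply(records, f, TRUE)]
  has_seq <- function(r) !is.na(r$sequence) && nzchar(r$sequence)
  full_qc <- function(r) {
    has_seq(r) && isTRUE(r$qc$translatable) && isTRUE(r$qc$length_ok) &&
      isTRUE(r$qc$n_free) && !isFALSE(r$qc$msa_gap_ok) && r$n_fixes == 0L
  }
  filt <- function(r) {
    has_seq(r) && isTRUE(r$qc$translatable) && isTRUE(r$qc$length_ok) &&
      r$n_count / nchar(r$sequence) < params$max_n_fraction_filtered &&
      r$n_fixes <= params$max_fixes_filtered && !isFALSE(r$qc$msa_gap_ok)
  }
  sets <- list(
    QC_compliant = in_set(function(r) full_qc(r) && r$status == "candidate"),
    Filtered = in_set(filt),
    Fixed_1to5 = in_set(function(r) has_seq(r) && r$n_fixes >= 1 &&
                          r$n_fixes <= 5 && r$status == "fixed"),
    Fixed_over5 = in_set(function(r) has_seq(r) && r$n_fixes > 5 &&
                           r$status == "fixed")
  )
  sets$Allbarcodes <- unique(c(sets$QC_compliant, sets$Filtered,
                               sets$Fixed_1to5, sets$Fixed_over5))
  sets$Remaining <- setdiff(ids, sets$Allbarcodes)
  records <- lapply(records, function(r) {
    r$out_class <-
      if (r$specimen_id %in% sets$QC_compliant) "QC_compliant"
      else if (r$specimen_id %in% sets$Filtered) "Filtered"
      else if (r$specimen_id %in% sets$Fixed_1to5) "Fixed_1to5"
      else if (r$specimen_id %in% sets$Fixed_over5) "Fixed_over5"
      else "Remaining"
    r
  })
  list(records = records, sets = sets)
}

#' Call barcodes for all bins (three phases + cross-barcode gap filter)
#'
#' Runs consensus by length on every bin, applies the cross-barcode gap
#' filter to the candidates, retries the failures with consensus by
#' similarity (gap-filtering new candidates against the accepted pool), and
#' finally fixes the remaining preliminaries by comparison against the
#' accepted pool. Bins are processed in specimen-id order, so results never
#' depend on scheduling.
#'
#' @param bins named list of read bins from [demultiplex()].
#' @param params a [consensus_params()].
#' @param config an [aligner_config()].
#' @return list with `records` (classified), `sets` and `phase_counts`.
#' @export
call_all_bins <- function(bins, params, config = aligner_config()) {
  ids <- sort(names(bins))
  records <- stats::setNames(lapply(ids, function(sp) {
    consensus_by_length(bins[[sp]], params, config, specimen_id = sp)
  }), ids)

  status_of <- function() vapply(records, function(r) r$status, "")
  seq_of <- function(sel) {
    vapply(records[sel], function(r) r$sequence, "")
  }

  # fourth QC criterion on phase-1 candidates
  cand <- names(records)[status_of() == "candidate"]
  if (length(cand)) {
    gf <- msa_gap_filter(seq_of(cand), config)
    for (sp in cand) {
      records[[sp]]$qc$msa_gap_ok <- unname(gf[sp])
      if (!gf[sp]) records[[sp]]$status <- "preliminary"
    }
  }
  pool <- seq_of(names(records)[status_of() == "candidate"])
  phase1_compliant <- length(pool)

  # phase 2: consensus by similarity for the failures
  prelim <- names(records)[status_of() == "preliminary"]
  for (sp in prelim) {
    records[[sp]] <- consensus_by_similarity(bins[[sp]], records[[sp]],
                                             params, config)
  }
  new_cand <- intersect(prelim, names(records)[status_of() == "candidate"])
  if (length(new_cand)) {
    gf <- msa_gap_filter(c(pool, seq_of(new_cand)), config)
    for (sp in new_cand) {
      records[[sp]]$qc$msa_gap_ok <- unname(gf[sp])
      if (!gf[sp]) records[[sp]]$status <- "preliminary"
    }
    pool <- seq_of(names(records)[status_of() == "candidate"])
  }

  # phase 3: fix leftover preliminaries against the accepted pool
  prelim <- names(records)[status_of() == "preliminary"]
  for (sp in prelim) {
    records[[sp]] <- consensus_by_comparison(records[[sp]], pool, params,
                                             config)
  }

  cls <- classify_barcodes(unname(records), params)
  names(cls$records) <- vapply(cls$records, function(r) r$specimen_id, "")
  phase_counts <- table(factor(
    vapply(cls$records, function(r) r$phase %||% NA_character_, ""),
    levels = c("length", "similarity", "comparison")
  ))
  list(records = cls$records, sets = cls$sets,
       phase_counts = as.list(phase_counts),
       phase1_compliant = phase1_compliant)
}

#' Summarise barcode records as a data.frame
#' @param records named list of `barcode_record`s.
#' @return data.frame, one row per specimen.
#' @export
records_table <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    data.frame(
      specimen_id = r$specimen_id,
      bin_size = r$bin_size,
      coverage_used = r$coverage_used %||% NA_integer_,
      barcode_length = if (is.na(r$sequence)) NA_integer_ else
        nchar(r$sequence),
      n_count = r$n_count %||% NA_integer_,
      n_fixes = r$n_fixes,
      phase = r$phase %||% NA_character_,
      status = r$status,
      out_class = r$out_class,
      reason = r$reason %||% NA_character_,
      stringsAsFactors = FALSE
    )
  }))
}
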