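# End-to-end pipeline: demultiplex -> three-phase consensus calling ->
# classification -> on-disk outputs, plus rarefaction-by-arrival analysis.

#' Pipeline run configuration
#'
#' @param fastq FASTQ path (or a named character vector of reads).
#' @param sheet demultiplexing sheet path (or a `demux_spec`).
#' @param scheme a [tag_scheme()].
#' @param outdir output directory.
#' @param demux a [demux_params()].
#' @param consensus a [consensus_params()].
#' @param aligner an [aligner_config()].
#' @return object of class `run_config`.
#' @export
run_config <- function(fastq, sheet, scheme, outdir,
                       demux = demux_params(scheme),
                       consensus = consensus_params(scheme$expected_len),
                       aligner = aligner_config()) {
  structure(list(fastq = fastq, sheet = sheet, scheme = scheme,
                 outdir = outdir, demux = demux, consensus = consensus,
                 aligner = aligner),
            class = "run_config")
}

#' Run the full barcoding pipeline
#'
#' Demultiplexes the reads, calls one barcode per bin in three phases with
#' the cross-barcode gap filter, classifies the results into the five output
#' sets, and writes bins, barcode FASTA files, `Outputtable.csv`,
#' `runsummary.csv` and the effective configuration into the output
#' directory. Reruns with identical inputs produce identical outputs.
#'
#' @param config a [run_config()].
#' @param write whether to write outputs to `config$outdir`.
#' @return list with `records`, `sets`, `demux_stats`, `table`
#'   (per-specimen data.frame) and `summary` (global tallies).
#' @export
run_pipeline <- function(config, write = TRUE) {
  scheme <- config$scheme
  spec <- if (inherits(config$sheet, "demux_spec")) config$sheet
          else parse_demux_sheet(config$sheet, scheme)
  dmx <- demultiplex(config$fastq, spec, scheme, config$demux)
  called <- call_all_bins(dmx$bins, config$consensus, config$aligner)
  tab <- records_table(called$records)
  tab$negative <- tab$specimen_id %in% spec$negatives
  summary <- pipeline_summary(dmx$stats, called, tab)
  out <- list(records = called$records, sets = called$sets,
              demux_stats = dmx$stats, table = tab, summary = summary)
  if (write) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_bins(dmx, config$outdir)
    write_barcode_sets(called, file.path(config$outdir))
    utils::write.csv(tab, file.path(config$outdir, "Outputtable.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(config$outdir, "runsummary.csv"),
                     row.names = FALSE)
    cfg <- list(
      fastq = if (is.character(config$fastq) && length(config$fastq) == 1)
        config$fastq else "<in-memory>",
      sheet = if (is.character(config$sheet)) config$sheet else "<in-memory>",
      expected_len = scheme$expected_len,
      tag_length = scheme$tag_length,
      fwd_primer = scheme$primer_pair$fwd,
      rev_primer = scheme$primer_pair$rev,
      demux = unclass(config$demux),
      consensus = unclass(config$consensus),
      aligner = list(engine = config$aligner$engine,
                     read_args = paste(config$aligner$read_args,
                                       collapse = " "),
                     barcode_args = paste(config$aligner$barcode_args,
                                          collapse = " "))
    )
    yaml::write_yaml(cfg, file.path(config$outdir, "effective_config.yaml"))
  }
  out
}

# FASTA headers: specimen;cov_used=..;bin=..;len=..;N=..;fixes=..;phase=..
barcode_header <- function(r) {
  sprintf("%s;cov_used=%s;bin=%d;len=%d;N=%d;fixes=%d;phase=%s",
          r$specimen_id, r$coverage_used %||% NA, r$bin_size,
          nchar(r$sequence), r$n_count, r$n_fixes, r$phase %||% "NA")
}

write_barcode_sets <- function(called, dir) {
  recs <- called$records
  sets <- called$sets
  files <- c(QC_compliant = "QC_compliant.fasta",
             Filtered = "Filtered_barcodes.fasta",
             Fixed_1to5 = "Fixed_barcodes_1to5.fasta",
             Fixed_over5 = "Fixed_barcodes_over5.fasta",
             Allbarcodes = "Allbarcodes.fasta",
             Remaining = "Remaining.fasta")
  for (set in names(files)) {
    ids <- sets[[set]]
    ids <- ids[vapply(recs[ids], function(r) !is.na(r$sequence), TRUE)]
    if (length(ids) == 0) next
    seqs <- vapply(recs[ids], function(r) r$sequence, "")
    names(seqs) <- vapply(recs[ids], barcode_header, "")
    write_fasta(seqs, file.path(dir, files[[set]]))
  }
  invisible(dir)
}

pipeline_summary <- function(demux_stats, called, tab) {
  classes <- c("QC_compliant", "Filtered", "Fixed_1to5", "Fixed_over5",
               "Allbarcodes", "Remaining")
  data.frame(
    metric = c("raw_reads", "too_short", "split_reads", "segments",
               "assigned", "unassigned",
               "specimens", "negatives",
               paste0("class_", classes),
               "no_barcode_bins"),
    value = c(demux_stats$raw_reads, demux_stats$too_short,
              demux_stats$split_reads, demux_stats$segments,
              demux_stats$assigned, demux_stats$unassigned_total,
              nrow(tab), sum(tab$negative),
              vapply(classes, function(cl) length(called$sets[[cl]]), 0L),
              sum(tab$status == "none")),
    stringsAsFactors = FALSE
  )
}

#' Rarefaction by arrival order
#'
#' Emulates stopping the sequencing run early: no random subsampling, the
#' first reads win. In `"reads"` mode the FASTQ stream is truncated to each
#' checkpoint and the full pipeline re-run. In `"coverage"` mode the reads
#' are demultiplexed once and each bin is truncated to its first `cap` reads
#' (arrival order) before calling.
#'
#' @param fastq FASTQ path or named character vector of reads.
#' @param spec a `demux_spec` (or sheet path).
#' @param scheme a [tag_scheme()].
#' @param checkpoints increasing read counts (`"reads"` mode) or per-bin
#'   coverage caps (`"coverage"` mode).
#' @param mode `"coverage"` or `"reads"`.
#' @param params a [consensus_params()].
#' @param demux_p a [demux_params()].
#' @param config an [aligner_config()].
#' @return data.frame with one row per checkpoint: `checkpoint`,
#'   `reads_consumed`, and counts per output class.
#' @export
rarefaction_curve <- function(fastq, spec, scheme, checkpoints,
                              mode = c("coverage", "reads"),
                              params = consensus_params(scheme$expected_len),
                              demux_p = demux_params(scheme),
                              config = aligner_config()) {
  mode <- match.arg(mode)
  stopifnot(all(diff(checkpoints) > 0))
  if (is.character(fastq) && length(fastq) == 1 && file.exists(fastq)) {
    fastq <- read_fastq(fastq)
  }
  if (is.character(spec)) spec <- parse_demux_sheet(spec, scheme)
  classes <- c("QC_compliant", "Filtered", "Fixed_1to5", "Fixed_over5",
               "Allbarcodes", "Remaining")
  count_sets <- function(called) {
    vapply(classes, function(cl) length(called$sets[[cl]]), 0L)
  }
  if (mode == "coverage") {
    dmx <- demultiplex(fastq, spec, scheme, demux_p)
    rows <- lapply(checkpoints, function(cap) {
      bins <- lapply(dmx$bins, function(b) utils::head(b, cap))
      called <- call_all_bins(bins, params, config)
      c(checkpoint = cap,
        reads_consumed = sum(vapply(bins, nrow, 0L)),
        count_sets(called))
    })
  } else {
    total <- length(fastq)
    rows <- lapply(checkpoints, function(k) {
      if (k > total) {
        warning("checkpoint ", k, " exceeds total reads (", total,
                "); clamped")
        k <- total
      }
      dmx <- demultiplex(fastq[seq_len(k)], spec, scheme, demux_p)
      called <- call_all_bins(dmx$bins, params, config)
      c(checkpoint = k, reads_consumed = k, count_sets(called))
    })
  }
  as.data.frame(do.call(rbind, rows))
}

#' Summarise a completed run directory
#'
#' Reads `Outputtable.csv` back, recomputes the global tallies and checks
#' that they reconcile: every specimen in the sheet is either in an output
#' class or accounted for as a no-barcode bin.
#'
#' @param dir run output directory.
#' @return list with `table`, `summary` and `reconciled` (logical).
#' @export
summarize_run <- function(dir) {
  p_tab <- file.path(dir, "Outputtable.csv")
  p_sum <- file.path(dir, "runsummary.csv")
  for (p in c(p_tab, p_sum)) {
    if (!file.exists(p)) stop("missing run artifact: ", p)
  }
  tab <- utils::read.csv(p_tab, stringsAsFactors = FALSE)
  summary <- utils::read.csv(p_sum, stringsAsFactors = FALSE)
  cls <- table(tab$out_class)
  g <- function(m) summary$value[summary$metric == m]
  reconciled <-
    sum(cls) == g("specimens") &&
    g("class_Allbarcodes") + g("class_Remaining") == g("specimens")
  list(table = tab, summary = summary, reconciled = reconciled)
}
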