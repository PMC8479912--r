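# Nanopore amplicon pool simulator.
#
# Generates ground-truth COI-like barcodes and nanopore-like reads of tagged
# amplicons so that demultiplexing, consensus calling and comparison are
# testable without any external data. The simulation mirrors the structure
# of a single-PCR dual-tagged amplicon pool: each read is
# tag-primer-barcode-primer-tag, on a uniformly random strand, corrupted by
# per-base substitution/insertion/deletion errors with an elevated deletion
# rate inside homopolymer runs. Bin sizes are highly skewed (log-uniform by
# default), and the pool can contain double-length chimeric reads and
# primer-free junk reads.

#' Nanopore-style read error model
#'
#' @param sub_rate,ins_rate,del_rate per-base error rates (all in [0, 0.3]).
#' @param homopolymer_del_multiplier factor applied to `del_rate` inside
#'   homopolymer runs of length >= 3.
#' @return object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.02, ins_rate = 0.015, del_rate = 0.015,
                        homopolymer_del_multiplier = 3) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.3, ins_rate >= 0, ins_rate <= 0.3,
            del_rate >= 0, del_rate <= 0.3)
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_del_multiplier = homopolymer_del_multiplier),
            class = "error_model")
}

# corrupt one sequence under the error model; uses the current RNG stream
mutate_seq <- function(seq, model) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  if (n == 0) return("")
  # deletion probability, elevated inside homopolymer runs >= 3
  p_del <- rep(model$del_rate, n)
  r <- rle(x)
  in_run <- rep(r$lengths >= 3, r$lengths)
  p_del[in_run] <- pmin(0.95, model$del_rate * model$homopolymer_del_multiplier)
  keep <- stats::runif(n) >= p_del
  x <- x[keep]
  m <- length(x)
  if (m == 0) return("")
  sub <- stats::runif(m) < model$sub_rate
  if (any(sub)) {
    x[sub] <- vapply(x[sub], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  }
  ins <- stats::runif(m) < model$ins_rate
  if (any(ins)) {
    extra <- sample(DNA_BASES, sum(ins), replace = TRUE)
    out <- character(m + sum(ins))
    pos <- seq_len(m) + cumsum(c(0, ins[-m]))
    out[pos] <- x
    out[setdiff(seq_along(out), pos)] <- extra
    x <- out
  }
  paste(x, collapse = "")
}

#' Generate reference (ground-truth) barcodes
#'
#' Emulates the barcodes of one homologous marker across a specimen pool:
#' a random stop-free ancestor is drawn and each species is derived from it
#' by codon-safe substitutions, so every barcode is stop-free in frame 1
#' under the given genetic code, all barcodes are alignable without indels
#' (as homologous protein-coding barcodes of one length are), and every
#' pair is at least `min_divergence` apart. Reproducible for a seed.
#'
#' @param n number of barcodes.
#' @param length barcode length in bp.
#' @param genetic_code NCBI translation table id.
#' @param seed integer seed (`NULL`: current RNG state).
#' @param min_divergence minimum pairwise divergence (fraction of `length`).
#' @param species_divergence target base-level divergence of each species
#'   from the common ancestor; 0.12 is typical of congeneric COI.
#' @param max_tries rejection-sampling budget.
#' @return named character vector (`sp001`, `sp002`, ...).
#' @export
generate_reference_barcodes <- function(n, length = 658L, genetic_code = "5",
                                        seed = NULL, min_divergence = 0.05,
                                        species_divergence = 0.12,
                                        max_tries = 50L * n) {
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::getGeneticCode(genetic_code)
  sense <- names(code)[code != "*"]
  n_codons <- length %/% 3L
  rest <- length - 3L * n_codons
  ancestor_codons <- sample(sense, n_codons, replace = TRUE)
  tail_bases <- if (rest > 0) sample(DNA_BASES, rest, replace = TRUE)
                else character(0)
  # a random replacement codon differs at ~2.25 of 3 bases, so the codon
  # replacement fraction is scaled up to hit the base-level target
  n_swap <- min(n_codons, round(species_divergence / 0.75 * n_codons))
  draw <- function() {
    cod <- ancestor_codons
    pos <- sample(n_codons, n_swap)
    cod[pos] <- vapply(cod[pos], function(cc) sample(setdiff(sense, cc), 1), "")
    paste0(paste(cod, collapse = ""), paste(tail_bases, collapse = ""))
  }
  min_d <- ceiling(min_divergence * length)
  kept <- character(0)
  tries <- 0L
  while (base::length(kept) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- draw()
    if (base::length(kept) == 0 ||
        all(utils::adist(cand, kept) >= min_d)) {
      kept <- c(kept, cand)
    }
  }
  if (base::length(kept) < n) {
    stop("could not generate ", n, " barcodes at divergence >= ",
         min_divergence)
  }
  stats::setNames(kept, sprintf("sp%03d", seq_len(n)))
}

#' Amplicon pool design
#'
#' @param n_specimens number of true specimens.
#' @param scheme a [tag_scheme()]; `NULL` generates one large enough.
#' @param bin_sizes either `c(min, max)` bounds of a log-uniform bin-size
#'   distribution, or an explicit integer vector of length `n_specimens`.
#' @param chimera_rate expected chimeric (double-amplicon) reads as a
#'   fraction of the amplicon reads.
#' @param junk_rate expected primer-free junk reads as a fraction of the
#'   amplicon reads.
#' @param n_negatives number of PCR negative-control wells; each receives
#'   0-3 tagged contamination reads.
#' @param expected_len barcode length (used when `scheme` is `NULL`).
#' @return object of class `pool_design`.
#' @export
pool_design <- function(n_specimens, scheme = NULL,
                        bin_sizes = c(5L, 300L),
                        chimera_rate = 0, junk_rate = 0,
                        n_negatives = 0L, expected_len = 658L) {
  structure(list(n_specimens = as.integer(n_specimens), scheme = scheme,
                 bin_sizes = bin_sizes, chimera_rate = chimera_rate,
                 junk_rate = junk_rate, n_negatives = as.integer(n_negatives),
                 expected_len = as.integer(expected_len)),
            class = "pool_design")
}

# a tag scheme with a fwd x rev tag grid covering n wells
default_scheme_for <- function(n_wells, expected_len) {
  k_rev <- min(96L, ceiling(sqrt(n_wells)))
  k_fwd <- ceiling(n_wells / k_rev)
  tags <- generate_tag_set(k_fwd + k_rev)
  tag_scheme(tags, folmer_primers(), expected_len)
}

#' Simulate a tagged nanopore amplicon pool
#'
#' @param truth named character vector of ground-truth barcodes (one per
#'   specimen; see [generate_reference_barcodes()]).
#' @param design a [pool_design()].
#' @param model an [error_model()].
#' @param seed integer seed (`NULL`: current RNG state).
#' @return list with `reads` (named character, arrival order), `sheet`
#'   (demux_spec), `scheme`, `labels` (data.frame read_id, kind,
#'   specimen_id, src1, src2, strand) and `truth`.
#' @export
simulate_reads <- function(truth, design, model = error_model(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_sp <- design$n_specimens
  stopifnot(length(truth) >= n_sp)
  truth <- truth[seq_len(n_sp)]
  n_wells <- n_sp + design$n_negatives
  scheme <- design$scheme %||%
    default_scheme_for(n_wells, design$expected_len)

  # assign tag combinations over a fwd x rev grid, plate-style
  k_rev <- min(96L, ceiling(sqrt(n_wells)))
  k_fwd <- ceiling(n_wells / k_rev)
  stopifnot(k_fwd + k_rev <= length(scheme$tags))
  fwd_tags <- scheme$tags[seq_len(k_fwd)]
  rev_tags <- scheme$tags[k_fwd + seq_len(k_rev)]
  well_ids <- c(names(truth),
                if (design$n_negatives > 0)
                  sprintf("neg%02d", seq_len(design$n_negatives)))
  entries <- data.frame(
    specimen_id = well_ids,
    fwd_tag = unname(fwd_tags[((seq_len(n_wells) - 1L) %/% k_rev) + 1L]),
    rev_tag = unname(rev_tags[((seq_len(n_wells) - 1L) %% k_rev) + 1L]),
    stringsAsFactors = FALSE
  )
  spec <- structure(list(entries = entries,
                         negatives = setdiff(well_ids, names(truth))),
                    class = "demux_spec")

  pp <- scheme$primer_pair
  amplicon_of <- function(id, inner) {
    e <- entries[entries$specimen_id == id, ]
    paste0(e$fwd_tag, pp$fwd, inner, revcomp(pp$rev), revcomp(e$rev_tag))
  }

  # bin sizes
  bs <- design$bin_sizes
  sizes <- if (length(bs) == 2L && is.null(names(bs)) &&
               length(bs) != n_sp) {
    round(exp(stats::runif(n_sp, log(bs[1]), log(bs[2]))))
  } else {
    stopifnot(length(bs) == n_sp)
    as.integer(bs)
  }

  src1 <- rep(names(truth), sizes)
  kind <- rep("amplicon", length(src1))
  src2 <- rep(NA_character_, length(src1))
  n_amp <- length(src1)

  n_chim <- stats::rbinom(1L, n_amp, design$chimera_rate)
  if (n_chim > 0) {
    c1 <- sample(names(truth), n_chim, replace = TRUE)
    c2 <- sample(names(truth), n_chim, replace = TRUE)
    src1 <- c(src1, c1); src2 <- c(src2, c2)
    kind <- c(kind, rep("chimera", n_chim))
  }
  n_junk <- stats::rbinom(1L, n_amp, design$junk_rate)
  if (n_junk > 0) {
    src1 <- c(src1, rep(NA_character_, n_junk))
    src2 <- c(src2, rep(NA_character_, n_junk))
    kind <- c(kind, rep("junk", n_junk))
  }
  # negative wells: 0-3 stray tagged reads with junk inserts
  if (design$n_negatives > 0) {
    nn <- sample(0:3, design$n_negatives, replace = TRUE)
    neg_ids <- rep(spec$negatives, nn)
    src1 <- c(src1, neg_ids); src2 <- c(src2, rep(NA_character_, length(neg_ids)))
    kind <- c(kind, rep("negative", length(neg_ids)))
  }

  n_total <- length(src1)
  lt <- tagged_length(scheme)
  templates <- vapply(seq_len(n_total), function(i) {
    switch(kind[i],
      amplicon = amplicon_of(src1[i], truth[[src1[i]]]),
      chimera = paste0(amplicon_of(src1[i], truth[[src1[i]]]),
                       amplicon_of(src2[i], truth[[src2[i]]])),
      junk = random_dna(1L, round(stats::runif(1, lt - 60, lt + 60))),
      negative = amplicon_of(src1[i],
                             random_dna(1L, design$expected_len))
    )
  }, "")
  reads <- vapply(templates, function(tp) mutate_seq(tp, model), "",
                  USE.NAMES = FALSE)
  strand <- sample(c("+", "-"), n_total, replace = TRUE)
  reads[strand == "-"] <- revcomp(reads[strand == "-"])

  ord <- sample.int(n_total)   # arrival order
  reads <- reads[ord]
  labels <- data.frame(
    read_id = sprintf("read%06d", seq_len(n_total)),
    kind = kind[ord],
    specimen_id = ifelse(kind[ord] == "amplicon", src1[ord], NA_character_),
    src1 = src1[ord], src2 = src2[ord], strand = strand[ord],
    stringsAsFactors = FALSE
  )
  names(reads) <- labels$read_id
  list(reads = reads, sheet = spec, scheme = scheme, labels = labels,
       truth = truth)
}

#' Write a named simulation preset to disk
#'
#' Presets (seeds are part of the preset definition, so bundles are
#' byte-identical across machines):
#' \describe{
#'   \item{clean_small}{10 specimens x 30 error-free reads.}
#'   \item{noisy_standard}{50 specimens, 658 bp, 5\% total read error,
#'     log-uniform bin sizes 5-300, 2\% chimeras, 5\% junk.}
#'   \item{skewed_bins}{30 specimens, bins log-uniform 2-500 (some below the
#'     minimum read count).}
#'   \item{contaminated}{20 specimens at 5\% error; in 5 bins, 30\% of the
#'     reads are a co-amplified contaminant ~40\% divergent from the truth.}
#'   \item{negatives}{10 specimens plus 4 PCR negative controls carrying 0-3
#'     stray tagged reads each.}
#' }
#'
#' @param preset preset name.
#' @param dir output directory (created).
#' @return list as from [simulate_reads()], plus `dir` and file paths;
#'   writes `reads.fastq`, `sheet.csv`, `truth.fasta`, `labels.csv` and
#'   `manifest.json`.
#' @export
make_fixture <- function(preset = c("clean_small", "noisy_standard",
                                    "skewed_bins", "contaminated",
                                    "negatives"),
                         dir) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    clean_small = list(seed = 11L, n = 10L,
                       model = error_model(0, 0, 0),
                       design = pool_design(10L, bin_sizes = rep(30L, 10L))),
    noisy_standard = list(seed = 42L, n = 50L,
                          model = error_model(0.02, 0.015, 0.015),
                          design = pool_design(50L, bin_sizes = c(5L, 300L),
                                               chimera_rate = 0.02,
                                               junk_rate = 0.05)),
    skewed_bins = list(seed = 77L, n = 30L,
                       model = error_model(0.02, 0.015, 0.015),
                       design = pool_design(30L, bin_sizes = c(2L, 500L))),
    contaminated = list(seed = 88L, n = 20L,
                        model = error_model(0.02, 0.015, 0.015),
                        design = pool_design(20L, bin_sizes = c(30L, 120L))),
    negatives = list(seed = 99L, n = 10L,
                     model = error_model(0.02, 0.015, 0.015),
                     design = pool_design(10L, bin_sizes = rep(30L, 10L),
                                          n_negatives = 4L))
  )
  set.seed(cfg$seed)
  truth <- generate_reference_barcodes(cfg$n, 658L)
  sim <- simulate_reads(truth, cfg$design, cfg$model)
  if (preset == "contaminated") {
    sim <- add_contamination(sim, cfg$model, frac_bins = 0.25,
                             frac_reads = 0.3)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    fastq = file.path(dir, "reads.fastq"),
    sheet = file.path(dir, "sheet.csv"),
    truth = file.path(dir, "truth.fasta"),
    labels = file.path(dir, "labels.csv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_fastq(sim$reads, paths$fastq)
  write_demux_sheet(sim$sheet, paths$sheet)
  write_fasta(sim$truth, paths$truth)
  utils::write.csv(sim$labels, paths$labels, row.names = FALSE)
  manifest <- list(
    preset = preset, seed = cfg$seed, n_specimens = cfg$n,
    expected_len = 658L,
    error_model = unclass(cfg$model),
    bin_sizes = cfg$design$bin_sizes,
    chimera_rate = cfg$design$chimera_rate,
    junk_rate = cfg$design$junk_rate,
    n_negatives = cfg$design$n_negatives,
    n_reads = length(sim$reads)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  c(sim, list(dir = dir, paths = paths, preset = preset))
}

# replace a fraction of the reads of some bins with reads from a divergent
# co-amplified contaminant carrying the same tag combination
add_contamination <- function(sim, model, frac_bins = 0.25,
                              frac_reads = 0.3, divergence = 0.4) {
  ids <- names(sim$truth)
  target <- sort(sample(ids, max(1L, round(frac_bins * length(ids)))))
  pp <- sim$scheme$primer_pair
  entries <- sim$sheet$entries
  for (id in target) {
    contam <- mutate_template(sim$truth[[id]], divergence)
    e <- entries[entries$specimen_id == id, ]
    rows <- which(sim$labels$specimen_id %in% id)
    n_swap <- round(frac_reads * length(rows))
    if (n_swap == 0) next
    swap <- sample(rows, n_swap)
    amp <- paste0(e$fwd_tag, pp$fwd, contam, revcomp(pp$rev),
                  revcomp(e$rev_tag))
    for (i in swap) {
      rd <- mutate_seq(amp, model)
      if (sim$labels$strand[i] == "-") rd <- revcomp(rd)
      sim$reads[[sim$labels$read_id[i]]] <- rd
      sim$labels$kind[i] <- "contaminant"
      sim$labels$specimen_id[i] <- NA_character_
      sim$labels$src1[i] <- id
    }
  }
  sim
}

# substitute a fraction of positions to create a divergent variant
mutate_template <- function(seq, divergence) {
  x <- strsplit(seq, "")[[1]]
  k <- round(divergence * length(x))
  pos <- sample(length(x), k)
  x[pos] <- vapply(x[pos], function(b) sample(setdiff(DNA_BASES, b), 1), "")
  paste(x, collapse = "")
}
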