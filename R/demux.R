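# Demultiplexing: length filtering and concatemer splitting, approximate
# primer localization at the read ends, tag extraction and assignment of
# each read to a specimen bin.
#
# A forward-oriented read is laid out as
#   [fwd tag][fwd primer][barcode][revcomp(rev primer)][revcomp(rev tag)]
# and a read may arrive on either strand. Primers are located by infix
# (semi-global) edit-distance alignment restricted to a window at each read
# end; the flanking tag_length bases outside each primer are then matched
# against the registered tags, allowing up to max_tag_errors Levenshtein
# edits. Tag sets with pairwise distance >= 5 guarantee that at most one tag
# can sit within 2 edits of any flank, so fuzzy matching cannot cross-assign.

#' Demultiplexing parameters
#'
#' @param scheme a [tag_scheme()]; supplies the defaults that depend on
#'   geometry.
#' @param max_tag_errors maximum Levenshtein distance between a read flank
#'   and a tag (must stay below `scheme$min_dist / 2` for unambiguous
#'   assignment; the constructor enforces `< 3` for the default distance 5).
#' @param max_primer_edits maximum edits tolerated when locating a primer.
#' @param end_window number of bases searched at each segment end. Default:
#'   tag length + longest primer + 2 * max_tag_errors + 10 bp slack.
#' @param split_window slack (bp) applied to length-window decisions when
#'   recognising and cutting double-length concatemer reads.
#' @param min_read_len reads shorter than this are dropped before
#'   demultiplexing. Default: the expected barcode length.
#' @return object of class `demux_params`.
#' @export
demux_params <- function(scheme,
                         max_tag_errors = 2L,
                         max_primer_edits = 10L,
                         end_window = NULL,
                         split_window = 100L,
                         min_read_len = NULL) {
  if (max_tag_errors >= 3L) {
    stop("max_tag_errors must be < 3 so that tag assignment is unambiguous ",
         "for tag sets with pairwise distance >= 5")
  }
  plen <- max(nchar(scheme$primer_pair$fwd), nchar(scheme$primer_pair$rev))
  end_window <- end_window %||%
    (scheme$tag_length + plen + 2L * max_tag_errors + 10L)
  min_read_len <- min_read_len %||% scheme$expected_len
  structure(
    list(max_tag_errors = as.integer(max_tag_errors),
         max_primer_edits = as.integer(max_primer_edits),
         end_window = as.integer(end_window),
         split_window = as.integer(split_window),
         min_read_len = as.integer(min_read_len)),
    class = "demux_params"
  )
}

# scoring matrix over IUPAC codes: 0 where the base sets intersect
# (a "match", so degenerate primer positions and read Ns cost nothing),
# -1 otherwise. With gap cost 1 the alignment score equals minus the
# edit distance.
iupac_edit_matrix <- function() {
  codes <- names(Biostrings::IUPAC_CODE_MAP)
  sets <- strsplit(Biostrings::IUPAC_CODE_MAP, "")
  m <- matrix(-1, length(codes), length(codes), dimnames = list(codes, codes))
  for (i in seq_along(codes)) {
    for (j in seq_along(codes)) {
      if (length(intersect(sets[[i]], sets[[j]]))) m[i, j] <- 0
    }
  }
  m
}

# Best infix (semi-global) match of `query` inside each of `windows`:
# the whole query is aligned, the window is local. Returns 1-based inclusive
# [start, end] within the window plus the edit count.
infix_match <- function(windows, query) {
  ok <- nchar(windows) >= 1L
  dist <- rep(Inf, length(windows))
  start <- end <- rep(NA_integer_, length(windows))
  if (any(ok)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(windows[ok]),
      Biostrings::DNAString(query),
      type = "local-global",
      substitutionMatrix = iupac_edit_matrix(),
      gapOpening = 0, gapExtension = 1
    )
    dist[ok] <- -Biostrings::score(aln)
    pat <- Biostrings::pattern(aln)
    start[ok] <- BiocGenerics::start(pat)
    end[ok] <- BiocGenerics::end(pat)
  }
  data.frame(dist = dist, start = start, end = end)
}

#' Length-filter reads and split double-length concatemers
#'
#' Reads shorter than `min_read_len` are dropped. Reads longer than 1.7x the
#' tagged-amplicon length are taken to span two ligated amplicons and are cut
#' at the midpoint into two segments, each demultiplexed independently;
#' intermediate lengths are processed whole.
#'
#' @param seqs named character vector of read sequences (arrival order) or a
#'   FASTQ path.
#' @param scheme a [tag_scheme()].
#' @param params a [demux_params()].
#' @return list with `segments` (data.frame seg_id, read_id, seq, arrival,
#'   from_split) and `stats` (raw_reads, too_short, split_reads, segments).
#' @export
prepare_reads <- function(seqs, scheme, params) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs)) {
    seqs <- read_fastq(seqs)
  }
  raw_n <- length(seqs)
  if (is.null(names(seqs)) && raw_n > 0) {
    names(seqs) <- paste0("read", seq_len(raw_n))
  }
  len <- nchar(seqs)
  too_short <- sum(len < params$min_read_len)
  keep <- len >= params$min_read_len
  seqs <- seqs[keep]
  arrival <- which(keep)
  len <- len[keep]

  lt <- tagged_length(scheme)
  do_split <- len >= 1.7 * lt
  n_split <- sum(do_split)

  ids <- names(seqs)
  seg_id <- seg_seq <- character(0)
  seg_read <- character(0)
  seg_arr <- numeric(0)
  seg_split <- logical(0)
  if (any(!do_split)) {
    seg_id <- ids[!do_split]
    seg_seq <- unname(seqs[!do_split])
    seg_read <- ids[!do_split]
    seg_arr <- arrival[!do_split]
    seg_split <- rep(FALSE, sum(!do_split))
  }
  if (n_split > 0) {
    sp_ids <- ids[do_split]
    sp_seq <- seqs[do_split]
    sp_len <- len[do_split]
    mid <- sp_len %/% 2L
    h1 <- substr(sp_seq, 1L, mid)
    h2 <- substr(sp_seq, mid + 1L, sp_len)
    seg_id <- c(seg_id, paste0(sp_ids, "/1"), paste0(sp_ids, "/2"))
    seg_seq <- c(seg_seq, unname(h1), unname(h2))
    seg_read <- c(seg_read, sp_ids, sp_ids)
    # halves keep the parent's arrival rank; /2 sorts after /1
    seg_arr <- c(seg_arr, arrival[do_split] + 0.25, arrival[do_split] + 0.5)
    seg_split <- c(seg_split, rep(TRUE, 2L * n_split))
  }
  # drop split halves that fall below the length threshold
  short_half <- seg_split & nchar(seg_seq) < params$min_read_len
  too_short <- too_short + sum(short_half)
  ord <- order(seg_arr)
  ord <- ord[!short_half[ord]]
  segments <- data.frame(
    seg_id = seg_id[ord], read_id = seg_read[ord], seq = seg_seq[ord],
    arrival = seg_arr[ord], from_split = seg_split[ord],
    stringsAsFactors = FALSE
  )
  list(segments = segments,
       stats = list(raw_reads = raw_n, too_short = too_short,
                    split_reads = n_split, segments = nrow(segments)))
}

#' Locate a primer in a single segment
#'
#' Searches both primers on both strands within `end_window` bases of each
#' segment end and reports the best hit with at most `max_primer_edits`
#' edits. Span coordinates are 0-based, half-open.
#'
#' @param segment a DNA string.
#' @param primer_pair a [primer_pair()].
#' @param params a [demux_params()].
#' @return list with `found`; when found also `primer` ("fwd"/"rev"),
#'   `orientation` ("forward" if the forward primer reads 5'->3' on the given
#'   strand), `start`, `end`, `edits`.
#' @export
locate_primer <- function(segment, primer_pair, params) {
  len <- nchar(segment)
  if (len < min(nchar(primer_pair$fwd), nchar(primer_pair$rev))) {
    return(list(found = FALSE))
  }
  w <- min(params$end_window, len)
  w5 <- substr(segment, 1L, w)
  off3 <- max(0L, len - w)
  w3 <- substr(segment, off3 + 1L, len)
  cand <- list(
    list(q = primer_pair$fwd,          win = w5, off = 0L,  primer = "fwd", orient = "forward"),
    list(q = revcomp(primer_pair$rev), win = w3, off = off3, primer = "rev", orient = "forward"),
    list(q = primer_pair$rev,          win = w5, off = 0L,  primer = "rev", orient = "reverse"),
    list(q = revcomp(primer_pair$fwd), win = w3, off = off3, primer = "fwd", orient = "reverse")
  )
  hits <- lapply(cand, function(cc) {
    h <- infix_match(cc$win, cc$q)
    list(dist = h$dist[1], start = cc$off + h$start[1] - 1L,
         end = cc$off + h$end[1], primer = cc$primer, orient = cc$orient)
  })
  d <- vapply(hits, function(h) h$dist, 0)
  best <- hits[[which.min(d)]]
  if (best$dist > params$max_primer_edits) return(list(found = FALSE))
  list(found = TRUE, primer = best$primer, orientation = best$orient,
       start = best$start, end = best$end, edits = as.integer(best$dist))
}

# Vectorised core: takes a segments data.frame (seg_id, seq, from_split) and
# returns one row per segment with the assignment outcome.
demux_segments <- function(segments, spec, scheme, params) {
  n <- nrow(segments)
  res <- data.frame(
    seg_id = segments$seg_id,
    specimen_id = rep(NA_character_, n), sequence = rep(NA_character_, n),
    reason = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  if (n == 0) return(res)
  pp <- scheme$primer_pair
  seqs <- toupper(segments$seq)
  len <- nchar(seqs)
  # split-derived segments inherit cut-position jitter, so their inner end
  # gets a wider search window
  w <- pmin(len, params$end_window + ifelse(segments$from_split, 50L, 0L))
  w5 <- substr(seqs, 1L, w)
  off3 <- pmax(0L, len - w)
  w3 <- substr(seqs, off3 + 1L, len)

  hF5 <- infix_match(w5, pp$fwd)            # fwd primer at 5' (forward read)
  hR3 <- infix_match(w3, revcomp(pp$rev))   # rev primer site at 3' (forward)
  hR5 <- infix_match(w5, pp$rev)            # rev primer at 5' (reverse read)
  hF3 <- infix_match(w3, revcomp(pp$fwd))   # fwd primer site at 3' (reverse)

  k <- params$max_primer_edits
  ok_fwd <- hF5$dist <= k & hR3$dist <= k
  ok_rev <- hR5$dist <= k & hF3$dist <= k
  sum_fwd <- hF5$dist + hR3$dist
  sum_rev <- hR5$dist + hF3$dist
  orient_fwd <- ok_fwd & (!ok_rev | sum_fwd <= sum_rev)
  orient_rev <- ok_rev & !orient_fwd
  res$reason[!(orient_fwd | orient_rev)] <- "missing-primer"

  # absolute 1-based inclusive primer spans on the *oriented* sequence
  fs <- fe <- rs <- re <- rep(NA_integer_, n)
  oseq <- seqs
  if (any(orient_fwd)) {
    i <- orient_fwd
    fs[i] <- hF5$start[i]
    fe[i] <- hF5$end[i]
    rs[i] <- off3[i] + hR3$start[i]
    re[i] <- off3[i] + hR3$end[i]
  }
  if (any(orient_rev)) {
    i <- orient_rev
    oseq[i] <- revcomp(seqs[i])
    # mirror [s, e] -> [L - e + 1, L - s + 1]
    fs[i] <- len[i] - (off3[i] + hF3$end[i]) + 1L
    fe[i] <- len[i] - (off3[i] + hF3$start[i]) + 1L
    rs[i] <- len[i] - hR5$end[i] + 1L
    re[i] <- len[i] - hR5$start[i] + 1L
  }
  located <- orient_fwd | orient_rev
  # degenerate geometry (primers overlapping or inverted) cannot be trimmed
  bad_geom <- located & (fe + 1L > rs - 1L)
  res$reason[bad_geom] <- "missing-primer"
  located <- located & !bad_geom

  if (any(located)) {
    i <- which(located)
    tg <- scheme$tag_length
    # flank windows are a few bases wider than the tag so that primer
    # boundary jitter (indels near the primer start) does not eat into the
    # 2-edit tag budget; tags are matched by infix (partial) edit distance
    f_flank <- substr(oseq[i], pmax(1L, fs[i] - tg - 3L),
                      pmin(len[i], fs[i] + 1L))
    r_flank <- revcomp(substr(oseq[i], pmax(1L, re[i] - 1L),
                              pmin(len[i], re[i] + tg + 3L)))
    fwd_tags <- unique(spec$entries$fwd_tag)
    rev_tags <- unique(spec$entries$rev_tag)
    match_tag <- function(flanks, tags) {
      d <- t(utils::adist(tags, flanks, partial = TRUE))
      within <- d <= params$max_tag_errors
      nwithin <- rowSums(within)
      hit <- rep(NA_character_, length(flanks))
      one <- nwithin == 1L
      if (any(one)) hit[one] <- tags[apply(within[one, , drop = FALSE], 1, which)]
      hit  # 0 hits or a tie (impossible for valid tag sets) -> NA
    }
    f_hit <- match_tag(f_flank, fwd_tags)
    r_hit <- match_tag(r_flank, rev_tags)
    combo_key <- paste(spec$entries$fwd_tag, spec$entries$rev_tag, sep = "+")
    sp_of <- stats::setNames(spec$entries$specimen_id, combo_key)
    sp <- unname(sp_of[paste(f_hit, r_hit, sep = "+")])
    reason <- rep(NA_character_, length(i))
    reason[is.na(f_hit)] <- "no-fwd-tag"
    reason[is.na(reason) & is.na(r_hit)] <- "no-rev-tag"
    reason[is.na(reason) & is.na(sp)] <- "unknown-combination"
    assigned <- is.na(reason)
    res$specimen_id[i[assigned]] <- sp[assigned]
    res$sequence[i[assigned]] <- substr(oseq[i], fe[i] + 1L, rs[i] - 1L)[assigned]
    res$reason[i[!assigned]] <- reason[!assigned]
  }
  res
}

#' Assign a single segment to a specimen
#'
#' Locates the primers, extracts the two tag flanks, matches each against the
#' registered tags within `max_tag_errors` edits and looks the pair up in the
#' demultiplexing sheet. The returned sequence is reoriented (forward primer
#' upstream) and trimmed of tags and primers.
#'
#' @param segment a DNA string.
#' @param spec a `demux_spec` from [parse_demux_sheet()].
#' @param scheme a [tag_scheme()].
#' @param params a [demux_params()].
#' @return list with `assigned`; when assigned also `specimen_id` and
#'   `sequence`; otherwise `reason` (one of "missing-primer", "no-fwd-tag",
#'   "no-rev-tag", "unknown-combination").
#' @export
assign_read <- function(segment, spec, scheme, params) {
  segs <- data.frame(seg_id = "seg", seq = segment, from_split = FALSE,
                     stringsAsFactors = FALSE)
  r <- demux_segments(segs, spec, scheme, params)
  if (!is.na(r$specimen_id[1])) {
    list(assigned = TRUE, specimen_id = r$specimen_id[1],
         sequence = r$sequence[1])
  } else {
    list(assigned = FALSE, reason = r$reason[1])
  }
}

#' Demultiplex a read set into specimen bins
#'
#' Runs [prepare_reads()] and assigns every candidate segment, preserving
#' arrival order within each bin. The result is independent of how reads are
#' batched, so worker counts can never change the output.
#'
#' @param seqs named character vector of reads or FASTQ path.
#' @param spec a `demux_spec`.
#' @param scheme a [tag_scheme()].
#' @param params a [demux_params()]; defaults to `demux_params(scheme)`.
#' @return list with `bins` (named list of data.frames: read_id, seq,
#'   length_dev, arrival) and `stats` (read/segment accounting, including
#'   per-reason unassigned counts).
#' @export
demultiplex <- function(seqs, spec, scheme, params = demux_params(scheme)) {
  prep <- prepare_reads(seqs, scheme, params)
  segs <- prep$segments
  res <- demux_segments(segs, spec, scheme, params)
  reasons <- c("missing-primer", "no-fwd-tag", "no-rev-tag",
               "unknown-combination")
  unassigned <- vapply(reasons, function(r) sum(res$reason %in% r), 0L)
  assigned <- !is.na(res$specimen_id)
  bins <- stats::setNames(
    vector("list", nrow(spec$entries)), spec$entries$specimen_id
  )
  if (any(assigned)) {
    df <- data.frame(
      read_id = segs$seg_id[assigned],
      seq = res$sequence[assigned],
      length_dev = abs(nchar(res$sequence[assigned]) - scheme$expected_len),
      arrival = segs$arrival[assigned],
      specimen_id = res$specimen_id[assigned],
      stringsAsFactors = FALSE
    )
    df <- df[order(df$arrival), , drop = FALSE]
    for (sp in unique(df$specimen_id)) {
      bins[[sp]] <- df[df$specimen_id == sp,
                       c("read_id", "seq", "length_dev", "arrival")]
    }
  }
  for (sp in names(bins)) {
    if (is.null(bins[[sp]])) {
      bins[[sp]] <- data.frame(read_id = character(0), seq = character(0),
                               length_dev = integer(0), arrival = numeric(0),
                               stringsAsFactors = FALSE)
    }
  }
  stats <- c(prep$stats,
             list(assigned = sum(assigned),
                  unassigned = unassigned,
                  unassigned_total = sum(unassigned)))
  list(bins = bins, stats = stats)
}

#' Write demultiplexed bins to FASTA files
#'
#' One `<specimen_id>.fasta` per non-empty bin under `dir/demultiplexed/`,
#' plus a `demux_stats.csv` accounting table in `dir`.
#'
#' @param dmx result of [demultiplex()].
#' @param dir output directory (created if needed).
#' @return the demultiplexed directory path, invisibly.
#' @export
write_bins <- function(dmx, dir) {
  bdir <- file.path(dir, "demultiplexed")
  dir.create(bdir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(dmx$bins)) {
    b <- dmx$bins[[sp]]
    if (nrow(b) == 0) next
    write_fasta(stats::setNames(b$seq, b$read_id),
                file.path(bdir, paste0(sp, ".fasta")))
  }
  st <- dmx$stats
  stats_df <- data.frame(
    metric = c("raw_reads", "too_short", "split_reads", "segments",
               "assigned", paste0("unassigned_", names(st$unassigned))),
    count = c(st$raw_reads, st$too_short, st$split_reads, st$segments,
              st$assigned, unname(st$unassigned))
  )
  utils::write.csv(stats_df, file.path(dir, "demux_stats.csv"),
                   row.names = FALSE)
  invisible(bdir)
}
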