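# Tag schemes and demultiplexing sheets.
#
# Specimens are traced through a pooled amplicon run by 13-bp tags appended to
# the 5' end of each PCR primer. Demultiplexing tolerates up to 2 edits per
# tag, which is safe only when all tags in the scheme are >= 5 edits apart
# (two edit balls of radius 2 around distinct tags are then disjoint), so the
# scheme constructor and the validator enforce that distance as well as a ban
# on homopolymer runs.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Define a PCR primer pair
#'
#' @param name label for the pair.
#' @param fwd,rev primer sequences written 5' to 3' (IUPAC codes allowed).
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(name, fwd, rev) {
  fwd <- toupper(fwd); rev <- toupper(rev)
  for (p in c(fwd, rev)) {
    if (!nzchar(p)) stop("primer sequences must be non-empty")
    bad <- setdiff(strsplit(p, "")[[1]], IUPAC_CHARS)
    if (length(bad)) {
      stop("primer contains non-IUPAC characters: ", paste(bad, collapse = ""))
    }
  }
  structure(list(name = name, fwd = fwd, rev = rev), class = "primer_pair")
}

#' The Folmer COI primer pair (LCO1490 / HCO2198)
#'
#' The standard primer pair for the 658-bp metazoan COI barcode.
#'
#' @return a [primer_pair()].
#' @export
folmer_primers <- function() {
  primer_pair("LCO1490/HCO2198",
              fwd = "GGTCAACAAATCATAAAGATATTGG",
              rev = "TAAACTTCAGGGTGACCAAAAAATCA")
}

#' Define a tag scheme
#'
#' Bundles the tag set, the primer pair and the amplicon geometry. The
#' constructor enforces the properties demultiplexing relies on: uniform tag
#' length, pairwise Levenshtein distance >= `min_dist`, and no homopolymer
#' run of length >= `run_limit`.
#'
#' @param tags character vector of tag sequences (may be named).
#' @param primer_pair a [primer_pair()].
#' @param expected_len expected barcode length in bp, without tags or primers
#'   (658 for full-length COI, 313 for the mini-barcode).
#' @param tag_length tag length in bp.
#' @param min_dist minimum pairwise Levenshtein distance between tags.
#' @param run_limit shortest forbidden homopolymer run.
#' @return object of class `tag_scheme`.
#' @export
tag_scheme <- function(tags, primer_pair, expected_len,
                       tag_length = 13L, min_dist = 5L, run_limit = 3L) {
  tags <- toupper(tags)
  if (is.null(names(tags))) names(tags) <- paste0("tag", seq_along(tags))
  if (any(nchar(tags) != tag_length)) {
    stop("all tags must have length ", tag_length)
  }
  rep_ <- validate_tag_set(tags, min_dist = min_dist,
                           max_homopolymer = run_limit - 1L)
  if (!rep_$valid) {
    stop("invalid tag set: ", nrow(rep_$close_pairs), " close pair(s), ",
         length(rep_$homopolymer_tags), " homopolymer tag(s)")
  }
  stopifnot(inherits(primer_pair, "primer_pair"), expected_len > 0)
  structure(
    list(tags = tags, primer_pair = primer_pair,
         expected_len = as.integer(expected_len),
         tag_length = as.integer(tag_length),
         min_dist = as.integer(min_dist), run_limit = as.integer(run_limit)),
    class = "tag_scheme"
  )
}

#' Length of a fully tagged amplicon under a scheme
#' @param scheme a [tag_scheme()].
#' @return integer: barcode + both primers + both tags, in bp.
#' @export
tagged_length <- function(scheme) {
  scheme$expected_len + nchar(scheme$primer_pair$fwd) +
    nchar(scheme$primer_pair$rev) + 2L * scheme$tag_length
}

#' Validate a tag set
#'
#' Reports every tag pair closer than `min_dist` Levenshtein edits
#' (substitutions, insertions and deletions all count) and every tag with a
#' homopolymer run longer than `max_homopolymer`. An empty report means the
#' set is safe for fuzzy demultiplexing at 2 allowed tag errors.
#'
#' @param tags character vector of tags.
#' @param min_dist required minimum pairwise distance.
#' @param max_homopolymer longest allowed run of identical bases.
#' @return list with `close_pairs` (data.frame tag_i, tag_j, dist),
#'   `homopolymer_tags` (character) and `valid` (logical).
#' @export
validate_tag_set <- function(tags, min_dist = 5L, max_homopolymer = 2L) {
  stopifnot(length(tags) >= 1)
  tags <- toupper(tags)
  d <- utils::adist(tags)
  idx <- which(upper.tri(d) & d < min_dist, arr.ind = TRUE)
  close_pairs <- data.frame(
    tag_i = tags[idx[, 1]], tag_j = tags[idx[, 2]],
    dist = d[idx], stringsAsFactors = FALSE
  )
  run_re <- paste0("([ACGT])\\1{", max_homopolymer, ",}")
  homopolymer_tags <- tags[grepl(run_re, tags)]
  list(close_pairs = close_pairs,
       homopolymer_tags = unname(homopolymer_tags),
       valid = nrow(close_pairs) == 0L && length(homopolymer_tags) == 0L)
}

#' Generate a valid tag set
#'
#' Draws random tags and greedily keeps those at Levenshtein distance
#' >= `min_dist` from every accepted tag and free of homopolymer runs of
#' `run_limit` or more. Deterministic for a given seed.
#'
#' @param n number of tags.
#' @param tag_length tag length in bp.
#' @param min_dist minimum pairwise distance.
#' @param run_limit shortest forbidden homopolymer run.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param max_tries draw budget before giving up.
#' @return named character vector of `n` tags.
#' @export
generate_tag_set <- function(n, tag_length = 13L, min_dist = 5L,
                             run_limit = 3L, seed = NULL, max_tries = 200000L) {
  if (!is.null(seed)) set.seed(seed)
  run_re <- paste0("([ACGT])\\1{", run_limit - 1L, ",}")
  kept <- character(0)
  tries <- 0L
  while (length(kept) < n && tries < max_tries) {
    # draw in batches; candidates are filtered for runs first (cheap)
    cand <- random_dna(64L, tag_length)
    cand <- cand[!grepl(run_re, cand)]
    tries <- tries + 64L
    for (tg in cand) {
      if (length(kept) >= n) break
      if (length(kept) == 0 || all(utils::adist(tg, kept) >= min_dist)) {
        kept <- c(kept, tg)
      }
    }
  }
  if (length(kept) < n) {
    stop("could not generate ", n, " tags of length ", tag_length,
         " at min distance ", min_dist)
  }
  names(kept) <- paste0("tag", seq_len(n))
  kept
}

#' Enumerate all sequences within a given edit distance of a tag
#'
#' Full Levenshtein neighbourhood (substitutions, insertions, deletions),
#' used for exhaustive demultiplexing-ambiguity checks: two tags can both
#' claim a read flank within `k` edits if and only if their `k`-edit
#' neighbourhoods intersect.
#'
#' @param tag a single DNA string.
#' @param k edit radius (0, 1 or 2 are practical).
#' @return character vector of unique variants, including `tag` itself.
#' @export
tag_edit_neighbors <- function(tag, k = 2L) {
  one_edit <- function(ss) {
    out <- vector("list", length(ss))
    for (j in seq_along(ss)) {
      s <- ss[[j]]
      x <- strsplit(s, "")[[1]]
      n <- length(x)
      subs <- unlist(lapply(seq_len(n), function(i) {
        paste0(substr(s, 1, i - 1),
               setdiff(DNA_BASES, x[i]),
               substr(s, i + 1, n))
      }))
      dels <- vapply(seq_len(n), function(i) {
        paste0(substr(s, 1, i - 1), substr(s, i + 1, n))
      }, "")
      inss <- unlist(lapply(seq_len(n + 1), function(i) {
        paste0(substr(s, 1, i - 1), DNA_BASES, substr(s, i, n))
      }))
      out[[j]] <- c(subs, dels, inss)
    }
    unique(unlist(out))
  }
  acc <- tag
  frontier <- tag
  for (round in seq_len(k)) {
    frontier <- setdiff(one_edit(frontier), acc)
    acc <- c(acc, frontier)
  }
  unique(acc)
}

#' Parse a demultiplexing sheet
#'
#' CSV with header `specimen_id,fwd_tag,rev_tag` and an optional `negative`
#' column whose truthy values mark PCR negative controls. Every tag must be
#' registered in the scheme and every (fwd, rev) combination must be unique.
#'
#' @param path CSV file path.
#' @param scheme a [tag_scheme()].
#' @return object of class `demux_spec`: list with `entries` (data.frame
#'   specimen_id, fwd_tag, rev_tag) and `negatives` (character).
#' @export
parse_demux_sheet <- function(path, scheme) {
  if (!file.exists(path)) stop("demultiplexing sheet not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("specimen_id", "fwd_tag", "rev_tag")
  if (!all(need %in% names(df))) {
    stop("sheet must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!nzchar(df$specimen_id) | !nzchar(df$fwd_tag) | !nzchar(df$rev_tag))
  if (length(bad)) {
    stop("malformed sheet row(s) (empty field) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  df$fwd_tag <- toupper(df$fwd_tag)
  df$rev_tag <- toupper(df$rev_tag)
  dup_id <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup_id)) {
    stop("duplicate specimen_id(s): ", paste(unique(dup_id), collapse = ", "))
  }
  unknown <- setdiff(unique(c(df$fwd_tag, df$rev_tag)), unname(scheme$tags))
  if (length(unknown)) {
    stop("tag(s) not in scheme: ", paste(unknown, collapse = ", "))
  }
  combo <- paste(df$fwd_tag, df$rev_tag, sep = "+")
  if (anyDuplicated(combo)) {
    clash <- split(df$specimen_id, combo)
    clash <- clash[lengths(clash) > 1]
    msg <- vapply(names(clash), function(k) {
      paste0(k, " -> ", paste(clash[[k]], collapse = ", "))
    }, "")
    stop("tag combination collision(s): ", paste(msg, collapse = "; "))
  }
  negatives <- character(0)
  if ("negative" %in% names(df)) {
    truthy <- tolower(df$negative) %in% c("1", "true", "t", "yes", "y")
    negatives <- df$specimen_id[truthy]
  }
  structure(
    list(entries = df[, need], negatives = negatives),
    class = "demux_spec"
  )
}

#' Write a demultiplexing sheet
#' @param spec a `demux_spec` (or data.frame with the sheet columns).
#' @param path output CSV path.
#' @export
write_demux_sheet <- function(spec, path) {
  df <- if (inherits(spec, "demux_spec")) {
    cbind(spec$entries,
          negative = as.integer(spec$entries$specimen_id %in% spec$negatives))
  } else spec
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
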