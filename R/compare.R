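# Barcode set comparison.
#
# Two barcodes are "identical" when they match perfectly and neither carries
# an ambiguity code, "compatible" when they differ only at positions
# explained by ambiguity codes (N matches anything, R matches A/G, ...),
# and "incorrect" when they differ by at least one substitution or indel at
# an unambiguous position. Errors are counted as substitutions + indels.
# Sequences of clearly different lengths (a mini-barcode against a
# full-length barcode) are compared over their best ends-free overlap so
# that the overhang is not penalised.

iupac_sets <- function() strsplit(Biostrings::IUPAC_CODE_MAP, "")

# TRUE where the two symbol vectors are consistent under IUPAC semantics
iupac_consistent <- function(a, b) {
  sets <- iupac_sets()
  mapply(function(x, y) {
    length(intersect(sets[[x]], sets[[y]])) > 0
  }, a, b, USE.NAMES = FALSE)
}

is_ambiguous <- function(ch) !(ch %in% DNA_BASES)

# +1 for consistent symbol pairs, -1 otherwise: used for the ends-free
# overlap mode where a maximal-score alignment needs positive matches
iupac_overlap_matrix <- function() {
  m <- iupac_edit_matrix()
  m[m == 0] <- 1
  m
}

#' Classify the correspondence of two barcodes
#'
#' Aligns the pair globally (or over the best ends-free overlap when the
#' lengths clearly differ, as for a 313-bp mini-barcode against a 658-bp
#' barcode) and counts substitution and indel errors at positions not
#' explained by IUPAC ambiguity codes.
#'
#' @param a,b DNA strings (IUPAC codes allowed).
#' @return list with `category` ("identical", "compatible" or "incorrect"),
#'   `error_count`, and `compared` (aligned positions with neither symbol
#'   ambiguous; the denominator used for identity percentages).
#' @export
classify_pair <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  a <- toupper(a); b <- toupper(b)
  no_amb <- !grepl("[^ACGT]", a) && !grepl("[^ACGT]", b)
  if (a == b && no_amb) {
    return(list(category = "identical", error_count = 0L,
                compared = nchar(a)))
  }
  overlap_mode <- min(nchar(a), nchar(b)) / max(nchar(a), nchar(b)) < 0.8
  if (overlap_mode) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
      substitutionMatrix = iupac_overlap_matrix(),
      gapOpening = 0, gapExtension = 1)
    # pattern()/subject() clip the ends-free overhang, which is exactly
    # what overlap mode should ignore
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = iupac_edit_matrix(),
      gapOpening = 0, gapExtension = 1)
    # alignedPattern()/alignedSubject() retain terminal gaps, which count
    # as indel errors in a global comparison
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  }
  gap <- pa == "-" | pb == "-"
  amb <- !gap & (is_ambiguous(pa) | is_ambiguous(pb))
  mism <- !gap & !amb & pa != pb
  # ambiguity-involving mismatches only count when the codes are inconsistent
  if (any(amb)) {
    inc <- amb & !iupac_consistent(pa, pb)
    mism <- mism | inc
    amb <- amb & !inc
  }
  errors <- sum(gap) + sum(mism)
  category <- if (errors > 0) "incorrect"
              else if (a == b && no_amb) "identical"
              else "compatible"
  list(category = category, error_count = as.integer(errors),
       compared = sum(!gap & !amb))
}

#' Compare two barcode sets
#'
#' Every specimen id shared by both sets is classified with
#' [classify_pair()]; ids present in only one set are listed per side. The
#' aggregate identity is `1 - sum(errors) / sum(compared positions)`, with
#' ambiguity-involving positions excluded from the denominator (the raw sums
#' are reported alongside).
#'
#' @param set_a,set_b named character vectors of barcodes, or FASTA paths.
#'   Names (or FASTA headers up to the first `;` or whitespace) are the
#'   specimen ids.
#' @param outdir optional directory: writes `identical.fasta`,
#'   `compatible.fasta`, `incorrect.fasta`, `only_in_A.fasta`,
#'   `only_in_B.fasta` (sequences taken from `set_a` where available) and a
#'   `comparison_summary.csv`.
#' @return object of class `comparison_report`: lists of ids per category,
#'   an `incorrect` data.frame (specimen_id, error_count), totals, and the
#'   aggregate identity.
#' @export
compare_sets <- function(set_a, set_b, outdir = NULL) {
  load_set <- function(x, label) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) x <- read_fasta(x)
    names(x) <- sub("[;[:space:]].*$", "", names(x))
    if (anyDuplicated(names(x))) {
      stop("duplicate specimen id(s) in set ", label, ": ",
           paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
    }
    toupper(x)
  }
  a <- load_set(set_a, "A")
  b <- load_set(set_b, "B")
  shared <- intersect(names(a), names(b))
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  cls <- lapply(shared, function(id) classify_pair(a[[id]], b[[id]]))
  cat_of <- vapply(cls, function(x) x$category, "")
  err_of <- vapply(cls, function(x) x$error_count, 0L)
  cmp_of <- vapply(cls, function(x) x$compared, 0)
  report <- structure(
    list(
      identical = shared[cat_of == "identical"],
      compatible = shared[cat_of == "compatible"],
      incorrect = data.frame(specimen_id = shared[cat_of == "incorrect"],
                             error_count = err_of[cat_of == "incorrect"],
                             stringsAsFactors = FALSE),
      only_in_A = only_a, only_in_B = only_b,
      totals = c(shared = length(shared),
                 identical = sum(cat_of == "identical"),
                 compatible = sum(cat_of == "compatible"),
                 incorrect = sum(cat_of == "incorrect"),
                 only_in_A = length(only_a), only_in_B = length(only_b)),
      total_errors = sum(err_of),
      total_compared = sum(cmp_of),
      aggregate_identity = if (sum(cmp_of) > 0) 1 - sum(err_of) / sum(cmp_of)
                           else NA_real_
    ),
    class = "comparison_report"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    take <- function(ids) {
      out <- ifelse(ids %in% names(a), a[ids], b[ids])
      stats::setNames(out, ids)
    }
    for (nm in c("identical", "compatible")) {
      ids <- report[[nm]]
      if (length(ids)) write_fasta(take(ids), file.path(outdir, paste0(nm, ".fasta")))
    }
    if (nrow(report$incorrect)) {
      ids <- report$incorrect$specimen_id
      both <- stats::setNames(c(a[ids], b[ids]),
                              c(paste0(ids, "|A"), paste0(ids, "|B")))
      write_fasta(both, file.path(outdir, "incorrect.fasta"))
    }
    if (length(only_a)) write_fasta(a[only_a], file.path(outdir, "only_in_A.fasta"))
    if (length(only_b)) write_fasta(b[only_b], file.path(outdir, "only_in_B.fasta"))
    df <- data.frame(specimen_id = shared, category = cat_of,
                     error_count = err_of, compared = cmp_of,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, file.path(outdir, "comparison_summary.csv"),
                     row.names = FALSE)
  }
  report
}

#' All-vs-all comparison of several barcode sets
#'
#' @param sets named list of barcode sets (named vectors or FASTA paths).
#' @return data.frame with one row per ordered set pair and the category
#'   totals plus aggregate identity.
#' @export
compare_all <- function(sets) {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) {
    r <- compare_sets(sets[[p[1]]], sets[[p[2]]])
    data.frame(set_a = p[1], set_b = p[2],
               shared = r$totals[["shared"]],
               identical = r$totals[["identical"]],
               compatible = r$totals[["compatible"]],
               incorrect = r$totals[["incorrect"]],
               errors = r$total_errors,
               aggregate_identity = r$aggregate_identity,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.comparison_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "Barcode comparison: %d shared (%d identical, %d compatible, %d incorrect), %d only in A, %d only in B\n",
    t[["shared"]], t[["identical"]], t[["compatible"]], t[["incorrect"]],
    t[["only_in_A"]], t[["only_in_B"]]))
  cat(sprintf("Errors: %d over %d compared positions (identity %.4f%%)\n",
              x$total_errors, x$total_compared,
              100 * x$aggregate_identity))
  invisible(x)
}
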