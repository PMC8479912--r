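# Multiple-sequence-alignment engine adapter.
#
# All alignments go through one injected engine configuration so that the
# caller never depends on a particular aligner. The default engine is MAFFT;
# read-level alignments use gap costs suited to indel-rich nanopore reads
# (zero gap opening, linear extension), while barcode-level alignments use
# the aligner's defaults. Parameters can be overridden through a key=value
# parameter file, passed verbatim to the engine.

#' Aligner configuration
#'
#' @param engine currently `"mafft"`.
#' @param read_args command-line arguments used when aligning raw reads.
#' @param barcode_args arguments used when aligning called barcodes
#'   (gap filter, neighbour comparison).
#' @param parfile optional path to a key=value parameter file; entries are
#'   appended to `read_args` (e.g. `op=0` becomes `--op 0`, a bare `nofft`
#'   becomes `--nofft`).
#' @return object of class `aligner_config`.
#' @export
aligner_config <- function(engine = "mafft",
                           read_args = c("--retree", "2", "--op", "0",
                                         "--ep", "1"),
                           barcode_args = c("--retree", "2"),
                           parfile = NULL) {
  if (!identical(engine, "mafft")) {
    stop("unknown alignment engine: ", engine)
  }
  if (!nzchar(Sys.which(engine))) {
    stop("alignment engine executable not found on PATH: ", engine)
  }
  if (!is.null(parfile)) {
    read_args <- c(read_args, read_parfile(parfile))
  }
  structure(list(engine = engine, read_args = read_args,
                 barcode_args = barcode_args),
            class = "aligner_config")
}

#' Parse an aligner parameter file
#'
#' Plain text, one `key=value` (or bare `key`) per line; `#` starts a
#' comment. Keys are turned into `--key value` argument pairs.
#'
#' @param path file path.
#' @return character vector of command-line arguments.
#' @export
read_parfile <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  unlist(lapply(lines, function(l) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    key <- paste0("--", trimws(kv[1]))
    if (length(kv) > 1 && nzchar(trimws(kv[2]))) c(key, trimws(kv[2])) else key
  }))
}

#' Align the reads of one bin
#'
#' Returns a multiple sequence alignment whose rows, after removing gaps,
#' reproduce the input reads exactly and in order. A single sequence is
#' returned as its own trivial alignment without invoking the engine.
#'
#' @param reads character vector of sequences (optionally named).
#' @param config an [aligner_config()].
#' @param mode `"reads"` (nanopore gap costs) or `"barcodes"` (engine
#'   defaults).
#' @return object of class `msa`: list with `seqs` (gapped rows, named) and
#'   `width`.
#' @export
align_bin <- function(reads, config = aligner_config(), mode = "reads") {
  if (length(reads) == 0) stop("cannot align an empty read set")
  nm <- names(reads) %||% paste0("s", seq_along(reads))
  reads <- toupper(unname(reads))
  if (length(reads) == 1) {
    return(structure(list(seqs = stats::setNames(reads, nm),
                          width = nchar(reads)), class = "msa"))
  }
  tmp_in <- tempfile(fileext = ".fasta")
  tmp_out <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(tmp_in, tmp_out)), add = TRUE)
  # engine-safe row labels; mapped back on read-in
  write_fasta(stats::setNames(reads, paste0("s", seq_along(reads))), tmp_in)
  args <- switch(mode, reads = config$read_args, barcodes = config$barcode_args,
                 stop("unknown alignment mode: ", mode))
  err <- tempfile()
  status <- suppressWarnings(
    system2(config$engine, c("--quiet", args, tmp_in),
            stdout = tmp_out, stderr = err)
  )
  if (status != 0L || !file.size(tmp_out)) {
    stop("alignment engine failed (exit ", status, "): ",
         paste(readLines(err, warn = FALSE), collapse = " "))
  }
  aln <- read_fasta(tmp_out)
  aln <- aln[order(as.integer(sub("^s", "", names(aln))))]  # input order
  names(aln) <- nm
  stopifnot(identical(unname(gsub("-", "", aln)), reads))
  structure(list(seqs = aln, width = nchar(aln[[1]])), class = "msa")
}

#' @export
as.matrix.msa <- function(x, ...) seq_matrix(x$seqs)

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", length(x$seqs), "rows x", x$width, "columns\n")
  invisible(x)
}
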