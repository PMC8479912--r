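# Small shared helpers: sequence string utilities and FASTQ/FASTA I/O wrappers.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement honouring IUPAC ambiguity codes.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  out <- character(length(x))
  nz <- nzchar(x)
  if (any(nz)) {
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz]))
    )
  }
  out
}

#' Read a FASTQ file as a named character vector
#'
#' Plain or gzip-compressed FASTQ. Qualities are discarded: all downstream
#' steps work from the base calls alone.
#'
#' @param path FASTQ file path (`.fastq` or `.fastq.gz`).
#' @return named character vector of read sequences, in file (arrival) order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- as.character(x)
  # keep only the read id (first whitespace-delimited token)
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to FASTQ with dummy qualities
#'
#' @param seqs named character vector.
#' @param path output path; a `.gz` suffix triggers compression.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(
    Biostrings::width(x),
    function(w) paste(rep("I", w), collapse = ""), ""
  ))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file path.
#' @return named character vector (names are full headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- names(x)
  seqs
}

#' Write a named character vector to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Split sequences into a character matrix (rows = sequences); all inputs must
# share one length.
seq_matrix <- function(seqs) {
  stopifnot(length(unique(nchar(seqs))) == 1L)
  m <- matrix("", nrow = length(seqs), ncol = nchar(seqs[[1]]))
  sp <- strsplit(toupper(seqs), "")
  for (i in seq_along(sp)) m[i, ] <- sp[[i]]
  rownames(m) <- names(seqs)
  m
}

count_char <- function(x, ch) {
  vapply(gregexpr(ch, x, fixed = TRUE), function(g) sum(g > 0), 0L)
}

# uniform random DNA string(s); uses the current RNG stream
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, "")
}
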