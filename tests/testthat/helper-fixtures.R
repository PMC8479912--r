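# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(preset) {
  if (!exists(preset, envir = .fixture_cache)) {
    dir <- file.path(tempdir(), paste0("fx_", preset))
    assign(preset, make_fixture(preset, dir), envir = .fixture_cache)
  }
  get(preset, envir = .fixture_cache)
}

# full pipeline result on a preset, cached (used by several tests)
get_pipeline_result <- function(preset) {
  key <- paste0("pipe_", preset)
  if (!exists(key, envir = .fixture_cache)) {
    fx <- get_fixture(preset)
    cfg <- run_config(fx$paths$fastq, fx$paths$sheet, fx$scheme,
                      file.path(tempdir(), paste0("out_", preset)))
    assign(key, run_pipeline(cfg), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small scheme shared by demux unit tests: 8 fwd + 8 rev tags
small_scheme <- function() {
  if (!exists("scheme16", envir = .fixture_cache)) {
    tags <- generate_tag_set(16, seed = 303)
    assign("scheme16", tag_scheme(tags, folmer_primers(), 658),
           envir = .fixture_cache)
  }
  get("scheme16", envir = .fixture_cache)
}

# build an error-free tagged amplicon for a sheet entry
build_amplicon <- function(scheme, fwd_tag, rev_tag, inner) {
  pp <- scheme$primer_pair
  paste0(fwd_tag, pp$fwd, inner, revcomp(pp$rev), revcomp(rev_tag))
}

# independent O(nm) Levenshtein oracle, written long-hand on purpose
lev_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, rep(0L, m))
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1]
}

# independent per-column consensus oracle: plain loop + table()
consensus_oracle <- function(m, thr, gap_major) {
  out <- character(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (sum(col == "-") / length(col) > gap_major) next
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    f <- tab / length(col)
    hits <- names(f)[f >= thr]
    out <- c(out, if (length(hits) == 1) hits else "N")
  }
  paste(out, collapse = "")
}

random_msa <- function(nrow, ncol) {
  matrix(sample(c("A", "C", "G", "T", "N", "-"), nrow * ncol, replace = TRUE),
         nrow = nrow)
}
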