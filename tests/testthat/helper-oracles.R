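# Independent oracles and small constructors used across the test files.
# The Levenshtein oracle is a plain-R dynamic program, written without
# reference to the package's identity code path.

lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  la <- length(x); lb <- length(y)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j] + (x[i] != y[j]), prev[j + 1L] + 1L, cur[j] + 1L)
    }
    prev <- cur
  }
  prev[lb + 1L]
}

oracle_identity <- function(a, b) {
  alen <- max(nchar(a), nchar(b))
  100 * (alen - min(lev_dp(a, b), alen)) / alen
}

# substitute k positions spread evenly over the sequence (base -> next in
# ACGT), giving a sequence at (L - k) / L * 100 percent identity; spreading
# keeps the unit-cost edit distance equal to k for non-repetitive sequences
sub_k <- function(seq, k) {
  if (k == 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  pos <- unique(round(seq(1, length(chars), length.out = k)))
  stopifnot(length(pos) == k)
  idx <- match(chars[pos], bases)
  chars[pos] <- bases[(idx %% 4L) + 1L]
  paste(chars, collapse = "")
}

# a fixed non-repetitive sequence for boundary constructions
random_seq <- function(len, seed = 1234) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# a hit list row-by-row constructor for decision-table tests
make_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(record_id = r$id %||% "REC1", identity = r$identity,
               species = r$species %||% "", genus = r$genus %||% "",
               family = r$family %||% "FamX", order = r$order %||% "OrdX",
               regional = r$regional %||% TRUE,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$identity, !nzchar(df$species), !df$regional, df$record_id), ]
  rownames(df) <- NULL
  class(df) <- c("hit_list", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a tiny hand-built reference library data.frame
toy_library <- function(seqs, species, genus, family = NULL, order = NULL,
                        regional = TRUE, known_error = FALSE) {
  n <- length(seqs)
  lib <- data.frame(
    record_id = sprintf("TOY%03d", seq_len(n)),
    sequence = seqs, species = species, genus = genus,
    family = if (is.null(family)) rep("FamA", n) else family,
    order = if (is.null(order)) rep("Lepidoptera", n) else order,
    regional = rep_len(regional, n), known_error = rep_len(known_error, n),
    stringsAsFactors = FALSE
  )
  class(lib) <- c("reference_library", "data.frame")
  lib
}

# assemble a full amplicon read around an insert, with concrete primers
# (W resolved to A), under the default config's primer layout
build_read <- function(insert, tag = "AAACCCGGG", qual_score = 30L,
                       config = run_config()) {
  fwd <- gsub("W", "A", config$primer_forward)
  rev <- gsub("W", "A", config$primer_reverse)
  seq <- paste0(tag, fwd, insert, revcomp(rev))
  data.frame(read_id = "read1", sequence = seq,
             quality = phred_to_string(rep(qual_score, nchar(seq))),
             stringsAsFactors = FALSE)
}
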