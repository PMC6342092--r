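## Demultiplexing and read filtering: exact 9-base tag lookup, the average
## Phred >= Q20 filter, and anchored IUPAC-aware matching of both first-stage
## primers. Filter order (tag -> quality -> primers) is fixed so the discard
## statistics are reproducible; the surviving set is order-independent.

#' IUPAC-aware pattern match
#'
#' `TRUE` iff the number of window positions whose base falls outside the
#' pattern's allowed IUPAC set is at most `max_mismatches`.
#'
#' @param pattern IUPAC string (e.g. a degenerate primer).
#' @param window plain nucleotide string of the same length.
#' @param max_mismatches tolerated disallowed positions.
#' @return logical scalar.
#' @examples
#' match_iupac("W", "A", 0)   # TRUE:  W = A or T
#' match_iupac("W", "G", 0)   # FALSE
#' @export
match_iupac <- function(pattern, window, max_mismatches = 0L) {
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window must have equal length")
  }
  mm <- iupac_mismatches(pattern, window)
  mm <= max_mismatches
}

## number of disallowed positions, vectorised over windows
iupac_mismatches <- function(pattern, windows) {
  pchars <- strsplit(pattern, "")[[1]]
  allowed <- lapply(pchars, function(ch) {
    code <- IUPAC_CODE_MAP[[ch]]
    if (is.null(code)) stop(sprintf("'%s' is not an IUPAC nucleotide symbol", ch))
    strsplit(code, "")[[1]]
  })
  mm <- integer(length(windows))
  for (i in seq_along(pchars)) {
    mm <- mm + !(substr(windows, i, i) %in% allowed[[i]])
  }
  mm
}

#' Demultiplex tagged amplicon reads
#'
#' A read is assigned to a sample iff (i) its first 9 bases exactly equal
#' that sample's index tag, (ii) the arithmetic mean of its Phred scores is
#' at least `min_avg_quality` (reads with average quality strictly below the
#' threshold are discarded, so a mean of exactly Q20 passes under the
#' default), and (iii) the forward primer matches immediately after the tag
#' and the reverse complement of the reverse primer matches at the 3' end,
#' each within `max_primer_mismatches`. Assigned reads are trimmed to the
#' insert (tag and both primer spans removed, qualities trimmed alike).
#' Every input read lands in exactly one bucket: a per-sample list, the
#' unassigned pool (unknown tag), or a discard reason.
#'
#' @param reads `data.frame` with columns `read_id`, `sequence`, `quality`
#'   (a `sample_id`/`source` ground-truth column, if present, is carried
#'   through).
#' @param manifest a `sample_manifest`.
#' @param config a [run_config()].
#' @return object of class `demux_result`: list with `per_sample` (named list
#'   of trimmed read data.frames), `unassigned`, and `stats` (counts per
#'   outcome: assigned, no_tag, low_quality, missing_primer).
#' @export
demultiplex <- function(reads, manifest, config = run_config()) {
  manifest <- as_sample_manifest(as.data.frame(manifest))
  reads <- as.data.frame(reads)
  n <- nrow(reads)
  fwd <- config$primer_forward
  rcr <- revcomp(config$primer_reverse)   # reverse primer as sequenced (3' end)
  flen <- nchar(fwd)
  rlen <- nchar(rcr)

  tag <- substr(reads$sequence, 1L, 9L)
  sample_id <- manifest$sample_id[match(tag, manifest$tag)]
  has_tag <- !is.na(sample_id) & nchar(reads$sequence) >= 9L + flen + rlen

  avgq <- mean_phred(reads$quality)
  good_q <- avgq >= config$min_avg_quality

  len <- nchar(reads$sequence)
  fwd_window <- substr(reads$sequence, 10L, 9L + flen)
  rev_window <- substr(reads$sequence, len - rlen + 1L, len)
  primer_ok <- rep(FALSE, n)
  idx <- which(has_tag & good_q)
  if (length(idx)) {
    primer_ok[idx] <-
      iupac_mismatches(fwd, fwd_window[idx]) <= config$max_primer_mismatches &
      iupac_mismatches(rcr, rev_window[idx]) <= config$max_primer_mismatches
  }

  outcome <- rep("assigned", n)
  outcome[!has_tag] <- "no_tag"
  outcome[has_tag & !good_q] <- "low_quality"
  outcome[has_tag & good_q & !primer_ok] <- "missing_primer"

  keep <- outcome == "assigned"
  trimmed <- reads[keep, , drop = FALSE]
  if (nrow(trimmed)) {
    tl <- nchar(trimmed$sequence)
    trimmed$sequence <- substr(trimmed$sequence, 9L + flen + 1L, tl - rlen)
    trimmed$quality <- substr(trimmed$quality, 9L + flen + 1L, tl - rlen)
    trimmed$sample_id <- sample_id[keep]
  } else {
    trimmed$sample_id <- character(0)
  }
  per_sample <- split(trimmed, factor(trimmed$sample_id, levels = manifest$sample_id))

  stats <- c(assigned = sum(keep),
             no_tag = sum(outcome == "no_tag"),
             low_quality = sum(outcome == "low_quality"),
             missing_primer = sum(outcome == "missing_primer"))
  stopifnot(sum(stats) == n)  # conservation

  structure(list(per_sample = per_sample,
                 unassigned = reads[outcome == "no_tag", , drop = FALSE],
                 stats = stats),
            class = "demux_result")
}

#' @export
print.demux_result <- function(x, ...) {
  cat("demultiplexing result\n")
  cat(sprintf("  %-15s %d\n", names(x$stats), x$stats), sep = "")
  cat("  per-sample assigned counts:\n")
  cnt <- vapply(x$per_sample, nrow, integer(1))
  cat(sprintf("    %-12s %d\n", names(cnt), cnt), sep = "")
  invisible(x)
}
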