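## De novo greedy OTU clustering at a fixed identity threshold, random
## representative picking, OTU table construction and the minimum-abundance
## filter.

#' Percent identity between two sequences
#'
#' Global end-to-end identity under a unit-cost edit alignment: gaps count as
#' mismatches and the alignment length is taken as the length of the longer
#' sequence, so `identity = 100 * (max(len) - edit_distance) / max(len)`.
#' For the equal-length, substitution-only sequences this pipeline produces,
#' this equals the Hamming identity exactly. Symmetric.
#'
#' @param a,b non-empty nucleotide strings.
#' @return percent identity in \[0, 100\].
#' @examples
#' percent_identity(strrep("A", 157), strrep("A", 157))  # 100
#' @export
percent_identity <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) stop("sequences must be non-empty")
  alen <- max(nchar(a), nchar(b))
  d <- adist(a, b)[1L, 1L]
  100 * (alen - min(d, alen)) / alen
}

## identity of one query against many subjects (same convention), vectorised
identity_to_many <- function(query, subjects) {
  alen <- pmax(nchar(query), nchar(subjects))
  d <- pmin(drop(adist(query, subjects)), alen)
  100 * (alen - d) / alen
}

## identities needed only at or above a threshold: banded edit distance with
## early exit (exact for every pair at or above the threshold; pairs below
## it come back as below-threshold values and are never joined anyway)
identity_to_many_bounded <- function(query, subjects, threshold) {
  alen <- pmax(nchar(query), nchar(subjects))
  max_dist <- max(0L, as.integer(floor(max(alen) * (1 - threshold / 100) + 1e-9)))
  d <- pmin(.bounded_edit_distance(query, subjects, max_dist), alen)
  100 * (alen - d) / alen
}

#' Greedy de novo clustering of insert sequences
#'
#' Dereplicates the trimmed insert sequences, orders the unique sequences by
#' descending replicate count (ties lexicographic), and assigns each in turn
#' to the existing seed with the highest identity at or above
#' `cluster_identity` (ties go to the earliest-created seed), founding a new
#' seed otherwise. High-abundance true variants therefore become seeds and
#' error reads are absorbed as members. With `first_fit = TRUE` in the
#' config, a sequence joins the first seed (in creation order) above the
#' threshold instead of the best one.
#'
#' @param reads `data.frame` of trimmed reads with columns `read_id`,
#'   `sequence`, `sample_id`.
#' @param config a [run_config()].
#' @return list of OTUs; each is a list with `otu_id`, `seed` (the seed
#'   sequence), `members` (`data.frame` of `read_id`, `sample_id`,
#'   `sequence`), `total_count`, and `representative`/`representative_id`
#'   (unset until [pick_representatives()]).
#' @export
cluster_de_novo <- function(reads, config = run_config()) {
  stopifnot(all(c("read_id", "sequence", "sample_id") %in% names(reads)))
  if (nrow(reads) == 0L) return(list())
  tab <- table(reads$sequence)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]

  seeds <- character(0)
  membership <- integer(length(uniq))   # seq index -> cluster index
  for (i in seq_along(uniq)) {
    if (length(seeds) == 0L) {
      seeds <- uniq[i]
      membership[i] <- 1L
      next
    }
    ident <- identity_to_many_bounded(uniq[i], seeds, config$cluster_identity)
    hit <- which(ident >= config$cluster_identity)
    if (length(hit) == 0L) {
      seeds <- c(seeds, uniq[i])
      membership[i] <- length(seeds)
    } else if (config$first_fit) {
      membership[i] <- hit[1L]
    } else {
      best <- max(ident[hit])
      membership[i] <- hit[which(ident[hit] == best)[1L]]
    }
  }

  cluster_of <- membership[match(reads$sequence, uniq)]
  otus <- lapply(seq_along(seeds), function(k) {
    m <- reads[cluster_of == k, c("read_id", "sample_id", "sequence")]
    rownames(m) <- NULL
    list(otu_id = sprintf("OTU%04d", k), seed = seeds[k], members = m,
         total_count = nrow(m), representative = NA_character_,
         representative_id = NA_character_)
  })
  otus
}

#' Pick a random representative sequence per OTU
#'
#' Uniform seeded choice among the member reads of each cluster (so a
#' sequence present in several copies is proportionally more likely), as in
#' the random `pick_rep_set` step of the workflow this package models.
#' Deterministic for a given cluster membership and seed.
#'
#' @param otus list of OTUs from [cluster_de_novo()].
#' @param seed integer seed.
#' @return the OTU list with `representative` and `representative_id` set.
#' @export
pick_representatives <- function(otus, seed = 1L) {
  set.seed(seed)
  lapply(otus, function(o) {
    i <- sample.int(nrow(o$members), 1L)
    o$representative <- o$members$sequence[i]
    o$representative_id <- o$members$read_id[i]
    o
  })
}

#' Build the OTU-by-sample count table
#'
#' Rows are OTUs ordered by descending total count (ties by representative
#' read id, lexicographic); columns follow the manifest's sample order.
#'
#' @param otus OTU list with representatives set.
#' @param sample_ids ordered sample ids (manifest order).
#' @return object of class `otu_table`: list with integer matrix `counts`
#'   (otu x sample), named vectors `representative` (sequences) and
#'   `representative_id`.
#' @export
make_otu_table <- function(otus, sample_ids) {
  stopifnot(length(otus) == 0L || !is.na(otus[[1L]]$representative))
  total <- vapply(otus, `[[`, numeric(1), "total_count")
  rep_id <- vapply(otus, `[[`, character(1), "representative_id")
  ord <- order(-total, rep_id)
  otus <- otus[ord]
  counts <- matrix(0L, nrow = length(otus), ncol = length(sample_ids),
                   dimnames = list(vapply(otus, `[[`, character(1), "otu_id"),
                                   sample_ids))
  for (o in otus) {
    tab <- table(factor(o$members$sample_id, levels = sample_ids))
    counts[o$otu_id, ] <- as.integer(tab)
    if (sum(tab) != o$total_count) {
      stop(sprintf("OTU %s has members outside the declared samples", o$otu_id))
    }
  }
  structure(list(counts = counts,
                 representative = stats::setNames(
                   vapply(otus, `[[`, character(1), "representative"),
                   rownames(counts)),
                 representative_id = stats::setNames(
                   vapply(otus, `[[`, character(1), "representative_id"),
                   rownames(counts))),
            class = "otu_table")
}

#' Drop low-abundance OTUs
#'
#' Retains exactly those OTUs whose total count over all samples combined is
#' at least `min_otu_reads` (default 8, i.e. OTUs with fewer than 8 reads in
#' all samples combined are discarded). Sample columns are unchanged.
#'
#' @param table an `otu_table`.
#' @param config a [run_config()].
#' @return the filtered `otu_table`.
#' @export
filter_low_abundance <- function(table, config = run_config()) {
  stopifnot(inherits(table, "otu_table"))
  keep <- rowSums(table$counts) >= config$min_otu_reads
  structure(list(counts = table$counts[keep, , drop = FALSE],
                 representative = table$representative[keep],
                 representative_id = table$representative_id[keep]),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d OTUs x %d samples, %d reads total\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  print(head(x$counts, 10L))
  if (nrow(x$counts) > 10L) cat("...\n")
  invisible(x)
}
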