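## Readers and writers for the on-disk artifacts: FASTQ, FASTA + taxonomy
## TSV, sample manifests, OTU tables and assignment tables. TSV dialect:
## tab-separated, UTF-8, no quoting, '.' decimal separator.

#' Read a 4-line FASTQ file (Phred+33)
#'
#' @param path FASTQ file path.
#' @return `data.frame` with columns `read_id` (id up to first whitespace),
#'   `sequence`, `quality` (Phred+33 string), in file order.
#' @export
read_fastq <- function(path) {
  ## structural validation first: the reference parser slices qualities by
  ## sequence length, so a short quality line must be caught at line level
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ file (%d lines, not a multiple of 4): %s",
                 length(lines), path))
  }
  first <- seq(1L, length(lines), by = 4L)
  bad <- nchar(lines[first + 1L]) != nchar(lines[first + 3L])
  if (any(bad)) {
    id <- sub("^@", "", sub("\\s.*$", "", lines[first][bad][1L]))
    stop(sprintf("FASTQ record '%s': sequence and quality lengths differ", id))
  }
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(read_id = sub("\\s.*$", "", names(seqs)),
             sequence = as.character(seqs),
             quality = as.character(S4Vectors::mcols(seqs)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads as 4-line FASTQ (Phred+33)
#'
#' @param reads `data.frame` with columns `read_id`, `sequence`, `quality`.
#'   Ground-truth columns from the simulator are not written.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a reference library from FASTA plus a taxonomy TSV
#'
#' The taxonomy table has columns `record_id`, `species`, `genus`, `family`,
#' `order`, `regional`, `known_error`. Every FASTA id must appear in the
#' taxonomy and vice versa; orphans on either side are a hard error. Empty
#' species fields are preserved (records usable for genus-level calls only).
#'
#' @param fasta_path FASTA of barcode sequences.
#' @param taxonomy_path 7-column taxonomy TSV with header.
#' @return a `reference_library` data.frame.
#' @export
read_reference <- function(fasta_path, taxonomy_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- read.delim(taxonomy_path, colClasses = list(species = "character",
                                                     genus = "character"),
                    stringsAsFactors = FALSE)
  need <- c("record_id", "species", "genus", "family", "order", "regional", "known_error")
  if (!all(need %in% names(tax))) {
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  }
  only_fasta <- setdiff(ids, tax$record_id)
  only_tax <- setdiff(tax$record_id, ids)
  if (length(only_fasta) || length(only_tax)) {
    stop("reference id mismatch; only in FASTA: [",
         paste(only_fasta, collapse = ", "), "]; only in taxonomy: [",
         paste(only_tax, collapse = ", "), "]")
  }
  tax <- tax[match(ids, tax$record_id), ]
  tax$species[is.na(tax$species)] <- ""
  tax$genus[is.na(tax$genus)] <- ""
  lib <- data.frame(record_id = ids, sequence = as.character(seqs),
                    species = tax$species, genus = tax$genus,
                    family = tax$family, order = tax$order,
                    regional = as.logical(tax$regional),
                    known_error = as.logical(tax$known_error),
                    stringsAsFactors = FALSE, row.names = NULL)
  validate_reference_library(lib)
  class(lib) <- c("reference_library", "data.frame")
  lib
}

#' @rdname read_reference
#' @param library a `reference_library`.
#' @export
write_reference <- function(library, fasta_path, taxonomy_path) {
  x <- Biostrings::DNAStringSet(library$sequence)
  names(x) <- library$record_id
  Biostrings::writeXStringSet(x, fasta_path)
  write_tsv(library[, c("record_id", "species", "genus", "family", "order",
                        "regional", "known_error")], taxonomy_path)
  invisible(c(fasta_path, taxonomy_path))
}

#' Read / write a sample manifest
#'
#' A manifest maps each sample to its 9-base index tag and sample type
#' (`bird_feces`, `wild_frass` or `lab_control`). Tags must be unique.
#'
#' @param path TSV with header columns `sample_id`, `tag`, `sample_type`.
#' @return `data.frame` of class `sample_manifest`.
#' @export
read_manifest <- function(path) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  as_sample_manifest(m)
}

#' @rdname read_manifest
#' @param manifest a `data.frame` with columns `sample_id`, `tag`,
#'   `sample_type`.
#' @export
as_sample_manifest <- function(manifest) {
  need <- c("sample_id", "tag", "sample_type")
  stopifnot(all(need %in% names(manifest)))
  m <- as.data.frame(manifest)[, need]
  if (any(nchar(m$tag) != 9L) || !all(grepl("^[ACGT]{9}$", m$tag))) {
    stop("index tags must be 9 bases over {A,C,G,T}")
  }
  if (anyDuplicated(m$tag)) stop("index tags must be unique")
  if (anyDuplicated(m$sample_id)) stop("sample ids must be unique")
  if (!all(m$sample_type %in% c("bird_feces", "wild_frass", "lab_control"))) {
    stop("sample_type must be bird_feces, wild_frass or lab_control")
  }
  class(m) <- c("sample_manifest", "data.frame")
  m
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write_tsv(as.data.frame(manifest), path)
  invisible(path)
}

#' Write / read an OTU table
#'
#' Rows are OTUs ordered by descending total count (ties broken by
#' representative read id, lexicographic); columns are `otu_id`,
#' `representative_id`, then one count column per sample in manifest order.
#'
#' @param table an `otu_table` object (see [make_otu_table()]).
#' @param path output TSV path.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(otu_id = rownames(table$counts),
                   representative_id = table$representative_id,
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$otu_id
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 representative_id = stats::setNames(df$representative_id, df$otu_id),
                 representative = NULL),
            class = "otu_table")
}

#' Write taxonomic assignments as TSV
#'
#' One row per OTU: the resolved rank, taxon, best identity, the rule that
#' fired, the supporting reference record, and the lineage columns.
#'
#' @param assignments assignment `data.frame` from [assign_all()].
#' @param path output TSV path.
#' @export
write_assignments <- function(assignments, path) {
  write_tsv(as.data.frame(assignments), path)
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = list(taxon = "character", species = "character",
                               genus = "character", family = "character",
                               order = "character"))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
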