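#' Pipeline run configuration
#'
#' Collects every threshold used by the pipeline. Defaults follow the
#' published workflow this package reimplements: reads with average quality
#' below Q20 are discarded, OTUs are clustered at 98% identity and dropped
#' below 8 reads total, species-level taxonomy requires a 97% match, calls
#' below 90% are unidentified, and the same-sample rescue operates at 95%.
#'
#' @param min_avg_quality minimum mean Phred score for a read to be kept.
#' @param cluster_identity percent identity for de novo OTU clustering.
#' @param min_otu_reads minimum total reads (all samples combined) for an OTU
#'   to be retained.
#' @param species_identity minimum percent identity for a species-rank call.
#' @param unidentified_below percent identity below which an OTU is
#'   unidentified at every rank.
#' @param rescue_identity identity threshold for the same-sample rescue rules.
#' @param seed integer seed governing every stochastic step.
#' @param primer_forward,primer_reverse locus-specific primer sequences
#'   (IUPAC allowed); defaults are the Zeale COI mini-barcode primers.
#' @param max_primer_mismatches mismatches tolerated when matching each primer.
#' @param control_genus genus expected in laboratory control samples.
#' @param top_k number of best reference hits retained per OTU.
#' @param first_fit if `TRUE` the clusterer joins the first seed above the
#'   threshold instead of the best one.
#' @return an object of class `run_config` (a validated named list).
#' @examples
#' cfg <- run_config(seed = 1)
#' cfg$cluster_identity
#' @export
run_config <- function(min_avg_quality = 20,
                       cluster_identity = 98,
                       min_otu_reads = 8L,
                       species_identity = 97,
                       unidentified_below = 90,
                       rescue_identity = 95,
                       seed = 1L,
                       primer_forward = "AGATATTGGAACWTTATATTTTATTTTTGG",
                       primer_reverse = "WACTAATCAATTWCCAAATCCTCC",
                       max_primer_mismatches = 0L,
                       control_genus = "Samia",
                       top_k = 20L,
                       first_fit = FALSE) {
  cfg <- list(
    min_avg_quality = as.numeric(min_avg_quality),
    cluster_identity = as.numeric(cluster_identity),
    min_otu_reads = as.integer(min_otu_reads),
    species_identity = as.numeric(species_identity),
    unidentified_below = as.numeric(unidentified_below),
    rescue_identity = as.numeric(rescue_identity),
    seed = as.integer(seed),
    primer_forward = toupper(primer_forward),
    primer_reverse = toupper(primer_reverse),
    max_primer_mismatches = as.integer(max_primer_mismatches),
    control_genus = as.character(control_genus),
    top_k = as.integer(top_k),
    first_fit = isTRUE(first_fit)
  )
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  bad <- function(msg) {
    stop(errorCondition(msg, class = c("dietbarcoder_config_error", "error")))
  }
  if (!(cfg$unidentified_below > 0 &&
        cfg$unidentified_below <= cfg$rescue_identity &&
        cfg$rescue_identity <= cfg$species_identity &&
        cfg$species_identity <= 100)) {
    bad("need 0 < unidentified_below <= rescue_identity <= species_identity <= 100")
  }
  if (!(cfg$cluster_identity > 0 && cfg$cluster_identity <= 100)) {
    bad("cluster_identity must be in (0, 100]")
  }
  if (cfg$min_otu_reads < 0L) bad("min_otu_reads must be non-negative")
  if (cfg$max_primer_mismatches < 0L) bad("max_primer_mismatches must be non-negative")
  if (cfg$top_k < 1L) bad("top_k must be at least 1")
  iupac <- names(IUPAC_CODE_MAP)
  for (p in c(cfg$primer_forward, cfg$primer_reverse)) {
    if (nchar(p) == 0L || !all(strsplit(p, "")[[1]] %in% iupac)) {
      bad(sprintf("primer '%s' is not an IUPAC nucleotide string", p))
    }
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("dietbarcoder run configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Read / write a run configuration as a flat key=value file
#'
#' @param path file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  args <- as.list(vals)
  names(args) <- keys
  defaults <- formals(run_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop(errorCondition(
      paste("unknown config keys:", paste(unknown, collapse = ", ")),
      class = c("dietbarcoder_config_error", "error")
    ))
  }
  for (nm in names(args)) {
    proto <- eval(defaults[[nm]])
    if (is.numeric(proto)) args[[nm]] <- as.numeric(args[[nm]])
    if (is.logical(proto)) args[[nm]] <- as.logical(args[[nm]])
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}
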