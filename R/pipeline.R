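## End-to-end orchestration: simulate -> demultiplex -> cluster -> assign ->
## summarise, from one config and one master seed, with a reproducibility
## manifest. One global seed fans out to per-stage seeds via fixed offsets
## so each stage is independently reproducible.

SEED_OFFSETS <- c(library = 101L, design = 202L, reads = 303L, reps = 404L)

#' Default synthetic study design
#'
#' Builds a small mock study around a reference library: bird-feces samples
#' (4-5 regional prey species each, geometrically skewed abundances),
#' wild-frass samples (2-3 species), and laboratory control samples of the
#' control genus only. Index tags are distinct random 9-mers. Field samples
#' draw only regional, non-control species.
#'
#' @param library a `reference_library`.
#' @param seed integer seed.
#' @param n_bird,n_frass,n_control sample counts per type.
#' @param read_depth reads per sample.
#' @param contamination_rate contaminant read fraction per sample.
#' @param control_species species used for control samples.
#' @return list with `manifest` (a `sample_manifest`) and `specs` (named
#'   list of [community_spec()]s).
#' @export
default_study_design <- function(library, seed = 1L,
                                 n_bird = 4L, n_frass = 3L, n_control = 2L,
                                 read_depth = 2000L,
                                 contamination_rate = 0.02,
                                 control_species = "Samia cynthia") {
  set.seed(seed)
  pool <- unique(library$species[library$regional & nzchar(library$species) &
                                   library$species != control_species &
                                   !library$known_error])
  if (length(pool) < 5L) stop("reference library has too few regional species")
  n <- n_bird + n_frass + n_control
  tags <- character(0)
  while (length(tags) < n) {
    tags <- unique(c(tags, random_dna(n, 9L)))
  }
  tags <- tags[seq_len(n)]
  ids <- c(sprintf("bird%02d", seq_len(n_bird)),
           sprintf("frass%02d", seq_len(n_frass)),
           sprintf("ctrl%02d", seq_len(n_control)))
  types <- rep(c("bird_feces", "wild_frass", "lab_control"),
               c(n_bird, n_frass, n_control))
  manifest <- as_sample_manifest(data.frame(sample_id = ids, tag = tags,
                                            sample_type = types,
                                            stringsAsFactors = FALSE))
  skewed <- function(k) {
    w <- 0.5^(seq_len(k) - 1L)
    w / sum(w)
  }
  specs <- lapply(seq_len(n), function(i) {
    if (types[i] == "lab_control") {
      comp <- stats::setNames(1, control_species)
    } else {
      k <- if (types[i] == "bird_feces") sample(4:5, 1L) else sample(2:3, 1L)
      comp <- stats::setNames(skewed(k), sample(pool, k))
    }
    community_spec(ids[i], types[i], comp,
                   contamination_rate = contamination_rate,
                   read_depth = read_depth)
  })
  names(specs) <- ids
  list(manifest = manifest, specs = specs)
}

#' Run the full pipeline
#'
#' Simulates (or loads) the inputs, demultiplexes, clusters, assigns
#' taxonomy and writes every stage output plus a reproducibility manifest to
#' `out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config a [run_config()] (or a path to a key=value config file).
#' @param out_dir output directory (created if needed).
#' @param simulate generate inputs with the synthetic module. With
#'   `simulate = FALSE`, supply `fastq`, `manifest_path`, `fasta_path` and
#'   `taxonomy_path`.
#' @param error_rate per-base substitution rate for simulated reads.
#' @param design optional list from [default_study_design()].
#' @param library optional `reference_library` (otherwise generated).
#' @param fastq,manifest_path,fasta_path,taxonomy_path input paths when
#'   `simulate = FALSE`.
#' @param dry_run print the stage plan and return without computing.
#' @return (invisibly) the run manifest: a list with the config snapshot,
#'   per-stage seeds, per-stage record counts and md5 digests of outputs.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         simulate = TRUE, error_rate = 0.005,
                         design = NULL, library = NULL,
                         fastq = NULL, manifest_path = NULL,
                         fasta_path = NULL, taxonomy_path = NULL,
                         dry_run = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- c("simulate/load", "demultiplex", "cluster", "assign", "summarise")
  if (dry_run) {
    cat("planned stages:", paste(stages, collapse = " -> "), "\n")
    cat("output directory:", out_dir, "(no files written in dry run)\n")
    return(invisible(NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- config$seed + SEED_OFFSETS
  counts <- list()
  stage_fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  ## stage 1: inputs
  tryCatch({
    if (simulate) {
      if (is.null(library)) {
        library <- generate_reference_library(3L, 3L, divergence_plan(),
                                              seed = seeds[["library"]])
      }
      if (is.null(design)) {
        design <- default_study_design(library, seed = seeds[["design"]])
      }
      manifest <- design$manifest
      reads <- do.call(rbind, lapply(seq_along(design$specs), function(i) {
        spec <- design$specs[[i]]
        simulate_reads(spec, library, error_rate = error_rate,
                       tag = manifest$tag[manifest$sample_id == spec$sample_id],
                       seed = seeds[["reads"]] + i, config = config)
      }))
      write_reference(library, file.path(out_dir, "reference.fasta"),
                      file.path(out_dir, "taxonomy.tsv"))
      write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
      write_fastq(reads, file.path(out_dir, "reads.fastq"))
      write_tsv(reads[, c("read_id", "sample_id", "source")],
                file.path(out_dir, "ground_truth.tsv"))
    } else {
      if (is.null(fastq) || is.null(manifest_path) ||
          is.null(fasta_path) || is.null(taxonomy_path)) {
        stop(errorCondition(
          "simulate = FALSE requires fastq, manifest_path, fasta_path, taxonomy_path",
          class = c("dietbarcoder_config_error", "error")))
      }
      library <- read_reference(fasta_path, taxonomy_path)
      manifest <- read_manifest(manifest_path)
      reads <- read_fastq(fastq)
    }
    counts$input_reads <- nrow(reads)
  }, error = function(e) stage_fail("simulate/load", e))

  ## stage 2: demultiplex
  demux <- tryCatch(demultiplex(reads, manifest, config),
                    error = function(e) stage_fail("demultiplex", e))
  counts$demux <- as.list(demux$stats)
  write_tsv(data.frame(outcome = names(demux$stats), count = demux$stats,
                       row.names = NULL),
            file.path(out_dir, "demux_stats.tsv"))
  for (s in names(demux$per_sample)) {
    if (nrow(demux$per_sample[[s]])) {
      write_fastq(demux$per_sample[[s]],
                  file.path(out_dir, sprintf("sample_%s.fastq", s)))
    }
  }

  ## stage 3: cluster
  table_filtered <- tryCatch({
    assigned <- do.call(rbind, demux$per_sample)
    otus <- cluster_de_novo(assigned, config)
    otus <- pick_representatives(otus, seed = seeds[["reps"]])
    tab <- make_otu_table(otus, manifest$sample_id)
    counts$otus_raw <- nrow(tab$counts)
    write_otu_table(tab, file.path(out_dir, "otu_table_raw.tsv"))
    tf <- filter_low_abundance(tab, config)
    counts$otus_filtered <- nrow(tf$counts)
    counts$reads_in_filtered_otus <- sum(tf$counts)
    write_otu_table(tf, file.path(out_dir, "otu_table.tsv"))
    if (nrow(tf$counts)) {
      reps <- data.frame(read_id = paste(rownames(tf$counts),
                                         tf$representative_id, sep = " "),
                         sequence = unname(tf$representative),
                         stringsAsFactors = FALSE)
      x <- Biostrings::DNAStringSet(reps$sequence)
      names(x) <- reps$read_id
      Biostrings::writeXStringSet(x, file.path(out_dir, "representatives.fasta"))
    }
    tf
  }, error = function(e) stage_fail("cluster", e))

  ## stage 4: assign
  assignments <- tryCatch({
    if (nrow(table_filtered$counts)) {
      assign_all(table_filtered, library, config, manifest)
    } else {
      NULL
    }
  }, error = function(e) stage_fail("assign", e))
  counts$assignments <- if (is.null(assignments)) 0L else nrow(assignments)
  if (!is.null(assignments)) {
    write_assignments(assignments, file.path(out_dir, "assignments.tsv"))
  }

  ## stage 5: summaries (degenerate inputs reported gracefully)
  tryCatch({
    if (!is.null(assignments) && nrow(assignments)) {
      write_tsv(rank_identifiability(assignments),
                file.path(out_dir, "rank_identifiability.tsv"))
      rd <- rule_distribution(assignments)
      write_tsv(data.frame(rule = names(rd), count = rd, row.names = NULL),
                file.path(out_dir, "rule_distribution.tsv"))
      split_by_type <- function(type) {
        ids <- manifest$sample_id[manifest$sample_type == type]
        m <- table_filtered$counts[, colnames(table_filtered$counts) %in% ids,
                                   drop = FALSE]
        assignments[assignments$otu_id %in% rownames(m)[rowSums(m) > 0L], ,
                    drop = FALSE]
      }
      ov <- overlap_summary(split_by_type("bird_feces"), split_by_type("wild_frass"))
      write_tsv(data.frame(
        measure = c("consumed_species", "available_species", "shared",
                    "shared_fraction_of_consumed"),
        value = c(length(ov$consumed_species), length(ov$available_species),
                  length(ov$shared), ov$shared_fraction_of_consumed)),
        file.path(out_dir, "overlap_summary.tsv"))
    } else {
      writeLines("no OTUs survived filtering; no summaries computed",
                 file.path(out_dir, "rank_identifiability.tsv"))
    }
  }, error = function(e) stage_fail("summarise", e))

  outputs <- sort(list.files(out_dir, full.names = FALSE))
  digests <- tools::md5sum(file.path(out_dir, outputs))
  names(digests) <- outputs
  manifest_out <- list(
    tool = "dietbarcoder",
    version = as.character(utils::packageVersion("dietbarcoder")),
    stages = stages,
    config = unclass(config),
    seeds = as.list(seeds),
    counts = counts,
    outputs = as.list(digests)
  )
  jsonlite::write_json(manifest_out, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest_out)
}
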