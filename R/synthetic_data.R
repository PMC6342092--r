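## Synthetic-data module: reference libraries, mock communities, amplicon
## reads and feeding-trial tables, all with known ground truth.

ORDER_NAMES <- c("Lepidoptera", "Diptera", "Araneae", "Coleoptera",
                 "Hymenoptera", "Hemiptera")

#' Divergence plan for a synthetic reference library
#'
#' Target pairwise divergences (percent of sequence length) used by
#' [generate_reference_library()]: the minimum divergence between congeneric
#' species, the minimum divergence between genera of the same order, and the
#' maximum divergence of an intraspecific variant from its species base.
#' Congeneric divergence must exceed 2% so that clustering at 98% identity
#' can never merge two species, and must exceed the intraspecific maximum.
#'
#' @param congeneric minimum percent divergence between congeneric species.
#' @param genus minimum percent divergence between genera within an order.
#' @param intraspecific_max maximum percent divergence of a variant from its
#'   species base sequence.
#' @return a named list of class `divergence_plan`.
#' @export
divergence_plan <- function(congeneric = 4, genus = 10, intraspecific_max = 0.6) {
  plan <- list(congeneric = as.numeric(congeneric),
               genus = as.numeric(genus),
               intraspecific_max = as.numeric(intraspecific_max))
  if (!(plan$intraspecific_max < plan$congeneric && plan$congeneric <= plan$genus)) {
    stop("infeasible divergence plan: need intraspecific_max < congeneric <= genus")
  }
  structure(plan, class = "divergence_plan")
}

#' Generate a synthetic barcode reference library
#'
#' Builds a multi-order, Lepidoptera-style reference library of COI
#' mini-barcode inserts with controlled pairwise divergences. Each order gets
#' an independent random ancestor; genera mutate the order ancestor at a
#' dedicated block of positions, species mutate their genus ancestor at a
#' further dedicated block, and intraspecific variants differ from the
#' species base at positions outside every block. Because all blocks are
#' disjoint, realized pairwise differences are the sums of block sizes, so
#' the plan's minimum divergences are met by construction (block sizes are
#' the nearest substitution counts to the targets, within one position).
#'
#' A configurable fraction of species is flagged non-regional (not occurring
#' in the study area), a fraction of genera contributes a record with no
#' species name, and a fraction of species contributes a duplicate record
#' carrying the taxonomy of a different species and flagged `known_error`
#' (a "clear mistake" that the search step must skip). When
#' `include_control = TRUE` the laboratory control taxon (*Samia cynthia*,
#' Saturniidae) is appended to the first order with its own blocks.
#'
#' @param n_orders number of insect orders.
#' @param species_per_genus species per genus.
#' @param plan a [divergence_plan()].
#' @param seed integer seed; identical seeds give byte-identical libraries.
#' @param genera_per_order genera per order.
#' @param seq_length barcode insert length in bp (157 for the Zeale COI
#'   mini-barcode).
#' @param n_variants records per species (one base sequence plus
#'   `n_variants - 1` intraspecific variants).
#' @param fraction_nonregional fraction of species flagged `regional = FALSE`.
#' @param fraction_unnamed fraction of genera contributing a species-empty
#'   record.
#' @param fraction_error fraction of species contributing a mislabeled
#'   duplicate flagged `known_error = TRUE`.
#' @param include_control append the control genus/species.
#' @return a `data.frame` of class `reference_library` with columns
#'   `record_id`, `sequence`, `species`, `genus`, `family`, `order`,
#'   `regional`, `known_error`.
#' @examples
#' lib <- generate_reference_library(2, 3, divergence_plan(), seed = 1)
#' head(lib[, -2])
#' @export
generate_reference_library <- function(n_orders, species_per_genus,
                                       plan = divergence_plan(),
                                       seed = 1L,
                                       genera_per_order = 4L,
                                       seq_length = 157L,
                                       n_variants = 2L,
                                       fraction_nonregional = 0.1,
                                       fraction_unnamed = 0.1,
                                       fraction_error = 0.05,
                                       include_control = TRUE) {
  stopifnot(n_orders >= 1L, species_per_genus >= 1L, genera_per_order >= 1L,
            seq_length >= 157L, n_variants >= 1L)
  if (!inherits(plan, "divergence_plan")) plan <- do.call(divergence_plan, plan)
  L <- as.integer(seq_length)
  ds <- max(1L, round(plan$congeneric * L / 200))
  dg <- max(1L, round(plan$genus * L / 200))
  v_subs <- max(1L, floor(plan$intraspecific_max * L / 100))

  set.seed(seed)
  recs <- list()
  genus_counter <- 0L
  family_counter <- 0L

  emit_order <- function(order_name, n_genera, spp_per_genus, unnamed_genera) {
    ancestor <- random_dna(1L, L)
    pool <- sample.int(L)          # random disjoint position blocks
    need <- n_genera * dg + (n_genera * spp_per_genus + length(unnamed_genera)) * ds
    if (need + v_subs > L) {
      stop("infeasible divergence plan: sequence too short for the requested taxa")
    }
    # variants draw from a reserved tail so their mutations never touch a
    # genus- or species-distinguishing block
    v_res <- max(v_subs, min(8L, L - need))
    variant_pool <- pool[seq(length(pool) - v_res + 1L, length(pool))]
    pool <- pool[seq_len(length(pool) - v_res)]
    take <- function(k) {
      idx <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      idx
    }
    out <- list()
    for (g in seq_len(n_genera)) {
      genus_counter <<- genus_counter + 1L
      if (g %% 2L == 1L) family_counter <<- family_counter + 1L
      genus_name <- sprintf("Genus%02d", genus_counter)
      family_name <- sprintf("Family%02d", family_counter)
      genus_seq <- mutate_positions(ancestor, take(dg))
      for (s in seq_len(spp_per_genus)) {
        species_name <- sprintf("%s species%02d", genus_name, s)
        base <- mutate_positions(genus_seq, take(ds))
        seqs <- base
        for (v in seq_len(n_variants - 1L)) {
          seqs <- c(seqs, mutate_positions(base, sample(variant_pool, v_subs)))
        }
        for (sq in seqs) {
          out[[length(out) + 1L]] <- list(sequence = sq, species = species_name,
                                          genus = genus_name, family = family_name,
                                          order = order_name)
        }
      }
      if (g %in% unnamed_genera) {
        out[[length(out) + 1L]] <- list(
          sequence = mutate_positions(genus_seq, take(ds)),
          species = "", genus = genus_name, family = family_name,
          order = order_name)
      }
    }
    out
  }

  for (o in seq_len(n_orders)) {
    order_name <- if (o <= length(ORDER_NAMES)) ORDER_NAMES[o] else sprintf("Order%02d", o)
    n_unnamed <- round(fraction_unnamed * genera_per_order)
    unnamed <- if (n_unnamed > 0L) sample.int(genera_per_order, n_unnamed) else integer(0)
    recs <- c(recs, emit_order(order_name, genera_per_order, species_per_genus, unnamed))
  }
  if (include_control) {
    genus_counter <- genus_counter + 1L
    family_counter <- family_counter + 1L
    control <- emit_order(if (n_orders >= 1L) ORDER_NAMES[1] else "Lepidoptera",
                          1L, 1L, integer(0))
    for (i in seq_along(control)) {
      control[[i]]$genus <- "Samia"
      control[[i]]$family <- "Saturniidae"
      if (nzchar(control[[i]]$species)) control[[i]]$species <- "Samia cynthia"
    }
    recs <- c(recs, control)
  }

  lib <- data.frame(
    record_id = sprintf("SYN%04d", seq_along(recs)),
    sequence = vapply(recs, `[[`, character(1), "sequence"),
    species = vapply(recs, `[[`, character(1), "species"),
    genus = vapply(recs, `[[`, character(1), "genus"),
    family = vapply(recs, `[[`, character(1), "family"),
    order = vapply(recs, `[[`, character(1), "order"),
    regional = TRUE,
    known_error = FALSE,
    stringsAsFactors = FALSE
  )

  species_names <- setdiff(unique(lib$species), c("", "Samia cynthia"))
  n_nonreg <- round(fraction_nonregional * length(species_names))
  if (n_nonreg > 0L) {
    nonreg <- sample(species_names, n_nonreg)
    lib$regional[lib$species %in% nonreg] <- FALSE
  }
  n_err <- round(fraction_error * length(species_names))
  if (n_err > 0L) {
    err_spp <- sample(species_names, n_err)
    for (sp in err_spp) {
      src <- lib[lib$species == sp, ][1L, ]
      others <- setdiff(species_names, sp)
      wrong <- lib[lib$species == sample(others, 1L), ][1L, ]
      row <- src
      row$record_id <- sprintf("SYN%04d", nrow(lib) + 1L)
      row$species <- wrong$species
      row$genus <- wrong$genus
      row$family <- wrong$family
      row$order <- wrong$order
      row$known_error <- TRUE
      lib <- rbind(lib, row)
    }
  }
  rownames(lib) <- NULL
  validate_reference_library(lib)
  class(lib) <- c("reference_library", "data.frame")
  lib
}

validate_reference_library <- function(lib) {
  stopifnot(anyDuplicated(lib$record_id) == 0L)
  ok_alpha <- grepl("^[ACGT]+$", lib$sequence)
  if (!all(ok_alpha)) stop("reference sequences must be over {A,C,G,T}")
  named <- nzchar(lib$species)
  if (any(named & !nzchar(lib$genus))) {
    stop("records with a species name must carry a genus")
  }
  invisible(lib)
}

#' Specify a mock community for read simulation
#'
#' @param sample_id sample identifier.
#' @param sample_type one of `"bird_feces"`, `"wild_frass"`, `"lab_control"`.
#' @param composition named numeric vector of relative abundances (names are
#'   species as they appear in the reference library); must sum to 1.
#' @param contamination_rate fraction of reads drawn from off-library random
#'   sequence (flanked by the true primers, so they survive primer checks).
#' @param read_depth total number of reads to emit for the sample.
#' @return an object of class `community_spec`.
#' @export
community_spec <- function(sample_id, sample_type, composition,
                           contamination_rate = 0, read_depth = 1000L) {
  sample_type <- match.arg(sample_type, c("bird_feces", "wild_frass", "lab_control"))
  stopifnot(is.numeric(composition), length(composition) >= 1L,
            !is.null(names(composition)), all(nzchar(names(composition))),
            all(composition > 0), all(composition <= 1),
            contamination_rate >= 0, contamination_rate < 1, read_depth >= 1L)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("relative abundances must sum to 1")
  }
  structure(list(sample_id = as.character(sample_id), sample_type = sample_type,
                 composition = composition,
                 contamination_rate = as.numeric(contamination_rate),
                 read_depth = as.integer(read_depth)),
            class = "community_spec")
}

#' Simulate tagged amplicon reads for one sample
#'
#' Emulates the two-stage amplicon construct: each read is the 9-base sample
#' index tag, the forward primer, a 157-bp insert copied from a reference
#' record of the source species, and the reverse complement of the reverse
#' primer. Degenerate primer positions are resolved to concrete bases per
#' read. Substitution errors are applied i.i.d. per base over the whole read;
#' qualities follow a Phred profile starting at `quality_peak` with a linear
#' 3' decay. Contaminant reads carry an off-library random insert between the
#' true tag and primers. Exactly `spec$read_depth` reads are returned, each
#' with its ground-truth source species in the `source` column (this ledger
#' is internal; FASTQ output carries only id, sequence and quality).
#'
#' @param spec a [community_spec()].
#' @param library a `reference_library`.
#' @param error_rate per-base substitution probability.
#' @param tag the sample's 9-base index tag.
#' @param seed integer seed.
#' @param config a [run_config()] supplying the primer sequences.
#' @param insert_length insert length in bp.
#' @param quality_peak Phred score at the first cycle.
#' @param quality_decay total Phred decay from first to last cycle.
#' @return `data.frame` of class `simulated_reads` with columns `read_id`,
#'   `sequence`, `quality`, `sample_id`, `source`.
#' @export
simulate_reads <- function(spec, library, error_rate = 0.005, tag, seed = 1L,
                           config = run_config(), insert_length = 157L,
                           quality_peak = 30L, quality_decay = 8L) {
  stopifnot(inherits(spec, "community_spec"))
  if (nchar(tag) != 9L) stop("index tag must be exactly 9 bases")
  usable <- library[!library$known_error, , drop = FALSE]
  species <- names(spec$composition)
  missing <- setdiff(species, usable$species)
  if (length(missing)) {
    stop("species missing from reference library: ", paste(missing, collapse = ", "))
  }
  if (spec$sample_type == "lab_control") {
    genera <- unique(usable$genus[usable$species %in% species])
    if (length(genera) != 1L) {
      stop("lab_control composition must draw from a single genus")
    }
  }

  set.seed(seed)
  depth <- spec$read_depth
  n_contam <- rbinom(1L, depth, spec$contamination_rate)
  n_true <- depth - n_contam
  counts <- as.integer(rmultinom(1L, n_true, spec$composition))

  fwd_len <- nchar(config$primer_forward)
  rev_len <- nchar(config$primer_reverse)
  read_len <- 9L + fwd_len + insert_length + rev_len
  qual <- phred_to_string(round(quality_peak -
                                  quality_decay * (seq_len(read_len) - 1L) / (read_len - 1L)))

  ## per-read inserts and ground truth
  src <- c(rep(species, counts), rep("contaminant", n_contam))
  inserts <- character(depth)
  k <- 0L
  for (i in seq_along(species)) {
    if (counts[i] == 0L) next
    variants <- substr(usable$sequence[usable$species == species[i]],
                       1L, insert_length)
    inserts[k + seq_len(counts[i])] <- variants[sample.int(length(variants),
                                                           counts[i], replace = TRUE)]
    k <- k + counts[i]
  }
  if (n_contam > 0L) {
    inserts[k + seq_len(n_contam)] <- random_dna(n_contam, insert_length)
  }

  ## assemble reads as a character matrix: tag + fwd primer + insert +
  ## revcomp(rev primer), resolving degenerate primer positions per read
  mat <- matrix("", nrow = depth, ncol = read_len)
  mat[, 1:9] <- matrix(strsplit(tag, "")[[1]], depth, 9L, byrow = TRUE)
  fill_primer <- function(pattern, cols) {
    chars <- strsplit(pattern, "")[[1]]
    for (j in seq_along(chars)) {
      opts <- strsplit(IUPAC_CODE_MAP[[chars[j]]], "")[[1]]
      mat[, cols[j]] <<- if (length(opts) == 1L) opts else {
        opts[sample.int(length(opts), depth, replace = TRUE)]
      }
    }
  }
  fill_primer(config$primer_forward, 9L + seq_len(fwd_len))
  fill_primer(revcomp(config$primer_reverse),
              9L + fwd_len + insert_length + seq_len(rev_len))
  ins_chars <- matrix(unlist(strsplit(inserts, "")), nrow = depth, byrow = TRUE)
  mat[, 9L + fwd_len + seq_len(insert_length)] <- ins_chars

  if (error_rate > 0) {
    n_err <- rbinom(depth, read_len, error_rate)
    rows <- rep.int(which(n_err > 0L), n_err[n_err > 0L])
    cols <- unlist(lapply(n_err[n_err > 0L], function(k) sample.int(read_len, k)))
    if (length(rows)) {
      idx <- cbind(rows, cols)
      cur <- match(mat[idx], DNA_BASES)
      shift <- sample.int(3L, length(rows), replace = TRUE)
      mat[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
  }
  seqs <- apply(mat, 1L, paste, collapse = "")

  ord <- sample.int(depth)
  out <- data.frame(
    read_id = sprintf("%s_r%06d", spec$sample_id, seq_len(depth)),
    sequence = seqs[ord],
    quality = qual,
    sample_id = spec$sample_id,
    source = src[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("simulated_reads", "data.frame")
  out
}

#' Feeding-trial design
#'
#' The laboratory feeding-trial emulation: dried, ground frass of a single
#' lepidopteran reared in the lab, divided into dry-mass classes and scored
#' for the percentage of correct species identifications. The default mass
#' classes are the six used in the trial this package models; the default
#' intercept and slope are the published log-mass model coefficients.
#'
#' @param mass_classes dry masses in mg.
#' @param replicates_per_class replicates per mass class.
#' @param detect_intercept expected percent correct at 1 mg.
#' @param detect_slope change in percent correct per ln(mg).
#' @param noise_sd Gaussian noise SD on the percent scale.
#' @param seed integer seed.
#' @return an object of class `trial_design`.
#' @export
trial_design <- function(mass_classes = c(0.1, 0.3, 1.2, 4.2, 14.4, 50),
                         replicates_per_class = 2L,
                         detect_intercept = 45.075,
                         detect_slope = 13.433,
                         noise_sd = 15,
                         seed = 1L) {
  stopifnot(all(mass_classes > 0), replicates_per_class >= 1L, noise_sd >= 0)
  structure(list(mass_classes = as.numeric(mass_classes),
                 replicates_per_class = as.integer(replicates_per_class),
                 detect_intercept = as.numeric(detect_intercept),
                 detect_slope = as.numeric(detect_slope),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' Simulate a frass feeding trial
#'
#' Per replicate, the percentage of correct identifications is
#' `clamp(intercept + slope * ln(mass) + N(0, noise_sd), 0, 100)`.
#'
#' @param design a [trial_design()].
#' @return `data.frame` with columns `dry_mass_mg`, `percent_correct`.
#' @export
simulate_trial <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(design$seed)
  mass <- rep(design$mass_classes, each = design$replicates_per_class)
  pc <- design$detect_intercept + design$detect_slope * log(mass) +
    rnorm(length(mass), 0, design$noise_sd)
  data.frame(dry_mass_mg = mass, percent_correct = pmin(pmax(pc, 0), 100))
}

#' Simulate field frass-pellet samples
#'
#' Pellet counts per collection funnel are uniform over the field range
#' (15-320 pellets per sample) and individual pellet dry mass is lognormal
#' around 0.25 mg, so that ~20 average-sized pellets weigh ~5 mg while the
#' size spread lets that number range over roughly 2-100.
#'
#' @param n_samples number of funnel samples.
#' @param seed integer seed.
#' @param meanlog,sdlog lognormal parameters for pellet dry mass in mg.
#' @return `data.frame` with columns `pellet_count`, `dry_mass_mg`.
#' @export
simulate_pellet_samples <- function(n_samples = 30L, seed = 1L,
                                    meanlog = log(0.25), sdlog = 0.6) {
  set.seed(seed)
  counts <- round(runif(n_samples, 15, 320))
  size <- exp(rnorm(n_samples, meanlog, sdlog))
  data.frame(pellet_count = counts, dry_mass_mg = counts * size)
}
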