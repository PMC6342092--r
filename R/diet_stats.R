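## Result-layer statistics: rank-level identifiability, consumed-versus-
## available overlap, sequence-variant vs prevalence correlation, the
## log-mass detection model for the feeding trial, the mass t-test and the
## pellet-count to dry-mass conversion.

RANKS <- c("order", "family", "genus", "species")

#' Rank-level identifiability of an assignment set
#'
#' Cumulative counts of OTUs resolved at or below each rank (a species call
#' counts toward genus, family and order as well), with fractions of the
#' total OTU count. `unidentified` and `contamination` calls count toward no
#' rank, so the fractions are monotone non-increasing from order to species.
#'
#' @param assignments output of [assign_all()] (non-empty).
#' @return `data.frame` with columns `rank`, `count`, `fraction`.
#' @export
rank_identifiability <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L) {
    stop("no assignments to summarise")
  }
  depth <- match(assignments$rank, RANKS)   # NA for unidentified/contamination
  total <- nrow(assignments)
  count <- vapply(seq_along(RANKS), function(k) sum(!is.na(depth) & depth >= k),
                  integer(1))
  data.frame(rank = RANKS, count = count, fraction = count / total)
}

#' Overlap between consumed and available prey
#'
#' Species-level calls from the predator-feces assignments (consumed) are
#' intersected with those from the frass assignments (available in the
#' habitat). Per-order breakdowns give, for each data set, the proportion of
#' species, of OTUs ("sequences"), and -- when the OTU tables are supplied --
#' of samples in which the order occurs.
#'
#' @param bird_assignments,frass_assignments outputs of [assign_all()].
#' @param bird_table,frass_table the corresponding `otu_table`s (optional;
#'   needed only for the per-sample order proportions).
#' @return object of class `overlap_summary`: list with `consumed_species`,
#'   `available_species`, `shared`, `shared_fraction_of_consumed`, and
#'   `per_order` (a `data.frame`).
#' @export
overlap_summary <- function(bird_assignments, frass_assignments,
                            bird_table = NULL, frass_table = NULL) {
  consumed <- sort(unique(bird_assignments$species[bird_assignments$rank == "species"]))
  available <- sort(unique(frass_assignments$species[frass_assignments$rank == "species"]))
  shared <- intersect(consumed, available)
  frac <- if (length(consumed)) length(shared) / length(consumed) else NA_real_

  per_order_one <- function(assignments, table, dataset) {
    a <- assignments[nzchar(assignments$order), , drop = FALSE]
    orders <- sort(unique(a$order))
    if (!length(orders)) return(NULL)
    n_species_total <- length(unique(a$species[a$rank == "species"]))
    rows <- lapply(orders, function(o) {
      in_o <- a$order == o
      prop_sp <- if (n_species_total) {
        length(unique(a$species[in_o & a$rank == "species"])) / n_species_total
      } else NA_real_
      prop_samples <- NA_real_
      if (!is.null(table)) {
        otus <- a$otu_id[in_o]
        m <- table$counts[rownames(table$counts) %in% otus, , drop = FALSE]
        prop_samples <- mean(colSums(m) > 0)
      }
      data.frame(dataset = dataset, order = o,
                 prop_species = prop_sp,
                 prop_otus = sum(in_o) / nrow(assignments),
                 prop_samples = prop_samples,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  per_order <- rbind(per_order_one(bird_assignments, bird_table, "bird_feces"),
                     per_order_one(frass_assignments, frass_table, "wild_frass"))

  structure(list(consumed_species = consumed, available_species = available,
                 shared = shared, shared_fraction_of_consumed = frac,
                 per_order = per_order),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("consumed species: %d; available species: %d; shared: %d (%.0f%% of consumed)\n",
              length(x$consumed_species), length(x$available_species),
              length(x$shared),
              100 * x$shared_fraction_of_consumed))
  if (!is.null(x$per_order)) print(x$per_order)
  invisible(x)
}

#' Correlation between sequence-variant richness and prevalence
#'
#' For each species with a species-level call, `x` is the number of distinct
#' OTUs assigned to it (dataset-wide by default; with `per_sample = TRUE`,
#' the mean number per sample in which it occurs) and `y` is the fraction of
#' samples in which it occurs. Returns the Pearson correlation with
#' `df = n_species - 2` and the two-sided p-value from the t transform.
#'
#' @param assignments output of [assign_all()].
#' @param otu_table the matching `otu_table`.
#' @param per_sample use the per-sample mean OTU count as `x`.
#' @return object of class `correlation_result`: list with `r`, `df`, `p`,
#'   `n`, and the per-species `points` data.frame.
#' @export
variant_prevalence_correlation <- function(assignments, otu_table,
                                           per_sample = FALSE) {
  sp_calls <- assignments[assignments$rank == "species", , drop = FALSE]
  species <- unique(sp_calls$species)
  if (length(species) < 3L) stop("need at least 3 species-level points")
  n_samples <- ncol(otu_table$counts)
  pts <- lapply(species, function(sp) {
    otus <- sp_calls$otu_id[sp_calls$species == sp]
    m <- otu_table$counts[rownames(otu_table$counts) %in% otus, , drop = FALSE]
    present <- colSums(m) > 0
    x <- if (per_sample) {
      mean(colSums(m[, present, drop = FALSE] > 0))
    } else {
      length(otus)
    }
    data.frame(species = sp, n_variants = x, prevalence = mean(present),
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  pearson_correlation(pts$n_variants, pts$prevalence, points = pts)
}

## Pearson r with df = n - 2 and two-sided p (thin wrapper over cor.test)
pearson_correlation <- function(x, y, points = NULL) {
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), df = unname(ct$parameter),
                 p = ct$p.value, n = length(x), points = points),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, df = %d, p = %.3g (n = %d species)\n",
              x$r, x$df, x$p, x$n))
  invisible(x)
}

#' Detection-model fit for the feeding trial
#'
#' `fit_detection_model()` regresses the percentage of correct
#' identifications on the natural log of frass dry mass (mg) by ordinary
#' least squares. `detection_model_fit()` instantiates the same object
#' directly from known coefficients (e.g. a published fit) so predictions
#' can be made without the underlying data.
#'
#' @param trial_table `data.frame` with columns `dry_mass_mg`,
#'   `percent_correct`, covering at least 3 distinct masses.
#' @return object of class `detection_model_fit` with fields `intercept`,
#'   `slope` (percent per ln-mg), `intercept_se`, `slope_se`, `t_intercept`,
#'   `t_slope`, `adj_r2`, `n`.
#' @export
fit_detection_model <- function(trial_table) {
  stopifnot(all(c("dry_mass_mg", "percent_correct") %in% names(trial_table)))
  if (length(unique(trial_table$dry_mass_mg)) < 3L) {
    stop("need at least 3 distinct dry masses to fit the detection model")
  }
  if (any(trial_table$dry_mass_mg <= 0)) stop("dry masses must be positive")
  fit <- lm(percent_correct ~ log(dry_mass_mg), data = trial_table)
  s <- summary(fit)
  co <- s$coefficients
  detection_model_fit(intercept = co[1L, 1L], slope = co[2L, 1L],
                      intercept_se = co[1L, 2L], slope_se = co[2L, 2L],
                      adj_r2 = s$adj.r.squared, n = nrow(trial_table))
}

#' @rdname fit_detection_model
#' @param intercept,slope coefficient estimates (percent; percent per ln-mg).
#' @param intercept_se,slope_se standard errors.
#' @param adj_r2 adjusted R-squared.
#' @param n number of observations behind the fit.
#' @export
detection_model_fit <- function(intercept, slope,
                                intercept_se = NA_real_, slope_se = NA_real_,
                                adj_r2 = NA_real_, n = NA_integer_) {
  structure(list(intercept = as.numeric(intercept), slope = as.numeric(slope),
                 intercept_se = as.numeric(intercept_se),
                 slope_se = as.numeric(slope_se),
                 t_intercept = as.numeric(intercept) / as.numeric(intercept_se),
                 t_slope = as.numeric(slope) / as.numeric(slope_se),
                 adj_r2 = as.numeric(adj_r2), n = n),
            class = "detection_model_fit")
}

#' @export
print.detection_model_fit <- function(x, ...) {
  cat("detection model: percent_correct ~ ln(dry mass, mg)\n")
  cat(sprintf("  (Intercept)        %8.3f  SE %7.3f  t %6.3f\n",
              x$intercept, x$intercept_se, x$t_intercept))
  cat(sprintf("  log(sample dry mass) %6.3f  SE %7.3f  t %6.3f\n",
              x$slope, x$slope_se, x$t_slope))
  if (is.finite(x$adj_r2)) cat(sprintf("  adjusted R-squared: %.4f\n", x$adj_r2))
  invisible(x)
}

#' Predict identification success; invert for a threshold mass
#'
#' `predict_success()` evaluates `intercept + slope * ln(mass)`, clamped to
#' \[0, 100\] for reporting. `threshold_mass()` inverts the (unclamped)
#' linear form: the dry mass at which the model predicts `target_percent`.
#'
#' @param fit a `detection_model_fit`.
#' @param dry_mass_mg positive dry mass(es) in mg.
#' @return predicted percent correct (vectorised over mass).
#' @export
predict_success <- function(fit, dry_mass_mg) {
  stopifnot(inherits(fit, "detection_model_fit"), all(dry_mass_mg > 0))
  pmin(pmax(fit$intercept + fit$slope * log(dry_mass_mg), 0), 100)
}

#' @rdname predict_success
#' @param target_percent target percentage of correct identifications.
#' @export
threshold_mass <- function(fit, target_percent) {
  stopifnot(inherits(fit, "detection_model_fit"))
  if (fit$slope <= 0) stop("threshold mass undefined for non-positive slope")
  exp((target_percent - fit$intercept) / fit$slope)
}

#' Two-sample t-test on sample masses
#'
#' Compares the dry masses of samples with successful and failed
#' identification. Pooled-variance by default (`df = n1 + n2 - 2`, matching
#' the integral degrees of freedom convention of the analysis this package
#' models); `welch = TRUE` switches to the Welch form.
#'
#' @param masses_success,masses_failure numeric vectors (each of length >= 2).
#' @param welch use the Welch (unequal-variance) test.
#' @return list with `t`, `df`, `p`.
#' @export
mass_success_ttest <- function(masses_success, masses_failure, welch = FALSE) {
  if (length(masses_success) < 2L || length(masses_failure) < 2L) {
    stop("each group needs at least 2 observations")
  }
  tt <- t.test(masses_success, masses_failure, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Pellet-count to dry-mass conversion
#'
#' Least-squares line through the origin (`mass = beta * count`; zero
#' pellets imply zero mass). `pellets_needed()` returns the pellet count
#' whose predicted mass reaches a target, rounded up.
#'
#' @param pellet_counts,dry_masses paired observations (>= 3 pairs, counts
#'   positive).
#' @return `pellets_to_mass()`: list of class `pellet_model` with `beta`
#'   (mg per pellet) and `n`; `pellets_needed()`: an integer count.
#' @export
pellets_to_mass <- function(pellet_counts, dry_masses) {
  stopifnot(length(pellet_counts) == length(dry_masses))
  if (length(pellet_counts) < 3L) stop("need at least 3 paired observations")
  if (any(pellet_counts <= 0)) stop("pellet counts must be positive")
  if (all(dry_masses == 0)) stop("all dry masses are zero")
  fit <- lm(dry_masses ~ 0 + pellet_counts)
  structure(list(beta = unname(coef(fit)[1L]), n = length(pellet_counts)),
            class = "pellet_model")
}

#' @rdname pellets_to_mass
#' @param model a `pellet_model`.
#' @param target_mg target dry mass in mg.
#' @export
pellets_needed <- function(model, target_mg) {
  stopifnot(inherits(model, "pellet_model"), model$beta > 0)
  as.integer(ceiling(target_mg / model$beta))
}
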