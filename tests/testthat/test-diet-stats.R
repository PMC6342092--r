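# Result-layer statistics: identifiability bookkeeping, overlap sets, the
# variant-prevalence correlation, the log-mass detection model, the mass
# t-test and the pellet-mass conversion.

fake_assignments <- function(ranks, species = NULL) {
  n <- length(ranks)
  if (is.null(species)) {
    species <- ifelse(ranks == "species", sprintf("Sp %02d", seq_len(n)), "")
  }
  data.frame(otu_id = sprintf("OTU%04d", seq_len(n)), rank = ranks,
             taxon = rep("", n), best_identity = rep(99, n),
             rule_fired = rep("R1", n), supporting_record = rep("", n),
             species = species, genus = rep("", n), family = rep("", n),
             order = rep("Lepidoptera", n), stringsAsFactors = FALSE)
}

test_that("rank identifiability accumulates correctly and is monotone", {
  a <- fake_assignments(c(rep("species", 6), rep("genus", 2), "family",
                          "unidentified"))
  out <- rank_identifiability(a)
  expect_equal(out$fraction[out$rank == "species"], 0.6)
  expect_equal(out$fraction[out$rank == "genus"], 0.8)
  expect_equal(out$fraction[out$rank == "family"], 0.9)
  expect_equal(out$fraction[out$rank == "order"], 0.9)
  expect_true(all(diff(out$fraction) <= 0))   # order -> species non-increasing
  all_sp <- rank_identifiability(fake_assignments(rep("species", 5)))
  expect_equal(all_sp$fraction, rep(1, 4))
  expect_error(rank_identifiability(fake_assignments(character(0))), "no assignments")
})

test_that("overlap summaries are plain set arithmetic", {
  bird <- fake_assignments(rep("species", 4), species = c("A", "B", "C", "D"))
  frass <- fake_assignments(rep("species", 3), species = c("B", "D", "E"))
  ov <- overlap_summary(bird, frass)
  expect_setequal(ov$shared, c("B", "D"))
  expect_equal(ov$shared_fraction_of_consumed, 0.5)
  disjoint <- overlap_summary(bird, fake_assignments("species", species = "Z"))
  expect_length(disjoint$shared, 0L)
  expect_equal(disjoint$shared_fraction_of_consumed, 0)
})

test_that("an end-to-end run recovers the planted consumed/available overlap", {
  lib <- generate_reference_library(2, 3, divergence_plan(), seed = 31,
                                    include_control = FALSE,
                                    fraction_nonregional = 0,
                                    fraction_unnamed = 0, fraction_error = 0)
  spp <- unique(lib$species)
  bird_spp <- spp[1:5]
  frass_spp <- c(spp[3:5], spp[6:7])   # 3 planted shared species
  cfg <- run_config()
  m <- as_sample_manifest(data.frame(
    sample_id = c("b1", "f1"), tag = c("AAACCCGGG", "TTTGGGAAA"),
    sample_type = c("bird_feces", "wild_frass")))
  reads <- rbind(
    simulate_reads(community_spec("b1", "bird_feces",
                                  setNames(rep(0.2, 5), bird_spp), 0, 600L),
                   lib, 0, tag = m$tag[1], seed = 41, config = cfg),
    simulate_reads(community_spec("f1", "wild_frass",
                                  setNames(rep(0.2, 5), frass_spp), 0, 600L),
                   lib, 0, tag = m$tag[2], seed = 42, config = cfg))
  dx <- demultiplex(reads, m, cfg)
  otus <- pick_representatives(cluster_de_novo(do.call(rbind, dx$per_sample), cfg),
                               seed = 43)
  tab <- filter_low_abundance(make_otu_table(otus, m$sample_id), cfg)
  asg <- assign_all(tab, lib, cfg, m)
  in_sample <- function(s) asg[asg$otu_id %in%
                                 rownames(tab$counts)[tab$counts[, s] > 0], ]
  ov <- overlap_summary(in_sample("b1"), in_sample("f1"))
  expect_length(ov$shared, 3L)
  expect_setequal(ov$consumed_species, bird_spp)
})

test_that("the variant-prevalence correlation follows the Pearson formula", {
  # exact line -> r = 1
  line <- list(x = c(1, 2, 3, 4), prev = c(0.1, 0.2, 0.3, 0.4))
  counts <- matrix(0L, 10, 10,
                   dimnames = list(sprintf("OTU%04d", 1:10), sprintf("s%d", 1:10)))
  asg <- NULL
  k <- 0
  for (i in seq_along(line$x)) {
    for (v in seq_len(line$x[i])) {
      k <- k + 1
      counts[k, seq_len(10 * line$prev[i])] <- 1L
    }
    asg <- rbind(asg, fake_assignments(rep("species", line$x[i]),
                                       species = rep(sprintf("Sp%d", i), line$x[i])))
  }
  asg$otu_id <- sprintf("OTU%04d", seq_len(nrow(asg)))
  tab <- structure(list(counts = counts[seq_len(nrow(asg)), , drop = FALSE]),
                   class = "otu_table")
  res <- variant_prevalence_correlation(asg, tab)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$df, 2L)   # 4 species - 2
  # hand-computed closed form on the extracted points
  pts <- res$points
  r_hand <- sum((pts$n_variants - mean(pts$n_variants)) *
                  (pts$prevalence - mean(pts$prevalence))) /
    sqrt(sum((pts$n_variants - mean(pts$n_variants))^2) *
           sum((pts$prevalence - mean(pts$prevalence))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_error(variant_prevalence_correlation(asg[1, ], tab), "at least 3")
})

test_that("correlation degrees of freedom follow the n - 2 convention", {
  for (n in c(17, 41)) {
    set.seed(n)
    v <- ((seq_len(n) - 1L) %% 3L) + 1L          # 1-3 OTUs per species
    species <- rep(sprintf("Sp %02d", seq_len(n)), times = v)
    n_otu <- length(species)
    counts <- matrix(0L, n_otu, 20,
                     dimnames = list(sprintf("OTU%04d", seq_len(n_otu)),
                                     sprintf("s%d", 1:20)))
    for (i in seq_len(n_otu)) counts[i, sample(20, sample(1:10, 1))] <- 1L
    asg <- fake_assignments(rep("species", n_otu), species = species)
    tab <- structure(list(counts = counts), class = "otu_table")
    res <- variant_prevalence_correlation(asg, tab)
    expect_equal(res$df, n - 2L)   # df = 15 for 17 species, 39 for 41
    expect_gte(res$p, 0); expect_lte(res$p, 1)
  }
})

test_that("the detection model recovers noise-free coefficients exactly", {
  d <- trial_design(replicates_per_class = 3, noise_sd = 0, seed = 1)
  fit <- suppressWarnings(fit_detection_model(simulate_trial(d)))  # exact fit
  expect_equal(fit$intercept, 45.075, tolerance = 1e-9)
  expect_equal(fit$slope, 13.433, tolerance = 1e-9)
  expect_equal(fit$t_intercept, fit$intercept / fit$intercept_se)
  expect_error(fit_detection_model(data.frame(dry_mass_mg = rep(5, 4),
                                              percent_correct = 1:4)),
               "distinct")
})

test_that("no-signal data gives non-positive adjusted R-squared", {
  masses <- rep(c(1, 3, 9, 27), each = 2)
  pc <- rep(c(52, 48), times = 4)      # class means equal: fitted slope 0
  fit <- fit_detection_model(data.frame(dry_mass_mg = masses, percent_correct = pc))
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_lte(fit$adj_r2, 0)
})

test_that("stochastic trials recover the generating model within 2 SEs", {
  # central mass classes: the linear mean stays inside the percentage scale,
  # so the clamp in the generator binds only in the far tails. A single
  # 2-SE check is a ~95%-coverage event, so recovery is asserted as
  # coverage over independent trials.
  fits <- lapply(1:20, function(s) {
    d <- trial_design(mass_classes = c(0.3, 1.2, 4.2, 14.4),
                      replicates_per_class = 50, noise_sd = 15, seed = s)
    fit_detection_model(simulate_trial(d))
  })
  ok <- vapply(fits, function(f) {
    abs(f$intercept - 45.075) < 2 * f$intercept_se &&
      abs(f$slope - 13.433) < 2 * f$slope_se
  }, logical(1))
  expect_gte(sum(ok), 16L)
  expect_true(all(vapply(fits, function(f) f$adj_r2 > 0, logical(1))))
})

test_that("prediction and threshold mass invert each other", {
  fit <- detection_model_fit(intercept = 45.075, slope = 13.433)
  expect_equal(predict_success(fit, 1), 45.075)
  m <- 2.5
  expect_equal(predict_success(fit, exp(1) * m) - predict_success(fit, m),
               13.433, tolerance = 1e-12)
  expect_equal(threshold_mass(fit, predict_success(fit, 5)), 5, tolerance = 1e-9)
  expect_equal(predict_success(fit, 1e9), 100)   # clamped for reporting
  flat <- detection_model_fit(intercept = 50, slope = 0)
  expect_error(threshold_mass(flat, 60), "slope")
})

test_that("the mass t-test uses the pooled form with df = n1 + n2 - 2", {
  g <- c(1.2, 3.4, 2.2, 5.1)
  same <- mass_success_ttest(g, g)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  a <- c(2.1, 4.4, 3.3, 1.8)
  b <- c(5.0, 2.2, 6.1, 3.3, 4.4, 2.9)
  out <- mass_success_ttest(a, b)
  expect_equal(out$df, 8)    # 4 + 6 - 2
  # closed-form pooled-variance oracle
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-10)
  expect_error(mass_success_ttest(1, b), "at least 2")
})

test_that("pellet-mass conversion goes through the origin", {
  reg <- pellets_to_mass(c(10, 20, 40), c(2.5, 5.0, 10.0))
  expect_equal(reg$beta, 0.25, tolerance = 1e-12)
  expect_equal(pellets_needed(reg, 5), 20L)
  rep3 <- pellets_to_mass(rep(8, 3), rep(2, 3))
  expect_equal(rep3$beta, 0.25, tolerance = 1e-12)
  field <- simulate_pellet_samples(30, seed = 3)
  n <- pellets_needed(pellets_to_mass(field$pellet_count, field$dry_mass_mg), 5)
  expect_gte(n, 2); expect_lte(n, 100)
  expect_error(pellets_to_mass(c(10, 20), c(1, 2)), "at least 3")
  expect_error(pellets_to_mass(c(10, 20, 30), c(0, 0, 0)), "zero")
})
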