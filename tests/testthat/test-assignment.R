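# The assignation engine: reference search with known-error exclusion, the
# frozen rule order over constructed hit lists, threshold boundaries, and
# totality/determinism.

test_that("reference search ranks by identity and skips known database errors", {
  base <- strrep("ACGTG", 30)   # 150 bp
  lib <- toy_library(
    seqs = c(base, sub_k(base, 2), sub_k(base, 9)),
    species = c("Aus aus", "Aus bus", "Cus cus"),
    genus = c("Aus", "Aus", "Cus"))
  hits <- search_reference(base, lib)
  expect_equal(hits$record_id[1], "TOY001")
  expect_equal(hits$identity[1], 100)
  # a 100% known-error record is ignored: the clean 99%-ish record ranks first
  lib2 <- toy_library(
    seqs = c(base, sub_k(base, 2)),
    species = c("Wrong label", "Aus bus"), genus = c("Wrong", "Aus"),
    known_error = c(TRUE, FALSE))
  hits2 <- search_reference(base, lib2)
  expect_equal(hits2$record_id[1], "TOY002")
  expect_false("TOY001" %in% hits2$record_id)
  expect_error(search_reference(base, lib2[lib2$known_error == FALSE & FALSE, ]),
               "empty")
})

test_that("search ranking agrees with a brute-force identity sort", {
  set.seed(17)
  base <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  seqs <- vapply(0:49, function(k) sub_k(base, k %% 20), character(1))
  lib <- toy_library(seqs, species = sprintf("Sp %02d", 1:50),
                     genus = sprintf("G%02d", 1:50))
  hits <- search_reference(base, lib, top_k = 50)
  oracle <- vapply(seqs, oracle_identity, numeric(1), b = base)
  expect_equal(hits$identity, unname(sort(oracle, decreasing = TRUE))[1:50])
  expect_true(all(diff(hits$identity) <= 0))
})

test_that("the rule decision table matches the frozen semantics", {
  cfg <- run_config()
  cases <- list(
    list(desc = "R1: regional best at 100%",
         hits = make_hits(list(identity = 100, species = "Aus aus", genus = "Aus")),
         rank = "species", taxon = "Aus aus", rule = "R1"),
    list(desc = "R1 at the 97% boundary",
         hits = make_hits(list(identity = 97, species = "Aus aus", genus = "Aus")),
         rank = "species", taxon = "Aus aus", rule = "R1"),
    list(desc = "R3: non-resident best, resident runner-up above 97%",
         hits = make_hits(
           list(id = "N", identity = 98.5, species = "Xus xus", genus = "Xus",
                regional = FALSE),
           list(id = "R", identity = 97.6, species = "Aus aus", genus = "Aus")),
         rank = "species", taxon = "Aus aus", rule = "R3"),
    list(desc = "R3 requires strictly more than 97% for the resident",
         hits = make_hits(
           list(id = "N", identity = 98.5, species = "Xus xus", genus = "Xus",
                regional = FALSE),
           list(id = "R", identity = 97.0, species = "Aus aus", genus = "Aus")),
         rank = "genus", taxon = "Xus", rule = "R2"),
    list(desc = "R4: congeneric tie falls to the genus",
         hits = make_hits(
           list(id = "A", identity = 99, species = "Aus aus", genus = "Aus"),
           list(id = "B", identity = 99, species = "Aus bus", genus = "Aus")),
         rank = "genus", taxon = "Aus", rule = "R4"),
    list(desc = "R4: cross-genus tie falls to the shared family",
         hits = make_hits(
           list(id = "A", identity = 99, species = "Aus aus", genus = "Aus",
                family = "FamA"),
           list(id = "B", identity = 99, species = "Bus bus", genus = "Bus",
                family = "FamA")),
         rank = "family", taxon = "FamA", rule = "R4"),
    list(desc = "A95: same-sample 100% anchor rescues a 95.5% hit to species",
         hits = make_hits(list(identity = 95.5, species = "Aus aus", genus = "Aus")),
         context = data.frame(rank = "species", species = "Aus aus",
                              genus = "Aus", best_identity = 100),
         rank = "species", taxon = "Aus aus", rule = "A95"),
    list(desc = "no A95 without an anchor: single-genus list goes to AMAJ",
         hits = make_hits(list(identity = 95.5, species = "Aus aus", genus = "Aus")),
         rank = "genus", taxon = "Aus", rule = "AMAJ"),
    list(desc = "R7: best record without species name gives its genus",
         hits = make_hits(list(identity = 98, species = "", genus = "Samia")),
         rank = "genus", taxon = "Samia", rule = "R7"),
    list(desc = "R2: species blocked by a non-resident best without rescue",
         hits = make_hits(list(identity = 98, species = "Xus xus", genus = "Xus",
                               regional = FALSE)),
         rank = "genus", taxon = "Xus", rule = "R2"),
    list(desc = "AGEN: genus-level rescue at 95% from a 100% same-genus anchor",
         hits = make_hits(list(identity = 95.5, species = "", genus = "Aus",
                               family = "FamA")),
         context = data.frame(rank = "species", species = "Aus zus",
                              genus = "Aus", best_identity = 100),
         rank = "genus", taxon = "Aus", rule = "AGEN"),
    list(desc = "AMAJ: strict majority of the hit list in one genus below 97%",
         hits = make_hits(
           list(id = "A", identity = 93, species = "Aus aus", genus = "Aus"),
           list(id = "B", identity = 92.5, species = "Aus bus", genus = "Aus"),
           list(id = "C", identity = 92.4, species = "Aus cus", genus = "Aus"),
           list(id = "D", identity = 92, species = "Dus dus", genus = "Dus")),
         rank = "genus", taxon = "Aus", rule = "AMAJ"),
    list(desc = "R5: no majority, hits within a point share a family",
         hits = make_hits(
           list(id = "A", identity = 93, species = "Aus aus", genus = "Aus",
                family = "FamA"),
           list(id = "B", identity = 92.5, species = "Bus bus", genus = "Bus",
                family = "FamA")),
         rank = "family", taxon = "FamA", rule = "R5"),
    list(desc = "R5: families differ, shared order remains",
         hits = make_hits(
           list(id = "A", identity = 93, species = "Aus aus", genus = "Aus",
                family = "FamA", order = "Lepidoptera"),
           list(id = "B", identity = 92.5, species = "Bus bus", genus = "Bus",
                family = "FamB", order = "Lepidoptera")),
         rank = "order", taxon = "Lepidoptera", rule = "R5"),
    list(desc = "R6: below 90% nothing is assignable",
         hits = make_hits(list(identity = 88, species = "Aus aus", genus = "Aus")),
         rank = "unidentified", rule = "R6"),
    list(desc = "R9: control sample resolving to the control genus",
         hits = make_hits(list(identity = 99, species = "Samia cynthia",
                               genus = "Samia")),
         sample_type = "lab_control",
         rank = "genus", taxon = "Samia sp.", rule = "R9"),
    list(desc = "R9: control sample resolving elsewhere is contamination",
         hits = make_hits(list(identity = 100, species = "Aus aus", genus = "Aus")),
         sample_type = "lab_control",
         rank = "contamination", rule = "R9")
  )
  expect_gte(length(cases), 12L)
  for (cs in cases) {
    got <- assign_taxon(cs$hits,
                        sample_context = cs$context,
                        sample_type = cs$sample_type %||% "bird_feces",
                        config = cfg)
    expect_equal(got$rank, cs$rank, label = cs$desc)
    expect_equal(got$rule_fired, cs$rule, label = cs$desc)
    if (!is.null(cs$taxon)) expect_equal(got$taxon, cs$taxon, label = cs$desc)
  }
})

test_that("rank thresholds sit exactly at the configured identities", {
  base <- random_seq(200)   # 200 bp: 0.5-point steps per substitution
  lib <- toy_library(base, species = "Aus aus", genus = "Aus")
  cfg <- run_config()
  sweep <- lapply(0:30, function(k) {
    hits <- search_reference(sub_k(base, k), lib)
    cbind(identity = 100 - k / 2, assign_taxon(hits, config = cfg))
  })
  sweep <- do.call(rbind, sweep)
  expect_equal(sweep$identity, sweep$best_identity)
  # species-rank calls begin exactly at species_identity
  expect_equal(min(sweep$identity[sweep$rank == "species"]), 97)
  expect_false(any(sweep$rank == "species" & sweep$identity < 97))
  # any-rank calls begin exactly at unidentified_below
  assigned <- sweep$rank %in% c("species", "genus", "family", "order")
  expect_equal(min(sweep$identity[assigned]), 90)
  expect_true(all(sweep$rank[sweep$identity < 90] == "unidentified"))
})

test_that("every hit list yields exactly one deterministic assignment", {
  base <- random_seq(200, seed = 77)
  lib <- toy_library(c(base, sub_k(base, 10)),
                     species = c("Aus aus", "Bus bus"), genus = c("Aus", "Bus"),
                     family = c("FamA", "FamB"))
  cfg <- run_config()
  for (k in seq(0, 40, by = 3)) {
    hits <- search_reference(sub_k(base, k), lib)
    a1 <- assign_taxon(hits, config = cfg)
    a2 <- assign_taxon(hits, config = cfg)
    expect_equal(nrow(a1), 1L)
    expect_identical(a1, a2)
  }
})
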