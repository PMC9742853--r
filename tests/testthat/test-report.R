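# End-to-end staged analysis on a generated fixture bundle.

make_bundle <- function(dir, n = 30, seed = 17) {
  sq <- random_sequence(n, seed = seed)
  s <- build_helix(sq)
  write_structure(s, file.path(dir, "model.pdb"), "pdb")
  jsonlite::write_json(list(list(id = "xtal", kind = "experimental",
                                 path = "model.pdb",
                                 coverage_range = c(1, n),
                                 resolution = 1.8)),
                       file.path(dir, "models.json"), auto_unbox = TRUE)
  ann <- synth_annotations(sq, seed = seed, features = 15, popvars = 15,
                           clinvars = 10, ptms = 10)
  write_annotation_set(ann, file.path(dir, "annotations.json"))
  list(sequence = sq, structure = s, ann = ann)
}

test_that("analyse emits a complete staged report on the fixture bundle", {
  dir <- tempfile(); dir.create(dir)
  b <- make_bundle(dir)
  sub <- paste0(substr(b$sequence, 5, 5), "5G")
  rep <- analyse(b$sequence, sub,
                 candidates = file.path(dir, "models.json"),
                 annotations = file.path(dir, "annotations.json"),
                 batch_max = 2, quiet = TRUE)
  expect_s3_class(rep, "analysis_report")
  expect_identical(rep$status, "complete")
  expect_false(is.null(rep$sequence_level))
  expect_identical(rep$selection$chosen$id, "xtal")
  expect_false(is.null(rep$neighbourhood))
  expect_false(is.null(rep$ddg))
  expect_false(is.null(rep$batch))
  # JSON serialisation is stable and parseable
  f1 <- file.path(dir, "r1.json"); f2 <- file.path(dir, "r2.json")
  write_report_json(rep, f1)
  rep2 <- analyse(b$sequence, sub,
                  candidates = file.path(dir, "models.json"),
                  annotations = file.path(dir, "annotations.json"),
                  batch_max = 2, quiet = TRUE)
  write_report_json(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
  parsed <- jsonlite::read_json(f1)
  expect_true(all(c("input", "selection", "neighbourhood", "ddg",
                    "batch") %in% names(parsed)))
  expect_true(is.numeric(parsed$ddg$protocol_ddg_kcal_mol))
  md <- report_markdown(rep)
  expect_true(any(grepl("^## Stability", md)))
})

test_that("reference mismatches are rejected before any stage runs", {
  sq <- random_sequence(20, seed = 23)
  pos5 <- substr(sq, 5, 5)
  wrong <- setdiff(c("A", "V", "L"), pos5)[1]
  expect_error(analyse(sq, paste0(wrong, "5G"), quiet = TRUE),
               paste0("expected ", wrong))
  expect_error(analyse(sq, "not-a-sub", quiet = TRUE), "malformed")
})

test_that("an empty manifest still yields sequence-level results", {
  sq <- random_sequence(20, seed = 29)
  rep <- analyse(sq, paste0(substr(sq, 8, 8), "8A"), candidates = list(),
                 quiet = TRUE)
  expect_true("NO_STRUCTURE" %in% rep$selection$warnings)
  expect_false(is.null(rep$sequence_level))
  expect_null(rep$ddg)
  expect_identical(rep$status, "complete")
})

test_that("a benchmark report from precomputed predictions is complete", {
  s <- build_helix(random_sequence(12, seed = 31))
  b <- synth_benchmark(s, n = 6, noise_sd = 0.5, seed = 9)
  rep <- benchmark_report(b)
  expect_s3_class(rep, "benchmark_report")
  expect_equal(rep$n, 6)
  expect_true(is.finite(rep$median_abs_error))
  # noise-free: exact recovery
  b0 <- synth_benchmark(s, n = 5, noise_sd = 0, seed = 9)
  expect_equal(median_abs_error(b0), 0)
})

test_that("engine-mode benchmarking equals the precomputed path", {
  s <- build_helix(random_sequence(14, seed = 37))
  b <- synth_benchmark(s, n = 4, noise_sd = 0.3, seed = 11)
  eng <- run_benchmark(s, data.frame(variant = b$variant,
                                     experimental_ddg = b$experimental_ddg,
                                     stringsAsFactors = FALSE))
  expect_equal(eng$predicted_ddg, b$predicted_ddg, tolerance = 1e-12)
  expect_equal(attr(eng, "n_skipped"), 0)
  # unscorable rows are skipped, not fatal
  eng2 <- run_benchmark(s, data.frame(variant = c(b$variant[1], "G99W"),
                                      experimental_ddg = c(1, 2),
                                      stringsAsFactors = FALSE))
  expect_equal(nrow(eng2), 1)
  expect_equal(attr(eng2, "n_skipped"), 1)
})

test_that("the cohort survey computes rows matching its construction", {
  sq <- random_sequence(20, seed = 41)
  s <- build_helix(sq)
  rt <- residue_table(s)
  mk <- function(i, alt) paste0(rt$aa[i], rt$seq_pos[i], alt)
  cohort <- data.frame(variant = c(mk(5, "G"), mk(8, "G"), "Z99W"),
                       significance = c("pathogenic", "benign",
                                        "pathogenic"),
                       stringsAsFactors = FALSE)
  rep <- run_survey(s, cohort)
  expect_s3_class(rep, "survey_report")
  expect_equal(nrow(rep$rows), 2)          # malformed row skipped
  expect_equal(attr(rep$rows, "n_skipped"), 1)
  # aggregates recompute from rows
  p <- rep$rows[rep$rows$significance == "pathogenic", ]
  expect_equal(rep$fractions$pathogenic$destabilising,
               mean(p$destabilising))
  # empty cohort: empty report, no error
  rep0 <- run_survey(s, cohort[0, , drop = FALSE])
  expect_equal(nrow(rep0$rows), 0)
  expect_true(is.na(rep0$fractions$pathogenic$destabilising))
})
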