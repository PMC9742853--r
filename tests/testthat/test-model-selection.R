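cand <- function(kind, cov = 1:100, ...) model_candidate(kind, cov, ...)

test_that("covers matches set membership", {
  c1 <- cand("experimental", 1:100, resolution = 2)
  expect_true(covers(c1, 50))
  expect_false(covers(c1, 101))
  set.seed(4)
  for (i in 1:20) {
    cov <- sort(sample.int(200, 50))
    cc <- cand("predicted", cov)
    p <- sample.int(200, 1)
    expect_identical(covers(cc, p), p %in% cov)
  }
})

test_that("experimental models are preferred, best resolution first", {
  r <- select_model(list(cand("predicted", plddt = setNames(rep(90, 100),
                                                            1:100),
                              id = "af"),
                         cand("experimental", resolution = 2.0,
                              id = "xtal")),
                    50)
  expect_identical(r$chosen$id, "xtal")
  r2 <- select_model(list(cand("experimental", resolution = 2.5,
                               id = "a"),
                          cand("experimental", resolution = 1.8,
                               id = "b")), 50)
  expect_identical(r2$chosen$id, "b")
})

test_that("low-identity homology models are excluded, never chosen", {
  r <- select_model(list(cand("homology", identity = 19, id = "swiss"),
                         cand("predicted",
                              plddt = setNames(rep(90, 100), 1:100),
                              id = "af")), 50)
  expect_identical(r$chosen$id, "af")
  expect_true("LOW_IDENTITY_EXCLUDED" %in% r$warnings)
  expect_true(any(grepl("LOW_IDENTITY_EXCLUDED", r$rationale)))
  # exclusion holds even when it is the only candidate
  r2 <- select_model(list(cand("homology", identity = 19)), 50)
  expect_null(r2$chosen)
  expect_true("NO_STRUCTURE" %in% r2$warnings)
})

test_that("partners rule prefers homology over single-chain predicted", {
  r <- select_model(list(cand("homology", identity = 97,
                              has_partners = TRUE, id = "swiss"),
                         cand("predicted",
                              plddt = setNames(rep(95, 100), 1:100),
                              id = "af")),
                    50, selection_settings(require_partners = TRUE))
  expect_identical(r$chosen$id, "swiss")
  # but never overrides the identity exclusion
  r2 <- select_model(list(cand("homology", identity = 15,
                               has_partners = TRUE, id = "swiss"),
                          cand("predicted",
                               plddt = setNames(rep(95, 100), 1:100),
                               id = "af")),
                     50, selection_settings(require_partners = TRUE))
  expect_identical(r2$chosen$id, "af")
})

test_that("quality flags follow the documented thresholds", {
  expect_identical(flag_quality(cand("homology", identity = 50,
                                     qmean = -2.5), 10), "LOW_QMEAN")
  expect_identical(flag_quality(cand("homology", identity = 50,
                                     qmean = -1.5), 10), character(0))
  expect_identical(flag_quality(cand("predicted",
                                     plddt = setNames(65, "10")), 10),
                   "LOW_PLDDT_AT_SITE")
  expect_identical(flag_quality(cand("predicted",
                                     plddt = setNames(c(65, 90),
                                                      c("9", "10"))), 10),
                   character(0))
  expect_identical(flag_quality(cand("experimental", resolution = 2), 10),
                   character(0))
})

test_that("empty candidate list gives NO_STRUCTURE, not an exception", {
  r <- select_model(list(), 5)
  expect_null(r$chosen)
  expect_true("NO_STRUCTURE" %in% r$warnings)
})

test_that("selection reproduces a hand-written decision table", {
  plddt_hi <- setNames(rep(90, 100), 1:100)
  plddt_lo <- setNames(rep(60, 100), 1:100)
  # scenario grid: each row the expected winner
  scenarios <- list(
    list(cands = list(cand("experimental", resolution = 3, id = "e"),
                      cand("homology", identity = 90, id = "h"),
                      cand("predicted", plddt = plddt_hi, id = "p")),
         want = "e", flags = character(0)),
    list(cands = list(cand("experimental", 60:70, resolution = 3,
                           id = "e"),
                      cand("homology", identity = 90, id = "h")),
         want = "h", flags = character(0)),   # experimental lacks coverage
    list(cands = list(cand("homology", identity = 25, qmean = -3,
                           id = "h"),
                      cand("predicted", plddt = plddt_hi, id = "p")),
         want = "h", flags = "LOW_QMEAN"),
    list(cands = list(cand("homology", identity = 10, id = "h"),
                      cand("predicted", plddt = plddt_lo, id = "p")),
         want = "p", flags = c("LOW_IDENTITY_EXCLUDED",
                               "LOW_PLDDT_AT_SITE")),
    list(cands = list(cand("homology", 60:70, identity = 90, id = "h")),
         want = NULL, flags = "NO_STRUCTURE"))
  for (sc in scenarios) {
    r <- select_model(sc$cands, 50)
    if (is.null(sc$want)) expect_null(r$chosen)
    else expect_identical(r$chosen$id, sc$want)
    expect_setequal(r$warnings, sc$flags)
  }
})

test_that("permuting candidates changes nothing except manifest ties", {
  plddt <- setNames(rep(90, 100), 1:100)
  cands <- list(cand("experimental", resolution = 2.2, id = "e1"),
                cand("homology", identity = 80, id = "h1"),
                cand("predicted", plddt = plddt, id = "p1"))
  base <- select_model(cands, 50)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    r <- select_model(cands[perm], 50)
    expect_identical(r$chosen$id, base$chosen$id)
  }
})

test_that("manifests round-trip through JSON including pLDDT", {
  dir <- tempfile(); dir.create(dir)
  h <- build_helix("ACDEFGH")
  h$atoms$b <- rep(88, nrow(h$atoms))
  write_structure(new_structure(h$atoms, "predicted"),
                  file.path(dir, "af.pdb"), "pdb")
  manifest <- list(
    list(id = "af", kind = "predicted", path = "af.pdb",
         coverage_range = c(1, 7), plddt_from_bfactor = TRUE),
    list(id = "xr", kind = "experimental", coverage_range = c(1, 5),
         resolution = 1.9))
  mf <- file.path(dir, "models.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE)
  cands <- read_model_manifest(mf)
  expect_length(cands, 2)
  expect_identical(cands[[1]]$kind, "predicted")
  expect_equal(unname(cands[[1]]$plddt[["3"]]), 88)
  r <- select_model(cands, 3)
  expect_identical(r$chosen$id, "xr")
  r2 <- select_model(cands, 7)     # beyond experimental coverage
  expect_identical(r2$chosen$id, "af")
})
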