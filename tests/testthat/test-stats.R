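rec <- function(pred, expv) data.frame(predicted_ddg = pred,
                                       experimental_ddg = expv)

test_that("Tukey fences use linear-interpolation quartiles", {
  expect_equal(unname(tukey_fences(1:9)), c(-3, 13))
  expect_equal(unname(tukey_fences(rep(2, 6))), c(2, 2))
  expect_error(tukey_fences(1:3), "at least 4")
  set.seed(6)
  for (i in 1:30) {
    x <- rnorm(sample(5:60, 1))
    f <- tukey_fences(x)
    q1 <- naive_quartile(x, 0.25); q3 <- naive_quartile(x, 0.75)
    expect_equal(unname(f), c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1)),
                 tolerance = 1e-12)
  }
})

test_that("median absolute error behaves as a median of |differences|", {
  x <- rnorm(20)
  expect_equal(median_abs_error(rec(x, x)), 0)
  expect_equal(median_abs_error(rec(x + 1, x)), 1)
  expect_error(median_abs_error(rec(numeric(0), numeric(0))), "no records")
  # half-normal median of N(0,1) errors ~ 0.674
  set.seed(99)
  e <- rnorm(10000)
  expect_equal(median_abs_error(rec(e, 0 * e)), 0.674, tolerance = 0.03)
})

test_that("outlier exclusion drops only out-of-fence errors", {
  set.seed(10)
  x <- rnorm(30)
  clean <- rec(x + rnorm(30, 0, 0.1), x)
  m0 <- outlier_excluded_metrics(clean)
  err <- abs(clean$predicted_ddg - clean$experimental_ddg)
  f <- tukey_fences(err)
  expect_equal(m0$n_excluded, sum(err < f[1] | err > f[2]))
  # one gross outlier is excluded; metrics match the manual exclusion
  dirty <- rbind(clean, rec(1e6, 0))
  m1 <- outlier_excluded_metrics(dirty)
  keep <- abs(dirty$predicted_ddg - dirty$experimental_ddg) <=
    tukey_fences(abs(dirty$predicted_ddg - dirty$experimental_ddg))[2]
  manual <- dirty[keep, ]
  expect_equal(m1$mean_abs_error,
               mean(abs(manual$predicted_ddg - manual$experimental_ddg)),
               tolerance = 1e-12)
  expect_false(1e6 %in% manual$predicted_ddg)
  # perfect linear relation keeps r = 1
  lin <- rec(2 * x, x)
  expect_equal(outlier_excluded_metrics(lin)$pearson_r, 1,
               tolerance = 1e-12)
})

test_that("confusion tables round predictions to one decimal first", {
  t1 <- confusion_at(rec(1.96, 2.3), 2)   # rounds to 2.0 -> >= 2
  expect_equal(t1$tp, 1)
  t2 <- confusion_at(rec(1.94, 2.3), 2)   # rounds to 1.9 -> < 2
  expect_equal(t2$fn, 1)
  # half-away-from-zero at one decimal
  expect_equal(varstab:::round_half_away(c(0.25, -0.25, 1.95, -1.95)),
               c(0.3, -0.3, 2.0, -2.0))
  # counting oracle on random vectors
  set.seed(3)
  for (i in 1:30) {
    n <- sample(5:80, 1)
    r <- rec(rnorm(n, 1, 2), rnorm(n, 1, 2))
    for (th in c(0, 2)) {
      ct <- confusion_at(r, th)
      p <- sign(r$predicted_ddg) *
        floor(abs(r$predicted_ddg) * 10 + 0.5) / 10 >= th
      e <- r$experimental_ddg >= th
      expect_equal(c(ct$tp, ct$fp, ct$tn, ct$fn),
                   c(sum(p & e), sum(p & !e), sum(!p & !e), sum(!p & e)))
    }
  }
})

test_that("phi equals the Pearson correlation of binary indicators", {
  perfect <- list(tp = 5, fp = 0, tn = 5, fn = 0)
  expect_equal(phi_coefficient(perfect), 1)
  indep <- list(tp = 5, fp = 5, tn = 5, fn = 5)
  expect_equal(phi_coefficient(indep), 0)
  degen <- phi_coefficient(list(tp = 0, fp = 0, tn = 7, fn = 0))
  expect_equal(as.numeric(degen), 0)
  expect_true(attr(degen, "degenerate"))
  set.seed(12)
  for (i in 1:200) {
    n <- sample(6:60, 1)
    p <- sample(c(TRUE, FALSE), n, replace = TRUE)
    e <- sample(c(TRUE, FALSE), n, replace = TRUE)
    t <- list(tp = sum(p & e), fp = sum(p & !e), tn = sum(!p & !e),
              fn = sum(!p & e))
    phi <- as.numeric(phi_coefficient(t))
    r <- suppressWarnings(stats::cor(as.numeric(p), as.numeric(e)))
    if (is.na(r)) expect_equal(phi, 0)
    else expect_equal(phi, r, tolerance = 1e-12)
  }
})

test_that("concordance counts agreements at the 2 kcal/mol threshold", {
  x <- c(0.5, 1.0, 2.5, 3.0)
  expect_equal(concordance_fraction(rec(x, x)), 1)
  expect_equal(concordance_fraction(rec(c(3, 3, 0, 0), c(0, 0, 3, 3))), 0)
  set.seed(21)
  r <- rec(rnorm(50, 1.5), rnorm(50, 1.5))
  ct <- confusion_at(r, 2)
  expect_equal(concordance_fraction(r), (ct$tp + ct$tn) / 50)
})

test_that("destabilising classification is strictly greater than 2", {
  expect_true(classify_destabilising(2.1))
  expect_false(classify_destabilising(2.0))
  expect_false(classify_destabilising(-1))
})

test_that("metrics are invariant under record permutation", {
  set.seed(5)
  r <- rec(rnorm(40, 1), rnorm(40, 1))
  perm <- r[sample(40), ]
  expect_equal(median_abs_error(r), median_abs_error(perm))
  expect_equal(outlier_excluded_metrics(r)$pearson_r,
               outlier_excluded_metrics(perm)$pearson_r)
  expect_equal(benchmark_report(r)$phi_2, benchmark_report(perm)$phi_2)
})

test_that("population rescue applies the frequency/homozygote filter", {
  s <- build_helix(random_sequence(20, seed = 19))
  base <- data.frame(seq_pos = 8L, ref_aa = "A", alt_aa = "V",
                     allele_frequency = 1e-3, homozygote_count = 0L,
                     ddg = 3.0, stringsAsFactors = FALSE)
  expect_false(population_rescue(s, "A", 10,
                                 base[0, , drop = FALSE]))
  expect_true(population_rescue(s, "A", 10, base))
  rare <- base; rare$allele_frequency <- 1e-5
  expect_false(population_rescue(s, "A", 10, rare))
  rare_hom <- rare; rare_hom$homozygote_count <- 1L
  expect_true(population_rescue(s, "A", 10, rare_hom))
  mild <- base; mild$ddg <- 1.0
  expect_false(population_rescue(s, "A", 10, mild))
  distant <- base; distant$seq_pos <- 20L   # beyond 10 A of residue 10
  expect_false(population_rescue(s, "A", 5, distant))
})

test_that("survey aggregates are recomputable from the rows", {
  # constructed cohort: exactly 20% of pathogenic rows destabilising
  rows <- data.frame(
    significance = c(rep("pathogenic", 10), rep("benign", 10)),
    ddg = c(rep(3, 2), rep(0.5, 8), rep(3, 1), rep(0, 9)),
    rescued = c(rep(FALSE, 10), rep(TRUE, 1), rep(FALSE, 9)),
    near_ligand = c(rep(TRUE, 4), rep(FALSE, 6),
                    rep(TRUE, 1), rep(FALSE, 9)),
    stringsAsFactors = FALSE)
  sv <- survey(rows)
  expect_equal(sv$fractions$pathogenic$destabilising, 0.20)
  expect_equal(sv$fractions$benign$destabilising, 0.10)
  expect_equal(sv$enrichments$near_ligand, 0.4 / 0.1)
  expect_true(is.na(sv$fractions$other$destabilising))
  # recomputation from rows
  p <- sv$rows[sv$rows$significance == "pathogenic", ]
  expect_equal(sv$fractions$pathogenic$destabilising,
               mean(p$destabilising))
  # all-benign cohort: pathogenic fractions absent, not zero
  sv2 <- survey(rows[rows$significance == "benign", ])
  expect_true(is.na(sv2$fractions$pathogenic$destabilising))
})

test_that("benchmark tables read with sign flips and skipped rows", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("id\tpredicted\texperimental",
               "v1\t1.5\t1.2", "v2\txx\t0.5", "v3\t-0.3\t-0.1"), f)
  tb <- read_benchmark_table(f)
  expect_equal(nrow(tb), 2)
  expect_equal(attr(tb, "n_skipped"), 1)
  tbf <- read_benchmark_table(f, flip_sign = TRUE)
  expect_equal(tbf$experimental_ddg, c(-1.2, 0.1))
})
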