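# Benchmarking metric suite and cohort survey logic: Tukey-fence outlier
# exclusion, median absolute error, one-decimal confusion tables, the phi
# coefficient, the strict >2 kcal/mol destabilising rule and the
# population-rescue filter.

#' Tukey fences
#'
#' `Q1 - k*IQR` and `Q3 + k*IQR` with quartiles by linear interpolation.
#'
#' @param values numeric vector (>= 4 values).
#' @param k scaling factor (default 1.5, the standard value).
#' @return numeric length 2: `c(lo, hi)`.
#' @export
tukey_fences <- function(values, k = 1.5) {
  if (length(values) < 4) stop("need at least 4 values for Tukey fences",
                               call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  c(lo = q[1] - k * iqr, hi = q[2] + k * iqr)
}

#' Median absolute error between predicted and experimental ddG
#' @param records data.frame with `predicted_ddg`, `experimental_ddg`.
#' @return kcal/mol.
#' @export
median_abs_error <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  stats::median(abs(records$predicted_ddg - records$experimental_ddg))
}

#' Outlier-excluded mean absolute error, RMSE and Pearson correlation
#'
#' Records whose absolute error falls outside the Tukey fences of the
#' error distribution are excluded before computing the metrics that a few
#' spuriously large values would otherwise dominate.
#'
#' @inheritParams median_abs_error
#' @param k Tukey scale (default 1.5).
#' @return list: `mean_abs_error`, `rmse`, `pearson_r`, `n_used`,
#'   `n_excluded`, `fences`.
#' @export
outlier_excluded_metrics <- function(records, k = 1.5) {
  err <- abs(records$predicted_ddg - records$experimental_ddg)
  fences <- tukey_fences(err, k)
  keep <- err >= fences[1] & err <= fences[2]
  r <- records[keep, , drop = FALSE]
  if (nrow(r) < 4) stop("fewer than 4 records remain after outlier ",
                        "exclusion", call. = FALSE)
  list(mean_abs_error = mean(abs(r$predicted_ddg - r$experimental_ddg)),
       rmse = sqrt(mean((r$predicted_ddg - r$experimental_ddg)^2)),
       pearson_r = stats::cor(r$predicted_ddg, r$experimental_ddg),
       n_used = nrow(r), n_excluded = sum(!keep), fences = fences)
}

# Half-away-from-zero rounding at `digits` decimals (round() rounds half
# to even, which is not the convention used for the one-decimal tables).
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Confusion table at a ddG threshold
#'
#' Predicted values are rounded to one decimal (half away from zero, to
#' the precision of experimental values) before classification; class is
#' `value >= threshold`; experimental values are classified unrounded.
#'
#' @inheritParams median_abs_error
#' @param threshold kcal/mol (0 or 2 in the standard suite).
#' @return list of class `confusion_table`: `tp`, `fp`, `tn`, `fn`,
#'   `threshold`.
#' @export
confusion_at <- function(records, threshold) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  pred <- round_half_away(records$predicted_ddg, 1) >= threshold
  expc <- records$experimental_ddg >= threshold
  structure(list(tp = sum(pred & expc), fp = sum(pred & !expc),
                 tn = sum(!pred & !expc), fn = sum(!pred & expc),
                 threshold = threshold),
            class = "confusion_table")
}

#' Phi coefficient of a confusion table
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; algebraically
#' the Pearson correlation of the two binary indicators. A zero margin
#' gives 0 with attribute `degenerate = TRUE`.
#'
#' @param t a [confusion_at()] table.
#' @return numeric in `[-1, 1]`.
#' @export
phi_coefficient <- function(t) {
  tp <- t$tp; fp <- t$fp; tn <- t$tn; fn <- t$fn
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) *
    sqrt((tn + fn))
  if (den == 0) return(structure(0, degenerate = TRUE))
  (tp * tn - fp * fn) / den
}

#' Fraction of records classified concordantly at a threshold
#' @inheritParams median_abs_error
#' @param threshold kcal/mol (default 2).
#' @return `(tp + tn) / n`.
#' @export
concordance_fraction <- function(records, threshold = 2.0) {
  ct <- confusion_at(records, threshold)
  (ct$tp + ct$tn) / nrow(records)
}

#' Is a ddG value destabilising?
#'
#' Strictly greater than the threshold (default 2 kcal/mol, the
#' conventional cut-off): 2.0 itself is not destabilising.
#'
#' @param ddg kcal/mol.
#' @param threshold kcal/mol.
#' @return logical.
#' @export
classify_destabilising <- function(ddg, threshold = 2.0) {
  stopifnot(is.finite(ddg))
  ddg > threshold
}

#' Full benchmark report
#'
#' @inheritParams outlier_excluded_metrics
#' @return list of class `benchmark_report`: `n`, `median_abs_error`,
#'   outlier-excluded `mean_abs_error` / `rmse` / `pearson_r`,
#'   `tukey_fences`, confusion tables and phi at 0 and 2 kcal/mol, and the
#'   2 kcal/mol `concordance`.
#' @export
benchmark_report <- function(records, k = 1.5) {
  ex <- outlier_excluded_metrics(records, k)
  c0 <- confusion_at(records, 0)
  c2 <- confusion_at(records, 2)
  structure(list(n = nrow(records),
                 median_abs_error = median_abs_error(records),
                 mean_abs_error = ex$mean_abs_error, rmse = ex$rmse,
                 pearson_r = ex$pearson_r,
                 tukey_fences = ex$fences, n_excluded = ex$n_excluded,
                 confusion_0 = c0, confusion_2 = c2,
                 phi_0 = as.numeric(phi_coefficient(c0)),
                 phi_2 = as.numeric(phi_coefficient(c2)),
                 concordance = concordance_fraction(records, 2)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> n = ", x$n, "\n",
      "  median |error|      ", sprintf("%.3f", x$median_abs_error),
      " kcal/mol\n",
      "  mean |error| (excl) ", sprintf("%.3f", x$mean_abs_error),
      " kcal/mol (", x$n_excluded, " outlier(s) excluded)\n",
      "  RMSE (excl)         ", sprintf("%.3f", x$rmse), " kcal/mol\n",
      "  Pearson r (excl)    ", sprintf("%.3f", x$pearson_r), "\n",
      "  phi @0 / @2         ", sprintf("%.3f / %.3f", x$phi_0, x$phi_2),
      "\n  concordance @2      ", sprintf("%.3f", x$concordance), "\n",
      sep = "")
  invisible(x)
}

#' Population-rescue filter
#'
#' A destabilisation-pathogenicity hypothesis is weakened when a
#' comparably destabilising population variant close in space is common or
#' homozygous in the healthy population: returns `TRUE` iff some
#' population variant within `radius` of the target (structural distance)
#' is destabilising and has at least one homozygote or an allele frequency
#' above `freq_threshold`.
#'
#' @param s a `varstab_structure`.
#' @param chain,position target residue.
#' @param popvars data.frame with `seq_pos`, `allele_frequency`,
#'   `homozygote_count` and a `ddg` column of scored values.
#' @param radius structural radius, A (default 10).
#' @param freq_threshold allele-frequency cut-off (default 5e-4).
#' @param ddg_threshold destabilising cut-off, kcal/mol (default 2).
#' @return logical.
#' @export
population_rescue <- function(s, chain, position, popvars, radius = 10,
                              freq_threshold = 5e-4, ddg_threshold = 2.0) {
  if (is.null(popvars) || !nrow(popvars)) return(FALSE)
  nb <- find_neighbours(s, chain, position, radius, "min_heavy")
  near <- c(position, nb$seq_pos[nb$chain == chain])
  pv <- popvars[popvars$seq_pos %in% near, , drop = FALSE]
  if (!nrow(pv)) return(FALSE)
  any(pv$ddg > ddg_threshold &
        (pv$homozygote_count >= 1 | pv$allele_frequency > freq_threshold))
}

#' Cohort survey of scored variants
#'
#' Aggregates per-variant rows (ddG, destabilising flag, rescue flag,
#' feature-proximity flags) into per-significance-class fractions and
#' pathogenic:benign fold enrichments. Classes with no variants are
#' reported as absent (`NA`), not zero. All aggregates are recomputable
#' from the returned rows.
#'
#' @param rows data.frame with columns `significance` (`"pathogenic"`,
#'   `"benign"`, `"other"`), `ddg`, and logical columns `rescued`,
#'   `near_ligand`, `near_interface`, `near_ptm` (missing flag columns are
#'   treated as all-`FALSE`).
#' @param ddg_threshold destabilising cut-off (default 2 kcal/mol).
#' @return list of class `survey_report`: `rows` (with `destabilising`
#'   added), `fractions` (per class), `enrichments`
#'   (pathogenic:benign per feature category), `counts`.
#' @export
survey <- function(rows, ddg_threshold = 2.0) {
  for (col in c("rescued", "near_ligand", "near_interface", "near_ptm"))
    if (!col %in% names(rows)) rows[[col]] <- FALSE
  rows$destabilising <- rows$ddg > ddg_threshold
  classes <- c("pathogenic", "benign", "other")
  frac <- function(cls, col) {
    r <- rows[rows$significance == cls, , drop = FALSE]
    if (!nrow(r)) return(NA_real_)
    mean(r[[col]])
  }
  fractions <- lapply(stats::setNames(classes, classes), function(cls) {
    r <- rows[rows$significance == cls, , drop = FALSE]
    dst <- r[r$destabilising, , drop = FALSE]
    list(n = nrow(r),
         destabilising = frac(cls, "destabilising"),
         rescued_among_destabilising =
           if (nrow(dst)) mean(dst$rescued) else NA_real_,
         near_ligand = frac(cls, "near_ligand"),
         near_interface = frac(cls, "near_interface"),
         near_ptm = frac(cls, "near_ptm"))
  })
  enr <- function(col) {
    p <- fractions$pathogenic[[col]]; b <- fractions$benign[[col]]
    if (is.na(p) || is.na(b) || b == 0) NA_real_ else p / b
  }
  structure(list(rows = rows, fractions = fractions,
                 enrichments = list(
                   destabilising = enr("destabilising"),
                   near_ligand = enr("near_ligand"),
                   near_interface = enr("near_interface"),
                   near_ptm = enr("near_ptm")),
                 counts = table(rows$significance)),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("<survey_report> ", nrow(x$rows), " variant(s)\n", sep = "")
  for (cls in names(x$fractions)) {
    f <- x$fractions[[cls]]
    if (f$n == 0) next
    cat("  ", cls, ": n = ", f$n, ", destabilising ",
        sprintf("%.2f", f$destabilising), ", rescued|destab ",
        ifelse(is.na(f$rescued_among_destabilising), "-",
               sprintf("%.2f", f$rescued_among_destabilising)), "\n",
        sep = "")
  }
  invisible(x)
}

#' Read a benchmark table
#'
#' Headered TSV with columns `id`, `predicted` (or `predicted_ddg`) and
#' `experimental` (or `experimental_ddg`); `flip_sign` accommodates
#' datasets with the opposite ddG sign convention.
#'
#' @param path TSV file path.
#' @param flip_sign multiply experimental values by -1.
#' @return data.frame with `id`, `predicted_ddg`, `experimental_ddg`, plus
#'   attribute `n_skipped` malformed rows.
#' @export
read_benchmark_table <- function(path, flip_sign = FALSE) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  pred_col <- intersect(c("predicted_ddg", "predicted"), names(tb))[1]
  exp_col <- intersect(c("experimental_ddg", "experimental"),
                       names(tb))[1]
  if (is.na(pred_col) || is.na(exp_col))
    stop("benchmark table needs predicted and experimental columns",
         call. = FALSE)
  pred <- suppressWarnings(as.numeric(tb[[pred_col]]))
  expv <- suppressWarnings(as.numeric(tb[[exp_col]]))
  ok <- is.finite(pred) & is.finite(expv)
  out <- data.frame(id = if ("id" %in% names(tb)) tb$id[ok]
                    else as.character(which(ok)),
                    predicted_ddg = pred[ok],
                    experimental_ddg = if (flip_sign) -expv[ok]
                    else expv[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}
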