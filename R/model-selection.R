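# Choosing the most suitable structural model for a substitution from a
# manifest of candidates: experimental structures first (best resolution),
# then homology models above the identity cut-off (best identity), then a
# predicted model, with quality warning flags; otherwise sequence-only
# analysis proceeds.

#' Construct a model candidate
#'
#' @param kind `"experimental"`, `"homology"`, `"predicted"` or `"user"`.
#' @param coverage integer vector of modelled 1-based sequence positions.
#' @param path structure file reference.
#' @param resolution resolution in A (experimental).
#' @param identity percent sequence identity to template (homology).
#' @param qmean model quality score (homology; more negative = worse).
#' @param plddt named numeric vector: per-residue confidence 0-100 keyed by
#'   sequence position (predicted).
#' @param has_partners non-target chains present in the model.
#' @param id candidate identifier.
#' @return a list of class `model_candidate`.
#' @export
model_candidate <- function(kind, coverage, path = NA_character_,
                            resolution = NA_real_, identity = NA_real_,
                            qmean = NA_real_, plddt = NULL,
                            has_partners = FALSE, id = NA_character_) {
  kind <- match.arg(kind, c("experimental", "homology", "predicted",
                            "user"))
  if (!length(coverage)) stop("coverage must be non-empty", call. = FALSE)
  if (!is.na(identity) && (identity < 0 || identity > 100))
    stop("identity outside [0,100]", call. = FALSE)
  if (!is.null(plddt) && any(plddt < 0 | plddt > 100))
    stop("pLDDT outside [0,100]", call. = FALSE)
  structure(list(kind = kind, coverage = as.integer(coverage), path = path,
                 resolution = resolution, identity = identity,
                 qmean = qmean, plddt = plddt,
                 has_partners = isTRUE(has_partners), id = id),
            class = "model_candidate")
}

#' Model-selection settings
#'
#' Defaults mirror the documented quality gates: homology models below 20
#' percent identity are excluded; QMEAN below -2 and per-site pLDDT below
#' 70 raise warnings only.
#'
#' @param min_identity exclusion threshold, percent (default 20).
#' @param qmean_warn QMEAN warning threshold (default -2).
#' @param plddt_warn per-site pLDDT warning threshold (default 70).
#' @param require_partners prefer a covering homology model with partner
#'   chains over a single-chain predicted model.
#' @param allow_homology,allow_predicted candidate classes considered.
#' @return a list of class `selection_settings`.
#' @export
selection_settings <- function(min_identity = 20, qmean_warn = -2,
                               plddt_warn = 70, require_partners = FALSE,
                               allow_homology = TRUE,
                               allow_predicted = TRUE) {
  structure(list(min_identity = min_identity, qmean_warn = qmean_warn,
                 plddt_warn = plddt_warn,
                 require_partners = isTRUE(require_partners),
                 allow_homology = isTRUE(allow_homology),
                 allow_predicted = isTRUE(allow_predicted)),
            class = "selection_settings")
}

#' Does a candidate model cover a sequence position?
#' @param candidate a [model_candidate()].
#' @param position 1-based sequence position.
#' @return logical.
#' @export
covers <- function(candidate, position) {
  stopifnot(position >= 1)
  position %in% candidate$coverage
}

#' Quality warning flags for a candidate at a position
#'
#' `LOW_QMEAN` iff a homology model's QMEAN is below the warning threshold;
#' `LOW_PLDDT_AT_SITE` iff a predicted model's confidence at the target
#' position is below the threshold; experimental models carry no flags.
#'
#' @inheritParams covers
#' @param settings a [selection_settings()] list.
#' @return character vector of flag codes.
#' @export
flag_quality <- function(candidate, position,
                         settings = selection_settings()) {
  flags <- character(0)
  if (candidate$kind == "homology" && !is.na(candidate$qmean) &&
      candidate$qmean < settings$qmean_warn)
    flags <- c(flags, "LOW_QMEAN")
  if (candidate$kind == "predicted" && !is.null(candidate$plddt)) {
    p <- candidate$plddt[as.character(position)]
    if (!is.na(p) && p < settings$plddt_warn)
      flags <- c(flags, "LOW_PLDDT_AT_SITE")
  }
  flags
}

#' Select the best structural model for a position
#'
#' Deterministic preference hierarchy: (1) covering experimental
#' candidates, best (lowest) resolution first; (2) covering homology
#' candidates at or above `min_identity`, best identity first (QMEAN only
#' warns); (3) a covering predicted candidate (low per-site pLDDT warns);
#' (4) none, flagged `NO_STRUCTURE` - sequence-level analysis still
#' proceeds. Ties break by manifest order. With `require_partners`, a
#' covering homology candidate that carries partner chains outranks a
#' single-chain predicted candidate (quality warnings do not skip it), but
#' the identity exclusion always stands. User-supplied candidates bypass
#' the quality gates (warnings still recorded) and take precedence.
#'
#' @param candidates list of [model_candidate()] objects, in manifest
#'   order.
#' @param position 1-based target sequence position.
#' @param settings a [selection_settings()] list.
#' @return a `selection_result`: list with `chosen` (candidate or `NULL`),
#'   `warnings` (flag codes), `rationale` (audit trail of rejections).
#' @export
select_model <- function(candidates, position,
                         settings = selection_settings()) {
  rationale <- character(0)
  warnings <- character(0)
  note <- function(msg) rationale <<- c(rationale, msg)
  lab <- function(cd, i) if (!is.na(cd$id)) cd$id else paste0("candidate#", i)

  pool <- list()
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    if (!covers(cd, position)) {
      note(paste0(lab(cd, i), ": does not cover position ", position))
      next
    }
    if (cd$kind == "homology") {
      if (!settings$allow_homology) {
        note(paste0(lab(cd, i), ": homology models disabled")); next
      }
      if (!is.na(cd$identity) && cd$identity < settings$min_identity) {
        note(paste0(lab(cd, i), ": LOW_IDENTITY_EXCLUDED (identity ",
                    cd$identity, "% < ", settings$min_identity, "%)"))
        warnings <- c(warnings, "LOW_IDENTITY_EXCLUDED")
        next
      }
    }
    if (cd$kind == "predicted" && !settings$allow_predicted) {
      note(paste0(lab(cd, i), ": predicted models disabled")); next
    }
    pool[[length(pool) + 1L]] <- list(cand = cd, idx = i)
  }
  pick <- function(kind, metric, decreasing) {
    sub <- Filter(function(p) p$cand$kind == kind, pool)
    if (!length(sub)) return(NULL)
    vals <- vapply(sub, function(p) {
      v <- p$cand[[metric]]
      if (is.null(v) || is.na(v)) if (decreasing) -Inf else Inf else v
    }, numeric(1))
    ord <- order(if (decreasing) -vals else vals,
                 vapply(sub, `[[`, numeric(1), "idx"))
    sub[[ord[1]]]
  }
  chosen <- NULL
  usr <- Filter(function(p) p$cand$kind == "user", pool)
  if (length(usr)) {
    chosen <- usr[[1]]
    note(paste0(lab(chosen$cand, chosen$idx),
                ": user-supplied model takes precedence"))
  }
  if (is.null(chosen)) chosen <- pick("experimental", "resolution", FALSE)
  if (is.null(chosen)) {
    hom <- pick("homology", "identity", TRUE)
    prd <- pick("predicted", "resolution", FALSE)  # manifest order only
    if (!is.null(hom) && settings$require_partners &&
        hom$cand$has_partners && !is.null(prd) && !prd$cand$has_partners) {
      chosen <- hom
      note(paste0(lab(hom$cand, hom$idx),
                  ": homology model with partner chains preferred over ",
                  "single-chain predicted model"))
    } else {
      chosen <- if (!is.null(hom)) hom else prd
    }
  }
  if (is.null(chosen)) {
    warnings <- c(warnings, "NO_STRUCTURE")
    note("no covering candidate: structure-independent analysis only")
    res <- list(chosen = NULL, warnings = unique(warnings),
                rationale = rationale)
  } else {
    warnings <- c(warnings, flag_quality(chosen$cand, position, settings))
    res <- list(chosen = chosen$cand, warnings = unique(warnings),
                rationale = rationale)
  }
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  if (is.null(x$chosen)) cat("<selection_result> no structure\n")
  else cat("<selection_result> chosen ",
           if (!is.na(x$chosen$id)) x$chosen$id else x$chosen$kind,
           " (", x$chosen$kind, ")",
           if (length(x$warnings)) paste0("; warnings: ",
                                          paste(x$warnings,
                                                collapse = ", ")),
           "\n", sep = "")
  invisible(x)
}

#' Read a model-candidate manifest from JSON
#'
#' The manifest is an array of candidate objects with fields matching
#' [model_candidate()]; `coverage` may be `[start, end]` shorthand via
#' `coverage_range`. Per-residue pLDDT may be inline (`plddt` object) or
#' read from the model file's B-factor column (`plddt_from_bfactor: true`).
#'
#' @param path JSON file path.
#' @param base_dir directory model paths are relative to (default: the
#'   manifest's directory).
#' @return list of `model_candidate` objects.
#' @export
read_model_manifest <- function(path, base_dir = dirname(path)) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(seq_along(j), function(i) {
    e <- j[[i]]
    cov <- if (!is.null(e$coverage_range))
      seq.int(e$coverage_range[[1]], e$coverage_range[[2]])
    else unlist(e$coverage)
    plddt <- NULL
    mpath <- if (!is.null(e$path)) file.path(base_dir, e$path)
    else NA_character_
    if (isTRUE(e$plddt_from_bfactor) && !is.na(mpath)) {
      sm <- read_structure(mpath, source_kind = "predicted")
      a <- sm$atoms[!sm$atoms$is_hetero & sm$atoms$atom == "CA", ]
      plddt <- stats::setNames(a$b, a$seq_pos)
    } else if (!is.null(e$plddt)) {
      plddt <- unlist(e$plddt)
    }
    model_candidate(kind = e$kind, coverage = cov, path = mpath,
                    resolution = e$resolution %||% NA_real_,
                    identity = e$identity %||% NA_real_,
                    qmean = e$qmean %||% NA_real_, plddt = plddt,
                    has_partners = isTRUE(e$has_partners),
                    id = e$id %||% paste0("candidate#", i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
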