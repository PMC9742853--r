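# Staged analysis of one substitution, mirroring the interactive tool's
# presentation order: sequence-level results first (motifs, features at
# the site), then model selection, neighbourhood annotation, ddG, and the
# nearby-variant batch. Later stages may fail or be skipped
# (NO_STRUCTURE); completed stages are always reported.

#' Analyse a substitution end to end
#'
#' @param sequence protein sequence (string) or path to a FASTA file.
#' @param substitution substitution string (`X123Y` / `p.X123Y`) or a
#'   [new_substitution()] object.
#' @param candidates list of [model_candidate()] objects, a manifest JSON
#'   path, or `NULL` (sequence-only analysis).
#' @param annotations an [new_annotation_set()], a path readable by
#'   [read_annotation_set()], or `NULL`.
#' @param patterns list of [motif_pattern()] objects, a TSV path, or
#'   `NULL` for the shipped demo set.
#' @param structure optional `varstab_structure` overriding the selected
#'   candidate's file.
#' @param settings a [ddg_settings()] list.
#' @param sel_settings a [selection_settings()] list.
#' @param annotation_radius neighbourhood radius for annotation joins, A
#'   (default 10, min-heavy-atom rule).
#' @param batch_radius radius for the nearby-variant ddG batch, A
#'   (default 10).
#' @param batch_max cap on the number of nearby variants scored.
#' @param quiet suppress progress messages.
#' @return list of class `analysis_report` with stages `input`,
#'   `sequence_level`, `selection`, `neighbourhood`, `ddg`, `batch`,
#'   `provenance`; `status` is `"complete"` or `"partial"`, and `errors`
#'   collects messages of failed stages.
#' @export
analyse <- function(sequence, substitution, candidates = NULL,
                    annotations = NULL, patterns = NULL, structure = NULL,
                    settings = ddg_settings(),
                    sel_settings = selection_settings(),
                    annotation_radius = 10, batch_radius = 10,
                    batch_max = 10, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (file.exists(sequence) && !grepl("^[A-Z]+$", sequence)) {
    fa <- bio3d::read.fasta(sequence)
    sequence <- paste(toupper(fa$ali[1, ]), collapse = "")
    sequence <- gsub("-", "", sequence)
  }
  sequence <- toupper(sequence)
  sub <- if (is.character(substitution)) parse_substitution(substitution)
  else substitution
  if (sub$seq_pos > nchar(sequence))
    stop("substitution position ", sub$seq_pos,
         " beyond sequence length ", nchar(sequence), call. = FALSE)
  have <- substr(sequence, sub$seq_pos, sub$seq_pos)
  if (have != sub$ref_aa)
    stop("reference mismatch at position ", sub$seq_pos, ": expected ",
         sub$ref_aa, ", sequence has ", have, call. = FALSE)
  if (is.character(annotations)) annotations <-
      read_annotation_set(annotations)
  if (is.null(annotations)) annotations <- new_annotation_set()
  if (is.character(patterns)) patterns <- read_motif_patterns(patterns)
  if (is.null(patterns))
    patterns <- read_motif_patterns(system.file("extdata",
                                                "demo_motifs.tsv",
                                                package = "varstab"))
  if (is.character(candidates)) candidates <-
      read_model_manifest(candidates)

  errors <- list()
  report <- list(input = list(substitution = format(sub),
                              sequence_length = nchar(sequence),
                              settings = list(
                                radius = settings$radius,
                                cycles = settings$cycles,
                                display_cap = settings$display_cap,
                                annotation_radius = annotation_radius)))

  say("stage 1/5: sequence-level analysis")
  report$sequence_level <- tryCatch({
    md <- motif_delta(sequence, sub, patterns)
    feats <- annotations$features[
      annotations$features$start <= sub$seq_pos &
        annotations$features$end >= sub$seq_pos, , drop = FALSE]
    list(motif_delta = md, features_at_site = feats,
         ptms_at_site = annotations$ptms[
           annotations$ptms$seq_pos == sub$seq_pos, , drop = FALSE])
  }, error = function(e) {
    errors$sequence_level <<- conditionMessage(e); NULL
  })

  say("stage 2/5: model selection")
  selection <- if (is.null(candidates))
    select_model(list(), sub$seq_pos, sel_settings)
  else select_model(candidates, sub$seq_pos, sel_settings)
  report$selection <- selection

  s <- structure
  if (is.null(s) && !is.null(selection$chosen) &&
      !is.na(selection$chosen$path) && file.exists(selection$chosen$path))
    s <- tryCatch(read_structure(selection$chosen$path,
                                 source_kind = selection$chosen$kind),
                  error = function(e) {
                    errors$structure <<- conditionMessage(e); NULL
                  })
  if (is.null(s)) {
    report$status <- if ("NO_STRUCTURE" %in% selection$warnings &&
                         !length(errors)) "complete" else "partial"
    report$errors <- errors
    report$provenance <- report_provenance()
    class(report) <- "analysis_report"
    return(report)
  }
  s <- strip_solvent(s)

  say("stage 3/5: neighbourhood annotation")
  report$neighbourhood <- tryCatch({
    nb <- find_neighbours(s, "A", sub$seq_pos, annotation_radius,
                          "min_heavy")
    rep <- annotate_neighbours(nb, list(chain = "A",
                                        seq_pos = sub$seq_pos,
                                        aa = sub$ref_aa), annotations)
    rep$ligand_contacts <- ligand_proximity(s, "A", sub$seq_pos,
                                            annotation_radius)
    rep
  }, error = function(e) {
    errors$neighbourhood <<- conditionMessage(e); NULL
  })

  say("stage 4/5: ddG estimation")
  report$ddg <- tryCatch(
    ddg_protocol(s, "A", sub, settings),
    error = function(e) { errors$ddg <<- conditionMessage(e); NULL })

  say("stage 5/5: nearby-variant ddG batch")
  report$batch <- tryCatch({
    if (!is.null(report$neighbourhood)) {
      near_pos <- unique(c(sub$seq_pos,
                           report$neighbourhood$neighbours$seq_pos[
                             report$neighbourhood$neighbours$chain == "A"]))
      pv <- annotations$popvars[annotations$popvars$seq_pos %in% near_pos,
                                , drop = FALSE]
      cv <- annotations$clinvars[annotations$clinvars$seq_pos %in%
                                   near_pos, , drop = FALSE]
      vars <- unique(rbind(pv[, c("seq_pos", "ref_aa", "alt_aa")],
                           cv[, c("seq_pos", "ref_aa", "alt_aa")]))
      vars <- vars[!(vars$seq_pos == sub$seq_pos &
                       vars$alt_aa == sub$alt_aa), , drop = FALSE]
      if (nrow(vars) > batch_max) vars <- vars[seq_len(batch_max), ,
                                               drop = FALSE]
      subs <- lapply(seq_len(nrow(vars)), function(i)
        new_substitution(vars$ref_aa[i], vars$seq_pos[i], vars$alt_aa[i]))
      ddg_batch(s, "A", subs, settings)
    } else list()
  }, error = function(e) { errors$batch <<- conditionMessage(e); NULL })

  report$errors <- errors
  report$status <- if (length(errors)) "partial" else "complete"
  report$provenance <- report_provenance()
  class(report) <- "analysis_report"
  report
}

report_provenance <- function() {
  list(package = "varstab",
       version = as.character(utils::packageVersion("varstab")))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", x$input$substitution, " [", x$status, "]\n",
      sep = "")
  if (!is.null(x$ddg)) print(x$ddg)
  invisible(x)
}

# JSON-serialisable view of a report (structures reduced to counts).
report_to_list <- function(x) {
  ddg <- x$ddg
  list(input = x$input,
       status = x$status,
       sequence_level = if (!is.null(x$sequence_level)) list(
         gained = x$sequence_level$motif_delta$gained,
         lost = x$sequence_level$motif_delta$lost,
         unchanged_overlapping =
           x$sequence_level$motif_delta$unchanged_overlapping,
         features_at_site = x$sequence_level$features_at_site,
         ptms_at_site = x$sequence_level$ptms_at_site),
       selection = list(
         chosen = if (!is.null(x$selection$chosen))
           x$selection$chosen[c("id", "kind", "resolution", "identity",
                                "qmean", "has_partners")],
         warnings = x$selection$warnings,
         rationale = x$selection$rationale),
       neighbourhood = if (!is.null(x$neighbourhood)) list(
         neighbours = x$neighbourhood$neighbours,
         summary = x$neighbourhood$summary,
         ligand_contacts = x$neighbourhood$ligand_contacts),
       ddg = if (!is.null(ddg)) list(
         substitution = format(ddg$substitution),
         quick_ddg_kcal_mol = ddg$quick_ddg,
         protocol_ddg_kcal_mol = ddg$protocol_ddg,
         display = ddg$display, capped = ddg$capped, rsa = ddg$rsa,
         n_neighbours = ddg$audit$n_neighbours),
       batch = if (!is.null(x$batch)) lapply(x$batch, function(b) {
         if (inherits(b, "ddg_error"))
           list(substitution = if (is.character(b$substitution))
             b$substitution else format(b$substitution),
             error = b$message)
         else list(substitution = format(b$substitution),
                   quick_ddg_kcal_mol = b$quick_ddg,
                   protocol_ddg_kcal_mol = b$protocol_ddg,
                   display = b$display, capped = b$capped, rsa = b$rsa)
       }),
       errors = x$errors,
       provenance = x$provenance)
}

#' Write an analysis report as JSON
#' @param report an [analyse()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Render an analysis report as markdown
#' @param report an [analyse()] result.
#' @return character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  l <- report_to_list(report)
  out <- c(paste0("# Analysis of ", l$input$substitution),
           "",
           paste0("Status: ", l$status), "",
           "## Sequence level")
  if (!is.null(l$sequence_level)) {
    out <- c(out,
             paste0("- motifs gained: ", nrow(l$sequence_level$gained),
                    ", lost: ", nrow(l$sequence_level$lost)),
             paste0("- features at site: ",
                    nrow(l$sequence_level$features_at_site)))
  }
  out <- c(out, "", "## Model selection",
           if (!is.null(l$selection$chosen))
             paste0("- chosen: ", l$selection$chosen$id, " (",
                    l$selection$chosen$kind, ")")
           else "- no structure available",
           if (length(l$selection$warnings))
             paste0("- warnings: ", paste(l$selection$warnings,
                                          collapse = ", ")))
  if (!is.null(l$neighbourhood))
    out <- c(out, "", "## Neighbourhood",
             paste0("- ", l$neighbourhood$summary$n_neighbours,
                    " residues within the annotation radius"),
             paste0("- annotation hits: ",
                    l$neighbourhood$summary$popvars, " population, ",
                    l$neighbourhood$summary$clinvars, " clinical, ",
                    l$neighbourhood$summary$ptms, " PTM, ",
                    l$neighbourhood$summary$features, " feature"))
  if (!is.null(l$ddg))
    out <- c(out, "", "## Stability",
             paste0("- protocol ddG: ", l$ddg$display,
                    sprintf(" (raw %.2f kcal/mol)",
                            l$ddg$protocol_ddg_kcal_mol)),
             sprintf("- quick estimate: %.2f kcal/mol (RSA %.2f)",
                     l$ddg$quick_ddg_kcal_mol, l$ddg$rsa))
  if (!is.null(l$batch) && length(l$batch))
    out <- c(out, "", "## Nearby variants",
             vapply(l$batch, function(b)
               if (!is.null(b$error))
                 paste0("- ", b$substitution, ": error (", b$error, ")")
               else paste0("- ", b$substitution, ": ", b$display),
               character(1)))
  out
}

#' Score a variant table against a structure (engine-mode benchmark)
#'
#' Takes a table of variants with experimental ddG values, scores each
#' variant with [ddg_protocol()] on the supplied structure and returns
#' benchmark records. Equivalent to the precomputed-predictions path when
#' the predictions came from the same engine and settings.
#'
#' @param s a `varstab_structure`.
#' @param table data.frame with columns `variant` (`X123Y` strings) and
#'   `experimental_ddg` (kcal/mol); optional `id`.
#' @param chain chain label.
#' @param settings a [ddg_settings()] list.
#' @return data.frame of benchmark records (`id`, `predicted_ddg`,
#'   `experimental_ddg`); unscorable rows are dropped with attribute
#'   `n_skipped` counting them.
#' @export
run_benchmark <- function(s, table, chain = "A",
                          settings = ddg_settings()) {
  stopifnot(all(c("variant", "experimental_ddg") %in% names(table)))
  res <- ddg_batch(s, chain, as.list(table$variant), settings)
  ok <- !vapply(res, inherits, logical(1), "ddg_error")
  out <- data.frame(id = if ("id" %in% names(table)) table$id[ok]
                    else table$variant[ok],
                    predicted_ddg = vapply(res[ok], `[[`, numeric(1),
                                           "protocol_ddg"),
                    experimental_ddg = table$experimental_ddg[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Run the cohort survey from raw inputs
#'
#' Scores every cohort variant on the structure, evaluates the
#' population-rescue filter and the feature-proximity flags (ligand or
#' cofactor, partner-chain interface, PTM, all within `radius`), and
#' aggregates with [survey()].
#'
#' @param s a `varstab_structure` (solvent already stripped).
#' @param cohort data.frame with columns `variant` (`X123Y` strings) and
#'   `significance` (`"pathogenic"`, `"benign"`, `"other"`).
#' @param ann an [new_annotation_set()] object; population variants are
#'   scored with the quick estimator for the rescue filter.
#' @param chain chain label.
#' @param radius proximity radius, A (default 10).
#' @param settings a [ddg_settings()] list.
#' @return a [survey()] report; unscorable cohort rows are dropped with
#'   attribute `n_skipped` on the report's `rows`.
#' @export
run_survey <- function(s, cohort, ann = new_annotation_set(),
                       chain = "A", radius = 10,
                       settings = ddg_settings()) {
  stopifnot(all(c("variant", "significance") %in% names(cohort)))
  coeffs <- default_quick_coefficients()
  sa <- compute_sasa(s)
  pv <- ann$popvars
  if (nrow(pv)) {
    pv$ddg <- vapply(seq_len(nrow(pv)), function(i) {
      row <- sa[sa$chain == chain & sa$seq_pos == pv$seq_pos[i] &
                  !sa$is_hetero, , drop = FALSE]
      if (!nrow(row)) return(NA_real_)
      aa <- aa_3to1(row$resid[1])
      if (is.na(aa) || aa != pv$ref_aa[i]) return(NA_real_)
      quick_ddg(new_substitution(pv$ref_aa[i], pv$seq_pos[i],
                                 pv$alt_aa[i]),
                relative_sasa(row$sasa[1], aa), coeffs)
    }, numeric(1))
    pv <- pv[is.finite(pv$ddg), , drop = FALSE]
  }
  cache <- new.env(parent = emptyenv())
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(cohort))) {
    r <- tryCatch(ddg_protocol(s, chain, cohort$variant[i], settings,
                               stack_cache = cache),
                  error = function(e) NULL)
    if (is.null(r)) { skipped <- skipped + 1L; next }
    pos <- r$substitution$seq_pos
    nb <- find_neighbours(s, chain, pos, radius, "min_heavy")
    near_pos <- nb$seq_pos[nb$chain == chain]
    rows[[length(rows) + 1L]] <- data.frame(
      variant = format(r$substitution),
      significance = cohort$significance[i],
      ddg = r$protocol_ddg,
      rescued = population_rescue(s, chain, pos, pv, radius),
      near_ligand = nrow(ligand_proximity(s, chain, pos, radius)) > 0,
      near_interface = any(nb$chain != chain),
      near_ptm = any(ann$ptms$seq_pos %in% c(pos, near_pos)),
      stringsAsFactors = FALSE)
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(0), significance = character(0),
               ddg = numeric(0), rescued = logical(0),
               near_ligand = logical(0), near_interface = logical(0),
               near_ptm = logical(0), stringsAsFactors = FALSE)
  rep <- survey(rows)
  attr(rep$rows, "n_skipped") <- skipped
  rep
}
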