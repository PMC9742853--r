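# Annotation container and file-based adapters. All positions are 1-based
# protein sequence positions, the same coordinate system structures use
# after renumbering.

#' Construct an annotation set
#'
#' Bundles the per-protein annotation tables: sequence features (intervals),
#' population variants (with allele frequency and homozygote counts),
#' clinical variants (with significance), PTM sites and per-residue
#' conservation scores.
#'
#' @param features data.frame: `name`, `category`, `start`, `end`, `source`.
#' @param popvars data.frame: `seq_pos`, `ref_aa`, `alt_aa`,
#'   `allele_frequency` (in `[0,1]`), `homozygote_count` (>= 0).
#' @param clinvars data.frame: `seq_pos`, `ref_aa`, `alt_aa`,
#'   `significance` (`"pathogenic"`, `"benign"`, `"other"`).
#' @param ptms data.frame: `seq_pos`, `modification`, `evidence`
#'   (`"curated"`, `"high_throughput"`).
#' @param conservation named numeric vector: names are sequence positions.
#' @return an object of class `annotation_set`.
#' @export
new_annotation_set <- function(features = NULL, popvars = NULL,
                               clinvars = NULL, ptms = NULL,
                               conservation = NULL) {
  empty <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  if (is.null(features))
    features <- empty(name = character(0), category = character(0),
                      start = integer(0), end = integer(0),
                      source = character(0))
  if (is.null(popvars))
    popvars <- empty(seq_pos = integer(0), ref_aa = character(0),
                     alt_aa = character(0), allele_frequency = numeric(0),
                     homozygote_count = integer(0))
  if (is.null(clinvars))
    clinvars <- empty(seq_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), significance = character(0))
  if (is.null(ptms))
    ptms <- empty(seq_pos = integer(0), modification = character(0),
                  evidence = character(0))
  if (is.null(conservation)) conservation <- stats::setNames(numeric(0),
                                                             character(0))
  if (nrow(features) && any(features$start > features$end))
    stop("feature with start > end", call. = FALSE)
  for (tb in list(features$start, popvars$seq_pos, clinvars$seq_pos,
                  ptms$seq_pos))
    if (length(tb) && any(tb < 1)) stop("annotation position < 1",
                                        call. = FALSE)
  if (nrow(popvars)) {
    if (any(popvars$allele_frequency < 0 | popvars$allele_frequency > 1))
      stop("allele_frequency outside [0,1]", call. = FALSE)
    if (any(popvars$homozygote_count < 0))
      stop("negative homozygote_count", call. = FALSE)
  }
  structure(list(features = features, popvars = popvars,
                 clinvars = clinvars, ptms = ptms,
                 conservation = conservation),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", nrow(x$features), " feature(s), ",
      nrow(x$popvars), " population variant(s), ", nrow(x$clinvars),
      " clinical variant(s), ", nrow(x$ptms), " PTM(s), ",
      length(x$conservation), " conservation score(s)\n", sep = "")
  invisible(x)
}

#' Read an annotation set from files
#'
#' Either a single JSON bundle (`path` ends in `.json`; top-level keys
#' `features`, `popvars`, `clinvars`, `ptms`, `conservation`) or a
#' directory of headered TSV files (`features.tsv`, `popvars.tsv`,
#' `clinvars.tsv`, `ptms.tsv`, `conservation.tsv` with columns `seq_pos`,
#' `score`); missing tables give empty joins.
#'
#' @param path JSON file or directory path.
#' @return an `annotation_set`.
#' @export
read_annotation_set <- function(path) {
  if (dir.exists(path)) {
    rd <- function(f) {
      fp <- file.path(path, f)
      if (file.exists(fp))
        utils::read.delim(fp, stringsAsFactors = FALSE)
      else NULL
    }
    cons <- rd("conservation.tsv")
    if (!is.null(cons))
      cons <- stats::setNames(cons$score, cons$seq_pos)
    new_annotation_set(rd("features.tsv"), rd("popvars.tsv"),
                       rd("clinvars.tsv"), rd("ptms.tsv"), cons)
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    cons <- j$conservation
    if (!is.null(cons) && is.data.frame(cons))
      cons <- stats::setNames(cons$score, cons$seq_pos)
    as_df <- function(x) if (is.null(x) || !length(x)) NULL else
      as.data.frame(x, stringsAsFactors = FALSE)
    new_annotation_set(as_df(j$features), as_df(j$popvars),
                       as_df(j$clinvars), as_df(j$ptms), cons)
  }
}

#' Write an annotation set as a JSON bundle
#' @param ann an `annotation_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_set <- function(ann, path) {
  cons <- data.frame(seq_pos = as.integer(names(ann$conservation)),
                     score = as.numeric(ann$conservation))
  jsonlite::write_json(list(features = ann$features, popvars = ann$popvars,
                            clinvars = ann$clinvars, ptms = ann$ptms,
                            conservation = cons),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
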