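# Short-linear-motif scanning: regular-expression patterns over the
# amino-acid alphabet, and the gained/lost classification of hits around a
# substitution site.

#' Construct a motif pattern
#' @param name identifier.
#' @param pattern regular expression over the uppercase amino-acid
#'   alphabet (POSIX-style classes; anchors permitted; no back-references).
#' @param description free text.
#' @return a list of class `motif_pattern`.
#' @export
motif_pattern <- function(name, pattern, description = "") {
  ok <- tryCatch({
    suppressWarnings(grepl(pattern, "ACDEFG", perl = TRUE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("pattern '", name, "' does not compile: ", pattern,
                call. = FALSE)
  if (grepl("\\\\[0-9]", pattern))
    stop("pattern '", name, "' uses back-references, which are not ",
         "supported", call. = FALSE)
  structure(list(name = name, pattern = pattern,
                 description = description), class = "motif_pattern")
}

#' Read motif patterns from a TSV file
#'
#' Headered TSV with columns `name`, `pattern`, `description` (the layout
#' of an ELM classes download). A small demo file ships with the package:
#' `system.file("extdata", "demo_motifs.tsv", package = "varstab")`.
#'
#' @param path TSV file path.
#' @return list of [motif_pattern()] objects.
#' @export
read_motif_patterns <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  lapply(seq_len(nrow(tb)), function(i)
    motif_pattern(tb$name[i], tb$pattern[i],
                  if ("description" %in% names(tb)) tb$description[i]
                  else ""))
}

#' Scan a sequence for motif hits
#'
#' Finds all matches of every pattern, including overlapping matches at
#' distinct start positions, in deterministic (pattern, start) order.
#'
#' @param seq uppercase amino-acid string (`X` allowed; it never matches a
#'   specific-letter pattern).
#' @param patterns list of [motif_pattern()] objects.
#' @return data.frame: `name`, `start`, `end` (1-based inclusive),
#'   `matched`.
#' @export
scan_motifs <- function(seq, patterns) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (seq != toupper(seq)) stop("sequence must be uppercase",
                                call. = FALSE)
  out <- list()
  for (p in patterns) {
    # capture inside a lookahead: all matches at distinct starts,
    # including overlapping ones
    la <- paste0("(?=(", p$pattern, "))")
    m <- gregexpr(la, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1]
    keep <- lens > 0                 # zero-width matches are not motifs
    starts <- starts[keep]; lens <- lens[keep]
    if (!length(starts)) next
    out[[length(out) + 1L]] <-
      data.frame(name = p$name, start = starts, end = starts + lens - 1L,
                 matched = substring(seq, starts, starts + lens - 1L),
                 stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(name = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  ord <- order(match(res$name, vapply(patterns, `[[`, character(1),
                                      "name")), res$start, res$end)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Motifs gained or lost by a substitution
#'
#' Scans the wild-type and mutant sequences, keeps hits overlapping the
#' window around the substitution site, and classifies hits present only
#' in the mutant as gained and only in the wild type as lost (keyed by
#' pattern name and span). Hits present in both that span the site are
#' reported as unchanged.
#'
#' @param seq wild-type sequence (uppercase).
#' @param sub a [new_substitution()] or substitution string; its reference
#'   letter must match `seq` at the position.
#' @param patterns list of [motif_pattern()] objects.
#' @param window residues considered on each side of the site (default
#'   25).
#' @return list of class `motif_delta`: data.frames `gained`, `lost`,
#'   `unchanged_overlapping`.
#' @export
motif_delta <- function(seq, sub, patterns, window = 25) {
  if (is.character(sub)) sub <- parse_substitution(sub)
  n <- nchar(seq)
  if (sub$seq_pos > n)
    stop("substitution position ", sub$seq_pos, " beyond sequence length ",
         n, call. = FALSE)
  have <- substr(seq, sub$seq_pos, sub$seq_pos)
  if (have != sub$ref_aa)
    stop("reference mismatch at position ", sub$seq_pos, ": expected ",
         sub$ref_aa, ", sequence has ", have, call. = FALSE)
  mut_seq <- seq
  substr(mut_seq, sub$seq_pos, sub$seq_pos) <- sub$alt_aa
  lo <- max(1L, sub$seq_pos - window)
  hi <- min(n, sub$seq_pos + window)
  in_window <- function(h) h[h$start <= hi & h$end >= lo, , drop = FALSE]
  wt <- in_window(scan_motifs(seq, patterns))
  mu <- in_window(scan_motifs(mut_seq, patterns))
  key <- function(h) paste(h$name, h$start, h$end, sep = "\r")
  gained <- mu[!key(mu) %in% key(wt), , drop = FALSE]
  lost <- wt[!key(wt) %in% key(mu), , drop = FALSE]
  both <- wt[key(wt) %in% key(mu), , drop = FALSE]
  unchanged <- both[both$start <= sub$seq_pos & both$end >= sub$seq_pos, ,
                    drop = FALSE]
  rownames(gained) <- rownames(lost) <- rownames(unchanged) <- NULL
  structure(list(gained = gained, lost = lost,
                 unchanged_overlapping = unchanged),
            class = "motif_delta")
}

#' @export
print.motif_delta <- function(x, ...) {
  cat("<motif_delta> gained ", nrow(x$gained), ", lost ", nrow(x$lost),
      ", unchanged overlapping ", nrow(x$unchanged_overlapping), "\n",
      sep = "")
  invisible(x)
}
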