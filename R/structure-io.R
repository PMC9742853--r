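# Reading, writing and normalising structural models. Parsing of PDB and
# mmCIF goes through bio3d; mmCIF writing is a minimal atom_site loop since
# no installed reader-independent writer exists for that direction.

#' Read a structural model from PDB or mmCIF
#'
#' ATOM and HETATM records are represented; hydrogens are dropped; for
#' alternate locations the highest-occupancy conformer is kept (ties: first
#' encountered). Files with insertion codes are rejected: all downstream
#' positions are plain 1-based sequence positions.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param source_kind provenance label stored on the structure.
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           source_kind = "user") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif",
                     stop("cannot infer structure format from extension '",
                          ext, "'", call. = FALSE))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes are not supported; renumber the structure first",
         call. = FALSE)
  element <- at$elesy
  if (is.null(element)) element <- rep(NA_character_, nrow(at))
  guess <- gsub("[0-9'*]", "", at$elety)
  guess <- toupper(substr(guess, 1, 1))
  element <- ifelse(is.na(element) | !nzchar(element), guess,
                    toupper(trimws(element)))
  keep <- !(element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  # altloc: highest occupancy per atom slot, ties first encountered
  alt <- at$alt
  occ <- at$o
  occ[is.na(occ)] <- 1
  if (any(!is.na(alt) & nzchar(alt))) {
    slot <- paste(at$chain, at$resno, at$resid, at$elety, sep = "\r")
    ord <- order(-occ)                      # stable: ties keep file order
    keep2 <- sort(ord[!duplicated(slot[ord])])
    at <- at[keep2, , drop = FALSE]
    element <- element[keep2]
  }
  chain <- at$chain
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  atoms <- data.frame(chain = chain,
                      seq_pos = as.integer(at$resno),
                      resid = toupper(at$resid),
                      atom = at$elety,
                      element = element,
                      x = at$x, y = at$y, z = at$z,
                      b = ifelse(is.na(at$b), 0, at$b),
                      is_hetero = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  new_structure(atoms, source_kind = source_kind,
                metadata = list(path = path, format = format))
}

#' Write a structure to PDB or mmCIF
#'
#' Round-trips through [read_structure()] preserve atom counts, chain
#' labels, numbering and coordinates to format precision (3 decimals).
#'
#' @param s a `varstab_structure`.
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- s$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path,
                     type = ifelse(a$is_hetero, "HETATM", "ATOM"),
                     xyz = as.numeric(t(coords_matrix(a))),
                     resno = a$seq_pos, resid = a$resid, chain = a$chain,
                     elety = a$atom, eleno = seq_len(nrow(a)),
                     o = rep(1, nrow(a)), b = a$b, elesy = a$element)
  } else {
    lines <- c("data_varstab", "#", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "label_asym_id",
                        "label_entity_id", "label_seq_id",
                        "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                        "Cartn_z", "occupancy", "B_iso_or_equiv",
                        "pdbx_formal_charge", "auth_seq_id",
                        "auth_comp_id", "auth_asym_id", "auth_atom_id",
                        "pdbx_PDB_model_num")),
               sprintf(paste("%-6s %5d %-2s %-4s . %-3s %s 1 %5d ? %8.3f",
                             "%8.3f %8.3f %4.2f %6.2f ? %5d %-3s %s %-4s 1"),
                       ifelse(a$is_hetero, "HETATM", "ATOM"),
                       seq_len(nrow(a)), a$element, a$atom, a$resid,
                       a$chain, a$seq_pos, a$x, a$y, a$z, 1, a$b,
                       a$seq_pos, a$resid, a$chain, a$atom),
               "#")
    ok <- tryCatch({writeLines(lines, path); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("cannot write to '", path, "'", call. = FALSE)
  }
  invisible(path)
}

#' Renumber a chain into 1-based sequence coordinates
#'
#' @param s a `varstab_structure`.
#' @param chain chain label to renumber.
#' @param offset either a single integer added to every polymer residue
#'   number of the chain, or a named mapping (names = current numbers,
#'   values = new numbers). Mappings must be injective.
#' @return the renumbered structure; other chains untouched.
#' @export
apply_offset <- function(s, chain, offset) {
  a <- s$atoms
  idx <- which(a$chain == chain & !a$is_hetero)
  if (!length(idx)) stop("chain '", chain, "' has no polymer residues",
                         call. = FALSE)
  old <- a$seq_pos[idx]
  if (is.null(names(offset))) {
    stopifnot(length(offset) == 1L)
    new <- old + as.integer(offset)
  } else {
    map <- as.integer(offset)
    names(map) <- names(offset)
    if (anyDuplicated(map)) stop("offset mapping is not injective",
                                 call. = FALSE)
    missing <- setdiff(as.character(unique(old)), names(map))
    if (length(missing))
      stop("offset mapping lacks position(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    new <- unname(map[as.character(old)])
  }
  if (anyDuplicated(unique(cbind(old, new))[, "new"]))
    stop("renumbering collides: duplicate target positions", call. = FALSE)
  a$seq_pos[idx] <- new
  new_structure(a, s$source_kind, s$metadata)
}

#' Remove solvent and crystallisation additives
#'
#' Hetero groups whose residue code is listed are removed; polymer residues
#' and unlisted het groups (cofactors, ligands) are retained. Idempotent.
#'
#' @param s a `varstab_structure`.
#' @param exclusion_codes character vector of het codes (default: shipped
#'   solvent/additive list, see [default_solvent_codes()]).
#' @return the stripped structure.
#' @export
strip_solvent <- function(s, exclusion_codes = default_solvent_codes()) {
  if (!length(exclusion_codes)) return(s)
  a <- s$atoms
  drop <- a$is_hetero & a$resid %in% toupper(exclusion_codes)
  new_structure(a[!drop, , drop = FALSE], s$source_kind, s$metadata)
}

#' Shipped solvent/additive exclusion list
#'
#' Reads the editable list from the package's `extdata/solvent_codes.txt`
#' (one code per line, `#` comments); falls back to the built-in default.
#' @return character vector of het codes.
#' @export
default_solvent_codes <- function() {
  f <- system.file("extdata", "solvent_codes.txt", package = "varstab")
  if (nzchar(f)) {
    x <- readLines(f, warn = FALSE)
    x <- trimws(sub("#.*", "", x))
    x <- x[nzchar(x)]
    if (length(x)) return(toupper(x))
  }
  DEFAULT_SOLVENT_CODES
}

#' Relabel the chain of interest to 'A'
#'
#' Partner chains are retained. If another chain already holds the label
#' 'A' it is moved to the next free letter; all relabellings are recorded in
#' `metadata$partners` / `metadata$relabelled`. Idempotent when the target
#' is already 'A'.
#'
#' @param s a `varstab_structure`.
#' @param chain current label of the chain of interest.
#' @return structure with the target chain labelled 'A'.
#' @export
isolate_target_chain <- function(s, chain) {
  a <- s$atoms
  if (!chain %in% a$chain) stop("chain '", chain, "' not present",
                                call. = FALSE)
  others <- setdiff(chain_labels(s), chain)
  relabel <- list()
  if (!identical(chain, "A")) {
    if ("A" %in% others) {
      free <- setdiff(LETTERS, c("A", others))
      if (!length(free)) stop("no free chain label available")
      relabel[["A"]] <- free[1]
      a$chain[a$chain == "A"] <- "\rTMP"
    }
    a$chain[a$chain == chain] <- "A"
    if (length(relabel)) a$chain[a$chain == "\rTMP"] <- relabel[["A"]]
  }
  partners <- setdiff(unique(a$chain), "A")
  md <- s$metadata
  md$partners <- partners
  md$partner_chains_copied <- length(partners) > 0
  if (length(relabel)) md$relabelled <- relabel
  new_structure(a, s$source_kind, md)
}

#' Detect steric clash between two chains
#'
#' @param s a `varstab_structure`.
#' @param chain_a,chain_b chain labels.
#' @param cutoff clash cutoff in A (default 2.0): any inter-chain
#'   heavy-atom pair closer than this is a clash.
#' @return logical.
#' @export
detect_interchain_clash <- function(s, chain_a, chain_b, cutoff = 2.0) {
  a <- s$atoms
  for (ch in c(chain_a, chain_b))
    if (!ch %in% a$chain) stop("chain '", ch, "' not present", call. = FALSE)
  xa <- coords_matrix(a[a$chain == chain_a, , drop = FALSE])
  xb <- coords_matrix(a[a$chain == chain_b, , drop = FALSE])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  min(d2) < cutoff^2
}

#' Paint per-residue conservation scores into B-factors
#'
#' Every atom of a scored residue carries the score in its B-factor field;
#' unscored residues of the chain receive a sentinel value recorded in
#' `metadata$conservation_sentinel`.
#'
#' @param s a `varstab_structure`.
#' @param chain chain label.
#' @param scores named numeric vector, names are 1-based sequence positions.
#' @param sentinel value for unscored residues (default -1).
#' @return the painted structure.
#' @export
paint_conservation <- function(s, chain, scores, sentinel = -1) {
  a <- s$atoms
  idx <- a$chain == chain & !a$is_hetero
  a$b[idx] <- sentinel
  if (length(scores)) {
    pos <- as.integer(names(scores))
    for (i in seq_along(scores)) {
      a$b[idx & a$seq_pos == pos[i]] <- scores[i]
    }
  }
  md <- s$metadata
  md$conservation_sentinel <- sentinel
  new_structure(a, s$source_kind, md)
}
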