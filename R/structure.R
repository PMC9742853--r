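# The structure container: a flat atom table plus provenance, in the style
# of bio3d's pdb$atom but with positions already in 1-based sequence
# coordinates after renumbering.

#' Construct a structure object
#'
#' A structure is a flat atom table with provenance. Columns of `atoms`:
#' `chain` (label), `seq_pos` (integer residue number; 1-based sequence
#' position for polymer residues after renumbering), `resid` (3-letter
#' residue/het code), `atom` (atom name), `element`, `x`, `y`, `z`
#' (coordinates, A), `b` (B-factor; repurposed for conservation when
#' painted) and `is_hetero` (logical).
#'
#' @param atoms data.frame with the columns listed above.
#' @param source_kind one of `"experimental"`, `"homology"`, `"predicted"`,
#'   `"user"`, `"synthetic"`.
#' @param metadata free-form provenance list.
#' @return an object of class `varstab_structure`.
#' @export
new_structure <- function(atoms, source_kind = "user", metadata = list()) {
  required <- c("chain", "seq_pos", "resid", "atom", "element",
                "x", "y", "z", "b", "is_hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  atoms$seq_pos <- as.integer(atoms$seq_pos)
  rownames(atoms) <- NULL
  s <- structure(list(atoms = atoms, source_kind = source_kind,
                      metadata = metadata),
                 class = "varstab_structure")
  validate_structure(s)
}

#' @export
print.varstab_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("<varstab_structure> ", sum(!rt$is_hetero), " polymer residue(s), ",
      sum(rt$is_hetero), " het group(s), ", nrow(x$atoms), " atoms, chains: ",
      paste(chain_labels(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

validate_structure <- function(s) {
  a <- s$atoms
  if (nrow(a)) {
    if (any(!is.finite(c(a$x, a$y, a$z))))
      stop("non-finite coordinates in structure")
    if (any(!nzchar(a$element)))
      stop("empty element symbol in structure")
    pol <- a[!a$is_hetero, , drop = FALSE]
    if (nrow(pol)) {
      if (any(pol$seq_pos < 1L))
        stop("polymer residue with seq_pos < 1: renumber before use")
      key <- paste(pol$chain, pol$seq_pos)
      nres <- tapply(pol$resid, key, function(r) length(unique(r)))
      if (any(nres > 1))
        stop("duplicate polymer (chain, seq_pos): ", names(nres)[nres > 1][1])
      bb <- tapply(pol$atom, key, function(at) any(at %in% c("N", "CA", "C")))
      if (any(!bb))
        stop("polymer residue without backbone atoms: ",
             names(bb)[!bb][1])
    }
  }
  s
}

#' List chain labels of a structure
#' @param s a `varstab_structure`.
#' @return character vector of chain labels in order of first appearance.
#' @export
chain_labels <- function(s) unique(s$atoms$chain)

#' Per-residue summary table
#'
#' @param s a `varstab_structure`.
#' @return data.frame with one row per residue: `chain`, `seq_pos`, `resid`,
#'   `aa` (one-letter, `NA` for het groups), `is_hetero`, `n_atoms`.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  if (!nrow(a)) {
    return(data.frame(chain = character(), seq_pos = integer(),
                      resid = character(), aa = character(),
                      is_hetero = logical(), n_atoms = integer(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(a$chain, a$seq_pos, a$is_hetero, a$resid, sep = "\r")
  first <- !duplicated(key)
  rt <- data.frame(chain = a$chain[first], seq_pos = a$seq_pos[first],
                   resid = a$resid[first], is_hetero = a$is_hetero[first],
                   stringsAsFactors = FALSE)
  rt$aa <- ifelse(rt$is_hetero, NA_character_, aa_3to1(rt$resid))
  rt$n_atoms <- as.integer(table(key)[key[first]])
  rt[, c("chain", "seq_pos", "resid", "aa", "is_hetero", "n_atoms")]
}

#' Extract the one-letter sequence of a chain
#'
#' @param s a `varstab_structure`.
#' @param chain chain label.
#' @return named character vector of one-letter codes, names are sequence
#'   positions (gaps in coverage are simply absent).
#' @export
extract_sequence <- function(s, chain) {
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero & rt$chain == chain, , drop = FALSE]
  rt <- rt[order(rt$seq_pos), , drop = FALSE]
  structure(rt$aa, names = rt$seq_pos)
}

# Atom-index helper: rows of s$atoms for a (chain, seq_pos) polymer residue.
residue_rows <- function(s, chain, seq_pos, hetero = FALSE) {
  a <- s$atoms
  which(a$chain == chain & a$seq_pos == seq_pos & a$is_hetero == hetero)
}

# Coordinates as an n x 3 matrix.
coords_matrix <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}

get_atom_xyz <- function(s, chain, seq_pos, atom) {
  i <- which(s$atoms$chain == chain & s$atoms$seq_pos == seq_pos &
               s$atoms$atom == atom & !s$atoms$is_hetero)
  if (!length(i)) return(NULL)
  as.numeric(s$atoms[i[1], c("x", "y", "z")])
}

# Representative atom for the Cbeta distance rule: CB, CA for glycine (or
# any residue lacking CB).
cbeta_coords <- function(s) {
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero, , drop = FALSE]
  xyz <- matrix(NA_real_, nrow(rt), 3)
  for (i in seq_len(nrow(rt))) {
    p <- get_atom_xyz(s, rt$chain[i], rt$seq_pos[i], "CB")
    if (is.null(p)) p <- get_atom_xyz(s, rt$chain[i], rt$seq_pos[i], "CA")
    if (!is.null(p)) xyz[i, ] <- p
  }
  list(residues = rt, xyz = xyz)
}
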