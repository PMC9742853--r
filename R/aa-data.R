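# Amino-acid lookup tables used across the package. All maps are keyed by
# one-letter code; three-letter conversion helpers sit at the bottom.

#' @name aa_tables
#' @title Amino-acid property tables
#' @description
#' Per-residue constants: Kyte-Doolittle hydropathy, mean residue volumes
#' (A^3), theoretical maximum solvent-accessible surface areas (A^2) used to
#' normalise SASA into relative solvent accessibility, and van der Waals
#' radii per element (A).
#' @keywords internal
NULL

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- structure(names(AA3), names = unname(AA3))

# Kyte & Doolittle hydropathy index.
HYDROPATHY <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# Mean residue volumes (Zamyatnin-style), A^3.
RESIDUE_VOLUME <- c(A =  88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                    Q = 143.8, E = 138.4, G =  60.1, H = 153.2, I = 166.7,
                    L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                    S =  89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

# Theoretical maximum ASA (Tien et al. 2013), A^2; denominators for RSA.
MAX_ASA <- c(A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
             Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
             L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
             S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0)

# van der Waals radii per element, A. Unknown elements fall back to carbon.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Default solvent / crystallisation-additive codes stripped by
# strip_solvent(). Editable copy shipped in inst/extdata/solvent_codes.txt;
# metals are not listed by default because they can be cofactors.
DEFAULT_SOLVENT_CODES <- c("HOH", "DOD", "GOL", "EDO", "PEG", "SO4", "PO4",
                           "CL", "NA", "K")

#' Convert between one- and three-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return character vector of converted codes; unknown codes give `NA`.
#' @examples
#' aa_1to3("A")
#' aa_3to1("TRP")
#' @export
aa_1to3 <- function(x) unname(AA3[toupper(x)])

#' @rdname aa_1to3
#' @export
aa_3to1 <- function(x) unname(AA3_TO_1[toupper(x)])

is_aa1 <- function(x) !is.na(x) & x %in% AA1

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

# Formal charge of the representative atom of a charged sidechain group,
# 0 elsewhere: Arg CZ +1, Lys NZ +1, Asp CG -1, Glu CD -1.
atom_charge <- function(resid3, atom_name) {
  q <- numeric(length(resid3))
  q[resid3 == "ARG" & atom_name == "CZ"] <- 1
  q[resid3 == "LYS" & atom_name == "NZ"] <- 1
  q[resid3 == "ASP" & atom_name == "CG"] <- -1
  q[resid3 == "GLU" & atom_name == "CD"] <- -1
  q
}

#' Parse a substitution string
#'
#' Accepts `X123Y` or `p.X123Y` notation (one-letter codes).
#'
#' @param x substitution string.
#' @return a `substitution` object: list with `ref_aa`, `seq_pos`, `alt_aa`.
#' @examples
#' parse_substitution("p.A5G")
#' @export
parse_substitution <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", x))[[1]]
  if (length(m) != 4L)
    stop("malformed substitution '", x, "': expected X123Y or p.X123Y",
         call. = FALSE)
  ref <- toupper(m[2]); alt <- toupper(m[4]); pos <- as.integer(m[3])
  if (!is_aa1(ref) || !is_aa1(alt))
    stop("substitution '", x, "' uses a letter outside the 20 amino acids",
         call. = FALSE)
  if (pos < 1L) stop("substitution position must be >= 1", call. = FALSE)
  new_substitution(ref, pos, alt)
}

#' Construct a substitution
#' @param ref_aa,alt_aa one-letter amino-acid codes (identity allowed).
#' @param seq_pos 1-based sequence position.
#' @return a `substitution` object.
#' @export
new_substitution <- function(ref_aa, seq_pos, alt_aa) {
  stopifnot(is_aa1(ref_aa), is_aa1(alt_aa), seq_pos >= 1)
  structure(list(ref_aa = ref_aa, seq_pos = as.integer(seq_pos),
                 alt_aa = alt_aa),
            class = "substitution")
}

#' @export
format.substitution <- function(x, ...) {
  paste0(x$ref_aa, x$seq_pos, x$alt_aa)
}

#' @export
print.substitution <- function(x, ...) {
  cat("<substitution>", format(x), "\n"); invisible(x)
}
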