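# Ideal sidechain templates in internal coordinates. Each heavy atom beyond
# C-beta is placed by NeRF from three previously placed atoms with an ideal
# bond length (A), bond angle (deg) and a torsion that is either fixed or a
# chi angle (plus a rigid offset for branches). C-beta itself comes from the
# backbone via an ideal tetrahedral construction.

sc_row <- function(atom, element, a, b, c, bond, angle,
                   chi = NA_integer_, offset = 0, value = NA_real_) {
  data.frame(atom = atom, element = element, a = a, b = b, c = c,
             bond = bond, angle = angle, chi = chi, offset = offset,
             value = value, stringsAsFactors = FALSE)
}

SIDECHAIN_TEMPLATES <- list(
  G = NULL,
  A = NULL,    # C-beta only
  S = sc_row("OG", "O", "N", "CA", "CB", 1.417, 110.8, chi = 1L),
  C = sc_row("SG", "S", "N", "CA", "CB", 1.808, 113.8, chi = 1L),
  T = rbind(sc_row("OG1", "O", "N", "CA", "CB", 1.433, 109.6, chi = 1L),
            sc_row("CG2", "C", "N", "CA", "CB", 1.521, 110.5, chi = 1L,
                   offset = -120)),
  V = rbind(sc_row("CG1", "C", "N", "CA", "CB", 1.527, 110.5, chi = 1L),
            sc_row("CG2", "C", "N", "CA", "CB", 1.527, 110.5, chi = 1L,
                   offset = 122)),
  L = rbind(sc_row("CG",  "C", "N",  "CA", "CB", 1.530, 116.3, chi = 1L),
            sc_row("CD1", "C", "CA", "CB", "CG", 1.521, 110.7, chi = 2L),
            sc_row("CD2", "C", "CA", "CB", "CG", 1.521, 110.7, chi = 2L,
                   offset = 122)),
  I = rbind(sc_row("CG1", "C", "N",  "CA", "CB",  1.530, 110.4, chi = 1L),
            sc_row("CG2", "C", "N",  "CA", "CB",  1.521, 110.5, chi = 1L,
                   offset = -122),
            sc_row("CD1", "C", "CA", "CB", "CG1", 1.513, 113.8, chi = 2L)),
  M = rbind(sc_row("CG", "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1L),
            sc_row("SD", "S", "CA", "CB", "CG", 1.803, 112.7, chi = 2L),
            sc_row("CE", "C", "CB", "CG", "SD", 1.791, 100.9, chi = 3L)),
  F = rbind(sc_row("CG",  "C", "N",  "CA",  "CB",  1.502, 113.8, chi = 1L),
            sc_row("CD1", "C", "CA", "CB",  "CG",  1.384, 120.8, chi = 2L),
            sc_row("CD2", "C", "CA", "CB",  "CG",  1.384, 120.8, chi = 2L,
                   offset = 180),
            sc_row("CE1", "C", "CB", "CG",  "CD1", 1.382, 121.0, value = 180),
            sc_row("CE2", "C", "CB", "CG",  "CD2", 1.382, 121.0, value = 180),
            sc_row("CZ",  "C", "CG", "CD1", "CE1", 1.372, 120.0, value = 0)),
  Y = rbind(sc_row("CG",  "C", "N",   "CA",  "CB",  1.502, 113.8, chi = 1L),
            sc_row("CD1", "C", "CA",  "CB",  "CG",  1.384, 120.8, chi = 2L),
            sc_row("CD2", "C", "CA",  "CB",  "CG",  1.384, 120.8, chi = 2L,
                   offset = 180),
            sc_row("CE1", "C", "CB",  "CG",  "CD1", 1.382, 121.0, value = 180),
            sc_row("CE2", "C", "CB",  "CG",  "CD2", 1.382, 121.0, value = 180),
            sc_row("CZ",  "C", "CG",  "CD1", "CE1", 1.372, 120.0, value = 0),
            sc_row("OH",  "O", "CD1", "CE1", "CZ",  1.376, 119.9, value = 180)),
  W = rbind(sc_row("CG",  "C", "N",   "CA",  "CB",  1.498, 113.6, chi = 1L),
            sc_row("CD1", "C", "CA",  "CB",  "CG",  1.365, 126.9, chi = 2L),
            sc_row("CD2", "C", "CA",  "CB",  "CG",  1.433, 126.7, chi = 2L,
                   offset = 180),
            sc_row("NE1", "N", "CB",  "CG",  "CD1", 1.374, 110.2, value = 180),
            sc_row("CE2", "C", "CB",  "CG",  "CD2", 1.409, 107.2, value = 180),
            sc_row("CE3", "C", "CB",  "CG",  "CD2", 1.398, 133.9, value = 0),
            sc_row("CZ2", "C", "CG",  "CD2", "CE2", 1.394, 122.4, value = 180),
            sc_row("CZ3", "C", "CG",  "CD2", "CE3", 1.382, 118.6, value = 180),
            sc_row("CH2", "C", "CD2", "CE2", "CZ2", 1.368, 117.5, value = 0)),
  D = rbind(sc_row("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, chi = 1L),
            sc_row("OD1", "O", "CA", "CB", "CG", 1.249, 118.4, chi = 2L),
            sc_row("OD2", "O", "CA", "CB", "CG", 1.249, 118.4, chi = 2L,
                   offset = 180)),
  N = rbind(sc_row("CG",  "C", "N",  "CA", "CB", 1.516, 112.6, chi = 1L),
            sc_row("OD1", "O", "CA", "CB", "CG", 1.231, 120.8, chi = 2L),
            sc_row("ND2", "N", "CA", "CB", "CG", 1.328, 116.4, chi = 2L,
                   offset = 180)),
  E = rbind(sc_row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1L),
            sc_row("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, chi = 2L),
            sc_row("OE1", "O", "CB", "CG", "CD", 1.249, 118.4, chi = 3L),
            sc_row("OE2", "O", "CB", "CG", "CD", 1.249, 118.4, chi = 3L,
                   offset = 180)),
  Q = rbind(sc_row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1L),
            sc_row("CD",  "C", "CA", "CB", "CG", 1.516, 112.6, chi = 2L),
            sc_row("OE1", "O", "CB", "CG", "CD", 1.231, 120.8, chi = 3L),
            sc_row("NE2", "N", "CB", "CG", "CD", 1.328, 116.4, chi = 3L,
                   offset = 180)),
  K = rbind(sc_row("CG", "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1L),
            sc_row("CD", "C", "CA", "CB", "CG", 1.520, 111.3, chi = 2L),
            sc_row("CE", "C", "CB", "CG", "CD", 1.520, 111.3, chi = 3L),
            sc_row("NZ", "N", "CG", "CD", "CE", 1.489, 111.9, chi = 4L)),
  R = rbind(sc_row("CG",  "C", "N",  "CA", "CB", 1.520, 114.1, chi = 1L),
            sc_row("CD",  "C", "CA", "CB", "CG", 1.520, 111.3, chi = 2L),
            sc_row("NE",  "N", "CB", "CG", "CD", 1.461, 112.0, chi = 3L),
            sc_row("CZ",  "C", "CG", "CD", "NE", 1.329, 124.2, chi = 4L),
            sc_row("NH1", "N", "CD", "NE", "CZ", 1.326, 120.0, value = 0),
            sc_row("NH2", "N", "CD", "NE", "CZ", 1.326, 120.0, value = 180)),
  H = rbind(sc_row("CG",  "C", "N",  "CA", "CB",  1.492, 113.6, chi = 1L),
            sc_row("ND1", "N", "CA", "CB", "CG",  1.380, 122.7, chi = 2L),
            sc_row("CD2", "C", "CA", "CB", "CG",  1.354, 129.7, chi = 2L,
                   offset = 180),
            sc_row("CE1", "C", "CB", "CG", "ND1", 1.326, 109.3, value = 180),
            sc_row("NE2", "N", "CB", "CG", "CD2", 1.373, 107.2, value = 180)),
  P = rbind(sc_row("CG", "C", "N",  "CA", "CB", 1.492, 104.5, value = 30),
            sc_row("CD", "C", "CA", "CB", "CG", 1.503, 106.1, value = -35))
)

# Number of searchable chi torsions per amino acid (proline ring is fixed).
CHI_COUNT <- c(A = 0L, G = 0L, P = 0L,
               S = 1L, C = 1L, T = 1L, V = 1L,
               L = 2L, I = 2L, F = 2L, Y = 2L, W = 2L, D = 2L, N = 2L,
               H = 2L,
               M = 3L, E = 3L, Q = 3L,
               K = 4L, R = 4L)

#' Number of rotatable chi torsions of an amino acid
#' @param aa one-letter code.
#' @return integer count (0 for Gly/Ala/Pro).
#' @export
chi_count <- function(aa) {
  n <- CHI_COUNT[aa]
  if (any(is.na(n))) stop("no sidechain template for '",
                          aa[is.na(n)][1], "'", call. = FALSE)
  unname(n)
}

# Build sidechain heavy atoms (CB onwards) for amino acid `aa` on backbone
# positions n/ca/c (3-vectors), with the given chi torsions (deg). Returns
# a data.frame (atom, element, x, y, z); empty for glycine.
build_sidechain <- function(aa, n, ca, c, chi = numeric(0)) {
  if (aa == "G") {
    return(data.frame(atom = character(0), element = character(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      stringsAsFactors = FALSE))
  }
  if (!aa %in% AA1) stop("no sidechain template for '", aa, "'",
                         call. = FALSE)
  tmpl <- SIDECHAIN_TEMPLATES[[aa]]
  nchi <- CHI_COUNT[[aa]]
  if (length(chi) < nchi)
    chi <- c(chi, rep(-60, nchi - length(chi)))   # default gauche- fill
  pos <- list(N = n, CA = ca, C = c, CB = ideal_cbeta(n, ca, c))
  out_atom <- "CB"; out_el <- "C"
  out_xyz <- matrix(pos$CB, ncol = 3)
  if (!is.null(tmpl) && nrow(tmpl)) {
    for (i in seq_len(nrow(tmpl))) {
      r <- tmpl[i, ]
      tor <- if (is.na(r$chi)) r$value else chi[r$chi] + r$offset
      p <- place_atom(pos[[r$a]], pos[[r$b]], pos[[r$c]],
                      r$bond, r$angle, tor)
      pos[[r$atom]] <- p
      out_atom <- c(out_atom, r$atom)
      out_el <- c(out_el, r$element)
      out_xyz <- rbind(out_xyz, p)
    }
  }
  data.frame(atom = out_atom, element = out_el,
             x = out_xyz[, 1], y = out_xyz[, 2], z = out_xyz[, 3],
             stringsAsFactors = FALSE)
}

# Measure the chi torsions of a residue's atoms (data.frame with atom,x,y,z).
# Returns numeric vector of length chi_count(aa); NA where atoms missing.
measure_chi <- function(aa, atoms) {
  nchi <- CHI_COUNT[[aa]]
  if (is.na(nchi) || nchi == 0L) return(numeric(0))
  chain <- chi_atom_chain(aa)
  get <- function(nm) {
    i <- match(nm, atoms$atom)
    if (is.na(i)) return(NULL)
    as.numeric(atoms[i, c("x", "y", "z")])
  }
  vapply(seq_len(nchi), function(k) {
    quad <- lapply(chain[k:(k + 3)], get)
    if (any(vapply(quad, is.null, logical(1)))) return(NA_real_)
    dihedral(quad[[1]], quad[[2]], quad[[3]], quad[[4]])
  }, numeric(1))
}

# Atom-name chain defining chi1..chik as successive quadruples.
chi_atom_chain <- function(aa) {
  switch(aa,
         S = c("N", "CA", "CB", "OG"),
         C = c("N", "CA", "CB", "SG"),
         T = c("N", "CA", "CB", "OG1"),
         V = c("N", "CA", "CB", "CG1"),
         I = c("N", "CA", "CB", "CG1", "CD1"),
         L = c("N", "CA", "CB", "CG", "CD1"),
         F = ,
         Y = c("N", "CA", "CB", "CG", "CD1"),
         W = c("N", "CA", "CB", "CG", "CD1"),
         D = c("N", "CA", "CB", "CG", "OD1"),
         N = c("N", "CA", "CB", "CG", "OD1"),
         H = c("N", "CA", "CB", "CG", "ND1"),
         M = c("N", "CA", "CB", "CG", "SD", "CE"),
         E = c("N", "CA", "CB", "CG", "CD", "OE1"),
         Q = c("N", "CA", "CB", "CG", "CD", "OE1"),
         K = c("N", "CA", "CB", "CG", "CD", "CE", "NZ"),
         R = c("N", "CA", "CB", "CG", "CD", "NE", "CZ"),
         stop("no chi chain for '", aa, "'"))
}

# Replace the sidechain of a polymer residue with a template-built one for
# amino acid `aa` at torsions `chi`. Backbone N/CA/C/O untouched.
install_sidechain <- function(s, chain, seq_pos, aa, chi = numeric(0)) {
  rows <- residue_rows(s, chain, seq_pos)
  if (!length(rows)) stop("residue ", chain, seq_pos, " not found",
                          call. = FALSE)
  a <- s$atoms
  res <- a[rows, , drop = FALSE]
  bb <- res[res$atom %in% BACKBONE_ATOMS, , drop = FALSE]
  need <- c("N", "CA", "C")
  if (!all(need %in% bb$atom))
    stop("residue ", chain, seq_pos, " lacks backbone atoms", call. = FALSE)
  gxyz <- function(nm) as.numeric(bb[match(nm, bb$atom), c("x", "y", "z")])
  sc <- build_sidechain(aa, gxyz("N"), gxyz("CA"), gxyz("C"), chi)
  keep <- a[-rows, , drop = FALSE]
  newres <- bb
  newres$resid <- AA3[[aa]]
  if (nrow(sc)) {
    scrows <- data.frame(chain = chain, seq_pos = as.integer(seq_pos),
                         resid = AA3[[aa]], atom = sc$atom,
                         element = sc$element, x = sc$x, y = sc$y, z = sc$z,
                         b = bb$b[1], is_hetero = FALSE,
                         stringsAsFactors = FALSE)
    newres <- rbind(newres, scrows)
  }
  # keep original residue ordering: re-insert at the first original row
  at <- rbind(if (rows[1] > 1) keep[seq_len(rows[1] - 1), ],
              newres,
              if (rows[1] <= nrow(keep)) keep[rows[1]:nrow(keep), ])
  new_structure(at, s$source_kind, s$metadata)
}
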