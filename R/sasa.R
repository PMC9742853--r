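# Numerical solvent-accessible surface area (Shrake-Rupley) and relative
# solvent accessibility.

#' Solvent-accessible surface area per residue
#'
#' Shrake-Rupley numerical SASA: each heavy atom is covered with a
#' deterministic quasi-uniform point shell at radius r_vdw + probe; points
#' inside any other atom's expanded sphere are occluded. Per-residue sums.
#'
#' @param s a `varstab_structure`.
#' @param probe probe radius, A (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 92).
#' @param vdw_radii named per-element radii, A.
#' @return data.frame: `chain`, `seq_pos`, `resid`, `is_hetero`, `sasa`
#'   (A^2).
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 92L,
                         vdw_radii = VDW_RADII) {
  a <- s$atoms
  el <- toupper(a$element)
  r <- unname(vdw_radii[el])
  r[is.na(r)] <- vdw_radii[["C"]]
  re <- r + probe
  xyz <- coords_matrix(a)
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  atom_sasa <- numeric(n)
  if (n) {
    d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
    for (i in seq_len(n)) {
      reach <- (re[i] + re)^2
      nb <- which(d2[i, ] < reach & seq_len(n) != i)
      shell <- sweep(pts * re[i], 2, xyz[i, ], "+")
      if (length(nb)) {
        acc <- rep(TRUE, n_points)
        for (j in nb) {
          dd <- sweep(shell, 2, xyz[j, ], "-")
          acc <- acc & (rowSums(dd^2) >= re[j]^2)
          if (!any(acc)) break
        }
        frac <- sum(acc) / n_points
      } else frac <- 1
      atom_sasa[i] <- frac * 4 * pi * re[i]^2
    }
  }
  key <- paste(a$chain, a$seq_pos, a$is_hetero, a$resid, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], seq_pos = a$seq_pos[first],
                    resid = a$resid[first], is_hetero = a$is_hetero[first],
                    stringsAsFactors = FALSE)
  out$sasa <- as.numeric(tapply(atom_sasa, key, sum)[key[first]])
  out
}

#' Relative solvent accessibility
#'
#' Absolute SASA divided by the shipped per-amino-acid maximum attainable
#' ASA, clamped to `[0, 1]`.
#'
#' @param abs_sasa absolute SASA, A^2.
#' @param aa one-letter amino-acid code.
#' @return RSA in `[0, 1]`.
#' @export
relative_sasa <- function(abs_sasa, aa) {
  stopifnot(abs_sasa >= 0)
  mx <- MAX_ASA[aa]
  if (any(is.na(mx)))
    stop("unknown amino acid '", aa[is.na(mx)][1], "'", call. = FALSE)
  pmin(1, pmax(0, abs_sasa / unname(mx)))
}

# RSA of one residue of a structure.
residue_rsa <- function(s, chain, seq_pos, probe = 1.4, n_points = 92L) {
  sa <- compute_sasa(s, probe = probe, n_points = n_points)
  row <- sa[sa$chain == chain & sa$seq_pos == seq_pos & !sa$is_hetero, ]
  if (!nrow(row)) stop("residue ", chain, seq_pos, " not found",
                       call. = FALSE)
  aa <- aa_3to1(row$resid[1])
  if (is.na(aa)) stop("residue ", chain, seq_pos, " is not a standard ",
                      "amino acid", call. = FALSE)
  relative_sasa(row$sasa[1], aa)
}
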