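# The empirical pairwise energy behind the repack/minimise protocol. The
# functional form is deliberately simple (soft-sphere repulsion, a
# carbon-carbon contact well, a distance-ramped hydrogen bond between N/O
# atoms, screened Coulomb between charged-group representative atoms plus
# per-residue reference constants); the protocol around it - neighbourhood
# selection, cycles, mutate-between-repacks, corrections, display cap - is
# the method. The backend is pluggable: see `backend` in ddg_settings().

#' Energy-function parameters
#'
#' @param k_rep soft-sphere repulsion constant, kcal/(mol A^2).
#' @param eps_contact carbon-carbon contact well depth, kcal/mol.
#' @param eps_hbond hydrogen-bond well depth (N/O donor-acceptor pairs),
#'   kcal/mol.
#' @param coulomb_scale Coulomb prefactor, kcal A/mol.
#' @param dielectric_slope distance-dependent dielectric slope (1/A):
#'   eps(d) = slope * d.
#' @param vdw_radii named per-element van der Waals radii, A.
#' @param reference_energies named per-amino-acid constants, kcal/mol
#'   (default all zero).
#' @param contact_cutoff outer cutoff of the contact ramp, A.
#' @param hbond_window numeric length 2: donor-acceptor distance window, A.
#' @return a list of class `energy_params`.
#' @export
energy_params <- function(k_rep = 10, eps_contact = 0.1, eps_hbond = 1.0,
                          coulomb_scale = 332, dielectric_slope = 4,
                          vdw_radii = VDW_RADII,
                          reference_energies = stats::setNames(rep(0, 20), AA1),
                          contact_cutoff = 6.0,
                          hbond_window = c(2.4, 3.5)) {
  stopifnot(k_rep >= 0, eps_contact >= 0, eps_hbond >= 0,
            coulomb_scale >= 0, dielectric_slope > 0,
            length(hbond_window) == 2, hbond_window[1] <= hbond_window[2])
  structure(list(k_rep = k_rep, eps_contact = eps_contact,
                 eps_hbond = eps_hbond, coulomb_scale = coulomb_scale,
                 dielectric_slope = dielectric_slope, vdw_radii = vdw_radii,
                 reference_energies = reference_energies,
                 contact_cutoff = contact_cutoff,
                 hbond_window = hbond_window),
            class = "energy_params")
}

# Per-atom scoring attributes for the C++ kernel.
atom_arrays <- function(s, params) {
  a <- s$atoms
  el <- toupper(a$element)
  radius <- unname(params$vdw_radii[el])
  radius[is.na(radius)] <- params$vdw_radii[["C"]]
  rkey <- paste(a$chain, a$seq_pos, a$is_hetero, a$resid, sep = "\r")
  rid <- as.integer(factor(rkey, levels = unique(rkey)))
  list(xyz = coords_matrix(a),
       radius = radius,
       isC = as.integer(el == "C"),
       isNO = as.integer(el %in% c("N", "O")),
       charge = atom_charge(a$resid, a$atom),
       rid = as.integer(rid),
       chain_id = as.integer(factor(a$chain, levels = unique(a$chain))),
       seq_pos = a$seq_pos,
       is_bb = as.integer(!a$is_hetero & a$atom %in% BACKBONE_ATOMS))
}

selection_mask <- function(s, selection) {
  a <- s$atoms
  key <- paste(a$chain, a$seq_pos)
  skey <- paste(selection$chain, selection$seq_pos)
  as.integer(key %in% skey & !a$is_hetero)
}

#' Score a residue selection under the empirical energy
#'
#' Sums the pairwise energy over nonbonded heavy-atom pairs with at least
#' one atom in the selection (all pairs when `neighbourhood_only = FALSE`),
#' excluding intra-residue pairs and backbone-backbone pairs of
#' sequence-adjacent residues, plus the per-residue reference energies of
#' the selection.
#'
#' @param s a `varstab_structure`.
#' @param selection data.frame with columns `chain`, `seq_pos`.
#' @param params an [energy_params()] list.
#' @param neighbourhood_only score only pairs touching the selection
#'   (default `TRUE`, the "score only the minimised neighbourhood"
#'   correction).
#' @return energy in kcal/mol.
#' @export
score_selection <- function(s, selection, params = energy_params(),
                            neighbourhood_only = TRUE) {
  if (!nrow(selection)) stop("empty selection", call. = FALSE)
  ar <- atom_arrays(s, params)
  sel <- selection_mask(s, selection)
  e <- cpp_score_pairs(ar$xyz, ar$radius, ar$isC, ar$isNO, ar$charge,
                       ar$rid, ar$chain_id, ar$seq_pos, ar$is_bb, sel,
                       neighbourhood_only, params[c("k_rep", "eps_contact",
                                                    "contact_cutoff",
                                                    "eps_hbond",
                                                    "hbond_window",
                                                    "coulomb_scale",
                                                    "dielectric_slope")])
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero, , drop = FALSE]
  key <- paste(rt$chain, rt$seq_pos)
  insel <- key %in% paste(selection$chain, selection$seq_pos)
  refs <- params$reference_energies[rt$aa[insel]]
  e + sum(refs, na.rm = TRUE)
}
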