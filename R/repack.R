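# Deterministic sidechain repacking: per-residue exhaustive grid search
# over chi torsions rebuilt from the ideal templates, greedy sequential
# visits, backbone fixed.

CHI12_GRID <- seq(-180, 150, by = 30)   # chi1, chi2: 30 degree steps
CHI34_GRID <- c(-180, -60, 60)          # chi3, chi4: 120 degree steps

# All chi vectors of an amino acid, in ascending lexicographic order
# (chi1 major). Matrix with chi_count columns; 1-row zero-column matrix for
# residues without rotatable torsions.
chi_grid <- function(aa) {
  k <- CHI_COUNT[[aa]]
  if (k == 0L) return(matrix(numeric(0), nrow = 1, ncol = 0))
  vals <- lapply(seq_len(k), function(i)
    if (i <= 2) CHI12_GRID else CHI34_GRID)
  g <- as.matrix(do.call(expand.grid, rev(vals)))
  g <- g[, rev(seq_len(k)), drop = FALSE]
  colnames(g) <- paste0("chi", seq_len(k))
  unname(g)
}

# Vectorised NeRF: place one atom for G candidates at once. a, b, c are
# G x 3 matrices, torsion a length-G vector (deg); bond/angle scalars.
place_atom_m <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- c - b
  bc <- bc / sqrt(rowSums(bc^2))
  ab <- b - a
  n <- cbind(ab[, 2] * bc[, 3] - ab[, 3] * bc[, 2],
             ab[, 3] * bc[, 1] - ab[, 1] * bc[, 3],
             ab[, 1] * bc[, 2] - ab[, 2] * bc[, 1])
  n <- n / sqrt(rowSums(n^2))
  m <- cbind(n[, 2] * bc[, 3] - n[, 3] * bc[, 2],
             n[, 3] * bc[, 1] - n[, 1] * bc[, 3],
             n[, 1] * bc[, 2] - n[, 2] * bc[, 1])
  d1 <- -bond * cos(ang)
  d2 <- bond * sin(ang) * cos(tor)
  d3 <- bond * sin(ang) * sin(tor)
  c + d1 * bc + d2 * m + d3 * n
}

# Candidate sidechain coordinate stack for a residue: all grid chi vectors,
# rows grouped in blocks of n_atoms (built simultaneously for the whole
# grid). Returns list(grid, xyz, atoms, elements, n_atoms).
candidate_stack <- function(aa, n, ca, c) {
  grid <- chi_grid(aa)
  G <- nrow(grid)
  tmpl <- SIDECHAIN_TEMPLATES[[aa]]
  cb <- ideal_cbeta(n, ca, c)
  ones <- rep(1, G)
  pos <- list(N = outer(ones, n), CA = outer(ones, ca),
              C = outer(ones, c), CB = outer(ones, cb))
  atoms <- "CB"; elements <- "C"
  if (!is.null(tmpl) && nrow(tmpl)) {
    for (i in seq_len(nrow(tmpl))) {
      r <- tmpl[i, ]
      tor <- if (is.na(r$chi)) rep(r$value, G) else grid[, r$chi] + r$offset
      pos[[r$atom]] <- place_atom_m(pos[[r$a]], pos[[r$b]], pos[[r$c]],
                                    r$bond, r$angle, tor)
      atoms <- c(atoms, r$atom)
      elements <- c(elements, r$element)
    }
  }
  n_atoms <- length(atoms)
  # interleave: block g holds atoms 1..n_atoms of candidate g
  xyz <- matrix(0, G * n_atoms, 3)
  for (k in seq_len(n_atoms))
    xyz[seq(k, by = n_atoms, length.out = G), ] <- pos[[atoms[k]]]
  list(grid = grid, xyz = xyz, atoms = atoms, elements = elements,
       n_atoms = n_atoms)
}

cpp_par <- function(params) {
  params[c("k_rep", "eps_contact", "contact_cutoff", "eps_hbond",
           "hbond_window", "coulomb_scale", "dielectric_slope")]
}

# Energy of a set of candidate sidechains against a fixed environment.
env_energies <- function(cand_xyz, n_atoms, atoms, elements, resid3,
                         env, params) {
  el <- toupper(elements)
  cr <- unname(params$vdw_radii[el]); cr[is.na(cr)] <- params$vdw_radii[["C"]]
  cpp_candidate_energies(cand_xyz, n_atoms, cr,
                         as.integer(el == "C"),
                         as.integer(el %in% c("N", "O")),
                         atom_charge(rep(resid3, n_atoms), atoms),
                         env$xyz, env$radius, env$isC, env$isNO,
                         env$charge, cpp_par(params))
}

env_arrays <- function(atoms_df, params) {
  el <- toupper(atoms_df$element)
  r <- unname(params$vdw_radii[el]); r[is.na(r)] <- params$vdw_radii[["C"]]
  list(xyz = coords_matrix(atoms_df), radius = r,
       isC = as.integer(el == "C"),
       isNO = as.integer(el %in% c("N", "O")),
       charge = atom_charge(atoms_df$resid, atoms_df$atom))
}

#' Repack sidechains of a residue selection
#'
#' For each of `settings$cycles` passes the selection residues are visited
#' in ascending distance from `origin` (C-beta rule); each visited residue
#' is subjected to an exhaustive grid search over its chi torsions (chi1,
#' chi2 at 30 degree steps; chi3, chi4 at 120 degree steps), sidechains
#' rebuilt from the ideal internal-coordinate templates, keeping the
#' assignment that minimises the selection score. With `reject_worse` the
#' previous conformation is retained unless the total strictly improves.
#' Backbones never move. Fully deterministic: fixed visit order, candidate
#' ties resolved to the lexicographically smallest torsion vector.
#'
#' @param s a `varstab_structure`.
#' @param selection data.frame with `chain`, `seq_pos`: residues to repack.
#' @param settings a [ddg_settings()] list.
#' @param origin optional list(`chain`, `seq_pos`) used for the visit
#'   order; defaults to the first selection row.
#' @param score_selection_df optional larger selection used for the
#'   per-cycle audit score (defaults to `selection`).
#' @param stack_cache optional environment memoising candidate sidechain
#'   coordinate stacks across repacks of the same (backbone-fixed)
#'   structure.
#' @return the repacked structure; `metadata$repack_trace` holds the
#'   per-cycle selection score.
#' @export
repack <- function(s, selection, settings = ddg_settings(), origin = NULL,
                   score_selection_df = NULL, stack_cache = NULL) {
  params <- settings$energy_params
  if (is.null(score_selection_df)) score_selection_df <- selection
  if (!nrow(selection)) {
    md <- s$metadata
    md$repack_trace <- score_selection(
      s, score_selection_df, params,
      settings$corrections$score_neighbourhood_only)
    return(new_structure(s$atoms, s$source_kind, md))
  }
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero, , drop = FALSE]
  skey <- paste(selection$chain, selection$seq_pos)
  sel_rt <- rt[paste(rt$chain, rt$seq_pos) %in% skey, , drop = FALSE]
  if (any(is.na(sel_rt$aa)))
    stop("selection contains a non-standard residue: no sidechain template",
         call. = FALSE)
  if (is.null(origin))
    origin <- list(chain = selection$chain[1],
                   seq_pos = selection$seq_pos[1])
  cb <- cbeta_coords(s)
  okey <- which(cb$residues$chain == origin$chain &
                  cb$residues$seq_pos == origin$seq_pos)
  dvec <- sqrt(rowSums(sweep(cb$xyz, 2, cb$xyz[okey, ], "-")^2))
  names(dvec) <- paste(cb$residues$chain, cb$residues$seq_pos)
  sel_rt$dist <- dvec[paste(sel_rt$chain, sel_rt$seq_pos)]
  sel_rt <- sel_rt[order(sel_rt$dist, sel_rt$chain, sel_rt$seq_pos), ,
                   drop = FALSE]
  sel_rt <- sel_rt[CHI_COUNT[sel_rt$aa] > 0L, , drop = FALSE]

  at <- s$atoms
  if (is.null(stack_cache)) stack_cache <- new.env(parent = emptyenv())
  trace <- numeric(0)
  for (cycle in seq_len(settings$cycles)) {
    for (i in seq_len(nrow(sel_rt))) {
      ch <- sel_rt$chain[i]; pos <- sel_rt$seq_pos[i]; aa <- sel_rt$aa[i]
      rows <- which(at$chain == ch & at$seq_pos == pos & !at$is_hetero)
      res <- at[rows, , drop = FALSE]
      bbrows <- rows[res$atom %in% BACKBONE_ATOMS]
      scrows <- setdiff(rows, bbrows)
      key <- paste(ch, pos, aa)
      st <- stack_cache[[key]]
      if (is.null(st)) {
        gx <- function(nm) as.numeric(res[match(nm, res$atom),
                                          c("x", "y", "z")])
        st <- candidate_stack(aa, gx("N"), gx("CA"), gx("C"))
        stack_cache[[key]] <- st
      }
      env <- env_arrays(at[-rows, , drop = FALSE], params)
      cand_e <- env_energies(st$xyz, st$n_atoms, st$atoms, st$elements,
                             AA3[[aa]], env, params)
      cur <- at[scrows, , drop = FALSE]
      cur_e <- if (nrow(cur))
        env_energies(as.matrix(cur[, c("x", "y", "z")]), nrow(cur),
                     cur$atom, cur$element, AA3[[aa]], env, params)
      else Inf
      best <- which.min(cand_e)
      accept <- if (settings$corrections$reject_worse)
        cand_e[best] < cur_e else TRUE
      if (accept) {
        blk <- ((best - 1) * st$n_atoms + 1):(best * st$n_atoms)
        newsc <- data.frame(chain = ch, seq_pos = pos, resid = AA3[[aa]],
                            atom = st$atoms, element = st$elements,
                            x = st$xyz[blk, 1], y = st$xyz[blk, 2],
                            z = st$xyz[blk, 3], b = res$b[1],
                            is_hetero = FALSE, stringsAsFactors = FALSE)
        keep <- at[-rows, , drop = FALSE]
        ins <- rows[1]
        at <- rbind(if (ins > 1) keep[seq_len(ins - 1), , drop = FALSE],
                    at[bbrows, , drop = FALSE], newsc,
                    if (ins <= nrow(keep))
                      keep[ins:nrow(keep), , drop = FALSE])
        rownames(at) <- NULL
      }
    }
    stmp <- new_structure(at, s$source_kind, s$metadata)
    trace <- c(trace, score_selection(
      stmp, score_selection_df, params,
      settings$corrections$score_neighbourhood_only))
  }
  md <- s$metadata
  md$repack_trace <- trace
  new_structure(at, s$source_kind, md)
}
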