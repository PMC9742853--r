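# Synthetic fixture generators: ideal-geometry structures, annotation
# tables and benchmark datasets with known ground truth. Everything any
# other module consumes can be generated here offline, seed-stable.

# Ideal backbone bond lengths (A) and angles (deg).
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

# Build a polypeptide chain from phi/psi/omega torsions with ideal bond
# geometry and template sidechains. `chi_default` fills every chi angle.
build_chain <- function(sequence, phi, psi, omega = 180, chain = "A",
                        chi_default = -60, start_pos = 1L) {
  seqv <- strsplit(toupper(sequence), "")[[1]]
  bad <- !is_aa1(seqv)
  if (any(bad)) stop("invalid amino-acid letter '", seqv[bad][1], "'",
                     call. = FALSE)
  nres <- length(seqv)
  phi <- rep_len(phi, nres); psi <- rep_len(psi, nres)
  omega <- rep_len(omega, nres)
  g <- BB_GEOM
  N <- vector("list", nres); CA <- vector("list", nres)
  C <- vector("list", nres); O <- vector("list", nres)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  a <- deg2rad(g$ang_n_ca_c)
  C[[1]] <- CA[[1]] + g$ca_c * c(cos(pi - a), sin(pi - a), 0)
  for (i in seq_len(nres)) {
    if (i < nres) {
      N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                               g$c_n, g$ang_ca_c_n, psi[i])
      CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                                g$n_ca, g$ang_c_n_ca, omega[i])
      C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                               g$ca_c, g$ang_n_ca_c, phi[i + 1])
    }
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         g$c_o, g$ang_ca_c_o, psi[i] + 180)
  }
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    aa <- seqv[i]
    bb <- data.frame(atom = c("N", "CA", "C", "O"),
                     element = c("N", "C", "C", "O"),
                     x = c(N[[i]][1], CA[[i]][1], C[[i]][1], O[[i]][1]),
                     y = c(N[[i]][2], CA[[i]][2], C[[i]][2], O[[i]][2]),
                     z = c(N[[i]][3], CA[[i]][3], C[[i]][3], O[[i]][3]),
                     stringsAsFactors = FALSE)
    sc <- build_sidechain(aa, N[[i]], CA[[i]], C[[i]],
                          rep(chi_default, CHI_COUNT[[aa]]))
    res <- rbind(bb, sc)
    rows[[i]] <- data.frame(chain = chain,
                            seq_pos = start_pos + i - 1L,
                            resid = AA3[[aa]], atom = res$atom,
                            element = res$element,
                            x = res$x, y = res$y, z = res$z,
                            b = 0, is_hetero = FALSE,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Build an ideal alpha-helix
#'
#' Ideal backbone (phi = -57, psi = -47, omega = 180, ideal bond geometry)
#' with template sidechains at default torsions. Deterministic.
#'
#' @param sequence one-letter amino-acid string.
#' @param chain chain label.
#' @return a `varstab_structure` (source_kind `"synthetic"`).
#' @export
build_helix <- function(sequence, chain = "A") {
  new_structure(build_chain(sequence, phi = -57, psi = -47, chain = chain),
                source_kind = "synthetic",
                metadata = list(conformation = "helix"))
}

#' Build an extended chain
#'
#' phi = -120, psi = 120; central residues maximally solvent-exposed, the
#' reference state for relative solvent accessibility checks.
#'
#' @inheritParams build_helix
#' @return a `varstab_structure`.
#' @export
build_extended <- function(sequence, chain = "A") {
  new_structure(build_chain(sequence, phi = -120, psi = 120, chain = chain),
                source_kind = "synthetic",
                metadata = list(conformation = "extended"))
}

#' Build a two-chain fixture
#'
#' Two ideal helices, the second translated by `separation` along the
#' inter-chain axis; small separations create steric clashes, large ones do
#' not. Used for partner-chain and clash tests.
#'
#' @param seq_a,seq_b sequences of chains A and B.
#' @param separation inter-chain translation in A.
#' @return a `varstab_structure`.
#' @export
build_two_chain <- function(seq_a, seq_b, separation = 10) {
  a <- build_chain(seq_a, phi = -57, psi = -47, chain = "A")
  b <- build_chain(seq_b, phi = -57, psi = -47, chain = "B")
  b$y <- b$y + separation
  new_structure(rbind(a, b), source_kind = "synthetic",
                metadata = list(conformation = "two_chain",
                                separation = separation))
}

#' Build a packed-cluster fixture (buried target site)
#'
#' One target residue whose sidechain site is enclosed by a spherical shell
#' of inward-pointing residues, giving a target relative solvent
#' accessibility below 0.05 and violent steric clashes for bulky
#' substitutions: the test-bed for burial and for the ">10 kcal/mol"
#' display cap.
#'
#' @param core_aa one-letter code of the target residue (default `"G"`).
#' @param shell_count number of shell residues (>= 8, default 16).
#' @param seed integer; small seed-derived jitter makes distinct but
#'   reproducible fixtures.
#' @param shell_radius distance of shell C-alpha atoms from the target
#'   C-alpha, A.
#' @param shell_aa one-letter code of shell residues.
#' @return a `varstab_structure`; the target is chain "A" position 1, shell
#'   residues sit at odd positions 3, 5, ... (no peptide bonds to the
#'   target, so no adjacency exclusions apply).
#' @export
build_packed_cluster <- function(core_aa = "G", shell_count = 16L,
                                 seed = 1L, shell_radius = 6.0,
                                 shell_aa = "L") {
  if (shell_count < 8L) stop("shell_count must be >= 8", call. = FALSE)
  stopifnot(is_aa1(core_aa), is_aa1(shell_aa))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  g <- BB_GEOM
  # target residue backbone centred at origin
  n0 <- c(-g$n_ca, 0, 0); ca0 <- c(0, 0, 0)
  a <- deg2rad(g$ang_n_ca_c)
  c0 <- ca0 + g$ca_c * c(-cos(pi - a), sin(pi - a), 0)
  o0 <- place_atom(n0, ca0, c0, g$c_o, g$ang_ca_c_o, 120)
  tgt_sc <- build_sidechain(core_aa, n0, ca0, c0,
                            rep(-60, CHI_COUNT[[core_aa]]))
  tgt <- data.frame(atom = c("N", "CA", "C", "O", tgt_sc$atom),
                    element = c("N", "C", "C", "O", tgt_sc$element),
                    x = c(n0[1], ca0[1], c0[1], o0[1], tgt_sc$x),
                    y = c(n0[2], ca0[2], c0[2], o0[2], tgt_sc$y),
                    z = c(n0[3], ca0[3], c0[3], o0[3], tgt_sc$z),
                    stringsAsFactors = FALSE)
  tgt <- data.frame(chain = "A", seq_pos = 1L, resid = AA3[[core_aa]],
                    atom = tgt$atom, element = tgt$element,
                    x = tgt$x, y = tgt$y, z = tgt$z, b = 0,
                    is_hetero = FALSE, stringsAsFactors = FALSE)
  dirs <- sphere_points(shell_count)
  jitter <- matrix(stats::rnorm(shell_count * 3, sd = 0.02),
                   ncol = 3)
  rows <- list(tgt)
  for (k in seq_len(shell_count)) {
    u <- unitv(dirs[k, ] + jitter[k, ])
    ca <- shell_radius * u
    # tangent frame
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- unitv(vcross(u, ref)); t2 <- vcross(u, t1)
    half <- deg2rad(g$ang_n_ca_c / 2)
    an <- cos(half) * u + sin(half) * t1
    ac <- cos(half) * u - sin(half) * t1
    n <- ca + g$n_ca * an
    cc <- ca + g$ca_c * ac
    o <- place_atom(n, ca, cc, g$c_o, g$ang_ca_c_o, 120)
    sc <- build_sidechain(shell_aa, n, ca, cc,
                          rep(180, CHI_COUNT[[shell_aa]]))
    res <- data.frame(atom = c("N", "CA", "C", "O", sc$atom),
                      element = c("N", "C", "C", "O", sc$element),
                      x = c(n[1], ca[1], cc[1], o[1], sc$x),
                      y = c(n[2], ca[2], cc[2], o[2], sc$y),
                      z = c(n[3], ca[3], cc[3], o[3], sc$z),
                      stringsAsFactors = FALSE)
    rows[[k + 1]] <- data.frame(chain = "A",
                                seq_pos = 1L + 2L * k,
                                resid = AA3[[shell_aa]],
                                atom = res$atom, element = res$element,
                                x = res$x, y = res$y, z = res$z, b = 0,
                                is_hetero = FALSE, stringsAsFactors = FALSE)
  }
  new_structure(do.call(rbind, rows), source_kind = "synthetic",
                metadata = list(conformation = "packed_cluster",
                                target = list(chain = "A", seq_pos = 1L),
                                seed = seed))
}

#' Generate synthetic annotation tables
#'
#' Emulates the tabular inputs a live deployment would pull from sequence
#' feature, population-variant, clinical-variant and PTM databases:
#' uniform random positions, log-uniform allele frequencies in
#' [1e-6, 1e-2], Poisson homozygote counts, random feature intervals and
#' PTM sites. A ground-truth manifest of the generated counts is attached
#' as attribute `"manifest"`.
#'
#' @param sequence protein sequence the tables refer to.
#' @param seed integer seed; fixed seed gives identical tables.
#' @param features,popvars,clinvars,ptms densities per 100 residues.
#' @return an [new_annotation_set()] object with attribute `manifest`.
#' @export
synth_annotations <- function(sequence, seed = 1L, features = 10,
                              popvars = 20, clinvars = 10, ptms = 10) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  seqv <- strsplit(toupper(sequence), "")[[1]]
  n <- length(seqv)
  count <- function(dens) stats::rpois(1, dens * n / 100)
  nf <- count(features); npv <- count(popvars)
  ncv <- count(clinvars); npt <- count(ptms)
  rand_alt <- function(ref) {
    vapply(ref, function(r) sample(setdiff(AA1, r), 1), character(1))
  }
  fstart <- if (nf) sample.int(n, nf, replace = TRUE) else integer(0)
  flen <- if (nf) sample.int(8, nf, replace = TRUE) else integer(0)
  feats <- data.frame(name = if (nf) sprintf("feat%02d", seq_len(nf)) else character(0),
                      category = if (nf) sample(c("domain", "binding site",
                                                  "transmembrane", "signal"),
                                                nf, replace = TRUE) else character(0),
                      start = fstart, end = pmin(fstart + flen, n),
                      source = if (nf) rep("synthetic", nf) else character(0),
                      stringsAsFactors = FALSE)
  ppos <- if (npv) sample.int(n, npv, replace = TRUE) else integer(0)
  pv <- data.frame(seq_pos = ppos, ref_aa = seqv[ppos],
                   alt_aa = rand_alt(seqv[ppos]),
                   allele_frequency = 10^stats::runif(npv, -6, -2),
                   homozygote_count = stats::rpois(npv, 0.3),
                   stringsAsFactors = FALSE)
  cpos <- if (ncv) sample.int(n, ncv, replace = TRUE) else integer(0)
  cv <- data.frame(seq_pos = cpos, ref_aa = seqv[cpos],
                   alt_aa = rand_alt(seqv[cpos]),
                   significance = if (ncv) sample(c("pathogenic", "benign",
                                                    "other"),
                                                  ncv, replace = TRUE,
                                                  prob = c(.4, .4, .2)) else character(0),
                   stringsAsFactors = FALSE)
  tpos <- if (npt) sample.int(n, npt, replace = TRUE) else integer(0)
  pt <- data.frame(seq_pos = tpos,
                   modification = if (npt) sample(c("phosphorylation",
                                                    "ubiquitination",
                                                    "acetylation"),
                                                  npt, replace = TRUE) else character(0),
                   evidence = if (npt) sample(c("curated", "high_throughput"),
                                              npt, replace = TRUE) else character(0),
                   stringsAsFactors = FALSE)
  cons <- stats::runif(n)
  names(cons) <- seq_len(n)
  ann <- new_annotation_set(features = feats, popvars = pv, clinvars = cv,
                            ptms = pt, conservation = cons)
  attr(ann, "manifest") <- list(seed = seed, n_residues = n,
                                n_features = nf, n_popvars = npv,
                                n_clinvars = ncv, n_ptms = npt)
  ann
}

#' Generate a synthetic benchmark dataset
#'
#' Random substitutions on a structure are scored with [ddg_protocol()] as
#' ground truth; "experimental" values are the truth plus Gaussian noise.
#' The true values are kept in the `true_ddg` column for recovery tests.
#'
#' @param s a `varstab_structure`.
#' @param chain chain label.
#' @param n number of benchmark records.
#' @param noise_sd standard deviation (kcal/mol) of the additive noise.
#' @param seed integer seed.
#' @param settings a [ddg_settings()] list.
#' @return data.frame with columns `id`, `variant`, `predicted_ddg`,
#'   `experimental_ddg`, `true_ddg`.
#' @export
synth_benchmark <- function(s, chain = "A", n = 50, noise_sd = 1.0,
                            seed = 1L, settings = ddg_settings()) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero & rt$chain == chain & !is.na(rt$aa), , drop = FALSE]
  pick <- sample.int(nrow(rt), n, replace = TRUE)
  alts <- vapply(rt$aa[pick], function(r) sample(setdiff(AA1, r), 1),
                 character(1))
  noise <- stats::rnorm(n, 0, noise_sd)
  out <- data.frame(id = sprintf("var%04d", seq_len(n)),
                    variant = paste0(rt$aa[pick], rt$seq_pos[pick], alts),
                    predicted_ddg = NA_real_, experimental_ddg = NA_real_,
                    true_ddg = NA_real_, stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())   # backbone fixed: stacks shared
  for (i in seq_len(n)) {
    sub <- new_substitution(rt$aa[pick[i]], rt$seq_pos[pick[i]], alts[i])
    res <- ddg_protocol(s, chain, sub, settings, stack_cache = cache)
    out$true_ddg[i] <- res$protocol_ddg
    out$predicted_ddg[i] <- res$protocol_ddg
    out$experimental_ddg[i] <- res$protocol_ddg + noise[i]
  }
  out
}

#' Random amino-acid sequence
#' @param n length.
#' @param seed integer seed.
#' @param alphabet letters to draw from (default the 20 amino acids).
#' @return character scalar.
#' @export
random_sequence <- function(n, seed = 1L, alphabet = AA1) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
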