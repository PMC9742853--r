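# Two-tier ddG estimation: a near-instant RSA-based second-degree
# estimator and the neighbourhood repack/minimise protocol.

#' Settings of the ddG protocol
#'
#' @param radius neighbourhood radius in A (C-beta rule; default 12).
#' @param cycles repack passes per arm (default 2).
#' @param display_cap values above this are displayed as
#'   `"> cap kcal/mol"` (default 10).
#' @param score_neighbourhood_only score only pairs touching the repacked
#'   neighbourhood (default `TRUE`).
#' @param constrain_shell freeze the sidechains of the outer shell of the
#'   neighbourhood during repacks, identically in both arms (default
#'   `TRUE`).
#' @param reject_worse never accept a sidechain move that worsens the
#'   total (default `TRUE`).
#' @param boundary_width width of the frozen outer shell, A (default 2).
#' @param energy_params an [energy_params()] list.
#' @return a list of class `ddg_settings`.
#' @export
ddg_settings <- function(radius = 12, cycles = 2, display_cap = 10,
                         score_neighbourhood_only = TRUE,
                         constrain_shell = TRUE, reject_worse = TRUE,
                         boundary_width = 2,
                         energy_params = varstab::energy_params()) {
  stopifnot(radius > 0, cycles >= 1)
  structure(list(radius = radius, cycles = as.integer(cycles),
                 display_cap = display_cap,
                 corrections = list(
                   score_neighbourhood_only = score_neighbourhood_only,
                   constrain_shell = constrain_shell,
                   reject_worse = reject_worse),
                 boundary_width = boundary_width,
                 energy_params = energy_params),
            class = "ddg_settings")
}

#' Coefficients of the quick RSA-based estimator
#'
#' The estimator is a second-degree equation over two structure-independent
#' variables (hydropathy and volume differences between wild-type and
#' mutant residue) and one structure-dependent variable (relative solvent
#' accessibility). Its value saturates at `surface_cap` for a fully exposed
#' residue and `buried_cap` for a fully buried one. Default coefficients
#' were calibrated once by least squares against protocol-generated
#' synthetic data and are shipped in `extdata/quick_coefficients.json`.
#'
#' @param c0,c1,c2,c3 polynomial coefficients.
#' @param hydropathy,volume named per-amino-acid scales.
#' @param surface_cap,buried_cap saturation caps, kcal/mol.
#' @return a list of class `quick_coefficients`.
#' @export
quick_coefficients <- function(c0, c1, c2, c3, hydropathy = HYDROPATHY,
                               volume = RESIDUE_VOLUME, surface_cap = 1.0,
                               buried_cap = 4.5) {
  stopifnot(surface_cap > 0, buried_cap > 0, surface_cap <= buried_cap)
  structure(list(c0 = c0, c1 = c1, c2 = c2, c3 = c3,
                 hydropathy = hydropathy, volume = volume,
                 surface_cap = surface_cap, buried_cap = buried_cap),
            class = "quick_coefficients")
}

#' Shipped default quick-estimator coefficients
#' @return a [quick_coefficients()] object read from the package's
#'   `extdata/quick_coefficients.json`.
#' @export
default_quick_coefficients <- function() {
  f <- system.file("extdata", "quick_coefficients.json",
                   package = "varstab")
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  quick_coefficients(j$c0, j$c1, j$c2, j$c3,
                     surface_cap = j$surface_cap,
                     buried_cap = j$buried_cap)
}

#' Saturation cap of the quick estimator
#' @param rsa relative solvent accessibility in `[0,1]`.
#' @param coeffs a [quick_coefficients()] object.
#' @return cap in kcal/mol: linear between `buried_cap` at RSA 0 and
#'   `surface_cap` at RSA 1.
#' @export
quick_cap <- function(rsa, coeffs = default_quick_coefficients()) {
  coeffs$buried_cap - (coeffs$buried_cap - coeffs$surface_cap) * rsa
}

#' Near-instant ddG estimate from relative solvent accessibility
#'
#' Evaluates `c0 + (1 - rsa) * (c1*dH + c2*dV + c3*dV^2)` where `dH` and
#' `dV` are hydropathy and volume differences (wild-type minus mutant),
#' clamped from above by [quick_cap()]. Identity substitutions return
#' exactly 0.
#'
#' @param sub a [new_substitution()] object.
#' @param rsa relative solvent accessibility in `[0,1]`.
#' @param coeffs a [quick_coefficients()] object.
#' @return ddG in kcal/mol (positive destabilises).
#' @export
quick_ddg <- function(sub, rsa, coeffs = default_quick_coefficients()) {
  stopifnot(rsa >= 0, rsa <= 1)
  if (sub$ref_aa == sub$alt_aa) return(0)
  dh <- coeffs$hydropathy[[sub$ref_aa]] - coeffs$hydropathy[[sub$alt_aa]]
  dv <- coeffs$volume[[sub$ref_aa]] - coeffs$volume[[sub$alt_aa]]
  val <- coeffs$c0 + (1 - rsa) * (coeffs$c1 * dh + coeffs$c2 * dv +
                                    coeffs$c3 * dv^2)
  min(val, quick_cap(rsa, coeffs))
}

# Install an amino acid at the target site: ideal-template sidechain,
# initial torsions from an exhaustive single-residue grid search.
install_best_sidechain <- function(s, chain, seq_pos, aa, settings,
                                   stack_cache = NULL) {
  s2 <- install_sidechain(s, chain, seq_pos, aa)
  if (chi_count(aa) > 0L) {
    one <- data.frame(chain = chain, seq_pos = seq_pos,
                      stringsAsFactors = FALSE)
    single <- settings
    single$cycles <- 1L
    s2 <- repack(s2, one, single,
                 origin = list(chain = chain, seq_pos = seq_pos),
                 stack_cache = stack_cache)
  }
  s2
}

#' Estimate ddG for a substitution (repack protocol + quick estimate)
#'
#' The neighbourhood (C-beta rule, `settings$radius`) around the target is
#' repacked once from the pristine input; from that shared state two
#' symmetric arms install the wild-type and the mutant residue from the
#' ideal template (initial torsions by exhaustive single-residue grid
#' search) and repack again. `ddG = E_mut - E_wt` with both arms scored
#' identically over the neighbourhood, so an identity substitution gives
#' exactly zero. With `constrain_shell` the outermost shell
#' (`boundary_width` A) of the neighbourhood keeps its sidechains fixed in
#' both arms. Values above `display_cap` are displayed as
#' `"> cap kcal/mol"` with `capped = TRUE`.
#'
#' @param s a `varstab_structure` (wild type).
#' @param chain chain of the target residue.
#' @param sub a [new_substitution()] or substitution string.
#' @param settings a [ddg_settings()] list.
#' @param coeffs a [quick_coefficients()] object for the quick estimate.
#' @param stack_cache optional environment memoising candidate sidechain
#'   stacks across calls on the same structure (see [repack()]).
#' @return a `ddg_result`: list with `quick_ddg`, `protocol_ddg`,
#'   `display`, `capped`, `rsa`, `wt_model`, `mut_model`, `audit`.
#' @export
ddg_protocol <- function(s, chain, sub, settings = ddg_settings(),
                         coeffs = default_quick_coefficients(),
                         stack_cache = NULL) {
  if (is.character(sub)) sub <- parse_substitution(sub)
  rt <- residue_table(s)
  ti <- which(rt$chain == chain & rt$seq_pos == sub$seq_pos & !rt$is_hetero)
  if (!length(ti))
    stop("no residue at ", chain, sub$seq_pos, " in structure",
         call. = FALSE)
  found <- rt$aa[ti[1]]
  if (is.na(found) || found != sub$ref_aa)
    stop("reference mismatch at position ", sub$seq_pos, ": expected ",
         sub$ref_aa, ", structure has ",
         if (is.na(found)) rt$resid[ti[1]] else found, call. = FALSE)
  if (!is_aa1(sub$alt_aa))
    stop("unknown replacement amino acid '", sub$alt_aa, "'",
         call. = FALSE)

  rsa <- residue_rsa(s, chain, sub$seq_pos)
  q <- quick_ddg(sub, rsa, coeffs)

  target <- list(chain = chain, seq_pos = sub$seq_pos)
  nb <- find_neighbours(s, chain, sub$seq_pos, settings$radius, "cbeta")
  selection <- rbind(data.frame(chain = chain, seq_pos = sub$seq_pos,
                                stringsAsFactors = FALSE),
                     nb[, c("chain", "seq_pos")])
  mobile <- selection
  if (settings$corrections$constrain_shell && nrow(nb)) {
    frozen <- nb[nb$distance > settings$radius - settings$boundary_width,
                 c("chain", "seq_pos")]
    if (nrow(frozen)) {
      fkey <- paste(frozen$chain, frozen$seq_pos)
      mobile <- mobile[!paste(mobile$chain, mobile$seq_pos) %in% fkey, ,
                       drop = FALSE]
    }
  }
  nonly <- settings$corrections$score_neighbourhood_only
  if (is.null(stack_cache)) stack_cache <- new.env(parent = emptyenv())

  s1 <- repack(s, mobile, settings, origin = target,
               score_selection_df = selection, stack_cache = stack_cache)
  arm <- function(aa) {
    sa <- install_best_sidechain(s1, chain, sub$seq_pos, aa, settings,
                                 stack_cache)
    sr <- repack(sa, mobile, settings, origin = target,
                 score_selection_df = selection,
                 stack_cache = stack_cache)
    list(structure = sr,
         energy = score_selection(sr, selection, settings$energy_params,
                                  nonly),
         trace = sr$metadata$repack_trace)
  }
  wt <- arm(sub$ref_aa)
  mut <- arm(sub$alt_aa)
  ddg <- mut$energy - wt$energy
  capped <- ddg > settings$display_cap
  display <- if (capped) paste0(">", settings$display_cap, " kcal/mol")
  else sprintf("%.1f kcal/mol", ddg)
  structure(list(substitution = sub,
                 quick_ddg = q, protocol_ddg = ddg,
                 display = display, capped = capped, rsa = rsa,
                 wt_model = wt$structure, mut_model = mut$structure,
                 audit = list(pre_trace = s1$metadata$repack_trace,
                              wt_trace = wt$trace, mut_trace = mut$trace,
                              e_wt = wt$energy, e_mut = mut$energy,
                              n_neighbours = nrow(nb),
                              n_mobile = nrow(mobile))),
            class = "ddg_result")
}

#' @export
print.ddg_result <- function(x, ...) {
  cat("<ddg_result> ", format(x$substitution), ": protocol ",
      x$display, " (raw ", sprintf("%.2f", x$protocol_ddg),
      "), quick ", sprintf("%.2f", x$quick_ddg), " kcal/mol, RSA ",
      sprintf("%.2f", x$rsa), "\n", sep = "")
  invisible(x)
}

#' Estimate ddG for a batch of substitutions
#'
#' Each variant is scored independently from the same pristine input
#' structure; per-item errors are collected and the batch continues.
#'
#' @param s a `varstab_structure`.
#' @param chain chain label.
#' @param subs list of substitutions (objects or strings).
#' @param settings a [ddg_settings()] list.
#' @param coeffs quick-estimator coefficients.
#' @return list, order preserved: `ddg_result` objects, or `ddg_error`
#'   (list with `substitution`, `message`) for failed items.
#' @export
ddg_batch <- function(s, chain, subs, settings = ddg_settings(),
                      coeffs = default_quick_coefficients()) {
  stack_cache <- new.env(parent = emptyenv())
  lapply(subs, function(sb) {
    tryCatch(ddg_protocol(s, chain, sb, settings, coeffs, stack_cache),
             error = function(e)
               structure(list(substitution = sb,
                              message = conditionMessage(e)),
                         class = "ddg_error"))
  })
}
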