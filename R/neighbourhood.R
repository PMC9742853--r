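# Structural neighbourhood enumeration and annotation joins: the
# per-neighbour report that is the tool's central output.

#' Enumerate residues around a target site
#'
#' Under the `cbeta` rule a residue is a neighbour iff its C-beta lies
#' within `radius` of the target's C-beta (C-alpha substitutes for C-beta
#' in glycine); under `min_heavy` iff the minimum heavy-atom inter-residue
#' distance is within `radius`. The target itself is excluded; residues of
#' partner chains are included; results are sorted by ascending distance.
#'
#' The energy neighbourhood uses the C-beta rule at 12 A; annotation joins
#' default to 10 A (see [annotate_neighbours()]).
#'
#' @param s a `varstab_structure`.
#' @param chain chain of the target residue.
#' @param position 1-based sequence position of the target.
#' @param radius neighbourhood radius, A.
#' @param atom_rule `"cbeta"` or `"min_heavy"`.
#' @return data.frame: `chain`, `seq_pos`, `aa`, `distance` (A), ascending.
#' @export
find_neighbours <- function(s, chain, position, radius = 12,
                            atom_rule = c("cbeta", "min_heavy")) {
  atom_rule <- match.arg(atom_rule)
  stopifnot(radius > 0)
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero, , drop = FALSE]
  ti <- which(rt$chain == chain & rt$seq_pos == position)
  if (!length(ti)) stop("target residue ", chain, position,
                        " not in structure", call. = FALSE)
  if (atom_rule == "cbeta") {
    cb <- cbeta_coords(s)
    rt2 <- cb$residues
    tj <- which(rt2$chain == chain & rt2$seq_pos == position)
    d <- sqrt(rowSums(sweep(cb$xyz, 2, cb$xyz[tj, ], "-")^2))
    res <- rt2
    res$distance <- d
  } else {
    a <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
    txyz <- coords_matrix(a[a$chain == chain & a$seq_pos == position, ,
                            drop = FALSE])
    xyz <- coords_matrix(a)
    d2 <- outer(rowSums(xyz^2), rowSums(txyz^2), "+") - 2 * xyz %*% t(txyz)
    dmin <- sqrt(pmax(0, apply(d2, 1, min)))
    key <- paste(a$chain, a$seq_pos)
    res <- rt
    res$distance <- as.numeric(tapply(dmin, key, min)[paste(res$chain,
                                                            res$seq_pos)])
  }
  res <- res[!(res$chain == chain & res$seq_pos == position), , drop = FALSE]
  res <- res[!is.na(res$distance) & res$distance <= radius, , drop = FALSE]
  res <- res[order(res$distance, res$chain, res$seq_pos), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("chain", "seq_pos", "aa", "distance")]
}

#' Join a neighbourhood with annotation tables
#'
#' Each neighbour (and the target) is joined with every population variant,
#' clinical variant and PTM record at its sequence position, its
#' conservation score, and every feature interval overlapping its position.
#' Annotations are in the target chain's sequence coordinates, so joins are
#' restricted to target-chain residues; partner-chain neighbours appear
#' with distances but no joins.
#'
#' @param neighbours data.frame from [find_neighbours()].
#' @param target list/row with `chain`, `seq_pos`, `aa`.
#' @param ann an [new_annotation_set()] object.
#' @return a `neighbour_report`: list with `target`, `neighbours` (each row
#'   carrying hit data.frames), `summary` counts.
#' @export
annotate_neighbours <- function(neighbours, target, ann) {
  join_one <- function(chain, pos) {
    if (!identical(chain, target$chain)) {
      return(list(popvars = ann$popvars[0, ], clinvars = ann$clinvars[0, ],
                  ptms = ann$ptms[0, ], features = ann$features[0, ],
                  conservation = NA_real_))
    }
    list(popvars = ann$popvars[ann$popvars$seq_pos == pos, , drop = FALSE],
         clinvars = ann$clinvars[ann$clinvars$seq_pos == pos, ,
                                 drop = FALSE],
         ptms = ann$ptms[ann$ptms$seq_pos == pos, , drop = FALSE],
         features = ann$features[ann$features$start <= pos &
                                   ann$features$end >= pos, , drop = FALSE],
         conservation = {
           sc <- ann$conservation[as.character(pos)]
           if (length(sc)) unname(sc) else NA_real_
         })
  }
  hits <- lapply(seq_len(nrow(neighbours)), function(i)
    join_one(neighbours$chain[i], neighbours$seq_pos[i]))
  target_hits <- join_one(target$chain, target$seq_pos)
  nsum <- function(field) sum(vapply(hits, function(h) nrow(h[[field]]),
                                     integer(1)))
  report <- list(target = target,
                 target_hits = target_hits,
                 neighbours = neighbours,
                 hits = hits,
                 summary = list(n_neighbours = nrow(neighbours),
                                popvars = nsum("popvars"),
                                clinvars = nsum("clinvars"),
                                ptms = nsum("ptms"),
                                features = nsum("features")))
  class(report) <- "neighbour_report"
  report
}

#' @export
print.neighbour_report <- function(x, ...) {
  cat("<neighbour_report> target ", x$target$chain, x$target$seq_pos,
      ": ", x$summary$n_neighbours, " neighbour(s); hits: ",
      x$summary$popvars, " popvar, ", x$summary$clinvars, " clinvar, ",
      x$summary$ptms, " PTM, ", x$summary$features, " feature\n", sep = "")
  invisible(x)
}

#' Hetero groups near a target residue
#'
#' Retained hetero groups (after [strip_solvent()]) whose minimum
#' heavy-atom distance to any atom of the target residue is within
#' `radius`.
#'
#' @inheritParams find_neighbours
#' @param radius query radius, A (default 10).
#' @return data.frame: `het_code`, `chain`, `seq_pos`, `min_distance`.
#' @export
ligand_proximity <- function(s, chain, position, radius = 10) {
  a <- s$atoms
  tr <- a[a$chain == chain & a$seq_pos == position & !a$is_hetero, ,
          drop = FALSE]
  if (!nrow(tr)) stop("target residue ", chain, position, " not found",
                      call. = FALSE)
  het <- a[a$is_hetero, , drop = FALSE]
  if (!nrow(het)) {
    return(data.frame(het_code = character(0), chain = character(0),
                      seq_pos = integer(0), min_distance = numeric(0),
                      stringsAsFactors = FALSE))
  }
  txyz <- coords_matrix(tr)
  hxyz <- coords_matrix(het)
  d2 <- outer(rowSums(hxyz^2), rowSums(txyz^2), "+") - 2 * hxyz %*% t(txyz)
  dmin <- sqrt(pmax(0, apply(d2, 1, min)))
  key <- paste(het$chain, het$seq_pos, het$resid, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(het_code = het$resid[first], chain = het$chain[first],
                    seq_pos = het$seq_pos[first], stringsAsFactors = FALSE)
  out$min_distance <- as.numeric(tapply(dmin, key, min)[key[first]])
  out <- out[out$min_distance <= radius, , drop = FALSE]
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
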