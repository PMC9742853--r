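# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (double loops, position-by-position matching) and
# share no code with the implementation paths they check.

# Naive pairwise energy: double loop over atoms, terms written out from
# their definitions.
naive_score_selection <- function(s, selection, params,
                                  neighbourhood_only = TRUE) {
  a <- s$atoms
  el <- toupper(a$element)
  rad <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    rad[i] <- if (el[i] %in% names(params$vdw_radii))
      params$vdw_radii[[el[i]]] else params$vdw_radii[["C"]]
  }
  q <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    q[i] <- switch(paste(a$resid[i], a$atom[i]),
                   "ARG CZ" = 1, "LYS NZ" = 1,
                   "ASP CG" = -1, "GLU CD" = -1, 0)
  }
  rid <- paste(a$chain, a$seq_pos, a$is_hetero, a$resid)
  selkey <- paste(selection$chain, selection$seq_pos)
  insel <- paste(a$chain, a$seq_pos) %in% selkey & !a$is_hetero
  bb <- !a$is_hetero & a$atom %in% c("N", "CA", "C", "O")
  hw <- params$hbond_window
  total <- 0
  n <- nrow(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (neighbourhood_only && !insel[i] && !insel[j]) next
      if (rid[i] == rid[j]) next
      if (bb[i] && bb[j] && a$chain[i] == a$chain[j] &&
          abs(a$seq_pos[i] - a$seq_pos[j]) == 1) next
      d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                  (a$z[i] - a$z[j])^2)
      rsum <- rad[i] + rad[j]
      if (d < rsum) total <- total + params$k_rep * (rsum - d)^2
      if (el[i] == "C" && el[j] == "C" && d >= rsum &&
          d <= params$contact_cutoff)
        total <- total - params$eps_contact *
          (params$contact_cutoff - d) / (params$contact_cutoff - rsum)
      if (el[i] %in% c("N", "O") && el[j] %in% c("N", "O") &&
          d >= hw[1] && d <= hw[2])
        total <- total - params$eps_hbond * (hw[2] - d) / (hw[2] - hw[1])
      if (q[i] != 0 && q[j] != 0)
        total <- total + params$coulomb_scale * q[i] * q[j] /
          (params$dielectric_slope * max(d, 2)^2)
    }
  }
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero & paste(rt$chain, rt$seq_pos) %in% selkey, ]
  total + sum(params$reference_energies[rt$aa], na.rm = TRUE)
}

# Exhaustive neighbour scan: all residue pairs, both atom rules.
naive_neighbours <- function(s, chain, position, radius, atom_rule) {
  rt <- residue_table(s)
  rt <- rt[!rt$is_hetero, , drop = FALSE]
  a <- s$atoms[!s$atoms$is_hetero, , drop = FALSE]
  rep_atom <- function(ch, pos) {
    res <- a[a$chain == ch & a$seq_pos == pos, , drop = FALSE]
    cb <- res[res$atom == "CB", , drop = FALSE]
    if (!nrow(cb)) cb <- res[res$atom == "CA", , drop = FALSE]
    as.numeric(cb[1, c("x", "y", "z")])
  }
  out <- list()
  for (i in seq_len(nrow(rt))) {
    ch <- rt$chain[i]; pos <- rt$seq_pos[i]
    if (ch == chain && pos == position) next
    if (atom_rule == "cbeta") {
      d <- sqrt(sum((rep_atom(ch, pos) - rep_atom(chain, position))^2))
    } else {
      r1 <- a[a$chain == ch & a$seq_pos == pos, , drop = FALSE]
      r2 <- a[a$chain == chain & a$seq_pos == position, , drop = FALSE]
      d <- Inf
      for (k in seq_len(nrow(r1))) for (l in seq_len(nrow(r2))) {
        dk <- sqrt((r1$x[k] - r2$x[l])^2 + (r1$y[k] - r2$y[l])^2 +
                     (r1$z[k] - r2$z[l])^2)
        if (dk < d) d <- dk
      }
    }
    if (d <= radius)
      out[[length(out) + 1]] <- data.frame(chain = ch, seq_pos = pos,
                                           distance = d)
  }
  if (!length(out)) return(data.frame(chain = character(0),
                                      seq_pos = integer(0),
                                      distance = numeric(0)))
  do.call(rbind, out)
}

# Position-by-position anchored regex matcher.
naive_scan <- function(seq, patterns) {
  n <- nchar(seq)
  out <- list()
  for (p in patterns) {
    anchored <- paste0("^(?:", p$pattern, ")")
    for (st in seq_len(n)) {
      suffix <- substr(seq, st, n)
      m <- regexpr(anchored, suffix, perl = TRUE)
      if (m == 1 && attr(m, "match.length") > 0) {
        len <- attr(m, "match.length")
        out[[length(out) + 1]] <-
          data.frame(name = p$name, start = st, end = st + len - 1,
                     matched = substr(seq, st, st + len - 1),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(data.frame(name = character(0),
                                      start = integer(0),
                                      end = integer(0),
                                      matched = character(0)))
  do.call(rbind, out)
}

# Sort-and-interpolate quartiles (independent of stats::quantile).
naive_quartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

helix30 <- function() build_helix(random_sequence(30, seed = 11))
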