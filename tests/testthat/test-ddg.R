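test_that("SASA of an isolated atom matches the closed form", {
  s <- new_structure(data.frame(chain = "A", seq_pos = 1L, resid = "GLY",
                                atom = c("N", "CA", "C"),
                                element = c("N", "C", "C"),
                                x = c(0, 100, 200), y = 0, z = 0, b = 0,
                                is_hetero = FALSE,
                                stringsAsFactors = FALSE))
  sa <- compute_sasa(s)
  # three isolated spheres: 4*pi*(r+1.4)^2 each
  want <- 4 * pi * ((1.55 + 1.4)^2 + 2 * (1.70 + 1.4)^2)
  expect_equal(sa$sasa, want, tolerance = 1e-6)
})

test_that("a fully enclosed atom has zero SASA", {
  # cage of carbons on a sphere of radius 2.8 around a central carbon:
  # every probe point of the centre is occluded
  pts <- varstab:::sphere_points(60) * 2.8
  at <- data.frame(chain = "A", seq_pos = 1L, resid = "GLY",
                   atom = c("CA", paste0("C", 1:60)),
                   element = "C",
                   x = c(0, pts[, 1]), y = c(0, pts[, 2]),
                   z = c(0, pts[, 3]), b = 0, is_hetero = FALSE,
                   stringsAsFactors = FALSE)
  s <- new_structure(at, "synthetic")
  el <- toupper(s$atoms$element)
  r <- varstab:::VDW_RADII[el] + 1.4
  xyz <- varstab:::coords_matrix(s$atoms)
  shell <- sweep(varstab:::sphere_points(92) * r[1], 2, xyz[1, ], "+")
  acc <- rep(TRUE, 92)
  for (j in 2:nrow(xyz)) {
    dd <- sweep(shell, 2, xyz[j, ], "-")
    acc <- acc & (rowSums(dd^2) >= r[j]^2)
  }
  expect_equal(sum(acc), 0)
})

test_that("two-sphere SASA agrees with the analytic cap formula", {
  d <- 2.0
  at <- data.frame(chain = "A", seq_pos = 1L, resid = "GLY",
                   atom = c("CA", "C1"), element = "C",
                   x = c(0, d), y = 0, z = 0, b = 0, is_hetero = FALSE,
                   stringsAsFactors = FALSE)
  s <- new_structure(at, "synthetic")
  sa <- compute_sasa(s)
  r <- 1.7 + 1.4
  # equal spheres at distance d: each loses a cap of height h = r - d/2
  h <- r - d / 2
  analytic <- 2 * (4 * pi * r^2 - 2 * pi * r * h)
  expect_equal(sa$sasa[1], analytic, tolerance = 0.02 * analytic)
})

test_that("relative SASA normalises and clamps", {
  expect_equal(relative_sasa(0, "W"), 0)
  expect_equal(relative_sasa(285, "W"), 1)
  expect_equal(relative_sasa(1e4, "G"), 1)
  expect_error(relative_sasa(10, "B"), "unknown amino acid")
  for (x in c("A", "L", "W", "D", "K")) {
    e <- build_extended(paste0("G", x, "G"))
    expect_gte(varstab:::residue_rsa(e, "A", 2), 0.8)
  }
})

test_that("quick estimator honours identity and the saturation caps", {
  co <- default_quick_coefficients()
  expect_identical(quick_ddg(new_substitution("A", 5L, "A"), 0.3, co), 0)
  aa <- varstab:::AA1
  for (rsa in seq(0, 1, by = 0.1)) {
    cap <- quick_cap(rsa, co)
    for (ref in aa) for (alt in aa) {
      if (ref == alt) next
      v <- quick_ddg(new_substitution(ref, 1L, alt), rsa, co)
      expect_lte(v, cap)
    }
  }
  expect_equal(quick_cap(1, co), 1.0)
  expect_equal(quick_cap(0, co), 4.5)
})

test_that("pair energy terms evaluate to their defined values", {
  p <- energy_params()
  two_carbons <- function(d) {
    new_structure(data.frame(chain = "A", seq_pos = c(1L, 3L),
                             resid = "GLY", atom = c("CA", "CA"),
                             element = "C", x = c(0, d), y = 0, z = 0,
                             b = 0, is_hetero = FALSE,
                             stringsAsFactors = FALSE), "synthetic")
  }
  sel <- data.frame(chain = "A", seq_pos = c(1L, 3L))
  # at contact distance r_sum = 3.4: no repulsion, full contact well
  expect_equal(score_selection(two_carbons(3.4), sel, p), -p$eps_contact,
               tolerance = 1e-12)
  # at 3.0: repulsion k_rep * 0.4^2 = 1.6
  expect_equal(score_selection(two_carbons(3.0), sel, p),
               p$k_rep * 0.4^2, tolerance = 1e-12)
})

test_that("selection scoring equals the naive double loop", {
  p <- energy_params()
  for (seed in 1:12) {
    s <- build_helix(random_sequence(10, seed = seed + 40))
    rt <- residue_table(s)
    set.seed(seed)
    sel <- rt[sample(nrow(rt), 4), c("chain", "seq_pos")]
    for (nonly in c(TRUE, FALSE)) {
      expect_equal(score_selection(s, sel, p, nonly),
                   naive_score_selection(s, sel, p, nonly),
                   tolerance = 1e-9)
    }
  }
})

test_that("reference energies shift the selection score additively", {
  s <- build_helix("ACDEF")
  sel <- data.frame(chain = "A", seq_pos = 2:3)
  p0 <- energy_params()
  refs <- stats::setNames(rep(0, 20), varstab:::AA1)
  refs["C"] <- 1.25; refs["D"] <- -0.5
  p1 <- energy_params(reference_energies = refs)
  expect_equal(score_selection(s, sel, p1) - score_selection(s, sel, p0),
               0.75, tolerance = 1e-12)
})

test_that("repacking an alanine-only selection changes nothing", {
  s <- build_helix("GAGAG")
  sel <- data.frame(chain = "A", seq_pos = c(2L, 4L))
  r <- repack(s, sel, ddg_settings())
  expect_equal(r$atoms[, c("x", "y", "z")], s$atoms[, c("x", "y", "z")])
})

test_that("single-residue repack equals exhaustive grid search", {
  set.seed(31)
  for (aa in c("S", "V", "L", "M", "K")) {
    s <- build_helix(paste0("GA", aa, "AG"))
    sel <- data.frame(chain = "A", seq_pos = 3L)
    st <- ddg_settings(cycles = 1)
    r <- repack(s, sel, st)
    # oracle: enumerate the full torsion grid with build_sidechain and
    # score each full structure
    grid <- varstab:::chi_grid(aa)
    energies <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      sg <- varstab:::install_sidechain(s, "A", 3L, aa, grid[g, ])
      energies[g] <- score_selection(sg, sel, st$energy_params)
    }
    e_cur <- score_selection(s, sel, st$energy_params)
    best <- which.min(energies)
    want <- if (energies[best] < e_cur)
      varstab:::install_sidechain(s, "A", 3L, aa, grid[best, ])
    else s
    expect_equal(r$atoms[, c("x", "y", "z")],
                 want$atoms[, c("x", "y", "z")], tolerance = 1e-9)
  }
})

test_that("the per-cycle energy trace is non-increasing", {
  s <- build_helix(random_sequence(20, seed = 15))
  sel <- data.frame(chain = "A", seq_pos = 5:15)
  r <- repack(s, sel, ddg_settings(cycles = 4))
  tr <- r$metadata$repack_trace
  expect_length(tr, 4)
  expect_true(all(diff(tr) <= 1e-9))
})

test_that("identity substitutions give exactly zero on all fixtures", {
  fixtures <- list(build_helix(random_sequence(20, seed = 21)),
                   build_extended(random_sequence(12, seed = 22)),
                   build_packed_cluster(core_aa = "V", seed = 5))
  for (s in fixtures) {
    rt <- residue_table(s)
    rt <- rt[!is.na(rt$aa), ]
    set.seed(8)
    for (i in sample(nrow(rt), min(3, nrow(rt)))) {
      sub <- new_substitution(rt$aa[i], rt$seq_pos[i], rt$aa[i])
      r <- ddg_protocol(s, rt$chain[i], sub)
      expect_identical(r$protocol_ddg, 0)
      expect_identical(r$quick_ddg, 0)
    }
  }
})

test_that("the protocol is deterministic across repeated runs", {
  sq <- random_sequence(18, seed = 33)
  s <- build_helix(sq)
  sub <- paste0(substr(sq, 9, 9), "9A")
  r1 <- ddg_protocol(s, "A", sub)
  r2 <- ddg_protocol(s, "A", sub)
  expect_identical(r1$protocol_ddg, r2$protocol_ddg)
  expect_identical(r1$mut_model$atoms, r2$mut_model$atoms)
})

test_that("the buried bulky substitution is capped and confirmed raw", {
  pc <- build_packed_cluster()
  r <- ddg_protocol(pc, "A", "G1W")
  expect_true(r$capped)
  expect_identical(r$display, ">10 kcal/mol")
  expect_gt(r$protocol_ddg, 10)
  # independent confirmation: naive direct term summation on the two
  # emitted models
  sel <- rbind(data.frame(chain = "A", seq_pos = 1L),
               find_neighbours(pc, "A", 1, 12, "cbeta")[, c("chain",
                                                            "seq_pos")])
  p <- energy_params()
  raw <- naive_score_selection(r$mut_model, sel, p) -
    naive_score_selection(r$wt_model, sel, p)
  expect_gt(raw, 10)
  expect_equal(raw, r$protocol_ddg, tolerance = 1e-6)
})

test_that("cap flag agrees with the threshold over engineered fixtures", {
  pc <- build_packed_cluster()
  cache <- new.env(parent = emptyenv())
  for (alt in c("A", "S", "W", "F")) {
    r <- ddg_protocol(pc, "A", paste0("G1", alt), stack_cache = cache)
    expect_identical(r$capped, r$protocol_ddg > 10)
    expect_identical(grepl("^>", r$display), r$capped)
  }
})

test_that("validation errors name the expected and found residues", {
  s <- build_helix("ACDEF")
  expect_error(ddg_protocol(s, "A", "G2V"), "expected G.*structure has C")
  expect_error(ddg_protocol(s, "A", "A9V"), "no residue")
  expect_error(parse_substitution("A5Z"), "outside the 20 amino acids")
})

test_that("batches preserve order, equal single runs, and collect errors", {
  s <- build_helix(random_sequence(15, seed = 44))
  rt <- residue_table(s)
  expect_identical(ddg_batch(s, "A", list()), list())
  sub1 <- new_substitution(rt$aa[5], rt$seq_pos[5], "A")
  single <- ddg_protocol(s, "A", sub1)
  batch <- ddg_batch(s, "A", list(sub1, "G99W",
                                  new_substitution(rt$aa[7],
                                                   rt$seq_pos[7],
                                                   rt$aa[7])))
  expect_identical(batch[[1]]$protocol_ddg, single$protocol_ddg)
  expect_identical(batch[[1]]$mut_model$atoms, single$mut_model$atoms)
  expect_s3_class(batch[[2]], "ddg_error")
  expect_identical(batch[[3]]$protocol_ddg, 0)
})
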