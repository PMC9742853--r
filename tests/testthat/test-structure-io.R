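test_that("minimal PDB and mmCIF files read to the same structure", {
  h <- build_helix("GAV")
  pdb <- tempfile(fileext = ".pdb")
  cif <- tempfile(fileext = ".cif")
  write_structure(h, pdb, "pdb")
  write_structure(h, cif, "mmcif")
  sp <- read_structure(pdb)
  sc <- read_structure(cif)
  expect_equal(nrow(sp$atoms), nrow(h$atoms))
  expect_equal(nrow(sc$atoms), nrow(h$atoms))
  expect_equal(sp$atoms$atom, sc$atoms$atom)
  expect_equal(sp$atoms$seq_pos, sc$atoms$seq_pos)
  expect_equal(coords_matrix(sp$atoms), coords_matrix(sc$atoms),
               tolerance = 1e-6)
})

test_that("a water-only file has zero polymer residues", {
  lines <- c(
    sprintf("HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
            1:3, 101:103, c(0, 5, 10), 0, 0),
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  s <- read_structure(f)
  rt <- residue_table(s)
  expect_equal(sum(!rt$is_hetero), 0)
  expect_equal(sum(rt$is_hetero), 3)
})

test_that("round-trip preserves counts, labels, numbering, coordinates", {
  for (seed in 1:20) {
    s <- build_helix(random_sequence(8, seed = seed))
    f <- tempfile(fileext = ".pdb")
    write_structure(s, f, "pdb")
    r <- read_structure(f)
    expect_equal(nrow(r$atoms), nrow(s$atoms))
    expect_equal(r$atoms$chain, s$atoms$chain)
    expect_equal(r$atoms$seq_pos, s$atoms$seq_pos)
    expect_equal(r$atoms$resid, s$atoms$resid)
    expect_equal(coords_matrix(r$atoms), coords_matrix(s$atoms),
                 tolerance = 1e-3)
    unlink(f)
  }
})

test_that("apply_offset renumbers into sequence coordinates", {
  s <- build_helix("ACDEFG")
  s$atoms$seq_pos <- s$atoms$seq_pos + 4L   # structure numbered 5..10
  s <- new_structure(s$atoms, s$source_kind)
  expect_identical(apply_offset(s, "A", 0)$atoms$seq_pos, s$atoms$seq_pos)
  r <- apply_offset(s, "A", -4L)
  expect_equal(sort(unique(r$atoms$seq_pos)), 1:6)
  # renumbered sequence equals the reference slice, randomised fixtures
  for (seed in 1:20) {
    sq <- random_sequence(10, seed = seed + 100)
    st <- build_helix(sq)
    off <- seed %% 7
    shifted <- st
    shifted$atoms$seq_pos <- shifted$atoms$seq_pos + off
    shifted <- new_structure(shifted$atoms, st$source_kind)
    back <- apply_offset(shifted, "A", -off)
    expect_identical(paste(extract_sequence(back, "A"), collapse = ""), sq)
  }
})

test_that("offset mapping collisions and gaps are rejected", {
  s <- build_helix("ACD")
  expect_error(apply_offset(s, "A", c(`1` = 5, `2` = 5, `3` = 6)),
               "injective")
  expect_error(apply_offset(s, "A", c(`1` = 5, `2` = 6)), "lacks")
})

test_that("strip_solvent removes listed codes, keeps cofactors, idempotent", {
  h <- build_helix("ACD")
  het <- data.frame(chain = "A",
                    seq_pos = c(201L, 202L, 203L, 301L),
                    resid = c("HOH", "HOH", "HOH", "HEM"),
                    atom = c("O", "O", "O", "FE"),
                    element = c("O", "O", "O", "C"),
                    x = 20, y = c(0, 2, 4, 6), z = 0, b = 0,
                    is_hetero = TRUE, stringsAsFactors = FALSE)
  s <- new_structure(rbind(h$atoms, het), "synthetic")
  r <- strip_solvent(s)
  expect_false(any(r$atoms$resid == "HOH"))
  expect_true(any(r$atoms$resid == "HEM"))
  expect_identical(strip_solvent(r)$atoms, r$atoms)
  expect_identical(strip_solvent(s, character(0))$atoms, s$atoms)
  # atom-count drop equals the removed groups' atom counts
  expect_equal(nrow(s$atoms) - nrow(r$atoms), 3)
})

test_that("isolate_target_chain relabels and records partners", {
  s1 <- build_helix("ACD", chain = "B")
  r1 <- isolate_target_chain(s1, "B")
  expect_identical(chain_labels(r1), "A")
  expect_length(r1$metadata$partners, 0)

  s2 <- build_two_chain("ACD", "EFG", separation = 12)
  r2 <- isolate_target_chain(s2, "B")
  expect_true("A" %in% chain_labels(r2))
  expect_true(length(r2$metadata$partners) == 1)
  expect_true(r2$metadata$partner_chains_copied)
  # former chain 'A' moved to the next free letter, recorded in metadata
  expect_identical(r2$metadata$relabelled[["A"]], r2$metadata$partners)
  expect_identical(sort(chain_labels(r2)),
                   sort(c("A", r2$metadata$partners)))
  # idempotent when target already A
  r3 <- isolate_target_chain(r2, "A")
  expect_identical(r3$atoms, r2$atoms)
})

test_that("interchain clash detection matches the exhaustive scan", {
  near <- build_two_chain("ACDEF", "ACDEF", separation = 1.5)
  far <- build_two_chain("ACDEF", "ACDEF", separation = 25)
  expect_true(detect_interchain_clash(near, "A", "B"))
  expect_false(detect_interchain_clash(far, "A", "B"))
  for (sep in c(1, 2, 5, 8, 15)) {
    s <- build_two_chain("AVLK", "AVLK", separation = sep)
    a <- s$atoms[s$atoms$chain == "A", ]
    b <- s$atoms[s$atoms$chain == "B", ]
    dmin <- Inf
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
      dmin <- min(dmin, sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                               (a$z[i] - b$z[j])^2))
    expect_identical(detect_interchain_clash(s, "A", "B", 2.0), dmin < 2.0)
  }
  expect_error(detect_interchain_clash(near, "A", "Z"), "not present")
})

test_that("conservation painting fills B-factors and survives round-trip", {
  s <- build_helix("ACDEF")
  r0 <- paint_conservation(s, "A", stats::setNames(numeric(0),
                                                   character(0)))
  expect_true(all(r0$atoms$b == -1))
  r <- paint_conservation(s, "A", c(`3` = 1.5))
  expect_true(all(r$atoms$b[r$atoms$seq_pos == 3] == 1.5))
  expect_true(all(r$atoms$b[r$atoms$seq_pos != 3] == -1))
  f <- tempfile(fileext = ".pdb")
  write_structure(r, f, "pdb")
  rr <- read_structure(f)
  expect_equal(rr$atoms$b, r$atoms$b, tolerance = 5e-3)
})

test_that("insertion codes are rejected with a clear error", {
  lines <- c(
    "ATOM      1  N   GLY A   1A      0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1A      1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1A      2.000   1.400   0.000  1.00  0.00           C",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(read_structure(f), "insertion codes")
})
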