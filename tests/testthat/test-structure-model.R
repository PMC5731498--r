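test_that("fixture complexes round-trip through the PDB reader", {
  cx <- make_complex(seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(cx$structure, f)
  st <- read_structure(f)
  expect_length(unique(st$chain), 2)
  expect_equal(nrow(st), nrow(cx$structure))
  expect_equal(st$x, cx$structure$x)
  expect_equal(st$aa, cx$structure$aa)
  expect_equal(st$res_id, cx$structure$res_id)
})

test_that("non-protein chains are dropped, protein chains kept", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_toy_pdb(c(8, 8), f))
  dna <- sprintf(
    "ATOM  %5d  P    DA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           P",
    900 + 1:4, "D", 1:4, 6 * (0:3), 500, 0, 1, 0
  )
  writeLines(c(head(lines, -1), dna, "END"), f)
  st <- expect_silent(read_structure(f))
  expect_setequal(unique(st$chain), c("A", "B"))
})

test_that("a file with no protein chains is an error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf(
      "HETATM%5d  O   HOH %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
      1:3, "W", 1:3, 3 * (0:2), 0, 0, 1, 0
    ),
    "END"
  ), f)
  expect_error(read_structure(f), "no protein chains")
})

test_that("highest-occupancy altloc wins, first on tie", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BGLY A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "ATOM      5  CA  GLY A   4      11.400   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  GLY A   5      15.200   0.000   0.000  1.00  0.00           C",
    "END"
  ), f)
  st <- read_structure(f)
  expect_equal(sum(st$resno == 1), 1)
  expect_equal(st$x[st$resno == 1], 9.0)
})

test_that("kb chain filters follow the strict less-than rules", {
  f <- withr::local_tempfile(fileext = ".pdb")
  st <- read_structure(write_toy_pdb(c(4, 20, 30), f))
  kept <- filter_chains_for_kb(st)
  expect_setequal(unique(kept$chain), c("B", "C"))
  expect_true(is_kb_eligible(kept))

  st2 <- read_structure(write_toy_pdb(c(4, 20), f))
  kept2 <- filter_chains_for_kb(st2)
  expect_false(is_kb_eligible(kept2))
  expect_setequal(unique(kept2$chain), "B")

  st3 <- read_structure(write_toy_pdb(c(5, 5), f))
  kept3 <- filter_chains_for_kb(st3)
  expect_true(is_kb_eligible(kept3))
  expect_setequal(unique(kept3$chain), c("A", "B"))

  # idempotence
  again <- filter_chains_for_kb(kept)
  expect_equal(as.data.frame(again), as.data.frame(kept))
  expect_true(is_kb_eligible(again))
})

test_that("RASA behaves physically and deterministically", {
  iso <- atoms_structure("A", 0, 0, 0, "C", aa = "G")
  r <- compute_rasa(iso)
  expect_gt(r$rasa, 0.9)

  # atom caged inside a dense shell of neighbors -> essentially buried
  sph <- ppisite:::fibonacci_sphere(40) * 3.0
  cage <- atoms_structure(
    chain = rep("A", 41),
    x = c(0, sph[, 1]), y = c(0, sph[, 2]), z = c(0, sph[, 3]),
    element = rep("C", 41)
  )
  rc <- compute_rasa(cage)
  expect_lt(rc$rasa[1], 0.02)

  cx <- make_complex(seed = 7)
  expect_identical(compute_rasa(cx$structure), compute_rasa(cx$structure))
})

test_that("RASA is invariant under rigid motion of the chain", {
  cx <- make_complex(seed = 9, n_res = c(8, 8))
  base <- compute_rasa(cx$structure)

  shifted <- cx$structure
  shifted$x <- shifted$x + 17.3
  shifted$y <- shifted$y - 5.1
  shifted$z <- shifted$z + 2.2
  expect_equal(compute_rasa(shifted)$rasa, base$rasa, tolerance = 1e-9)

  # rotation: exact up to the angular resolution of the quadrature
  th <- 0.7
  rot <- cx$structure
  xn <- cos(th) * rot$x - sin(th) * rot$y
  yn <- sin(th) * rot$x + cos(th) * rot$y
  rot$x <- xn
  rot$y <- yn
  expect_equal(compute_rasa(rot)$rasa, base$rasa, tolerance = 1e-2)
})

test_that("decile bin edges and binning follow the stated conventions", {
  set.seed(1)
  u <- runif(1e5)
  edges <- derive_bin_edges(u)
  expect_equal(edges, seq(0.1, 0.9, by = 0.1), tolerance = 0.01)

  v <- rep(0.05 * (0:9), each = 50)
  e2 <- derive_bin_edges(v)
  bins <- bin_rasa(v, e2)
  expect_equal(unname(table(bins)), rep(50L, 10), ignore_attr = TRUE)

  expect_error(derive_bin_edges(rep(0.5, 100)), "degenerate")
  expect_error(derive_bin_edges(c(0.1, 0.2)), "degenerate")

  expect_equal(bin_rasa(0, edges), 0L)
  expect_equal(bin_rasa(1, edges), 9L)
  expect_equal(bin_rasa(5, edges), 9L)
  # value equal to an edge goes to the higher bin (left-closed bins)
  e3 <- (1:9) / 10
  expect_equal(bin_rasa(0.3, e3), 3L)
  expect_error(bin_rasa(-0.1, edges), ">= 0")
})

test_that("interface rule is the 0.5 A vdW surface gap, cross-chain only", {
  # radii: C = 1.70, N = 1.55; gap = d - r1 - r2
  near <- atoms_structure(c("A", "B"), c(0, 3.70), c(0, 0), c(0, 0),
                          c("C", "N"))
  lab <- label_interfaces(near)
  expect_true(all(lab$interface))

  far <- atoms_structure(c("A", "B"), c(0, 3.80), c(0, 0), c(0, 0),
                         c("C", "N"))
  expect_false(any(label_interfaces(far)$interface))

  same <- atoms_structure(c("A", "A", "B"), c(0, 3.4, 50), c(0, 0, 0),
                          c(0, 0, 0), c("C", "C", "C"))
  lab3 <- label_interfaces(same)
  expect_false(any(lab3$interface))

  single <- atoms_structure("A", 0, 0, 0, "C")
  expect_warning(lab1 <- label_interfaces(single), "single-chain")
  expect_false(any(lab1$interface))
})

test_that("grid labeling equals brute force and is chain-symmetric", {
  for (seed in 1:8) {
    cx <- make_complex(seed = seed, jitter = 0.15,
                       contact_window = seq(3, 3 + seed %% 5))
    g <- label_interfaces(cx$structure, method = "grid")
    b <- label_interfaces(cx$structure, method = "brute")
    expect_equal(g, b)
    expect_setequal(g$res_id[g$interface],
                    oracle_interface_residues(cx$structure))

    # relabel chains: the labeled residue set must be unchanged
    sw <- cx$structure
    sw$chain <- c(A = "B", B = "A")[sw$chain]
    sw$res_id <- paste(sw$chain, sw$resno, sw$icode, sep = ":")
    g2 <- label_interfaces(sw)
    expect_setequal(chartr("AB", "BA", g2$res_id[g2$interface]),
                    g$res_id[g$interface])
  }
})

test_that("mmCIF files parse to the same structure as PDB", {
  cx <- make_complex(seed = 12, n_res = c(6, 6), contact_window = 3:4)
  fcif <- withr::local_tempfile(fileext = ".cif")
  a <- tibble::as_tibble(cx$structure)
  hdr <- paste0("_atom_site.", c(
    "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
    "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"
  ))
  rows <- sprintf(
    "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
    seq_len(nrow(a)), a$resid, a$chain, a$resno, a$x, a$y, a$z,
    a$resno, a$resid, a$chain
  )
  writeLines(c("data_fix", "loop_", hdr, rows), fcif)
  st <- read_structure(fcif, format = "cif", structure_id = "fix")
  expect_equal(st$res_id, cx$structure$res_id)
  expect_equal(st$x, cx$structure$x)
  expect_equal(st$aa, cx$structure$aa)
})
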