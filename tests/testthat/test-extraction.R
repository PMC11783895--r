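# PDB parsing, fragment harvesting and chemical completion.

min_ala_pdb <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  1.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  1.00           C",
    "ATOM      3  C   ALA A   1       2.010   1.420   0.000  1.00  1.00           C",
    "ATOM      4  O   ALA A   1       1.250   2.390   0.000  1.00  1.00           O",
    "ATOM      5  CB  ALA A   1       2.010  -0.760   1.220  1.00  1.00           C",
    "END"), collapse = "\n")
}

test_that("minimal PDB text parses into chains and residues", {
  mod <- parse_structure(min_ala_pdb())
  expect_length(mod$chains, 1)
  expect_length(mod$chains[["A"]], 1)
  expect_equal(mod$chains[["A"]][[1]]$resid, "ALA")
  expect_equal(nrow(mod$chains[["A"]][[1]]$atoms), 5)
})

test_that("alternate locations collapse to a single coordinate", {
  txt <- paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  1.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.60  1.00           C",
    "ATOM      3  CA BALA A   1       9.999   9.999   9.999  0.40  1.00           C",
    "ATOM      4  C   ALA A   1       2.010   1.420   0.000  1.00  1.00           C",
    "ATOM      5  O   ALA A   1       1.250   2.390   0.000  1.00  1.00           O",
    "ATOM      6  CB  ALA A   1       2.010  -0.760   1.220  1.00  1.00           C",
    "END"), collapse = "\n")
  mod <- parse_structure(txt)
  at <- mod$chains[["A"]][[1]]$atoms
  expect_equal(sum(at$name == "CA"), 1)
  expect_equal(at$x[at$name == "CA"], 1.458)  # altloc A kept
})

test_that("inputs without ATOM records are rejected", {
  expect_error(parse_structure("HEADER    NOTHING HERE\nEND"), "ATOM|unreadable")
})

test_that("a continuous 3-residue chain yields 3 singles and 2 duals", {
  mod <- parse_structure(fixture_tripeptide_pdb())
  si <- extract_single_fragments(mod)
  expect_equal(vapply(si, `[[`, "", "label"), c("ALA", "GLY", "SER"))
  du <- extract_dual_fragments(mod)
  expect_equal(vapply(du, `[[`, "", "label"), c("ALAGLY", "GLYSER"))
  # L - 1 pairs for a continuous chain of length L
  expect_length(du, 2)
  done <- lapply(du, complete_fragment)
  expect_equal(vapply(done, function(f) nrow(f$coords), 0L),
               c(atom_count("ALAGLY"), atom_count("GLYSER")))
})

test_that("chain breaks terminate dipeptide pairing", {
  # shift the SER residue far away: C(2)-N(3) >> 1.7 A
  txt <- strsplit(fixture_tripeptide_pdb(), "\n")[[1]]
  is_ser <- grepl(" SER A", txt, fixed = TRUE)
  txt[is_ser] <- vapply(txt[is_ser], function(line) {
    x <- as.numeric(substr(line, 31, 38)) + 50
    paste0(substr(line, 1, 30), sprintf("%8.3f", x), substr(line, 39, 80))
  }, "")
  mod <- parse_structure(paste(txt, collapse = "\n"))
  du <- extract_dual_fragments(mod)
  expect_equal(vapply(du, `[[`, "", "label"), "ALAGLY")
  expect_equal(attr(du, "skipped"), 1L)
})

test_that("residues missing side-chain heavy atoms are skipped and counted", {
  txt <- strsplit(min_ala_pdb(), "\n")[[1]]
  txt <- txt[!grepl(" CB ", txt)]
  mod <- parse_structure(paste(txt, collapse = "\n"))
  si <- extract_single_fragments(mod)
  expect_length(si, 0)
  expect_equal(attr(si, "skipped"), 1L)
})

test_that("completion anchors on observed heavy atoms and never moves them", {
  mod <- parse_structure(fixture_dipeptide_pdb())
  raw <- extract_dual_fragments(mod)[[1]]
  done <- complete_fragment(raw)
  expect_equal(nrow(done$coords), atom_count(raw$label))
  key_in <- paste(raw$atom_names, raw$res)
  key_out <- paste(done$atom_names, done$res)
  m <- match(key_in, key_out)
  # PDB rounding aside, the parsed heavy coordinates pass through unchanged
  expect_identical(raw$coords, done$coords[m, ])
  expect_identical(complete_fragment(done)$coords, done$coords)
  expect_true(validate_fragment(done))
  # input hydrogens are discarded and rebuilt from the template
  with_h <- parse_structure(paste(
    write_fragment_pdb(done, heavy_only = FALSE), collapse = "\n"))
  redone <- complete_fragment(extract_dual_fragments(with_h)[[1]])
  expect_equal(nrow(redone$coords), atom_count(raw$label))
})

test_that("heavy-atom mismatches are rejected naming the offender", {
  fr <- fixture_conformer("ALA", 3)
  heavy <- fr$elements != "H"
  no_cb <- fragment("ALA", fr$atom_names[heavy & fr$atom_names != "CB"],
                    fr$elements[heavy & fr$atom_names != "CB"],
                    fr$coords[heavy & fr$atom_names != "CB", ],
                    complete = FALSE)
  expect_error(complete_fragment(no_cb), "CB")
})

test_that("proline completion restores the 17-atom free form", {
  fr <- fixture_conformer("PRO", 4)
  heavy <- fr$elements != "H" & fr$atom_names != "OXT"
  raw <- fragment("PRO", fr$atom_names[heavy], fr$elements[heavy],
                  fr$coords[heavy, ], complete = FALSE)
  expect_equal(nrow(raw$coords), 7)  # N CA C O CB CG CD
  done <- complete_fragment(raw)
  expect_equal(nrow(done$coords), 17)
  expect_true("OXT" %in% done$atom_names)
})
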