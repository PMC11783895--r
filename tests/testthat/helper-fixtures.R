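# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# A clash-free conformer with pinned dihedrals (retries psi if needed).
fixture_conformer <- function(label, seed = 1L) {
  fixture(paste0("conf:", label, ":", seed), function() {
    generate_class_ensemble(conformer_spec(label, 1L, seed = seed))[[1]]
  })
}

# Small ensembles reused across featurization and split tests.
fixture_ensemble <- function(label, n, seed = 1L,
                             mode = "uniform_dihedrals", ...) {
  fixture(paste(c("ens", label, n, seed, mode, ...), collapse = ":"),
          function()
    generate_class_ensemble(conformer_spec(label, n, seed = seed,
                                           mode = mode, ...)))
}

# Two-residue PDB text from a built conformer (heavy atoms only).
fixture_dipeptide_pdb <- function(label = "METGLN", seed = 5L) {
  fixture(paste0("pdb:", label, ":", seed), function() {
    fr <- fixture_conformer(label, seed)
    paste(write_fragment_pdb(fr, heavy_only = TRUE), collapse = "\n")
  })
}

# Three-residue chain PDB (ALA-GLY-SER) assembled from two dipeptide
# conformers sharing the middle glycine backbone (superposed by Kabsch).
fixture_tripeptide_pdb <- function() {
  fixture("pdb:AGS", function() {
    f1 <- fixture_conformer("ALAGLY", 11L)
    f2 <- fixture_conformer("GLYSER", 12L)
    key1 <- paste(f1$atom_names, f1$res)
    key2 <- paste(f2$atom_names, f2$res)
    # N/CA/C triads are congruent across fragments (identical internal
    # geometry), so the superposition is exact and the peptide bond to the
    # third residue keeps its ideal length
    anchor <- c("N 2", "CA 2", "C 2")            # GLY backbone in frame 1
    target <- c("N 1", "CA 1", "C 1")            # GLY backbone in frame 2
    A <- f1$coords[match(anchor, key1), ]
    B <- f2$coords[match(target, key2), ]
    # Kabsch: rotate/translate f2 so its GLY backbone lands on f1's
    cb <- colMeans(B); ca <- colMeans(A)
    Bc <- sweep(B, 2, cb); Ac <- sweep(A, 2, ca)
    sv <- svd(crossprod(Bc, Ac))
    R <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    co2 <- sweep(sweep(f2$coords, 2, cb) %*% t(R), 2, -ca)
    # chain: ALA (res1 of f1), GLY (res2 of f1), SER (res2 of f2 moved)
    sel1 <- f1$res == 1 & f1$elements != "H"
    sel2 <- f1$res == 2 & f1$elements != "H" & f1$atom_names != "OXT"
    sel3 <- f2$res == 2 & f2$elements != "H"
    pdb_res <- function(names, elems, co, resid, resno, start_serial) {
      vapply(seq_along(names), function(k) {
        nm <- names[k]
        nm4 <- if (nchar(nm) < 4) paste0(" ", formatC(nm, width = -3)) else nm
        sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                start_serial + k - 1L, nm4, resid, resno,
                co[k, 1], co[k, 2], co[k, 3], elems[k])
      }, "")
    }
    l1 <- pdb_res(f1$atom_names[sel1], f1$elements[sel1],
                  f1$coords[sel1, , drop = FALSE], "ALA", 1L, 1L)
    l2 <- pdb_res(f1$atom_names[sel2], f1$elements[sel2],
                  f1$coords[sel2, , drop = FALSE], "GLY", 2L,
                  length(l1) + 1L)
    l3 <- pdb_res(f2$atom_names[sel3], f2$elements[sel3],
                  co2[sel3, , drop = FALSE], "SER", 3L,
                  length(l1) + length(l2) + 1L)
    paste(c(l1, l2, l3, "END"), collapse = "\n")
  })
}

# A small labeled voxel dataset for classifier tests.
fixture_voxel_xy <- function(classes, n_per, seed) {
  fixture(paste(c("xy", classes, n_per, seed), collapse = ":"), function() {
    xs <- list(); ys <- integer(0)
    for (ci in seq_along(classes)) {
      ens <- generate_class_ensemble(
        conformer_spec(classes[ci], n_per, seed = seed * 1000L + ci))
      xs <- c(xs, list(stack_features(ens, "voxel")))
      ys <- c(ys, rep(ci, n_per))
    }
    list(x = do.call(cbind, xs), y = ys, codes = classes)
  })
}
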