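# Residue chemistry: completed neutral-form templates, atom-count
# arithmetic, protonation conventions, and bond-graph properties.

test_that("completed atom counts match the neutral free amino-acid formulas", {
  # independent oracle: element counts of the molecular formula
  for (code in standard_residues()) {
    expect_equal(atom_count(code), sum(residue_formula(code)), info = code)
    tpl <- get_template(code)
    expect_equal(tpl$n_atoms, nrow(tpl$atoms))
    # per-element counts of the atom table match the formula
    tab <- table(tpl$atoms$elem)
    frm <- residue_formula(code)
    expect_identical(as.integer(tab[names(frm)]), unname(as.integer(frm)),
                     info = code)
  }
  # the printed reference counts
  expect_equal(atom_count("MET"), 20)
  expect_equal(atom_count("HIS"), 20)
  expect_equal(atom_count("GLN"), 20)
  expect_equal(atom_count("LEU"), 22)
  expect_equal(atom_count("ILE"), 22)
  expect_equal(atom_count("PRO"), 17)
  expect_equal(atom_count("THR"), 17)
  expect_equal(atom_count("GLY"), 10)  # C2H5NO2
})

test_that("protonation conventions: His Nd tautomer, Cys S-H, neutral termini", {
  his <- get_template("HIS")
  # exactly one H bonded to ND1, none to NE2
  nd1 <- which(his$atoms$name == "ND1")
  ne2 <- which(his$atoms$name == "NE2")
  h_idx <- which(his$atoms$elem == "H")
  bonded_h <- function(tpl, i) {
    b <- tpl$bonds
    nb <- c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
    sum(tpl$atoms$elem[nb] == "H")
  }
  expect_equal(bonded_h(his, nd1), 1)
  expect_equal(bonded_h(his, ne2), 0)
  cys <- get_template("CYS")
  sg <- which(cys$atoms$name == "SG")
  expect_equal(bonded_h(cys, sg), 1)
  # free amine: two H on N (one for proline), acid H on OXT
  for (code in c("ALA", "GLY", "TRP")) {
    tpl <- get_template(code)
    expect_equal(bonded_h(tpl, which(tpl$atoms$name == "N")), 2, info = code)
    expect_equal(bonded_h(tpl, which(tpl$atoms$name == "OXT")), 1,
                 info = code)
  }
  pro <- get_template("PRO")
  expect_equal(bonded_h(pro, which(pro$atoms$name == "N")), 1)
})

test_that("unknown residue codes are rejected by name", {
  expect_error(get_template("XYZ"), "XYZ")
  expect_error(atom_count("ZZZ"), "ZZZ")
  expect_error(dipeptide_template("ALA", "XXX"), "XXX")
})

test_that("bond graph invariants: connected, hydrogens univalent", {
  for (code in standard_residues()) {
    tpl <- get_template(code)
    n <- tpl$n_atoms
    deg <- tabulate(c(tpl$bonds), nbins = n)
    expect_true(all(deg[tpl$atoms$elem == "H"] == 1), info = code)
    # connectivity via union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(tpl$bonds))) {
      a <- find(tpl$bonds[r, 1]); b <- find(tpl$bonds[r, 2])
      if (a != b) parent[a] <- b
    }
    expect_equal(length(unique(vapply(seq_len(n), find, 0L))), 1L,
                 info = code)
  }
})

test_that("dipeptide condensation removes one water equivalent", {
  expect_equal(dipeptide_template("GLY", "GLY")$n_atoms, 17)
  expect_equal(dipeptide_template("MET", "GLN")$n_atoms, 37)
  for (pair in list(c("ALA", "PRO"), c("PRO", "TRP"), c("SER", "CYS"))) {
    tpl <- dipeptide_template(pair[1], pair[2])
    expect_equal(tpl$n_atoms, atom_count(pair[1]) + atom_count(pair[2]) - 3L,
                 info = paste(pair, collapse = "-"))
    expect_equal(sort(unique(tpl$atoms$res)), c(1L, 2L))
  }
  # 400 distinct labels from 20 codes
  labels <- as.vector(outer(standard_residues(), standard_residues(),
                            paste0))
  expect_equal(length(unique(labels)), 400L)
})

test_that("internal coordinates rebuild to the stated bond geometry", {
  # rebuilding Cartesians and measuring back recovers the Z-matrix bond
  # lengths and angles essentially exactly
  for (code in c("ALA", "THR", "ARG", "HIS")) {
    tpl <- get_template(code)
    vars <- rotatable_dihedral_names(code)
    fr <- build_conformer(tpl, setNames(rep(170, length(vars)), vars))
    at <- tpl$atoms
    for (i in seq_len(nrow(at))) {
      if (is.na(at$ip[i]) || is.na(at$ia[i])) next
      r_meas <- sqrt(sum((fr$coords[i, ] - fr$coords[at$ip[i], ])^2))
      expect_lt(abs(r_meas - at$r[i]), 1e-6)
      th_meas <- bond_angle(fr$coords[i, ], fr$coords[at$ip[i], ],
                            fr$coords[at$ia[i], ])
      expect_lt(abs(th_meas - at$th[i]), 1e-4)
    }
  }
})

test_that("only Ser and Cys share an element-blind bond graph", {
  skip_if_not_installed("igraph")
  graphs <- lapply(standard_residues(), function(code) {
    tpl <- get_template(code)
    igraph::graph_from_edgelist(tpl$bonds, directed = FALSE)
  })
  names(graphs) <- standard_residues()
  iso_pairs <- list()
  codes <- standard_residues()
  for (i in seq_along(codes)) for (j in seq_along(codes)) {
    if (j <= i) next
    if (igraph::vcount(graphs[[i]]) != igraph::vcount(graphs[[j]])) next
    if (igraph::isomorphic(graphs[[i]], graphs[[j]]))
      iso_pairs <- c(iso_pairs, list(c(codes[i], codes[j])))
  }
  expect_equal(iso_pairs, list(c("CYS", "SER")))
})

test_that("templates export to a self-contained plain-text table", {
  tt <- template_table("HIS")
  expect_equal(nrow(tt$atoms), atom_count("HIS"))
  path <- tempfile(fileext = ".tsv")
  write.table(tt$atoms, path, sep = "\t", row.names = FALSE)
  back <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  expect_equal(back$name, tt$atoms$name)
  expect_equal(back$r, tt$atoms$r)
  expect_equal(nrow(template_table("GLYGLY")$atoms), 17L)
})
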