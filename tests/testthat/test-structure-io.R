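test_that("minimal PDB parses into one chain with one residue", {
  p <- write_pdb_fixture(c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.46, 0, 0),
    pdb_line(3, " C  ", "ALA", "A", 1, 2.0, 1.2, 0),
    pdb_line(4, " O  ", "ALA", "A", 1, 3.1, 1.3, 0.5),
    pdb_line(5, " CB ", "ALA", "A", 1, 1.8, -0.9, 1.0)))
  s <- classify_entities(preprocess_structure(parse_structure(p, "pdb")))
  expect_length(s$chains, 1)
  expect_equal(nrow(s$chains[["A"]]$res), 1)
  expect_equal(s$chains[["A"]]$res$comp, "ALA")
  expect_false(s$chains[["A"]]$res$incomplete)
})

test_that("only the first model of a multi-model file is retained", {
  p <- write_pdb_fixture(c(
    "MODEL        1",
    pdb_line(1, " CA ", "GLY", "A", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(2, " CA ", "GLY", "A", 1, 9, 9, 9),
    "ENDMDL"))
  s <- parse_structure(p, "pdb")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 0)
})

test_that("unreadable and empty files give informative errors", {
  expect_error(parse_structure(tempfile(), "pdb"), "not found")
  empty <- write_pdb_fixture(character(0))
  expect_error(parse_structure(empty, "pdb"), "empty structure")
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1        a bad line"), bad)
  expect_error(parse_structure(bad, "pdb"), "bad record|unparseable")
})

test_that("preprocess removes H/D, water, and keeps first altloc", {
  lines <- c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.46, 0, 0, altloc = "A"),
    pdb_line(3, " CA ", "ALA", "A", 1, 1.50, 0.2, 0, altloc = "B"),
    pdb_line(4, " C  ", "ALA", "A", 1, 2.0, 1.2, 0),
    pdb_line(5, " O  ", "ALA", "A", 1, 3.1, 1.3, 0.5),
    pdb_line(6, " H  ", "ALA", "A", 1, -0.5, 0.3, 0, element = "H"),
    vapply(1:10, function(k)
      pdb_line(10 + k, " O  ", "HOH", "W", k, k * 3, 0, 10,
               record = "HETATM", element = "O"), ""),
    pdb_line(30, " D  ", "ALA", "A", 1, -0.6, 0.5, 0, element = "D"))
  s <- preprocess_structure(parse_structure(write_pdb_fixture(lines), "pdb"))
  expect_false(any(s$atoms$element %in% c("H", "D")))
  expect_false(any(s$atoms$comp == "HOH"))
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$altloc, "A")          # first in file order
  expect_equal(ca$x, 1.46, tolerance = 1e-6)
  # idempotence
  expect_identical(preprocess_structure(s)$atoms, s$atoms)
})

test_that("registry loads with the exact 20/8/16/31/4 split", {
  reg <- read_registry()
  expect_equal(nrow(reg$entries), 79)
  expect_equal(as.integer(table(reg$entries$category)[
    c("amino_acid", "nucleotide", "ion", "ligand", "lipid")]),
    c(20L, 8L, 16L, 31L, 4L))
  expect_equal(registry_category(reg, c("ZN", "FAD", "CLR", "DA", "GLY")),
               c("ion", "ligand", "lipid", "nucleotide", "amino_acid"))
  expect_true(is.na(registry_category(reg, "SO4")))
  # malformed registry rejected
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(reg$entries[-1, ], bad, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(read_registry(bad), "counts")
})

test_that("entities classify into chains and registered partners", {
  s <- small_complex()$structure
  expect_setequal(names(s$chains), c("A", "B"))
  cats <- vapply(s$partners, function(p) p$category, "")
  expect_setequal(cats, c("ion", "ligand"))
  comps <- vapply(s$partners, function(p) p$comp[1], "")
  expect_setequal(comps, c("ZN", "FAD"))
})

test_that("unregistered hetero components are excluded but reported", {
  p <- write_pdb_fixture(c(
    pdb_line(1, " N  ", "GLY", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "GLY", "A", 1, 1.46, 0, 0),
    pdb_line(3, " C  ", "GLY", "A", 1, 2.0, 1.2, 0),
    pdb_line(4, " O  ", "GLY", "A", 1, 3.1, 1.3, 0.5),
    pdb_line(5, " S  ", "SO4", "B", 1, 5, 5, 5, record = "HETATM",
             element = "S")))
  expect_message(s <- classify_entities(preprocess_structure(
    parse_structure(p, "pdb"))), "SO4")
  expect_length(s$partners, 0)
  expect_equal(s$unregistered, "SO4")
})

test_that("virtual atoms follow the centroid rule", {
  ch <- small_chain()
  res <- ch$res
  # ALA-like: R equals CB when CB is the only side-chain atom
  at <- ch$atoms
  for (i in which(res$comp != "GLY")[1:3]) {
    side <- at[at$res_index == i - 1 & !(at$atom %in% c("N", "CA", "C", "O",
                                                        "OXT")), ]
    expect_equal(unname(ch$virtual[i, "R", ]),
                 unname(colMeans(side[, c("x", "y", "z")])), tolerance = 1e-9)
  }
  gly <- which(res$comp == "GLY")
  if (length(gly)) {
    expect_equal(ch$virtual[gly[1], "R", ], ch$virtual[gly[1], "CA", ],
                 tolerance = 1e-12)
  }
})

test_that("side-chain centroid equals the arithmetic mean (LEU oracle)", {
  set.seed(42)
  side <- matrix(rnorm(12, sd = 2), 4, 3)   # CB, CG, CD1, CD2
  lines <- c(
    pdb_line(1, " N  ", "LEU", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "LEU", "A", 1, 1.46, 0, 0),
    pdb_line(3, " C  ", "LEU", "A", 1, 2.0, 1.2, 0),
    pdb_line(4, " O  ", "LEU", "A", 1, 3.1, 1.3, 0.5),
    pdb_line(5, " CB ", "LEU", "A", 1, side[1, 1], side[1, 2], side[1, 3]),
    pdb_line(6, " CG ", "LEU", "A", 1, side[2, 1], side[2, 2], side[2, 3]),
    pdb_line(7, " CD1", "LEU", "A", 1, side[3, 1], side[3, 2], side[3, 3]),
    pdb_line(8, " CD2", "LEU", "A", 1, side[4, 1], side[4, 2], side[4, 3]))
  s <- classify_entities(preprocess_structure(
    parse_structure(write_pdb_fixture(lines), "pdb")))
  ch <- compute_virtual_atoms(s$chains[["A"]])
  expect_equal(unname(ch$virtual[1, "R", ]), colMeans(side),
               tolerance = 1e-3)
  # centroid lies inside the convex hull: here, within the bounding box
  expect_true(all(ch$virtual[1, "R", ] >= apply(side, 2, min) - 1e-3))
  expect_true(all(ch$virtual[1, "R", ] <= apply(side, 2, max) + 1e-3))
})

test_that("sequence extraction maps modified residues", {
  lines <- c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.4, 0, 0),
    pdb_line(3, " C  ", "ALA", "A", 1, 2, 1, 0),
    pdb_line(4, " O  ", "ALA", "A", 1, 3, 1, 0),
    pdb_line(5, " N  ", "GLY", "A", 2, 4, 0, 0),
    pdb_line(6, " CA ", "GLY", "A", 2, 5.4, 0, 0),
    pdb_line(7, " C  ", "GLY", "A", 2, 6, 1, 0),
    pdb_line(8, " O  ", "GLY", "A", 2, 7, 1, 0),
    pdb_line(9, " N  ", "MSE", "A", 3, 8, 0, 0, record = "HETATM"),
    pdb_line(10, " CA ", "MSE", "A", 3, 9.4, 0, 0, record = "HETATM"),
    pdb_line(11, " C  ", "MSE", "A", 3, 10, 1, 0, record = "HETATM"),
    pdb_line(12, " O  ", "MSE", "A", 3, 11, 1, 0, record = "HETATM"),
    pdb_line(13, " SE ", "MSE", "A", 3, 9.9, -1, 1, record = "HETATM",
             element = "SE"))
  s <- classify_entities(preprocess_structure(
    parse_structure(write_pdb_fixture(lines), "pdb")))
  expect_equal(extract_sequence(s$chains[["A"]]), "AGM")
})

test_that("mmCIF write/parse round trip preserves atoms and coordinates", {
  s <- small_complex()$structure
  f <- tempfile(fileext = ".cif")
  write_mmcif(s, f)
  s2 <- classify_entities(preprocess_structure(parse_structure(f, "mmcif")))
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-3)
  expect_equal(s2$atoms$comp, s$atoms$comp)
})

test_that("residues missing backbone atoms are kept but flagged", {
  lines <- c(
    pdb_line(1, " N  ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, " CA ", "ALA", "A", 1, 1.4, 0, 0),
    pdb_line(3, " C  ", "ALA", "A", 1, 2, 1, 0),
    pdb_line(4, " O  ", "ALA", "A", 1, 3, 1, 0),
    pdb_line(5, " CA ", "SER", "A", 2, 5, 0, 0))   # CA-only residue
  s <- classify_entities(preprocess_structure(
    parse_structure(write_pdb_fixture(lines), "pdb")))
  ch <- s$chains[["A"]]
  expect_equal(ch$res$incomplete, c(FALSE, TRUE))
  expect_error(featurize_chain(ch), "incomplete")
})
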