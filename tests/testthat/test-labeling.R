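test_that("min_heavy_distance matches closed forms and is symmetric", {
  expect_equal(min_heavy_distance(matrix(c(0, 0, 0), 1),
                                  matrix(c(3, 4, 0), 1)), 5.0)
  A <- rbind(c(0, 0, 0), c(1, 0, 0)); B <- matrix(c(4, 0, 0), 1)
  expect_equal(min_heavy_distance(A, B), 3.0)
  expect_equal(min_heavy_distance(B, A), 3.0)
  expect_error(min_heavy_distance(A[0, , drop = FALSE], B), "empty")
})

test_that("min distance over random clouds equals the O(n^2) brute force", {
  set.seed(11)
  for (rep in 1:5) {
    A <- matrix(rnorm(600, sd = 8), 200, 3)
    B <- matrix(rnorm(600, sd = 8), 200, 3)
    brute <- min(as.matrix(stats::dist(rbind(A, B)))[1:200, 201:400])
    expect_equal(min_heavy_distance(A, B), brute, tolerance = 1e-12)
  }
})

test_that("grid and brute-force contact sets are identical", {
  set.seed(21)
  for (rep in 1:20) {
    fx <- make_complex(fixture_spec(
      seed = 300 + rep, n_res = 25, geometry = "random_walk",
      partners = data.frame(
        category = c("ion", "ligand"), comp_id = c("MG", "ATP"),
        anchor = sample(3:23, 2), distance = runif(2, 3, 6)),
      strict_isolation = FALSE))
    g <- compute_contacts(fx$structure, "A", method = "grid")
    b <- compute_contacts(fx$structure, "A", method = "brute")
    expect_identical(contact_key(g), contact_key(b))
    expect_equal(g$min_distance[order(g$residue_index, g$partner_id)],
                 b$min_distance[order(b$residue_index, b$partner_id)],
                 tolerance = 1e-12)
  }
})

test_that("a contact at exactly 5.000 A is included", {
  lines <- c(
    pdb_line(1, " N  ", "ALA", "A", 1, -2, 1, 0),
    pdb_line(2, " CA ", "ALA", "A", 1, -1.4, 0, 0),
    pdb_line(3, " C  ", "ALA", "A", 1, -2, -1, 0),
    pdb_line(4, " O  ", "ALA", "A", 1, -3, -1.5, 0),
    pdb_line(5, " CB ", "ALA", "A", 1, 0, 0, 0),
    pdb_line(6, "ZN  ", " ZN", "B", 1, 5, 0, 0, record = "HETATM",
             element = "ZN"))
  s <- classify_entities(preprocess_structure(
    parse_structure(write_pdb_fixture(lines), "pdb")))
  cc <- compute_contacts(s, "A", cutoff = 5.0)
  expect_equal(nrow(cc), 1)
  expect_equal(cc$min_distance, 5.0, tolerance = 1e-9)
  cc49 <- compute_contacts(s, "A", cutoff = 4.999)
  expect_equal(nrow(cc49), 0)
})

test_that("planted partners just inside/outside the cutoff label correctly", {
  for (d in c(4.99, 5.01)) {
    fx <- make_complex(fixture_spec(
      seed = 77, n_res = 20, partners = data.frame(
        category = "ion", comp_id = "ZN", anchor = 10, distance = d)))
    lab <- fx$labels$labels
    s <- fx$structure
    y <- reduce_to_task_labels(compute_contacts(s, "A"),
                               s$chains[["A"]])$labels
    if (d <= 5.0) {
      expect_equal(sum(y[, "ion"]), 1)
      expect_equal(which(y[, "ion"] == 1), 10)
    } else {
      expect_equal(sum(y[, "ion"]), 0)
    }
    expect_identical(y, lab)     # fixture ground truth agrees
  }
})

test_that("raising the cutoff never removes contacts (monotonicity)", {
  s <- small_complex()$structure
  c5 <- compute_contacts(s, "A", cutoff = 5.0)
  c6 <- compute_contacts(s, "A", cutoff = 6.0)
  expect_true(all(contact_key(c5) %in% contact_key(c6)))
})

test_that("interface matrix projects contacts onto the 20 x 79 grid", {
  reg <- read_registry()
  ch <- small_chain()
  # single HIS-ZN style contact: exactly one nonzero cell
  one <- data.frame(residue_index = 0L, category = "ion",
                    partner_id = "ZN:C:1", partner_comp = "ZN",
                    partner_monomer = 0L, partner_auth = 1L,
                    min_distance = 3.2)
  M <- build_interface_matrix(one, ch, reg)
  expect_equal(dim(M), c(20, 79))
  expect_equal(sum(M), 1)
  expect_equal(M[ch$res$comp[1], "ZN"], 1L)
  # no contacts: all-zero matrix
  M0 <- build_interface_matrix(one[0, ], ch, reg)
  expect_equal(sum(M0), 0)
  # unregistered partner comp is a consistency error
  bad <- one; bad$partner_comp <- "XXX"; bad$category <- "ligand"
  expect_error(build_interface_matrix(bad, ch, reg), "unregistered")
})

test_that("matrix nonzero column count equals planted partner types", {
  fx <- make_complex(fixture_spec(
    seed = 55, n_res = 40, geometry = "ideal_helix",
    partners = data.frame(category = c("ion", "ligand", "nucleotide"),
                          comp_id = c("ZN", "ATP", "DA"),
                          anchor = c(8, 20, 32), distance = c(4, 4, 4))))
  res <- label_structure(fx$path)
  expect_equal(sum(colSums(res$matrix) > 0), 3)
  expect_equal(sum(res$matrix) > 0, nrow(res$contacts) > 0)
})

test_that("task reduction merges nucleotides and keeps tasks separate", {
  fx <- make_complex(fixture_spec(
    seed = 60, n_res = 30, partners = data.frame(
      category = "nucleotide", comp_id = "DA", anchor = 15, distance = 4)))
  y <- fx$labels$labels
  expect_equal(sum(y[, "nucleic"]), 1)
  expect_equal(sum(y[, c("protein", "ligand", "ion", "lipid")]), 0)
  # residue with no contacts: all five labels zero
  expect_true(all(y[1, ] == 0))
})

test_that("protein contacts are symmetric across the interface", {
  fx <- make_complex(fixture_spec(
    seed = 88, n_res = 25, partner_chain = list(n_res = 15, anchor = 12,
                                                distance = 4.0)))
  s <- fx$structure
  yA <- reduce_to_task_labels(compute_contacts(s, "A"), s$chains[["A"]])
  yB <- reduce_to_task_labels(compute_contacts(s, "B"), s$chains[["B"]])
  expect_gt(sum(yA$labels[, "protein"]), 0)
  expect_gt(sum(yB$labels[, "protein"]), 0)
  cA <- compute_contacts(s, "A")
  cA <- cA[cA$category == "amino_acid", ]
  cB <- compute_contacts(s, "B")
  cB <- cB[cB$category == "amino_acid", ]
  expect_setequal(paste(cA$residue_index, cA$partner_monomer),
                  paste(cB$partner_monomer, cB$residue_index))
})

test_that("dataset filter applies both size thresholds at the boundary", {
  chains <- data.frame(chain = c("a", "b", "c", "d", "e"),
                       atom_count = c(8192, 8193, 100, 400, 8192),
                       residue_count = c(50, 50, 47, 48, 48))
  kept <- dataset_filter(chains)
  expect_setequal(kept$chain, c("a", "d", "e"))
  expect_equal(nrow(dataset_filter(chains[0, ])), 0)
})

test_that("label export writes residue table and interval file", {
  fx <- small_complex()
  ch <- fx$structure$chains[["A"]]
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".bed")
  write_labels_tsv(fx$labels, ch, f1)
  tab <- utils::read.delim(f1)
  expect_equal(nrow(tab), 30)
  expect_equal(tab$ion, as.integer(fx$labels$labels[, "ion"]))
  write_labels_bed(fx$labels, f2)
  bed <- utils::read.delim(f2)
  expect_true(all(bed$end > bed$start))
  covered <- unlist(lapply(seq_len(nrow(bed)), function(k)
    (bed$start[k] + 1):bed$end[k]))
  expect_equal(sort(unique(covered)),
               which(rowSums(fx$labels$labels) > 0))
})
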