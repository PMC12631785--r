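# Shared fixtures and independent oracles for the suite.  Everything is
# generated in code under fixed seeds; no binary data on disk.

# memoize expensive fixtures for the session
.fixture_env <- new.env(parent = emptyenv())
memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- fn()
  .fixture_env[[key]]
}

# small mixed complex: helix + ion + ligand + second chain
small_complex <- function() memo("small_complex", function() {
  make_complex(fixture_spec(
    seed = 101, n_res = 30, geometry = "ideal_helix",
    partners = data.frame(category = c("ion", "ligand"),
                          comp_id = c("ZN", "FAD"),
                          anchor = c(10, 20), distance = c(4.0, 4.5)),
    partner_chain = list(n_res = 12, anchor = 3, distance = 4.2)))
})

small_chain <- function() memo("small_chain", function() {
  compute_virtual_atoms(small_complex()$structure$chains[["A"]])
})

small_graph <- function() memo("small_graph", function() {
  featurize_chain(small_chain())
})

# reduced feature widths for fast model tests (node total 111)
tiny_node_cfg <- function() node_feature_config(prottrans = 16,
                                                prostt5_aa = 16, dssp = 9,
                                                geometric_residue = 40,
                                                atomic_residue = 30)

tiny_graph <- function() memo("tiny_graph", function() {
  fx <- make_complex(fixture_spec(
    seed = 33, n_res = 14, geometry = "random_walk",
    partners = data.frame(category = "ion", comp_id = "ZN",
                          anchor = 6, distance = 4.0)))
  featurize_chain(compute_virtual_atoms(fx$structure$chains[["A"]]),
                  cfg = tiny_node_cfg())
})

tiny_model <- function(seed = 7) {
  egnn_model(egnn_config(hidden_dim = 8, message_dim = 8, head_hidden = 4,
                         node_dim = ncol(tiny_graph()$node_features),
                         edge_dim = 450, seed = seed))
}

# hand-written PDB text for parser unit tests
pdb_line <- function(serial, name, comp, chain, seq, x, y, z,
                     record = "ATOM", altloc = " ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, comp, chain, seq, x, y, z, 1.0, 0.0,
          element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# ---- independent oracles ----------------------------------------------

# O(n^2) pairwise AUROC: ties count one half
auroc_oracle <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (n in sn) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(sp) * length(sn))
}

# exhaustive threshold-sweep average precision
auprc_oracle <- function(scores, labels) {
  P <- sum(labels == 1)
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; ap <- 0
  for (t in ths) {
    call <- scores >= t
    tp <- sum(call & labels == 1)
    prec <- tp / sum(call); rec <- tp / P
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# plain double-loop edge oracle for graph topology
edges_oracle <- function(coords, cutoff) {
  L <- nrow(coords)
  out <- NULL
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i != j && sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff) {
      out <- rbind(out, c(i, j))
    }
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# contact set (residue, partner_id) as sorted strings, for set equality
contact_key <- function(contacts) {
  sort(paste(contacts$residue_index, contacts$partner_id,
             contacts$partner_monomer))
}

rigid_copy_structure <- function(s, motion) {
  s$atoms[, c("x", "y", "z")] <-
    apply_rigid_motion(as.matrix(s$atoms[, c("x", "y", "z")]), motion)
  classify_entities(preprocess_structure(s))
}
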