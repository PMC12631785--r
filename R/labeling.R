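#' @title Contact-derived binding-site labels
#' @description Heavy-atom contacts at a 5 A cutoff between a target chain
#'   and every other registered molecule in the structure, the 20 x 79
#'   interface-type matrix, the reduction to five per-residue task labels
#'   (protein, nucleic, ligand, ion, lipid), and the dataset size filter.
#' @name labeling
NULL

#' Binding task names, in canonical column order
#' @export
TASKS <- c("protein", "nucleic", "ligand", "ion", "lipid")

#' Minimum heavy-atom distance between two atom sets
#'
#' @param a,b numeric matrices (n x 3, m x 3) of heavy-atom coordinates.
#' @return smallest Euclidean distance over all cross pairs.
#' @export
min_heavy_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("min_heavy_distance: empty atom set")
  # |a_i - b_j|^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

# Cell-list lookup: for each query atom, candidate target atoms from the 27
# neighbouring cells of an axis-aligned grid with cell size = cutoff.
grid_pairs_within <- function(A, B, cutoff) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  orig <- pmin(apply(A, 2, min), apply(B, 2, min))
  cell <- function(X) {
    G <- floor(sweep(X, 2, orig) / cutoff)
    G[, 1] * 73856093 + G[, 2] * 19349663 + G[, 3] * 83492791
  }
  keyfun <- function(G) paste(G[, 1], G[, 2], G[, 3])
  GB <- floor(sweep(B, 2, orig) / cutoff)
  bkey <- keyfun(GB)
  bmap <- split(seq_len(nrow(B)), bkey)
  GA <- floor(sweep(A, 2, orig) / cutoff)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  cut2 <- cutoff^2
  for (ai in seq_len(nrow(A))) {
    cand <- integer(0)
    for (o in seq_len(27)) {
      k <- paste(GA[ai, 1] + offs[o, 1], GA[ai, 2] + offs[o, 2],
                 GA[ai, 3] + offs[o, 3])
      hit <- bmap[[k]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    d2 <- (B[cand, 1] - A[ai, 1])^2 + (B[cand, 2] - A[ai, 2])^2 +
          (B[cand, 3] - A[ai, 3])^2
    keep <- which(d2 <= cut2)
    if (length(keep)) {
      out_i <- c(out_i, rep.int(ai, length(keep)))
      out_j <- c(out_j, cand[keep])
      out_d <- c(out_d, sqrt(d2[keep]))
    }
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}

brute_pairs_within <- function(A, B, cutoff) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  data.frame(i = hit[, 1], j = hit[, 2], d = sqrt(d2[hit]))
}

chain_coord_matrix <- function(chain) {
  cbind(chain$atoms$x, chain$atoms$y, chain$atoms$z)
}

#' Compute heavy-atom contacts for one target chain
#'
#' A target residue is in contact with a partner monomer (ion, ligand or
#' lipid entity, nucleotide of a nucleic chain, or residue of a *different*
#' protein chain) when the minimum distance between their heavy atoms is
#' within `cutoff` (inclusive).  Intra-chain residue pairs never produce
#' protein contacts.
#'
#' @param s a classified `complex_structure`.
#' @param chain_id id of the target chain in `s$chains`.
#' @param cutoff contact cutoff in Angstrom (default 5.0).
#' @param method `"grid"` (cell lists) or `"brute"` (dense O(n^2) oracle);
#'   both return identical contact sets.
#' @return data.frame with one row per (residue, partner monomer) contact:
#'   `residue_index` (0-based), `category`, `partner_id`, `partner_comp`,
#'   `partner_monomer`, `min_distance`.
#' @export
compute_contacts <- function(s, chain_id, cutoff = 5.0,
                             method = c("grid", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(s, "complex_structure"))
  if (is.null(s$chains)) stop("structure must be classified first")
  target <- s$chains[[chain_id]]
  if (is.null(target)) stop("target chain not found: ", chain_id)
  pairs_within <- if (method == "grid") grid_pairs_within else brute_pairs_within
  Tm <- chain_coord_matrix(target)
  t_res <- target$atoms$res_index
  res <- list()
  add <- function(P, p_group, category, partner_id, comps, auth) {
    pr <- pairs_within(Tm, P, cutoff)
    if (!nrow(pr)) return()
    key <- paste(t_res[pr$i], p_group[pr$j])
    mins <- tapply(pr$d, key, min)
    parts <- strsplit(names(mins), " ", fixed = TRUE)
    ridx <- as.integer(vapply(parts, `[`, "", 1))
    mono <- as.integer(vapply(parts, `[`, "", 2))
    res[[length(res) + 1L]] <<- data.frame(
      residue_index = ridx, category = category, partner_id = partner_id,
      partner_comp = comps[mono + 1L], partner_monomer = mono,
      partner_auth = auth[mono + 1L],
      min_distance = as.numeric(mins), stringsAsFactors = FALSE)
  }
  # partner entities (nucleic chains per monomer; ions/ligands/lipids)
  for (p in s$partners) {
    P <- cbind(p$atoms$x, p$atoms$y, p$atoms$z)
    add(P, p$atoms$monomer, p$category, p$id,
        p$monomers$comp, p$monomers$auth_seq)
  }
  # residues of other protein chains
  for (oc in s$chains) {
    if (identical(oc$chain_id, target$chain_id)) next
    P <- chain_coord_matrix(oc)
    add(P, oc$atoms$res_index, "amino_acid", paste0("chain:", oc$chain_id),
        oc$res$comp, oc$res$auth_seq)
  }
  if (!length(res)) {
    return(data.frame(residue_index = integer(0), category = character(0),
                      partner_id = character(0), partner_comp = character(0),
                      partner_monomer = integer(0), partner_auth = integer(0),
                      min_distance = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$residue_index, out$partner_id, out$partner_monomer), ]
  rownames(out) <- NULL
  out
}

#' Build the 20 x 79 interface-type matrix
#'
#' Rows are the 20 standard amino acids in alphabetical one-letter order;
#' columns are the 79 registry molecules in registry file order.  A cell is
#' 1 when at least one residue of that amino-acid type contacts a molecule
#' of that type; the per-pair combinations are OR-reduced across partners.
#'
#' @param contacts contact table from [compute_contacts()].
#' @param chain the target `residue_chain`.
#' @param registry the `molecule_registry` (defines column order).
#' @return binary 20 x 79 matrix with dimnames.
#' @export
build_interface_matrix <- function(contacts, chain, registry = read_registry()) {
  cols <- registry$entries$comp_id
  M <- matrix(0L, nrow = 20, ncol = length(cols),
              dimnames = list(AA_THREE[AA_ONE], cols))
  if (nrow(contacts)) {
    aa <- chain$res$comp[contacts$residue_index + 1L]
    pc <- contacts$partner_comp
    # modified residues on either side map to their standard component
    std <- function(comp) {
      one <- comp_to_one_letter(comp)
      out <- unname(AA_THREE[one])
      out[one == "X"] <- NA_character_
      ifelse(comp %in% cols, comp, out)
    }
    aa <- std(aa); pc0 <- contacts$partner_comp; pc <- std(pc)
    bad <- (!is.na(pc) & !(pc %in% cols)) |
      (is.na(pc) & !(contacts$category %in% "amino_acid"))
    if (any(bad)) stop("contact references unregistered molecule: ",
                       paste(unique(pc0[bad]), collapse = ", "))
    if (any(is.na(pc))) {
      warning("dropping contacts to unmappable residues: ",
              paste(unique(pc0[is.na(pc)]), collapse = ", "))
    }
    ok <- !is.na(aa) & !is.na(pc)
    M[cbind(match(aa[ok], rownames(M)), match(pc[ok], cols))] <- 1L
  }
  M
}

#' Reduce contacts to five per-residue task labels
#'
#' `protein` marks residues contacting a residue of a different chain;
#' `nucleic` merges DNA and RNA partners; `ligand`, `ion`, `lipid` follow
#' their registry categories.  A residue may be positive in several tasks.
#'
#' @param contacts contact table from [compute_contacts()].
#' @param chain the target `residue_chain`.
#' @return an `interface_labels` object: list with `chain_id` and `labels`,
#'   an `L x 5` binary matrix with columns
#'   `protein, nucleic, ligand, ion, lipid`.
#' @export
reduce_to_task_labels <- function(contacts, chain) {
  L <- nrow(chain$res)
  Y <- matrix(0L, nrow = L, ncol = 5, dimnames = list(NULL, TASKS))
  if (nrow(contacts)) {
    task <- c(amino_acid = "protein", nucleotide = "nucleic",
              ligand = "ligand", ion = "ion", lipid = "lipid")[contacts$category]
    ok <- !is.na(task)
    Y[cbind(contacts$residue_index[ok] + 1L, match(task[ok], TASKS))] <- 1L
  }
  structure(list(chain_id = chain$chain_id, labels = Y),
            class = "interface_labels")
}

#' @export
print.interface_labels <- function(x, ...) {
  cat("<interface_labels> chain", x$chain_id, "-", nrow(x$labels),
      "residues; positives:",
      paste(colnames(x$labels), colSums(x$labels), sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Label one chain of a structure file end to end
#'
#' Convenience wrapper: parse, preprocess, classify, contact, reduce.
#'
#' @param path structure file.
#' @param chain_id target chain id (default: first protein chain).
#' @param cutoff contact cutoff in Angstrom.
#' @param registry a `molecule_registry`.
#' @param format passed to [parse_structure()].
#' @return list with `structure`, `chain`, `contacts`, `labels`, `matrix`.
#' @export
label_structure <- function(path, chain_id = NULL, cutoff = 5.0,
                            registry = read_registry(), format = NULL) {
  s <- parse_structure(path, format)
  s <- preprocess_structure(s)
  s <- classify_entities(s, registry)
  if (!length(s$chains)) stop("no protein chain found in ", path)
  if (is.null(chain_id)) chain_id <- names(s$chains)[1]
  contacts <- compute_contacts(s, chain_id, cutoff = cutoff)
  chain <- s$chains[[chain_id]]
  labels <- reduce_to_task_labels(contacts, chain)
  list(structure = s, chain = chain, contacts = contacts, labels = labels,
       matrix = build_interface_matrix(contacts, chain, registry))
}

#' Filter chains by size for benchmark-style test sets
#'
#' Keeps chains with at most 8192 atoms (1024 x 8) and at least 48
#' residues, the selection rule used to carve a tractable test set out of
#' a full PDB split.
#'
#' @param chains data.frame with columns `chain`, `atom_count`,
#'   `residue_count`.
#' @param max_atoms,min_residues thresholds (defaults 8192 and 48).
#' @return the kept subset, same columns.
#' @export
dataset_filter <- function(chains, max_atoms = 8192L, min_residues = 48L) {
  stopifnot(all(c("atom_count", "residue_count") %in% names(chains)))
  chains[chains$atom_count <= max_atoms &
           chains$residue_count >= min_residues, , drop = FALSE]
}

#' Export labels as a TSV table
#'
#' One row per residue: chain, author number, insertion code, residue type
#' and the five 0/1 task columns.
#'
#' @param labels an `interface_labels`.
#' @param chain the matching `residue_chain`.
#' @param path output file.
#' @export
write_labels_tsv <- function(labels, chain, path) {
  df <- data.frame(chain = chain$chain_id,
                   auth_number = chain$res$auth_seq,
                   icode = chain$res$icode, comp = chain$res$comp,
                   labels$labels, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export per-task binding intervals (BED-like)
#'
#' Runs of consecutive positive residues per task, as 0-based half-open
#' intervals on the chain index.
#'
#' @param labels an `interface_labels`.
#' @param path output file.
#' @export
write_labels_bed <- function(labels, path) {
  rows <- list()
  for (t in TASKS) {
    y <- labels$labels[, t]
    r <- rle(y)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    pos <- which(r$values == 1)
    for (k in pos) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = labels$chain_id, start = starts[k], end = ends[k], task = t)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(chain = character(0), start = integer(0),
                        end = integer(0), task = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
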