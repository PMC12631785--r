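#' @title Synthetic complexes and datasets
#' @description Deterministic generators of multi-chain complexes with
#'   planted binding partners, so that labeling, featurization, model and
#'   training code paths are all testable without downloading a single
#'   structure.  Backbones are built from ideal internal coordinates; the
#'   generated structure is written as a real mmCIF file and re-read
#'   through the parser, so the full I/O path is exercised.  Ground-truth
#'   labels are computed by direct brute-force distance checks inside this
#'   module, independent of the contact-labeling module.
#' @name fixtures
NULL

# Ideal backbone internal coordinates (Angstrom / degrees, trans peptide).
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530,
  a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.4, omega = 180.0)

# Natural extension reference frame: place D given positions A, B, C, the
# bond length |C-D|, the angle B-C-D and the dihedral A-B-C-D.
nerf_place <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ang <- angle_deg * pi / 180
  dih <- dihedral_deg * pi / 180
  bc <- normalize(C - B)
  n <- normalize(pracma_cross(B - A, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

phi_psi_for <- function(geometry, L) {
  switch(geometry,
    ideal_helix = list(phi = rep(-57, L), psi = rep(-47, L)),
    extended    = list(phi = rep(-139, L), psi = rep(135, L)),
    random_walk = {
      # sample from the two main Ramachandran basins
      basin <- stats::runif(L) < 0.6
      list(phi = ifelse(basin, stats::rnorm(L, -63, 6), stats::rnorm(L, -120, 15)),
           psi = ifelse(basin, stats::rnorm(L, -42, 6), stats::rnorm(L, 135, 15)))
    },
    stop("unknown backbone geometry: ", geometry))
}

#' Build an ideal-geometry protein backbone
#'
#' @param sequence one-letter amino-acid string; residues other than
#'   glycine receive a CB atom (side chains beyond CB are not built).
#' @param geometry `"ideal_helix"` (phi=-57, psi=-47), `"extended"`, or
#'   `"random_walk"` (basin-sampled phi/psi; seed the RNG first).
#' @return data.frame of atoms: `res` (1-based), `comp`, `atom`, `element`,
#'   `x`, `y`, `z`.
#' @export
build_backbone <- function(sequence, geometry = "ideal_helix") {
  L <- nchar(sequence)
  stopifnot(L >= 1)
  letters1 <- strsplit(sequence, "")[[1]]
  comp <- unname(AA_THREE[letters1])
  comp[is.na(comp)] <- "ALA"
  pp <- phi_psi_for(geometry, L)
  g <- BB_GEOM
  N <- matrix(NA_real_, L, 3); CAm <- N; Cm <- N; Om <- N; CBm <- N
  N[1, ] <- c(0, 0, 0)
  CAm[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  Cm[1, ] <- CAm[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(L)) {
    if (i > 1) {
      N[i, ] <- nerf_place(N[i - 1, ], CAm[i - 1, ], Cm[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, pp$psi[i - 1])
      CAm[i, ] <- nerf_place(CAm[i - 1, ], Cm[i - 1, ], N[i, ],
                             g$b_n_ca, g$a_c_n_ca, g$omega)
      Cm[i, ] <- nerf_place(Cm[i - 1, ], N[i, ], CAm[i, ],
                            g$b_ca_c, g$a_n_ca_c, pp$phi[i])
    }
    psi_i <- if (i < L) pp$psi[i] else -47
    Om[i, ] <- nerf_place(N[i, ], CAm[i, ], Cm[i, ],
                          g$b_c_o, g$a_ca_c_o, psi_i + 180)
    if (comp[i] != "GLY") {
      CBm[i, ] <- nerf_place(Cm[i, ], N[i, ], CAm[i, ],
                             g$b_ca_cb, g$a_n_ca_cb, -122.6)
    }
  }
  rows <- list()
  for (i in seq_len(L)) {
    nm <- c("N", "CA", "C", "O"); el <- c("N", "C", "C", "O")
    xyz <- rbind(N[i, ], CAm[i, ], Cm[i, ], Om[i, ])
    if (comp[i] != "GLY") {
      nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, CBm[i, ])
    }
    rows[[i]] <- data.frame(res = i, comp = comp[i], atom = nm, element = el,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Template partner geometries: small rigid atom sets (offsets in Angstrom).
partner_template <- function(category, comp_id) {
  if (category == "ion") {
    return(data.frame(atom = toupper(comp_id), element = toupper(comp_id),
                      dx = 0, dy = 0, dz = 0, stringsAsFactors = FALSE))
  }
  if (category %in% c("ligand", "lipid")) {
    k <- 6
    ang <- 2 * pi * (seq_len(k) - 1) / k
    return(data.frame(atom = paste0("C", seq_len(k)), element = "C",
                      dx = 0.75 * cos(ang), dy = 0.75 * sin(ang),
                      dz = rep(c(0, 0.4), length.out = k),
                      stringsAsFactors = FALSE))
  }
  if (category == "nucleotide") {
    return(data.frame(
      atom = c("P", "O5'", "C5'", "C4'", "C3'", "N1"),
      element = c("P", "O", "C", "C", "C", "N"),
      dx = c(0, 0.8, 1.6, 2.4, 3.2, 4.0), dy = c(0, 0.6, 0, 0.6, 0, 0.6),
      dz = 0, stringsAsFactors = FALSE))
  }
  stop("no template for category ", category)
}

#' Specify a synthetic complex
#'
#' @param seed integer RNG seed; fixtures with the same spec are identical.
#' @param n_res residues in the target chain.
#' @param geometry backbone geometry (see [build_backbone()]).
#' @param partners data.frame with columns `category`, `comp_id`,
#'   `anchor` (1-based residue index), `distance` (planted minimum
#'   heavy-atom distance, Angstrom).
#' @param partner_chain optional list(`n_res`, `anchor`, `distance`) to
#'   plant a second protein chain whose nearest heavy atom to the anchor
#'   residue sits at `distance`.
#' @param strict_isolation when TRUE (default), non-protein partners are
#'   placed so no residue other than the anchor is within the 5 A label
#'   cutoff; placement retries with jitter and errors after 100 tries.
#' @param sequence optional explicit sequence; otherwise random.
#' @export
fixture_spec <- function(seed = 1L, n_res = 30L, geometry = "ideal_helix",
                         partners = NULL, partner_chain = NULL,
                         strict_isolation = TRUE, sequence = NULL) {
  if (!is.null(partners)) {
    stopifnot(all(c("category", "comp_id", "anchor", "distance") %in%
                    names(partners)))
    stopifnot(all(partners$distance > 0),
              all(partners$anchor >= 1 & partners$anchor <= n_res))
  }
  structure(list(seed = as.integer(seed), n_res = as.integer(n_res),
                 geometry = geometry, partners = partners,
                 partner_chain = partner_chain,
                 strict_isolation = isTRUE(strict_isolation),
                 sequence = sequence),
            class = "fixture_spec")
}

# place a rigid template so its minimum distance to the anchor residue's
# heavy atoms is exactly `dist`, along direction u from the anchor atom.
place_template <- function(tpl, anchor_xyz, anchor_atoms, u, dist) {
  base <- as.matrix(tpl[, c("dx", "dy", "dz")])
  # orient the template's long (x) axis outward along u so elongated
  # partners stretch away from the chain rather than across it
  v <- pracma_cross(c(1, 0, 0), u)
  s <- vnorm(v); cth <- u[1]
  if (s > 1e-9) {
    K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + K + K %*% K * ((1 - cth) / s^2)
    base <- base %*% t(R)
  } else if (cth < 0) {
    base <- -base
  }
  f <- function(t) {
    P <- sweep(base, 2, anchor_xyz + t * u, "+")
    min_heavy_distance(P, anchor_atoms) - dist
  }
  lo <- 0; hi <- dist + 5
  if (f(hi) < 0) hi <- dist + 20
  for (k in 1:80) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  t <- (lo + hi) / 2
  sweep(base, 2, anchor_xyz + t * u, "+")
}

#' Generate a synthetic complex with planted partners
#'
#' Builds the target backbone from ideal internal coordinates, places each
#' planted partner so the nearest heavy atom of its anchor residue is at
#' exactly the specified distance, writes the assembly to mmCIF, re-reads
#' it through [parse_structure()], and returns the classified structure
#' together with ground-truth labels computed by brute-force distance
#' checks in this module (independent of [compute_contacts()]).
#'
#' @param spec a [fixture_spec()].
#' @param path optional output mmCIF path (default: tempfile).
#' @param label_cutoff cutoff used for the ground-truth labels (5 A).
#' @return list: `structure` (classified), `labels` (`interface_labels`
#'   ground truth for the target chain "A"), `path`, `spec`.
#' @export
make_complex <- function(spec, path = tempfile(fileext = ".cif"),
                         label_cutoff = 5.0) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, function() {
    seqc <- spec$sequence %||%
      paste(sample(AA_ONE, spec$n_res, replace = TRUE), collapse = "")
    bb <- build_backbone(seqc, spec$geometry)
    coords <- as.matrix(bb[, c("x", "y", "z")])
    centroid <- colMeans(coords)
    atoms_list <- list(cbind_chain(bb, "A"))
    planted <- list()
    if (!is.null(spec$partners)) {
      for (k in seq_len(nrow(spec$partners))) {
        p <- spec$partners[k, ]
        tpl <- partner_template(p$category, p$comp_id)
        anchor_rows <- bb$res == p$anchor
        anchor_atoms <- coords[anchor_rows, , drop = FALSE]
        aref <- anchor_atoms[nrow(anchor_atoms), ]   # CB if present, else O
        placed <- NULL
        u0 <- normalize(aref - centroid)
        for (try in 0:100) {
          u <- if (try == 0) u0 else normalize(u0 + stats::rnorm(3, sd = 0.35))
          P <- place_template(tpl, aref, anchor_atoms, u, p$distance)
          other <- coords[!anchor_rows, , drop = FALSE]
          d_other <- min_heavy_distance(P, other)
          clash <- min_heavy_distance(P, coords) < 1.0 ||
            (length(planted) &&
               any(vapply(planted, function(q)
                 min_heavy_distance(P, q$xyz) < 1.0, logical(1))))
          ok <- !clash &&
            (!spec$strict_isolation || d_other > label_cutoff + 0.05)
          if (ok) { placed <- P; break }
        }
        if (is.null(placed)) {
          stop("could not place partner ", p$comp_id, " at anchor ",
               p$anchor, " after 100 tries")
        }
        planted[[k]] <- list(category = p$category, comp = p$comp_id,
                             anchor = p$anchor, xyz = placed, tpl = tpl)
      }
    }
    if (!is.null(spec$partner_chain)) {
      pc <- spec$partner_chain
      seq2 <- paste(sample(AA_ONE, pc$n_res, replace = TRUE), collapse = "")
      bb2 <- build_backbone(seq2, spec$geometry)
      c2 <- as.matrix(bb2[, c("x", "y", "z")])
      anchor_rows <- bb$res == pc$anchor
      anchor_atoms <- coords[anchor_rows, , drop = FALSE]
      aref <- anchor_atoms[nrow(anchor_atoms), ]
      u <- normalize(aref - centroid)
      # shift chain 2 along u until its min distance to the anchor residue
      # is the requested one
  c2 <- sweep(c2, 2, colMeans(c2)) ; c2 <- sweep(c2, 2, aref, "+")
      f <- function(t) min_heavy_distance(sweep(c2, 2, t * u, "+"),
                                          anchor_atoms) - pc$distance
      lo <- 0; hi <- 60
      for (k in 1:80) { mid <- (lo + hi) / 2
        if (f(mid) < 0) lo <- mid else hi <- mid }
      c2 <- sweep(c2, 2, ((lo + hi) / 2) * u, "+")
      bb2$x <- c2[, 1]; bb2$y <- c2[, 2]; bb2$z <- c2[, 3]
      atoms_list[[length(atoms_list) + 1L]] <- cbind_chain(bb2, "B")
    }
    # partner entities appended as HETATM / nucleic chains
    het_chain_ids <- setdiff(LETTERS, c("A", "B"))
    for (k in seq_along(planted)) {
      pl <- planted[[k]]
      cid <- het_chain_ids[k]
      grp <- if (pl$category == "nucleotide") "ATOM" else "HETATM"
      atoms_list[[length(atoms_list) + 1L]] <- data.frame(
        group = grp, atom = pl$tpl$atom, altloc = "",
        comp = pl$comp, chain = cid, seq = 1L, icode = "",
        x = pl$xyz[, 1], y = pl$xyz[, 2], z = pl$xyz[, 3],
        element = pl$tpl$element, model = 1L, stringsAsFactors = FALSE)
    }
    all_atoms <- do.call(rbind, atoms_list)
    all_atoms$serial <- seq_len(nrow(all_atoms))
    s_out <- new_complex_structure(
      all_atoms[, ATOM_COLS], source_id = sprintf("fixture_seed%d", spec$seed),
      format = "mmcif")
    write_mmcif(s_out, path)
    s <- classify_entities(preprocess_structure(parse_structure(path, "mmcif")))
    # ---- ground-truth labels: brute-force, independent of compute_contacts
    L <- spec$n_res
    Y <- matrix(0L, L, 5, dimnames = list(NULL, TASKS))
    for (i in seq_len(L)) {
      ra <- coords[bb$res == i, , drop = FALSE]
      for (pl in planted) {
        dmin <- min_heavy_distance(ra, pl$xyz)
        if (dmin <= label_cutoff) {
          t <- c(ion = "ion", ligand = "ligand", lipid = "lipid",
                 nucleotide = "nucleic")[pl$category]
          Y[i, t] <- 1L
        }
      }
      if (!is.null(spec$partner_chain)) {
        c2 <- atoms_list[[2]]
        dmin <- min_heavy_distance(ra, cbind(c2$x, c2$y, c2$z))
        if (dmin <= label_cutoff) Y[i, "protein"] <- 1L
      }
    }
    labels <- structure(list(chain_id = "A", labels = Y),
                        class = "interface_labels")
    list(structure = s, labels = labels, path = path, spec = spec)
  })
}

cbind_chain <- function(bb, chain_id) {
  data.frame(group = "ATOM", atom = bb$atom, altloc = "", comp = bb$comp,
             chain = chain_id, seq = bb$res, icode = "",
             x = bb$x, y = bb$y, z = bb$z, element = bb$element, model = 1L,
             stringsAsFactors = FALSE)
}

#' Generate a featurized, labeled training task with planted signal
#'
#' Builds `n_chains` helical chains with ions planted near anchor residues
#' (about 10% of residues end up positive for the ion task), featurizes
#' every chain with the deterministic stub embedders, and adds a constant
#' offset to a small slice of the first embedding block for every residue
#' that carries a positive label.  The offset makes the task separable by
#' construction, which is what the learnability tests rely on.
#'
#' @param seed integer seed.
#' @param n_chains number of chains.
#' @param n_res residues per chain.
#' @param n_anchors planted ions per chain.
#' @param offset additive signal magnitude (stub embeddings are ~N(0,1);
#'   2.0 gives a cleanly separable but non-degenerate task).
#' @param cfg a [node_feature_config()]; reduced widths keep tests fast.
#' @return list of per-chain items: `graph` (residue_graph), `labels`
#'   (L x 5 matrix), `chain_id`.
#' @export
make_training_task <- function(seed = 1L, n_chains = 50L, n_res = 200L,
                               n_anchors = 10L, offset = 2.0,
                               cfg = node_feature_config()) {
  items <- vector("list", n_chains)
  for (k in seq_len(n_chains)) {
    anchors <- with_seed(seed * 1000L + k, function()
      sort(sample(seq(3, n_res - 2), n_anchors)))
    spec <- fixture_spec(seed = seed * 1000L + k, n_res = n_res,
                         geometry = "ideal_helix",
                         partners = data.frame(category = "ion",
                                               comp_id = "ZN",
                                               anchor = anchors,
                                               distance = 4.0),
                         strict_isolation = FALSE)
    fx <- make_complex(spec)
    chain <- compute_virtual_atoms(fx$structure$chains[["A"]])
    labels <- reduce_to_task_labels(
      compute_contacts(fx$structure, "A"), chain)$labels
    g <- featurize_chain(chain, cfg = cfg)
    pos <- which(rowSums(labels) > 0)
    sl <- seq_len(min(16L, cfg$dims[[1]]))
    g$node_features[pos, sl] <- g$node_features[pos, sl] + offset
    unlink(fx$path)
    items[[k]] <- list(graph = g, labels = labels,
                       chain_id = sprintf("chain%03d", k))
  }
  items
}
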