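#' @title Structure parsing and preprocessing
#' @description Readers for mmCIF and legacy PDB coordinate files, the
#'   cleaning rules applied before contact extraction (drop hydrogen and
#'   deuterium atoms, water and heavy water, keep only the first alternate
#'   location and only the first model), classification of every entity
#'   against the 79-molecule registry, and per-residue virtual atoms.
#' @name structure_io
NULL

ATOM_COLS <- c("group", "serial", "atom", "altloc", "comp", "chain",
               "seq", "icode", "x", "y", "z", "element", "model")

new_complex_structure <- function(atoms, source_id, format) {
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id, format = format,
                 preprocessed = FALSE, chains = NULL, partners = NULL,
                 unregistered = character(0)),
            class = "complex_structure")
}

#' Parse an mmCIF or PDB structure file
#'
#' Only the first model of multi-model files is retained.  Alternate
#' locations are preserved as read; [preprocess_structure()] resolves them.
#'
#' @param path file path.
#' @param format `"mmcif"`, `"pdb"`, or `NULL` to guess from the extension.
#' @return a `complex_structure` holding a flat atom table.
#' @export
parse_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else stop("cannot guess format from extension: ", path)
  }
  format <- match.arg(format, c("mmcif", "pdb"))
  atoms <- switch(format,
                  mmcif = parse_mmcif_atoms(path),
                  pdb   = parse_pdb_atoms(path))
  if (nrow(atoms) == 0) stop("empty structure: no atom records in ", path)
  first_model <- atoms$model[1]
  atoms <- atoms[atoms$model == first_model, , drop = FALSE]
  new_complex_structure(atoms, source_id = sub("\\.[^.]*$", "", basename(path)),
                        format = format)
}

# Tokenize one mmCIF data line, honouring single/double quoting.
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  tok <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
  gsub("^['\"]|['\"]$", "", tok)
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  cols <- character(0); rows <- list(); in_atom_loop <- FALSE
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^\\s*loop_\\s*$", ln)) {
      # gather the tag block that follows
      tags <- character(0); j <- i + 1L
      while (j <= n && grepl("^\\s*_", lines[j])) {
        tags <- c(tags, sub("\\s.*$", "", trimws(lines[j]))); j <- j + 1L
      }
      if (length(tags) && all(startsWith(tags, "_atom_site."))) {
        cols <- sub("^_atom_site\\.", "", tags)
        in_atom_loop <- TRUE
        i <- j
        buf <- character(0)
        while (i <= n) {
          dl <- lines[i]
          if (grepl("^\\s*(_|loop_|#|data_)", dl)) break
          t <- cif_tokens(dl)
          if (length(t)) {
            buf <- c(buf, t)
            while (length(buf) >= length(cols)) {
              rows[[length(rows) + 1L]] <- buf[seq_along(cols)]
              buf <- buf[-seq_along(cols)]
            }
          }
          i <- i + 1L
        }
        if (length(buf)) stop("malformed _atom_site loop near line ", i,
                              " of ", path)
        next
      } else { i <- j; next }
    }
    i <- i + 1L
  }
  if (!in_atom_loop || length(rows) == 0) {
    return(empty_atom_table())
  }
  M <- do.call(rbind, rows)
  colnames(M) <- cols
  getc <- function(nm, alt = NULL, default = "") {
    if (nm %in% cols) M[, nm]
    else if (!is.null(alt) && alt %in% cols) M[, alt]
    else rep(default, nrow(M))
  }
  dotq <- function(v) { v[v %in% c(".", "?")] <- ""; v }
  seq_raw <- dotq(getc("auth_seq_id", "label_seq_id", "0"))
  data.frame(
    group   = getc("group_PDB", default = "ATOM"),
    serial  = as.integer(seq_len(nrow(M))),
    atom    = dotq(getc("label_atom_id", "auth_atom_id")),
    altloc  = dotq(getc("label_alt_id")),
    comp    = dotq(getc("label_comp_id", "auth_comp_id")),
    chain   = dotq(getc("auth_asym_id", "label_asym_id")),
    seq     = suppressWarnings(as.integer(seq_raw)),
    icode   = dotq(getc("pdbx_PDB_ins_code")),
    x       = as.numeric(getc("Cartn_x")),
    y       = as.numeric(getc("Cartn_y")),
    z       = as.numeric(getc("Cartn_z")),
    element = normalize_element(dotq(getc("type_symbol"))),
    model   = {v <- dotq(getc("pdbx_PDB_model_num", default = "1"))
               v[v == ""] <- "1"; as.integer(v)},
    stringsAsFactors = FALSE)
}

empty_atom_table <- function() {
  data.frame(group = character(0), serial = integer(0), atom = character(0),
             altloc = character(0), comp = character(0), chain = character(0),
             seq = integer(0), icode = character(0), x = numeric(0),
             y = numeric(0), z = numeric(0), element = character(0),
             model = integer(0), stringsAsFactors = FALSE)
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model <- 1L; cur_model <- 1L
  keep <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM") |
          startsWith(lines, "MODEL")
  lines <- lines[keep]
  if (!length(lines)) return(empty_atom_table())
  models <- integer(length(lines)); cur <- 1L
  is_model <- startsWith(lines, "MODEL")
  for (i in seq_along(lines)) {
    if (is_model[i]) cur <- suppressWarnings(as.integer(trimws(substr(lines[i], 11, 14))))
    models[i] <- if (is.na(cur)) 1L else cur
  }
  lines <- lines[!is_model]; models <- models[!is_model]
  fx <- function(a, b) trimws(substr(lines, a, b))
  el <- fx(77, 78)
  # fall back to the atom-name column when the element field is blank
  name <- fx(13, 16)
  el[el == ""] <- element_from_name(name[el == ""])
  xyz <- suppressWarnings(cbind(as.numeric(fx(31, 38)),
                                as.numeric(fx(39, 46)),
                                as.numeric(fx(47, 54))))
  if (anyNA(xyz)) stop("unparseable coordinate field in PDB file ", path,
                       " (first bad record: ",
                       lines[which(rowSums(is.na(xyz)) > 0)[1]], ")")
  data.frame(
    group = fx(1, 6), serial = suppressWarnings(as.integer(fx(7, 11))),
    atom = name, altloc = trimws(substr(lines, 17, 17)),
    comp = fx(18, 20), chain = trimws(substr(lines, 22, 22)),
    seq = suppressWarnings(as.integer(fx(23, 26))),
    icode = trimws(substr(lines, 27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = normalize_element(el), model = models,
    stringsAsFactors = FALSE)
}

normalize_element <- function(el) {
  el <- toupper(gsub("[^A-Za-z]", "", el))
  el
}

element_from_name <- function(name) {
  # PDB atom names: columns 1-2 hold the element, right-justified
  first <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9']+", "", name)))
  two <- substr(first, 1, 2)
  one <- substr(first, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "NA", "CL", "BR", "MN", "CU", "CO",
                    "NI", "CD", "HG", "SE"), two, one)
}

#' Apply the structure cleaning rules
#'
#' Removes hydrogen and deuterium atoms, water (HOH) and heavy water (DOD)
#' entities, and, for atoms refined at alternate locations, keeps only the
#' first location in file order.  The operation is idempotent.
#'
#' @param s a `complex_structure` from [parse_structure()].
#' @return the cleaned `complex_structure` (`preprocessed = TRUE`).
#' @export
preprocess_structure <- function(s) {
  stopifnot(inherits(s, "complex_structure"))
  a <- s$atoms
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  a <- a[!(a$comp %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  # first altloc in file order per atom position
  key <- paste(a$chain, a$seq, a$icode, a$comp, a$atom, sep = "\r")
  keep <- !duplicated(key)
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  s$atoms <- a
  s$preprocessed <- TRUE
  # classification is stale after editing the atom table
  s$chains <- NULL; s$partners <- NULL; s$unregistered <- character(0)
  s
}

new_chain <- function(chain_id, res, atoms) {
  structure(list(chain_id = chain_id, res = res, atoms = atoms,
                 virtual = NULL),
            class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat("<residue_chain>", x$chain_id, "with", nrow(x$res), "residues,",
      nrow(x$atoms), "heavy atoms\n")
  invisible(x)
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("<complex_structure>", x$source_id, "-", nrow(x$atoms), "atoms")
  if (!is.null(x$chains)) {
    cat(";", length(x$chains), "protein chain(s),",
        length(x$partners), "partner entit(ies)")
  }
  cat("\n")
  invisible(x)
}

#' Classify entities against the molecule registry
#'
#' Polymer stretches of (possibly modified) amino acids become protein
#' chains; nucleotide polymer stretches become one nucleic partner entity
#' per chain; registered ions/ligands/lipids become one partner entity per
#' monomer.  Components absent from the registry (crystallization
#' additives, unusual cofactors) are excluded from partner consideration
#' but retained as inert context and reported in `$unregistered`.
#'
#' @param s a preprocessed `complex_structure`.
#' @param registry a `molecule_registry`; defaults to the shipped one.
#' @return `s` with `$chains`, `$partners`, `$unregistered` populated.
#' @export
classify_entities <- function(s, registry = read_registry()) {
  stopifnot(inherits(s, "complex_structure"))
  if (!isTRUE(s$preprocessed)) s <- preprocess_structure(s)
  a <- s$atoms
  res_key <- paste(a$chain, a$seq, a$icode, a$comp, sep = "\r")
  first_idx <- which(!duplicated(res_key))
  res_tab <- data.frame(key = res_key[first_idx],
                        chain = a$chain[first_idx], seq = a$seq[first_idx],
                        icode = a$icode[first_idx], comp = a$comp[first_idx],
                        stringsAsFactors = FALSE)
  res_tab$kind <- ifelse(is_polymer_aa(res_tab$comp), "aa",
                  ifelse(is_nucleotide(res_tab$comp), "nt",
                  ifelse(!is.na(registry_category(registry, res_tab$comp)),
                         registry_category(registry, res_tab$comp), "other")))
  # ions named like amino acids cannot collide: ion comps (e.g. CA) are not
  # valid 3-letter AA ids, and nucleotide/AA sets are disjoint by length.
  chains <- list(); partners <- list(); unreg <- character(0)
  row_of_res <- match(res_key, res_tab$key)
  for (cid in unique(res_tab$chain)) {
    sel <- res_tab$chain == cid
    aa_rows <- which(sel & res_tab$kind == "aa")
    if (length(aa_rows)) {
      keys <- res_tab$key[aa_rows]
      asel <- res_key %in% keys
      ca <- a[asel, , drop = FALSE]
      ridx <- match(res_key[asel], keys) - 1L
      res <- data.frame(comp = res_tab$comp[aa_rows],
                        one_letter = comp_to_one_letter(res_tab$comp[aa_rows]),
                        auth_seq = res_tab$seq[aa_rows],
                        icode = res_tab$icode[aa_rows],
                        index = seq_along(aa_rows) - 1L,
                        stringsAsFactors = FALSE)
      atoms <- data.frame(res_index = ridx, atom = ca$atom,
                          element = ca$element, x = ca$x, y = ca$y, z = ca$z,
                          stringsAsFactors = FALSE)
      bb <- c("N", "CA", "C", "O")
      res$incomplete <- vapply(seq_len(nrow(res)) - 1L, function(i) {
        nm <- atoms$atom[atoms$res_index == i]
        !all(bb %in% nm)
      }, logical(1))
      ch <- new_chain(cid, res, atoms)
      chains[[cid]] <- ch
    }
    nt_rows <- which(sel & res_tab$kind == "nt")
    if (length(nt_rows)) {
      keys <- res_tab$key[nt_rows]
      asel <- res_key %in% keys
      na_ <- a[asel, , drop = FALSE]
      midx <- match(res_key[asel], keys) - 1L
      partners[[length(partners) + 1L]] <- structure(list(
        id = paste0("nucleic:", cid), category = "nucleotide",
        comp = res_tab$comp[nt_rows], chain_id = cid,
        monomers = data.frame(comp = res_tab$comp[nt_rows],
                              auth_seq = res_tab$seq[nt_rows],
                              stringsAsFactors = FALSE),
        atoms = data.frame(monomer = midx, atom = na_$atom,
                           element = na_$element,
                           x = na_$x, y = na_$y, z = na_$z,
                           stringsAsFactors = FALSE),
        size = length(nt_rows)), class = "partner_entity")
    }
    het_rows <- which(sel & !(res_tab$kind %in% c("aa", "nt")))
    for (r in het_rows) {
      cat_ <- res_tab$kind[r]
      asel <- res_key == res_tab$key[r]
      ha <- a[asel, , drop = FALSE]
      if (cat_ == "other") {
        unreg <- c(unreg, res_tab$comp[r])
        next
      }
      partners[[length(partners) + 1L]] <- structure(list(
        id = paste(res_tab$comp[r], cid, res_tab$seq[r], sep = ":"),
        category = cat_, comp = res_tab$comp[r], chain_id = cid,
        monomers = data.frame(comp = res_tab$comp[r],
                              auth_seq = res_tab$seq[r],
                              stringsAsFactors = FALSE),
        atoms = data.frame(monomer = 0L, atom = ha$atom, element = ha$element,
                           x = ha$x, y = ha$y, z = ha$z,
                           stringsAsFactors = FALSE),
        size = nrow(ha)), class = "partner_entity")
    }
  }
  s$chains <- chains
  s$partners <- partners
  s$unregistered <- unique(unreg)
  if (length(s$unregistered)) {
    message("unregistered components excluded from labeling: ",
            paste(s$unregistered, collapse = ", "))
  }
  s
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Compute the five virtual atoms of each residue
#'
#' Each residue is summarized by five reference points: backbone N, C,
#' CA, O, and `R`, the unweighted centroid of the side-chain heavy atoms.
#' Glycine (and any residue whose side-chain atoms are missing) uses
#' `R = CA`.  Residues missing backbone atoms keep `NA` rows and stay
#' flagged `incomplete`; featurization refuses them downstream.
#'
#' @param chain a `residue_chain`.
#' @return the chain with `$virtual`, an `L x 5 x 3` array with slices
#'   `N`, `C`, `CA`, `O`, `R`.
#' @export
compute_virtual_atoms <- function(chain) {
  stopifnot(inherits(chain, "residue_chain"))
  L <- nrow(chain$res)
  V <- array(NA_real_, dim = c(L, 5, 3),
             dimnames = list(NULL, c("N", "C", "CA", "O", "R"), NULL))
  at <- chain$atoms
  for (i in seq_len(L)) {
    sub <- at[at$res_index == i - 1L, , drop = FALSE]
    for (nm in c("N", "C", "CA", "O")) {
      k <- which(sub$atom == nm)
      if (length(k)) V[i, nm, ] <- c(sub$x[k[1]], sub$y[k[1]], sub$z[k[1]])
    }
    side <- sub[!(sub$atom %in% BACKBONE_ATOMS), , drop = FALSE]
    if (nrow(side) > 0) {
      V[i, "R", ] <- c(mean(side$x), mean(side$y), mean(side$z))
    } else {
      V[i, "R", ] <- V[i, "CA", ]
    }
  }
  chain$virtual <- V
  chain
}

#' Extract the one-letter sequence of a chain
#'
#' Modified residues are mapped through a small decision table (e.g.
#' MSE -> M); anything unmapped becomes `X`.
#'
#' @param chain a `residue_chain`.
#' @return single string of length `L`.
#' @export
extract_sequence <- function(chain) {
  stopifnot(inherits(chain, "residue_chain"))
  paste(chain$res$one_letter, collapse = "")
}

#' Write a structure as mmCIF
#'
#' Emits a minimal `atom_site` loop (coordinates at 0.001 A precision)
#' that [parse_structure()] reads back losslessly.
#'
#' @param s a `complex_structure`.
#' @param path output path.
#' @export
write_mmcif <- function(s, path) {
  stopifnot(inherits(s, "complex_structure"))
  a <- s$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("data_", gsub("\\s", "_", s$source_id)), "#", "loop_",
               paste0("_atom_site.",
                      c("group_PDB", "id", "type_symbol", "label_atom_id",
                        "label_alt_id", "label_comp_id", "auth_asym_id",
                        "auth_seq_id", "pdbx_PDB_ins_code",
                        "Cartn_x", "Cartn_y", "Cartn_z",
                        "pdbx_PDB_model_num"))), con)
  q <- function(v) { v[v == ""] <- "."; v }
  lines <- sprintf("%s %d %s %s %s %s %s %d %s %.3f %.3f %.3f %d",
                   a$group, seq_len(nrow(a)), q(a$element), q(a$atom),
                   q(a$altloc), q(a$comp), q(a$chain), a$seq, q(a$icode),
                   a$x, a$y, a$z, a$model)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}
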