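#' Molecule registry
#'
#' The registry enumerates the 79 molecule types considered when deriving
#' binding-site labels: the 20 standard amino acids, the 8 common
#' nucleotides (DA, DC, DG, DT, A, C, G, U), 16 common ions, 31 common
#' ligands/cofactors, and 4 common lipids.  The category *counts*
#' (20/8/16/31/4, total 79) are fixed and validated at load time; the exact
#' membership of the ion/ligand/lipid categories is configurable — the
#' default list shipped in `inst/extdata/molecule_registry.tsv` covers the
#' most frequent PDB chemical components in each category and users may
#' supply their own file with the same column layout.
#'
#' @param path path to a two-column TSV (`comp_id`, `category`).  Defaults
#'   to the registry shipped with the package.
#' @return a `molecule_registry` object: data.frame with columns `comp_id`
#'   and `category` plus a lookup environment.
#' @export
read_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "molecule_registry.tsv", package = "resbind")
  }
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("comp_id", "category") %in% names(df))) {
    stop("registry must have columns comp_id and category")
  }
  validate_registry(df)
  lookup <- new.env(parent = emptyenv(), size = nrow(df))
  for (i in seq_len(nrow(df))) assign(df$comp_id[i], df$category[i], envir = lookup)
  structure(list(entries = df, lookup = lookup), class = "molecule_registry")
}

# Category sizes are printed pipeline constants; enforce them.
REGISTRY_COUNTS <- c(amino_acid = 20L, nucleotide = 8L, ion = 16L,
                     ligand = 31L, lipid = 4L)

validate_registry <- function(df) {
  if (anyDuplicated(df$comp_id)) stop("registry has duplicated comp_ids")
  cnt <- table(factor(df$category, levels = names(REGISTRY_COUNTS)))
  bad <- which(as.integer(cnt) != REGISTRY_COUNTS)
  if (length(bad)) {
    stop("registry category counts must be 20/8/16/31/4 (amino_acid/",
         "nucleotide/ion/ligand/lipid); got ",
         paste(names(cnt), as.integer(cnt), sep = "=", collapse = ", "))
  }
  if (nrow(df) != 79L) stop("registry must have exactly 79 entries")
  invisible(df)
}

#' @export
print.molecule_registry <- function(x, ...) {
  cat("<molecule_registry> 79 molecule types:",
      paste(names(REGISTRY_COUNTS), REGISTRY_COUNTS, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Look up the category of a chemical component
#'
#' @param registry a `molecule_registry`.
#' @param comp_id character vector of 1-3 letter component ids.
#' @return character vector of categories, `NA` where unregistered.
#' @export
registry_category <- function(registry, comp_id) {
  vapply(comp_id, function(cc) {
    v <- mget(cc, envir = registry$lookup, ifnotfound = list(NA_character_))[[1]]
    v
  }, character(1), USE.NAMES = FALSE)
}

# Standard amino acids: three-letter ids in alphabetical one-letter order.
# This ordering is the canonical row order of the interface-type matrix.
AA_ONE <- c("A","C","D","E","F","G","H","I","K","L",
            "M","N","P","Q","R","S","T","V","W","Y")
AA_THREE <- c(A="ALA", C="CYS", D="ASP", E="GLU", F="PHE", G="GLY", H="HIS",
              I="ILE", K="LYS", L="LEU", M="MET", N="ASN", P="PRO", Q="GLN",
              R="ARG", S="SER", T="THR", V="VAL", W="TRP", Y="TYR")

# Common modified residues mapped to a standard one-letter code; anything
# else maps to 'X'.
MODIFIED_AA <- c(MSE = "M", SEC = "C", PYL = "K", SEP = "S", TPO = "T",
                 PTR = "Y", CSO = "C", HYP = "P", MLY = "K", M3L = "K",
                 KCX = "K", CME = "C", OCS = "C", FME = "M", PCA = "Q")

comp_to_one_letter <- function(comp) {
  out <- names(AA_THREE)[match(comp, AA_THREE)]
  mod <- MODIFIED_AA[comp]
  out[is.na(out) & !is.na(mod)] <- mod[is.na(out) & !is.na(mod)]
  out[is.na(out)] <- "X"
  out
}

NUCLEOTIDE_COMPS <- c("DA", "DC", "DG", "DT", "A", "C", "G", "U")

is_standard_aa <- function(comp) comp %in% AA_THREE
is_polymer_aa <- function(comp) comp %in% AA_THREE | comp %in% names(MODIFIED_AA)
is_nucleotide <- function(comp) comp %in% NUCLEOTIDE_COMPS
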