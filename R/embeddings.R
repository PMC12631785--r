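#' @title Residue embedding providers
#' @description Pluggable per-residue embedding sources.  Real protein
#'   language models (ProtTrans, ProstT5) are consumed through
#'   precomputed-embedding files; the package never downloads model
#'   weights.  A deterministic stub provider stands in for them in tests
#'   and offline runs: it produces pseudo-random but fully reproducible
#'   vectors that depend only on the residue letter, a small sequence
#'   context window, and the provider name.
#' @name embeddings
NULL

#' Deterministic stub embedding provider
#'
#' Each residue's vector is a fixed pseudo-random draw seeded by a hash of
#' `(name, 5-letter context window)`.  Stable across runs and platforms;
#' changing one sequence position only changes rows whose window covers
#' that position.
#'
#' @param name provider name (part of the hash, so "prottrans" and
#'   "prostt5_aa" stubs differ).
#' @param dim embedding width (default 1024).
#' @param window context radius in residues (default 2).
#' @return function(sequence) -> L x dim matrix.
#' @export
stub_embedder <- function(name, dim = 1024L, window = 2L) {
  cache <- new.env(parent = emptyenv())
  force(name); force(dim); force(window)
  function(sequence) {
    letters1 <- strsplit(sequence, "")[[1]]
    L <- length(letters1)
    padded <- c(rep("-", window), letters1, rep("-", window))
    out <- matrix(0, L, dim)
    for (i in seq_len(L)) {
      ctx <- paste(padded[i:(i + 2 * window)], collapse = "")
      key <- paste0(name, "|", dim, "|", ctx)
      v <- cache[[key]]
      if (is.null(v)) {
        v <- with_seed(string_hash(key), function() stats::rnorm(dim))
        cache[[key]] <- v
      }
      out[i, ] <- v
    }
    out
  }
}

#' File-backed embedding provider
#'
#' Reads a precomputed embedding table (TSV, one residue per row, no
#' header) produced by an external protein language model run, keyed by
#' the md5 of the sequence: for sequence S the provider looks for
#' `<dir>/<md5(S)>.tsv`.
#'
#' @param dir directory of embedding files.
#' @param dim expected width; rows must match the query sequence length.
#' @return function(sequence) -> L x dim matrix.
#' @export
file_embedder <- function(dir, dim = 1024L) {
  force(dir); force(dim)
  function(sequence) {
    f <- file.path(dir, paste0(text_md5(sequence), ".tsv"))
    if (!file.exists(f)) {
      stop("no precomputed embedding for this sequence (expected ", f, ")")
    }
    M <- as.matrix(data.table::fread(f, header = FALSE))
    if (nrow(M) != nchar(sequence) || ncol(M) != dim) {
      stop("embedding file ", f, " has shape ", nrow(M), "x", ncol(M),
           ", expected ", nchar(sequence), "x", dim)
    }
    unname(M)
  }
}
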