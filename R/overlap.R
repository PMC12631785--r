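#' @title Annotation-overlap analysis
#' @description Intersects residue feature spans (UniProt-style start/end
#'   annotations) with predicted binding sites, computes per-feature
#'   overlap proportions across proteins, and applies the pLDDT/PAE
#'   quality gate used to select high-confidence predicted structures.
#'   A single overlapping residue qualifies a protein.
#' @name proteome_overlap
NULL

#' Overlap between a feature span and predicted positions
#'
#' @param start,end 1-based inclusive span bounds.
#' @param predicted integer vector of predicted binding-site positions
#'   (1-based).
#' @return sorted integer vector of overlapping positions (possibly
#'   empty).
#' @export
overlap_span <- function(start, end, predicted) {
  if (!(is.numeric(start) && is.numeric(end) && start >= 1 && start <= end)) {
    stop("invalid span: need 1 <= start <= end")
  }
  sort(unique(predicted[predicted >= start & predicted <= end]))
}

#' Proportion of proteins whose feature region overlaps predictions
#'
#' For each (feature name, task) cell: numerator = proteins with at least
#' one residue shared between any span of that feature and the task's
#' predicted sites; denominator = proteins carrying the feature.
#'
#' @param features data.frame with columns `protein_id`, `feature_name`,
#'   `start`, `end`.
#' @param predictions named list: `predictions[[protein_id]][[task]]` is
#'   an integer vector of predicted positions.
#' @param tasks task names (default the five binding tasks).
#' @return data.frame `feature_name` x task columns of fractions in
#'   `[0, 1]` (`NA` for empty denominators), plus `n_proteins`.
#' @export
proportion_with_overlap <- function(features, predictions, tasks = TASKS) {
  stopifnot(all(c("protein_id", "feature_name", "start", "end") %in%
                  names(features)))
  missing <- setdiff(unique(features$protein_id), names(predictions))
  if (length(missing)) {
    stop("predictions missing for protein(s): ",
         paste(missing, collapse = ", "))
  }
  feats <- unique(features$feature_name)
  out <- data.frame(feature_name = feats, stringsAsFactors = FALSE)
  for (t in tasks) out[[t]] <- NA_real_
  out$n_proteins <- 0L
  for (fi in seq_along(feats)) {
    sub <- features[features$feature_name == feats[fi], , drop = FALSE]
    prots <- unique(sub$protein_id)
    out$n_proteins[fi] <- length(prots)
    for (t in tasks) {
      hit <- vapply(prots, function(p) {
        spans <- sub[sub$protein_id == p, , drop = FALSE]
        pred <- predictions[[p]][[t]] %||% integer(0)
        any(vapply(seq_len(nrow(spans)), function(k) {
          length(overlap_span(spans$start[k], spans$end[k], pred)) > 0
        }, logical(1)))
      }, logical(1))
      out[[t]][fi] <- if (length(prots)) mean(hit) else NA_real_
    }
  }
  out
}

#' Quality gate for predicted structures
#'
#' Keeps records with `plddt > min_plddt` and `pae < max_pae` (both
#' strict, matching the selection wording for high-quality predicted
#' structures).  Records with a missing scalar are skipped with a
#' warning.
#'
#' @param records data.frame with columns `plddt` (per-structure mean
#'   predicted lDDT) and `pae` (mean predicted aligned error).
#' @param min_plddt,max_pae gate thresholds (defaults 70.0 and 10.0).
#' @return the kept subset.
#' @export
quality_filter <- function(records, min_plddt = 70.0, max_pae = 10.0) {
  stopifnot(all(c("plddt", "pae") %in% names(records)))
  bad <- is.na(records$plddt) | is.na(records$pae)
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: missing pLDDT or PAE")
    records <- records[!bad, , drop = FALSE]
  }
  records[records$plddt > min_plddt & records$pae < max_pae, , drop = FALSE]
}
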