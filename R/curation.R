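# Candidate selection: correlation threshold, annotation filters and the
# Venn-style accounting of the selection.

#' Annotation table constructor / validator
#'
#' @param annotations data.frame with columns \code{protein_id},
#'   \code{essential} (logical or 0/1), \code{tm_spans} (integer >= 0) and
#'   \code{localization} (semicolon-separated labels; empty or "unknown"
#'   treated as no known compartment)
#' @return validated data.frame of class \code{annotation_table}
#' @export
annotation_table <- function(annotations) {
  need <- c("protein_id", "essential", "tm_spans", "localization")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(annotations$protein_id))
    stop("input integrity: duplicate protein_id in annotations",
         call. = FALSE)
  annotations$protein_id <- as.character(annotations$protein_id)
  annotations$essential <- as.logical(annotations$essential)
  annotations$tm_spans <- as.integer(annotations$tm_spans)
  if (any(annotations$tm_spans < 0, na.rm = TRUE))
    stop("tm_spans must be >= 0", call. = FALSE)
  annotations$localization <- as.character(annotations$localization)
  class(annotations) <- c("annotation_table", "data.frame")
  annotations
}

#' Select proteins whose profile correlates with the activity profile
#'
#' @param records aggregated correlation records
#'   (\code{\link{aggregate_replicates}} output, or any data.frame with
#'   \code{protein_id} and \code{r_mean})
#' @param threshold correlation cut-off in [-1, 1] (default 0.9)
#' @param inclusive if \code{TRUE} (default) the comparison is
#'   \code{r_mean >= threshold}, else strictly greater
#' @return character vector of selected protein ids; proteins with an
#'   undefined score never pass
#' @export
select_correlated <- function(records, threshold = 0.9, inclusive = TRUE) {
  stopifnot(all(c("protein_id", "r_mean") %in% names(records)))
  if (threshold < -1 || threshold > 1)
    stop("'threshold' must lie in [-1, 1]", call. = FALSE)
  r <- records$r_mean
  pass <- !is.na(r) & (if (inclusive) r >= threshold else r > threshold)
  records$protein_id[pass]
}

#' Proteins just below the correlation cut-off
#'
#' Lists proteins with \code{threshold - margin <= r_mean < threshold} for
#' manual rescue review (the near-miss rescue of a biologically compelling
#' candidate, made reproducible).
#'
#' @inheritParams select_correlated
#' @param margin width of the near-miss window, > 0 (a margin of 0 yields
#'   an empty report)
#' @return data.frame with \code{protein_id} and \code{r_mean}, sorted by
#'   decreasing score
#' @export
near_threshold_report <- function(records, threshold = 0.9, margin = 0.02) {
  stopifnot(all(c("protein_id", "r_mean") %in% names(records)))
  if (margin < 0) stop("'margin' must be >= 0", call. = FALSE)
  r <- records$r_mean
  hit <- !is.na(r) & r >= threshold - margin & r < threshold
  out <- data.frame(protein_id = records$protein_id[hit], r_mean = r[hit],
                    stringsAsFactors = FALSE)
  out[order(-out$r_mean), , drop = FALSE]
}

#' Region and intersection sizes of a system of sets
#'
#' @param sets named list of character vectors
#' @return list with \code{intersections} (named sizes of every non-empty
#'   combination's intersection), \code{exclusive} (sizes of the disjoint
#'   Venn regions) and \code{union} (size of the union)
#' @export
venn_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  k <- length(sets)
  inter <- list()
  excl <- list()
  for (m in seq_len(k)) {
    combos <- utils::combn(k, m, simplify = FALSE)
    for (idx in combos) {
      members <- Reduce(intersect, sets[idx])
      others <- setdiff(seq_len(k), idx)
      only <- if (length(others)) setdiff(members, unlist(sets[others]))
              else members
      key <- paste(nm[idx], collapse = "&")
      inter[[key]] <- length(members)
      excl[[key]] <- length(only)
    }
  }
  list(intersections = unlist(inter), exclusive = unlist(excl),
       union = length(unique(unlist(sets))))
}

#' Apply annotation filters to the correlated set
#'
#' Intersects the high-correlation set with annotation-derived filters —
#' essentiality, a minimum number of predicted transmembrane spans, and a
#' subcellular localization label — and reports the Venn accounting plus a
#' machine-readable exclusion reason for every dropped protein. Proteins
#' absent from the annotation table are conservatively excluded
#' (\code{"unannotated"}). Multi-localized proteins (semicolon-separated
#' labels) pass the localization rule if any label matches.
#'
#' @param correlated character vector of protein ids passing the
#'   correlation threshold
#' @param annotations an \code{\link{annotation_table}} (or coercible
#'   data.frame)
#' @param rules list with elements \code{essential} (logical; require
#'   essentiality?), \code{min_tm} (integer; minimum TM spans) and
#'   \code{localization} (label, or \code{NULL} to skip)
#' @return object of class \code{curation_result}: list with
#'   \code{correlated_set}, \code{essential_overlap},
#'   \code{membrane_overlap}, \code{final_candidates}, \code{venn_counts},
#'   \code{excluded} (data.frame id, reason) and \code{rules}
#' @export
apply_filters <- function(correlated, annotations,
                          rules = list(essential = TRUE, min_tm = 3L,
                                       localization = "ER")) {
  if (!inherits(annotations, "annotation_table"))
    annotations <- annotation_table(annotations)
  correlated <- unique(as.character(correlated))
  rules$essential <- isTRUE(rules$essential)
  rules$min_tm <- if (is.null(rules$min_tm)) 0L else as.integer(rules$min_tm)

  ann_idx <- match(correlated, annotations$protein_id)
  annotated <- !is.na(ann_idx)

  essential_ids <- annotations$protein_id[annotations$essential %in% TRUE]
  membrane_ids <- annotations$protein_id[annotations$tm_spans >= rules$min_tm]
  loc_match <- function(labels, want) {
    vapply(strsplit(labels, ";", fixed = TRUE),
           function(l) want %in% trimws(l), logical(1))
  }
  loc_ids <- if (is.null(rules$localization)) annotations$protein_id
             else annotations$protein_id[loc_match(annotations$localization,
                                                   rules$localization)]

  reasons <- character(0)
  ids_excl <- character(0)
  final <- character(0)
  for (i in seq_along(correlated)) {
    id <- correlated[i]
    if (!annotated[i]) {
      ids_excl <- c(ids_excl, id); reasons <- c(reasons, "unannotated")
      next
    }
    fails <- character(0)
    if (rules$essential && !(id %in% essential_ids))
      fails <- c(fails, "not_essential")
    if (!(id %in% membrane_ids))
      fails <- c(fails, sprintf("tm_spans<%d", rules$min_tm))
    if (!is.null(rules$localization) && !(id %in% loc_ids))
      fails <- c(fails, sprintf("not_%s", rules$localization))
    if (length(fails)) {
      ids_excl <- c(ids_excl, id)
      reasons <- c(reasons, paste(fails, collapse = ";"))
    } else final <- c(final, id)
  }

  vsets <- list(correlated = correlated)
  if (rules$essential) vsets$essential <- essential_ids
  vsets$membrane <- membrane_ids
  structure(list(
    r_threshold = NA_real_,  # filled by callers that know the threshold
    rules = rules,
    correlated_set = correlated,
    essential_overlap = intersect(correlated, essential_ids),
    membrane_overlap = intersect(correlated, membrane_ids),
    final_candidates = final,
    venn_counts = venn_counts(vsets),
    excluded = data.frame(protein_id = ids_excl, reason = reasons,
                          stringsAsFactors = FALSE)),
    class = "curation_result")
}

#' Full curation pipeline: threshold then filters
#'
#' @inheritParams select_correlated
#' @inheritParams apply_filters
#' @return a \code{curation_result} (see \code{\link{apply_filters}}) with
#'   the threshold recorded
#' @export
curate_candidates <- function(records, annotations,
                              threshold = 0.9, inclusive = TRUE,
                              rules = list(essential = TRUE, min_tm = 3L,
                                           localization = "ER")) {
  correlated <- select_correlated(records, threshold, inclusive)
  res <- apply_filters(correlated, annotations, rules)
  res$r_threshold <- threshold
  res$inclusive <- inclusive
  res
}

#' @export
print.curation_result <- function(x, ...) {
  cat("Activity correlation curation\n")
  if (!is.na(x$r_threshold))
    cat(sprintf("  correlation threshold: %s %.3g\n",
                if (isTRUE(x$inclusive)) ">=" else ">", x$r_threshold))
  cat(sprintf("  correlated proteins:   %d\n", length(x$correlated_set)))
  cat(sprintf("  ... also essential:    %d\n", length(x$essential_overlap)))
  cat(sprintf("  ... also membrane:     %d\n", length(x$membrane_overlap)))
  cat(sprintf("  final candidates:      %d\n", length(x$final_candidates)))
  if (length(x$final_candidates))
    cat("   ", paste(x$final_candidates, collapse = ", "), "\n")
  invisible(x)
}
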