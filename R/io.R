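# Readers and writers for the pipeline's plain-text formats. All files are
# UTF-8 with a header row; abundance TSVs use "NA" for missing cells.

.check_rect <- function(path, sep) {
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            comment.char = "")
  if (length(nf) == 0L) stop("empty file: ", path, call. = FALSE)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop("parse error in ", path, ": ragged row at line ", bad[1L] + 0L,
         " (", nf[bad[1L]], " fields, expected ", nf[1L], ")",
         call. = FALSE)
}

#' Write / read a profile matrix as TSV
#'
#' Tab-separated, first column \code{protein_id}, remaining columns the
#' fraction labels \code{F<k>}; one file per technical replicate. Missing
#' abundances are written and read as \code{NA}.
#'
#' @param mat a \code{profile_matrix}
#' @param path file path
#' @return \code{write_profile_matrix} returns \code{path} invisibly;
#'   \code{read_profile_matrix} returns a \code{profile_matrix}
#' @export
write_profile_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "profile_matrix"))
  df <- data.frame(protein_id = rownames(mat), unclass(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_profile_matrix
#' @param replicate_id label attached to the matrix on read (default: the
#'   file name without extension)
#' @export
read_profile_matrix <- function(path, replicate_id = NULL) {
  .check_rect(path, "\t")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  if (names(df)[1L] != "protein_id")
    stop("parse error in ", path, ": first column must be 'protein_id'",
         call. = FALSE)
  fr_lab <- names(df)[-1L]
  if (!all(grepl("^F[0-9]+$", fr_lab)))
    stop("parse error in ", path, ": fraction columns must be labelled F<k>",
         call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$protein_id
  if (is.null(replicate_id))
    replicate_id <- sub("\\.[^.]*$", "", basename(path))
  profile_matrix(m, fractions = as.integer(sub("^F", "", fr_lab)),
                 replicate_id = replicate_id)
}

#' Write / read an activity profile as CSV
#'
#' Comma-separated with header \code{fraction,replicate,value,readout}.
#'
#' @param activity an \code{activity_profile} data.frame
#' @param path file path
#' @export
write_activity_profile <- function(activity, path) {
  stopifnot(all(c("fraction", "replicate", "value", "readout")
                %in% names(activity)))
  utils::write.csv(activity, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_activity_profile
#' @export
read_activity_profile <- function(path) {
  .check_rect(path, ",")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("fraction", "replicate", "value", "readout")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df$fraction <- as.integer(df$fraction)
  class(df) <- c("activity_profile", "data.frame")
  df
}

#' Write / read assay counts as CSV
#'
#' Rows of scintillation counts: \code{sample_id, condition, P_cpm, S_cpm}
#' with condition one of \code{buffer}, \code{conA}, \code{conA_TX}.
#'
#' @param counts data.frame with the four columns above
#' @param path file path
#' @export
write_assay_counts <- function(counts, path) {
  need <- c("sample_id", "condition", "P_cpm", "S_cpm")
  stopifnot(all(need %in% names(counts)))
  utils::write.csv(counts[, need], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_assay_counts
#' @export
read_assay_counts <- function(path) {
  .check_rect(path, ",")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("sample_id", "condition", "P_cpm", "S_cpm")
  if (!all(need %in% names(df)))
    stop("parse error in ", path, ": need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ok <- df$condition %in% c("buffer", "conA", "conA_TX")
  if (!all(ok))
    stop("parse error in ", path, ": unknown condition at row ",
         which(!ok)[1L], call. = FALSE)
  df
}

#' Flipping percentages from a table of assay counts
#'
#' Groups counts by \code{sample_id} (each sample needs the full
#' buffer / conA / conA_TX triplet) and evaluates
#' \code{\link{flipping_percent}}.
#'
#' @param counts data.frame as returned by \code{\link{read_assay_counts}}
#' @return data.frame with \code{sample_id}, the three capture
#'   percentages, and \code{flipping}
#' @export
assay_counts_to_flipping <- function(counts) {
  out <- lapply(split(counts, counts$sample_id), function(d) {
    get1 <- function(cond) {
      row <- d[d$condition == cond, , drop = FALSE]
      if (nrow(row) != 1L)
        stop("sample ", d$sample_id[1L], ": need exactly one '", cond,
             "' row", call. = FALSE)
      capture_ratio(row$P_cpm, row$S_cpm)
    }
    r <- c(buffer = get1("buffer"), conA = get1("conA"),
           conA_TX = get1("conA_TX"))
    data.frame(sample_id = d$sample_id[1L],
               R_buffer = r[["buffer"]], R_conA = r[["conA"]],
               R_conA_TX = r[["conA_TX"]],
               flipping = flipping_percent(r[["buffer"]], r[["conA"]],
                                           r[["conA_TX"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read an annotation table as TSV
#'
#' Columns \code{protein_id}, \code{essential} (0/1), \code{tm_spans}
#' (integer) and \code{localization} (semicolon-separated labels).
#'
#' @param annotations an \code{\link{annotation_table}}
#' @param path file path
#' @export
write_annotations <- function(annotations, path) {
  df <- as.data.frame(annotations)
  df$essential <- as.integer(df$essential)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  .check_rect(path, "\t")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  annotation_table(df)
}

#' Write a correlation report as TSV
#'
#' One row per protein: per-replicate scores, mean, SD and the number of
#' replicates with a defined score.
#'
#' @param records \code{\link{aggregate_replicates}} output
#' @param path file path
#' @export
write_correlation_report <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_correlation_report
#' @export
read_correlation_report <- function(path) {
  .check_rect(path, "\t")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(c("protein_id", "r_mean") %in% names(df)))
    stop("parse error in ", path, ": need columns protein_id, r_mean",
         call. = FALSE)
  df
}

#' Serialize a curation result to JSON
#'
#' Sets are written as sorted arrays; counts and rules are echoed so the
#' report is self-describing.
#'
#' @param result a \code{curation_result}
#' @param path file path
#' @export
write_curation_json <- function(result, path) {
  stopifnot(inherits(result, "curation_result"))
  payload <- list(
    r_threshold = result$r_threshold,
    inclusive = isTRUE(result$inclusive),
    rules = result$rules,
    correlated_set = sort(result$correlated_set),
    essential_overlap = sort(result$essential_overlap),
    membrane_overlap = sort(result$membrane_overlap),
    final_candidates = sort(result$final_candidates),
    venn_counts = as.list(result$venn_counts$intersections),
    excluded = result$excluded)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulator / assay configuration (YAML or JSON)
#'
#' @param path file ending in \code{.yaml}, \code{.yml} or \code{.json}
#' @return named list
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml, .yml or .json: ", path, call. = FALSE)
}
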