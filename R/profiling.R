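# Correlation of per-protein abundance profiles with the activity profile,
# and replicate aggregation.

#' Pearson product-moment correlation with explicit degeneracy handling
#'
#' Thin wrapper around \code{stats::cor} that returns \code{NA} (an
#' undefined correlation, never 0) when either vector has zero variance.
#' Invariant under positive-slope affine maps of either argument.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return correlation in [-1, 1], or \code{NA_real_} if undefined
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Correlate protein profiles with the activity profile
#'
#' For one technical replicate: averages duplicate activity measurements
#' per fraction, restricts both the profile matrix and the activity vector
#' to their common fractions (by default the six MS fractions), and computes
#' a Pearson correlation score per protein. Proteins with zero-variance
#' (flat) profiles get an undefined score (\code{NA}).
#'
#' @param mat a \code{profile_matrix} (one replicate)
#' @param activity an \code{activity_profile} (duplicates allowed) or a
#'   data.frame with columns \code{fraction} and \code{value}
#' @return data.frame with columns \code{protein_id}, \code{r},
#'   \code{replicate}
#' @export
correlate_profiles <- function(mat, activity) {
  stopifnot(inherits(mat, "profile_matrix"))
  act <- average_activity(activity)
  common <- intersect(pm_fractions(mat), act$fraction)
  if (length(common) < 3L)
    stop("insufficient overlap: need >= 3 common fractions, got ",
         length(common), call. = FALSE)
  a <- act$value[match(common, act$fraction)]
  sub <- unclass(mat)[, match(common, pm_fractions(mat)), drop = FALSE]
  if (stats::var(a) == 0) {
    r <- rep(NA_real_, nrow(sub))
  } else {
    r <- apply(sub, 1L, function(p) {
      if (anyNA(p) || stats::var(p) == 0) NA_real_ else stats::cor(p, a)
    })
  }
  data.frame(protein_id = rownames(mat), r = unname(r),
             replicate = attr(mat, "replicate_id") %||% "rep1",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate per-replicate correlation scores
#'
#' Combines the per-replicate Pearson scores of each protein into
#' mean +/- SD over the replicates in which the score is defined. Sample
#' (n - 1) standard deviation; a single defined replicate reports SD 0 by
#' convention. Proteins defined in no replicate keep \code{NA} mean and are
#' flagged by \code{n_defined = 0}.
#'
#' @param per_replicate list of data.frames as returned by
#'   \code{\link{correlate_profiles}} (>= 1 replicate)
#' @return data.frame with columns \code{protein_id}, one \code{r_rep<i>}
#'   column per replicate, \code{r_mean}, \code{r_sd}, \code{n_defined}
#' @export
aggregate_replicates <- function(per_replicate) {
  if (is.data.frame(per_replicate)) per_replicate <- list(per_replicate)
  if (length(per_replicate) < 1L)
    stop("need at least one replicate", call. = FALSE)
  ids <- unique(unlist(lapply(per_replicate, `[[`, "protein_id")))
  rmat <- vapply(per_replicate, function(d) {
    d$r[match(ids, d$protein_id)]
  }, numeric(length(ids)))
  rmat <- matrix(rmat, nrow = length(ids))
  n_def <- rowSums(!is.na(rmat))
  r_mean <- ifelse(n_def > 0, rowMeans(rmat, na.rm = TRUE), NA_real_)
  r_sd <- apply(rmat, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) <= 1L) {
      if (length(v) == 1L) 0 else NA_real_
    } else stats::sd(v)
  })
  out <- data.frame(protein_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(per_replicate))
    out[[paste0("r_rep", i)]] <- rmat[, i]
  out$r_mean <- r_mean
  out$r_sd <- r_sd
  out$n_defined <- as.integer(n_def)
  out
}

#' Fraction of maximum abundance
#'
#' Index of the profile maximum; ties are broken toward the lowest
#' (earliest, i.e. slowest-sedimenting) fraction.
#'
#' @param values per-fraction values (nonempty)
#' @param fractions fraction indices (default \code{seq_along(values)})
#' @return the fraction index of the maximum
#' @export
peak_fraction <- function(values, fractions = seq_along(values)) {
  if (length(values) == 0L) stop("empty profile", call. = FALSE)
  fractions[which.max(values)]
}

#' Mean molecular mass of proteins peaking in each fraction
#'
#' Groups proteins by the fraction of their maximum abundance and averages
#' their molecular masses — the diagnostic showing that average mass grows
#' from early to late fractions (monomers and small complexes on top,
#' higher-order complexes deeper in the gradient).
#'
#' @param mat a \code{profile_matrix}
#' @param masses named numeric vector of masses (kDa) keyed by protein id
#' @return data.frame with columns \code{fraction}, \code{mean_mass},
#'   \code{n_proteins}; fractions with no peaking protein are absent
#' @export
mean_mass_by_peak <- function(mat, masses) {
  stopifnot(inherits(mat, "profile_matrix"))
  ids <- rownames(mat)
  known <- ids %in% names(masses)
  if (!all(known)) {
    warning(sum(!known), " protein(s) without mass excluded", call. = FALSE)
    mat <- mat[known, , drop = FALSE]
    ids <- ids[known]
  }
  fr <- pm_fractions(mat)
  peaks <- apply(unclass(mat), 1L, function(v) fr[which.max(v)])
  m <- unname(masses[ids])
  mean_mass <- tapply(m, peaks, mean)
  n_proteins <- tapply(m, peaks, length)
  out <- data.frame(fraction = as.integer(names(mean_mass)),
                    mean_mass = unname(mean_mass),
                    n_proteins = as.integer(n_proteins))
  out[order(out$fraction), , drop = FALSE]
}
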