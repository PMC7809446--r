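# Velocity-gradient sedimentation simulator: species pools, S-value
# calibration, Gaussian banding and TMT-style multiplicative noise.

#' Default mass-to-Svedberg scaling constant
#'
#' Globular-protein scaling constant linking molecular mass to sedimentation
#' coefficient, \code{s = k * M^(2/3)} with M in Da. The default is
#' back-solved so that a 29 kDa globular protein (carbonic anhydrase, the
#' smallest sedimentation standard) sediments at 2.8 S.
#'
#' @export
K_SVEDBERG <- 2.8 / 29000^(2 / 3)

#' Sedimentation coefficient from molecular mass
#'
#' Globular-protein power law \code{s = k * (1000 * mass_kda)^(2/3)}. Used to
#' give simulated species plausible S values consistent with standard
#' sedimentation markers; real complexes deviate from it (shape, bound
#' detergent), which is irrelevant for a synthetic ground truth.
#'
#' @param mass_kda molecular mass in kDa, > 0 (vectorised)
#' @param k scaling constant in Svedberg * Da^(-2/3), > 0
#' @return sedimentation coefficient(s) in Svedberg
#' @examples
#' s_from_mass(29)   # ~2.8 S
#' s_from_mass(660)  # large complex
#' @export
s_from_mass <- function(mass_kda, k = K_SVEDBERG) {
  if (!is.numeric(mass_kda) || any(!is.finite(mass_kda)) || any(mass_kda <= 0))
    stop("'mass_kda' must be positive and finite", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single positive number", call. = FALSE)
  k * (mass_kda * 1000)^(2 / 3)
}

#' Inverse of \code{s_from_mass}
#'
#' @param s sedimentation coefficient(s) in Svedberg, > 0
#' @param k scaling constant, as in \code{\link{s_from_mass}}
#' @return molecular mass in kDa
#' @export
mass_from_s <- function(s, k = K_SVEDBERG) {
  if (any(s <= 0)) stop("'s' must be positive", call. = FALSE)
  (s / k)^(3 / 2) / 1000
}

#' Gradient fraction layout
#'
#' Describes how a velocity gradient is cut into fractions, which fractions
#' are assayed for activity and which are quantified by multiplexed MS.
#' Fractions are indexed 1-based from the top of the gradient (fractions are
#' collected from the top; larger S sediments into higher indices).
#'
#' @param n_fractions total number of fractions (>= 2)
#' @param assayed_fractions indices assayed for activity (default 5:11, the
#'   middle section of the gradient that carries the bulk of the activity)
#' @param ms_fractions indices quantified by MS (default 5:10, six TMT
#'   channels)
#' @param band_sigma Gaussian band spread, in fraction units (> 0)
#' @return object of class \code{gradient_spec}
#' @export
gradient_spec <- function(n_fractions = 12L, assayed_fractions = 5:11,
                          ms_fractions = 5:10, band_sigma = 0.8) {
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 2L)
    stop("'n_fractions' must be an integer >= 2", call. = FALSE)
  assayed_fractions <- as.integer(assayed_fractions)
  ms_fractions <- as.integer(ms_fractions)
  if (!all(assayed_fractions %in% seq_len(n_fractions)))
    stop("'assayed_fractions' must lie within 1..n_fractions", call. = FALSE)
  if (!all(ms_fractions %in% seq_len(n_fractions)))
    stop("'ms_fractions' must lie within 1..n_fractions", call. = FALSE)
  if (!is.numeric(band_sigma) || band_sigma <= 0)
    stop("'band_sigma' must be > 0", call. = FALSE)
  structure(list(n_fractions = n_fractions,
                 assayed_fractions = assayed_fractions,
                 ms_fractions = ms_fractions,
                 band_sigma = band_sigma),
            class = "gradient_spec")
}

#' Default sedimentation standards
#'
#' Four standards (2.8, 3.6, 4.2 and 8.9 S: carbonic anhydrase, ovalbumin,
#' BSA, beta-amylase) with peak positions placed on the package's default
#' linear gradient map, position = 0.82 * S + 2.2. Real gradient runs report
#' the standards' S values only; the positions here are the package's
#' calibration convention, spanning the middle of a 12-fraction gradient.
#'
#' @return data.frame with columns \code{s_value} and \code{peak_position}
#' @export
default_standards <- function() {
  s <- c(2.8, 3.6, 4.2, 8.9)
  data.frame(s_value = s, peak_position = 0.82 * s + 2.2)
}

#' Calibrate the S-to-fraction-position map
#'
#' Least-squares straight line \code{position = slope * S + intercept} fitted
#' to sedimentation standards resolved on a parallel gradient. With exactly
#' two standards the fit is exact.
#'
#' @param standards data.frame with columns \code{s_value} and
#'   \code{peak_position} (or a 2-column matrix / list of pairs)
#' @return object of class \code{gradient_calibration} with elements
#'   \code{slope}, \code{intercept}, \code{fitted_from}
#' @examples
#' calibrate_gradient(data.frame(s_value = c(2.8, 8.9),
#'                               peak_position = c(4.0, 10.1)))
#' @export
calibrate_gradient <- function(standards = default_standards()) {
  if (is.matrix(standards)) {
    standards <- data.frame(s_value = standards[, 1],
                            peak_position = standards[, 2])
  }
  if (!all(c("s_value", "peak_position") %in% names(standards)))
    stop("'standards' needs columns 's_value' and 'peak_position'",
         call. = FALSE)
  s <- as.numeric(standards$s_value)
  p <- as.numeric(standards$peak_position)
  if (length(s) < 2L || length(unique(s)) < 2L)
    stop("calibration failure: need >= 2 standards with distinct S values",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, s), p)
  slope <- unname(fit$coefficients[2L])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration failure: fitted slope must be positive ",
         "(larger S must sediment deeper)", call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(fit$coefficients[1L]),
                 fitted_from = data.frame(s_value = s, peak_position = p)),
            class = "gradient_calibration")
}

#' Map sedimentation coefficients to gradient positions
#'
#' @param s S values (Svedberg)
#' @param cal a \code{gradient_calibration}
#' @return continuous fraction positions
#' @export
position_from_s <- function(s, cal) {
  stopifnot(inherits(cal, "gradient_calibration"))
  cal$slope * s + cal$intercept
}

#' Species pool constructor
#'
#' A pool of sedimenting species: each row is one physical sedimenting
#' entity (monomer or complex). \code{pool_of} links oligomeric states of
#' the same protein: rows sharing a parent id are reported under one id in
#' the MS output (their per-fraction signals sum), mirroring the fact that
#' MS quantifies a protein, not its quaternary state.
#'
#' @param id character ids, unique per row
#' @param mass_kda molecular masses (kDa, > 0)
#' @param abundance arbitrary units, >= 0
#' @param is_active logical; carries the assayed activity
#' @param s_value Svedberg; if NA, derived from mass via
#'   \code{\link{s_from_mass}}
#' @param pool_of optional parent protein id (NA for a standalone species)
#' @return data.frame of class \code{species_pool}
#' @export
species_pool <- function(id, mass_kda, abundance, is_active = FALSE,
                         s_value = NA_real_, pool_of = NA_character_) {
  n <- length(id)
  if (n == 0L) stop("empty species pool", call. = FALSE)
  pool <- data.frame(id = as.character(id),
                     mass_kda = as.numeric(mass_kda),
                     s_value = rep_len(as.numeric(s_value), n),
                     abundance = as.numeric(abundance),
                     is_active = rep_len(as.logical(is_active), n),
                     pool_of = rep_len(as.character(pool_of), n),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(pool$id))
    stop("species ids must be unique", call. = FALSE)
  if (any(pool$abundance < 0))
    stop("abundance must be >= 0", call. = FALSE)
  miss <- is.na(pool$s_value)
  pool$s_value[miss] <- s_from_mass(pool$mass_kda[miss])
  if (any(pool$s_value <= 0))
    stop("s_value must be > 0", call. = FALSE)
  class(pool) <- c("species_pool", "data.frame")
  pool
}

#' MS reporting id of each species (pool parent if pooled)
#' @param pool a \code{species_pool}
#' @return character vector
#' @export
ms_id <- function(pool) {
  ifelse(is.na(pool$pool_of), pool$id, pool$pool_of)
}

#' Gaussian sedimentation band of one species
#'
#' Discretises a Gaussian band centred at the calibrated position of the
#' species' S value, width \code{band_sigma}, over fractions
#' \code{1..n_fractions}, and renormalises so the per-fraction amounts sum
#' to the species' abundance (mass conservation; tails clipped at the
#' gradient ends are folded back by the renormalisation).
#'
#' @param s_value sedimentation coefficient (Svedberg)
#' @param abundance total amount of the species
#' @param gradient a \code{gradient_spec}
#' @param cal a \code{gradient_calibration}
#' @return numeric vector of length \code{n_fractions}, summing to
#'   \code{abundance}
#' @export
band_profile <- function(s_value, abundance, gradient, cal) {
  stopifnot(inherits(gradient, "gradient_spec"))
  centre <- position_from_s(s_value, cal)
  f <- seq_len(gradient$n_fractions)
  dens <- stats::dnorm(f, mean = centre, sd = gradient$band_sigma)
  tot <- sum(dens)
  if (tot <= 0 || !is.finite(tot)) {
    # band centred far outside the gradient: everything pellets at the
    # nearest end
    dens <- numeric(gradient$n_fractions)
    dens[if (centre < 1) 1L else gradient$n_fractions] <- 1
    tot <- 1
  }
  abundance * dens / tot
}

#' True fraction-by-protein profile matrix of a species pool
#'
#' Sums the sedimentation bands of all species, merging pooled oligomeric
#' states under their parent protein id (one row per reported protein).
#'
#' @param pool a \code{species_pool}
#' @param gradient a \code{gradient_spec}
#' @param cal a \code{gradient_calibration}
#' @param fractions fraction indices to report (default: all)
#' @param replicate_id label stored on the matrix
#' @return a \code{profile_matrix}: numeric matrix, rows = proteins,
#'   columns = fractions (labelled \code{F<k>})
#' @export
truth_profiles <- function(pool, gradient, cal,
                           fractions = seq_len(gradient$n_fractions),
                           replicate_id = "truth") {
  stopifnot(inherits(pool, "species_pool"))
  bands <- vapply(seq_len(nrow(pool)), function(i) {
    band_profile(pool$s_value[i], pool$abundance[i], gradient, cal)
  }, numeric(gradient$n_fractions))
  bands <- t(bands)  # species x fraction
  ids <- ms_id(pool)
  m <- rowsum(bands, group = ids, reorder = FALSE)
  m <- m[, fractions, drop = FALSE]
  profile_matrix(m, fractions = fractions, replicate_id = replicate_id)
}

#' Centroid (abundance-weighted mean position) of a band profile
#'
#' Continuous estimate of a band's peak position from its discretised
#' per-fraction amounts. For a Gaussian band of the default width well
#' inside the gradient the centroid recovers the generating centre to high
#' accuracy (the grid-discretisation error decays like
#' \code{exp(-2 pi^2 sigma^2)}); very narrow bands collapse onto single
#' fractions and the centroid then rounds toward integer positions.
#'
#' @param values per-fraction amounts (>= 0, not all zero)
#' @param fractions fraction indices
#' @return continuous fraction position
#' @export
profile_centroid <- function(values, fractions = seq_along(values)) {
  tot <- sum(values)
  if (tot <= 0) stop("profile has no mass", call. = FALSE)
  sum(values * fractions) / tot
}

#' Profile matrix constructor
#'
#' @param values nonnegative numeric matrix (proteins x fractions) with
#'   rownames = protein ids
#' @param fractions integer fraction indices (columns)
#' @param replicate_id label
#' @return object of class \code{profile_matrix}
#' @export
profile_matrix <- function(values, fractions, replicate_id = "rep1") {
  values <- as.matrix(values)
  fractions <- as.integer(fractions)
  if (ncol(values) != length(fractions))
    stop("'fractions' must match the number of columns", call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("profile values must be >= 0", call. = FALSE)
  if (is.null(rownames(values)))
    stop("'values' must carry protein ids as rownames", call. = FALSE)
  colnames(values) <- paste0("F", fractions)
  structure(values, fractions = fractions, replicate_id = replicate_id,
            class = c("profile_matrix", class(values)))
}

#' Fraction indices of a profile matrix
#' @param x a \code{profile_matrix}
#' @return integer vector
#' @export
pm_fractions <- function(x) {
  f <- attr(x, "fractions")
  if (is.null(f)) as.integer(sub("^F", "", colnames(x))) else f
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate TMT-quantified technical replicates
#'
#' Applies multiplicative log-normal measurement noise to a true profile
#' matrix: each replicate cell is \code{truth * exp(eps)} with
#' \code{eps ~ N(0, sigma)} and \code{sigma = sqrt(log(1 + cv^2))}, so the
#' per-cell coefficient of variation equals \code{cv}. The noise is unbiased
#' in the median (\code{median(exp(eps)) = 1}). \code{cv = 0} returns the
#' truth unchanged.
#'
#' @param truth a \code{profile_matrix} (typically restricted to the MS
#'   fractions)
#' @param cv per-cell coefficient of variation, >= 0
#' @param n_replicates number of technical replicates (>= 1)
#' @param seed integer seed; replicates differ only through the seeded RNG
#' @return list of \code{profile_matrix}, one per replicate
#' @export
simulate_tmt <- function(truth, cv = 0.1, n_replicates = 2L, seed = 1L) {
  stopifnot(inherits(truth, "profile_matrix"))
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("'n_replicates' must be a positive integer", call. = FALSE)
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  sigma <- sqrt(log(1 + cv^2))
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      vals <- if (cv == 0) unclass(truth) else
        unclass(truth) * exp(matrix(stats::rnorm(length(truth), 0, sigma),
                                    nrow = nrow(truth)))
      profile_matrix(vals, fractions = pm_fractions(truth),
                     replicate_id = paste0("rep", r))
    })
  })
}

#' Generate a synthetic crude-extract mixture
#'
#' Builds a species pool emulating a detergent extract of ER membrane
#' proteins resolved on a velocity gradient: one active species (the
#' scramblase) plus decoy species with masses drawn log-uniformly and
#' abundances drawn log-normally. All randomness flows through \code{seed}.
#'
#' @param n_decoys number of inactive decoy species (>= 0)
#' @param mass_range decoy mass range in kDa (log-uniform draw)
#' @param abundance_meanlog,abundance_sdlog log-normal abundance parameters
#' @param active_s sedimentation coefficient assigned to the active species
#'   (default 6.5 S, the nominal value of the activity peak); its mass is
#'   derived via \code{\link{mass_from_s}}
#' @param active_id id of the active species
#' @param seed integer seed
#' @return a \code{species_pool}; exactly one row has \code{is_active = TRUE}
#' @export
generate_mixture <- function(n_decoys = 2999L, mass_range = c(20, 300),
                             abundance_meanlog = log(100),
                             abundance_sdlog = 1,
                             active_s = 6.5, active_id = "active_1",
                             seed = 1L) {
  n_decoys <- as.integer(n_decoys)
  if (is.na(n_decoys) || n_decoys < 0L)
    stop("'n_decoys' must be >= 0", call. = FALSE)
  if (length(mass_range) != 2L || any(mass_range <= 0) ||
      mass_range[1] > mass_range[2])
    stop("'mass_range' must be an increasing positive pair", call. = FALSE)
  with_seed(seed, {
    masses <- exp(stats::runif(n_decoys, log(mass_range[1]),
                               log(mass_range[2])))
    abund <- stats::rlnorm(n_decoys + 1L, abundance_meanlog, abundance_sdlog)
    species_pool(
      id = c(active_id, sprintf("decoy_%04d", seq_len(n_decoys))),
      mass_kda = c(mass_from_s(active_s), masses),
      s_value = c(active_s, rep(NA_real_, n_decoys)),
      abundance = abund,
      is_active = c(TRUE, rep(FALSE, n_decoys)))
  })
}
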