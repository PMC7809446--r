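# Method-performance experiments: the 'X + XY' quaternary-structure failure
# mode and the end-to-end recovery benchmark.

#' Configuration of the 'X + XY' scenario
#'
#' One physical protein X occupies two oligomeric states: an active monomer
#' and an inactive 1:1 heterodimer with protein Y. MS cannot distinguish the
#' states — both report under the id of X — so X's measured profile is the
#' sum of the two sedimentation bands, while the activity tracks only the
#' monomer band.
#'
#' @param mass_x monomer mass of X (kDa)
#' @param mass_y mass of Y (kDa); the complex sediments at the mass
#'   \code{mass_x + mass_y} (1:1 stoichiometry)
#' @param complex_fraction share of X's copies bound in the XY complex,
#'   in [0, 1]
#' @param complex_active is the complex itself active? (default FALSE —
#'   the failure mode; TRUE restores a matching profile)
#' @param abundance total abundance of X (arbitrary units)
#' @param cv TMT measurement noise coefficient of variation
#' @param seed integer seed
#' @return object of class \code{xxy_config}
#' @export
xxy_config <- function(mass_x = 60, mass_y = 80, complex_fraction = 0.5,
                       complex_active = FALSE, abundance = 100,
                       cv = 0, seed = 1L) {
  if (complex_fraction < 0 || complex_fraction > 1)
    stop("'complex_fraction' must lie in [0, 1]", call. = FALSE)
  structure(list(mass_x = mass_x, mass_y = mass_y,
                 complex_fraction = complex_fraction,
                 complex_active = isTRUE(complex_active),
                 abundance = abundance, cv = cv, seed = as.integer(seed)),
            class = "xxy_config")
}

# species pool realizing an xxy_config: monomer X + pooled XY complex + free Y
.xxy_pool <- function(cfg) {
  cf <- cfg$complex_fraction
  species_pool(
    id = c("X", "X:XY", "Y"),
    mass_kda = c(cfg$mass_x, cfg$mass_x + cfg$mass_y, cfg$mass_y),
    abundance = c((1 - cf) * cfg$abundance, cf * cfg$abundance,
                  0.5 * cfg$abundance),
    is_active = c(TRUE, cfg$complex_active, FALSE),
    pool_of = c(NA, "X", NA))
}

#' Run the 'X + XY' experiment
#'
#' Builds the two-state pool, simulates the gradient, derives the activity
#' profile from the active state(s) only, and computes the Pearson score of
#' X's composite MS profile against the activity profile. With a large
#' complexed share and well-separated bands, X's broadened profile
#' correlates poorly with the activity and X is discarded by curation —
#' the quaternary-structure failure mode of activity correlation profiling.
#'
#' @param cfg an \code{\link{xxy_config}}
#' @param gradient a \code{gradient_spec}
#' @param cal a \code{gradient_calibration}
#' @param params a \code{recon_params}; if \code{occupancy_scale} is
#'   \code{NULL} (default) it is calibrated once at
#'   \code{complex_fraction = 0} so the peak assayed fraction reads the
#'   target capture, then held fixed
#' @param target_capture peak capture used for calibration (default 70)
#' @return list with \code{r_x} (Pearson score of X, \code{NA} if the
#'   activity is flat), \code{profile_x} (X's per-fraction MS signal over
#'   the MS window), \code{activity} (the activity profile), \code{pool}
#' @export
xxy_experiment <- function(cfg, gradient = gradient_spec(),
                           cal = calibrate_gradient(),
                           params = NULL, target_capture = 70) {
  stopifnot(inherits(cfg, "xxy_config"))
  pool <- .xxy_pool(cfg)
  if (is.null(params)) {
    # fixed assay calibration: enough protein that a pure monomer pool
    # would peak at the target capture
    ref <- .xxy_pool(xxy_config(mass_x = cfg$mass_x, mass_y = cfg$mass_y,
                                complex_fraction = 0,
                                abundance = cfg$abundance))
    ref_amt <- active_amounts(ref, gradient, cal)
    params <- calibrate_occupancy(ref_amt, recon_params(), target_capture)
  }
  amounts <- active_amounts(pool, gradient, cal)
  act <- activity_profile(amounts,
                          fractions = gradient$assayed_fractions,
                          params = params, readout = "capture")
  truth <- truth_profiles(pool, gradient, cal,
                          fractions = gradient$ms_fractions)
  mat <- if (cfg$cv > 0)
    simulate_tmt(truth, cv = cfg$cv, n_replicates = 1L, seed = cfg$seed)[[1]]
  else truth
  rec <- correlate_profiles(mat, act)
  list(r_x = rec$r[rec$protein_id == "X"],
       profile_x = unclass(mat)["X", ],
       activity = act,
       pool = pool,
       params = params)
}

# per-assayed-fraction amounts of all active species in a pool
#' Per-fraction amount of active protein
#'
#' Sums the sedimentation bands of all species flagged active, over the
#' assayed fractions of the gradient.
#'
#' @param pool a \code{species_pool}
#' @param gradient a \code{gradient_spec}
#' @param cal a \code{gradient_calibration}
#' @param fractions fraction indices (default: the assayed fractions)
#' @return numeric vector of amounts, one per fraction
#' @export
active_amounts <- function(pool, gradient, cal,
                           fractions = gradient$assayed_fractions) {
  act <- pool[pool$is_active, , drop = FALSE]
  if (nrow(act) == 0L) return(numeric(length(fractions)))
  bands <- vapply(seq_len(nrow(act)), function(i) {
    band_profile(act$s_value[i], act$abundance[i], gradient, cal)
  }, numeric(gradient$n_fractions))
  rowSums(matrix(bands, nrow = gradient$n_fractions))[fractions]
}

#' Correlation of X as a function of the complexed share
#'
#' Deterministic (noise-free) sweep of \code{\link{xxy_experiment}} over a
#' grid of \code{complex_fraction} values, with the assay calibration held
#' fixed at the \code{complex_fraction = 0} reference. Reports the smallest
#' grid value at which X's score drops below the curation threshold.
#'
#' @param grid complex_fraction values in [0, 1)
#' @param threshold curation correlation threshold (default 0.9)
#' @param cfg template \code{\link{xxy_config}} (its
#'   \code{complex_fraction} and \code{cv} are overridden; the sweep is
#'   noise-free)
#' @inheritParams xxy_experiment
#' @return list with \code{curve} (data.frame complex_fraction, r) and
#'   \code{first_failing} (smallest complex_fraction with r < threshold,
#'   or \code{NA})
#' @export
r_vs_complex_fraction <- function(grid = seq(0, 0.9, by = 0.1),
                                  threshold = 0.9,
                                  cfg = xxy_config(),
                                  gradient = gradient_spec(),
                                  cal = calibrate_gradient(),
                                  target_capture = 70) {
  if (any(grid < 0) || any(grid >= 1))
    stop("'grid' must lie in [0, 1)", call. = FALSE)
  ref <- .xxy_pool(xxy_config(mass_x = cfg$mass_x, mass_y = cfg$mass_y,
                              complex_fraction = 0,
                              abundance = cfg$abundance))
  params <- calibrate_occupancy(active_amounts(ref, gradient, cal),
                                recon_params(), target_capture)
  r <- vapply(grid, function(cf) {
    c2 <- cfg
    c2$complex_fraction <- cf
    c2$cv <- 0
    xxy_experiment(c2, gradient, cal, params = params)$r_x
  }, numeric(1))
  below <- grid[!is.na(r) & r < threshold]
  list(curve = data.frame(complex_fraction = grid, r = r),
       first_failing = if (length(below)) min(below) else NA_real_)
}

#' End-to-end recovery benchmark
#'
#' Quantifies how often activity correlation profiling recovers the true
#' active species under measurement noise: for each of \code{n_sims} seeded
#' simulations, a fresh mixture is generated, fractionated, TMT-noised into
#' replicates and correlated against the (noise-free) activity profile; the
#' rank of the active species by mean Pearson score is recorded, along with
#' whether it passes the correlation threshold.
#'
#' @param n_sims number of simulations (>= 1)
#' @param n_decoys decoy species per mixture
#' @param cv TMT noise coefficient of variation
#' @param n_replicates technical replicates
#' @param threshold curation correlation threshold
#' @param gradient,cal gradient layout and calibration
#' @param target_capture assay design rule: capture percentage at the peak
#'   assayed fraction
#' @param seed master seed; simulation i uses \code{seed + i}
#' @param mixture_args extra arguments passed to
#'   \code{\link{generate_mixture}}
#' @return list with \code{ranks} (integer vector, rank 1 = best),
#'   \code{top1_rate}, \code{threshold_pass_rate} (share of runs where the
#'   active species' mean R meets the threshold), \code{r_active} (its mean
#'   R per run)
#' @export
recovery_benchmark <- function(n_sims = 100L, n_decoys = 2999L, cv = 0.1,
                               n_replicates = 2L, threshold = 0.9,
                               gradient = gradient_spec(),
                               cal = calibrate_gradient(),
                               target_capture = 70,
                               seed = 1L, mixture_args = list()) {
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L)
    stop("'n_sims' must be >= 1", call. = FALSE)
  ranks <- integer(n_sims)
  r_active <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    pool <- do.call(generate_mixture,
                    c(list(n_decoys = n_decoys, seed = seed + i),
                      mixture_args))
    active_id <- pool$id[pool$is_active][1]
    amounts <- active_amounts(pool, gradient, cal)
    params <- calibrate_occupancy(amounts, recon_params(), target_capture)
    act <- activity_profile(amounts, fractions = gradient$assayed_fractions,
                            params = params, readout = "capture")
    truth <- truth_profiles(pool, gradient, cal,
                            fractions = gradient$ms_fractions)
    reps <- simulate_tmt(truth, cv = cv, n_replicates = n_replicates,
                         seed = seed + i)
    agg <- aggregate_replicates(lapply(reps, correlate_profiles,
                                       activity = act))
    ord_r <- agg$r_mean
    ord_r[is.na(ord_r)] <- -Inf
    ranks[i] <- rank(-ord_r, ties.method = "min")[agg$protein_id == active_id]
    r_active[i] <- agg$r_mean[agg$protein_id == active_id]
  }
  list(ranks = ranks,
       top1_rate = mean(ranks == 1L),
       threshold_pass_rate = mean(!is.na(r_active) & r_active >= threshold),
       r_active = r_active)
}
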