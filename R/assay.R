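# Con A end-point capture model of the proteoliposome reconstitution assay:
# Poisson occupancy statistics, capture / flipping readouts, in-silico
# depletion experiments.

#' Reconstitution model parameters
#'
#' @param f_out fraction of reporter lipid in the outer leaflet after
#'   reconstitution (default 0.5, symmetric vesicles)
#' @param occupancy_scale mean active-protein copies per vesicle contributed
#'   per unit of reconstituted active amount (links simulated amounts to the
#'   Poisson mean)
#' @param reconstituted_share share of each gradient fraction that is
#'   reconstituted (default 0.5: half of each fraction goes into vesicles,
#'   the other half to MS)
#' @return object of class \code{recon_params}
#' @export
recon_params <- function(f_out = 0.5, occupancy_scale = 1,
                         reconstituted_share = 0.5) {
  if (f_out < 0 || f_out > 1) stop("'f_out' must lie in [0, 1]", call. = FALSE)
  if (occupancy_scale < 0) stop("'occupancy_scale' must be >= 0", call. = FALSE)
  if (reconstituted_share < 0 || reconstituted_share > 1)
    stop("'reconstituted_share' must lie in [0, 1]", call. = FALSE)
  structure(list(f_out = f_out, occupancy_scale = occupancy_scale,
                 reconstituted_share = reconstituted_share),
            class = "recon_params")
}

#' Percent of reporter lipid captured in the pellet
#'
#' \code{R = 100 * P / (P + S)} from pellet (P) and supernatant (S)
#' scintillation counts.
#'
#' @param P pellet counts (cpm, >= 0); vectorised
#' @param S supernatant counts (cpm, >= 0); vectorised
#' @return capture percentage in [0, 100]
#' @export
capture_ratio <- function(P, S) {
  if (any(P < 0) || any(S < 0)) stop("counts must be >= 0", call. = FALSE)
  tot <- P + S
  if (any(tot == 0))
    stop("undefined measurement: P + S = 0", call. = FALSE)
  100 * P / tot
}

# accept either a capture percentage or a (P, S) counts record
.as_capture <- function(x) {
  if (is.numeric(x) && length(x) == 1L) return(x)
  if (is.list(x) && all(c("P", "S") %in% names(x)))
    return(capture_ratio(x$P, x$S))
  stop("expected a capture percentage or a list with elements P and S",
       call. = FALSE)
}

#' Flipping percentage from the assay triplet
#'
#' Normalised end-point statistic
#' \code{100 * (R_ConA - R_buffer) / (R_ConA_TX - R_buffer)}, where each R
#' is the pellet share of the matching condition: \emph{buffer} (no lectin,
#' background), \emph{ConA} (lectin captures outer-leaflet plus scrambled
#' reporter) and \emph{ConA-TX} (lectin plus detergent, captures everything
#' — the 100% reference). Being a ratio of differences it is invariant
#' under uniform rescaling of all counts.
#'
#' @param buffer,conA,conA_TX capture percentages, or lists with elements
#'   \code{P} and \code{S} (cpm)
#' @return flipping percentage (0 when \code{R_ConA = R_buffer}, 100 when
#'   \code{R_ConA = R_ConA_TX})
#' @export
flipping_percent <- function(buffer, conA, conA_TX) {
  r_buf <- .as_capture(buffer)
  r_cona <- .as_capture(conA)
  r_tx <- .as_capture(conA_TX)
  den <- r_tx - r_buf
  if (abs(den) < .Machine$double.eps * 100)
    stop("assay window collapse: R_ConA_TX equals R_buffer", call. = FALSE)
  100 * (r_cona - r_buf) / den
}

#' Expected end-point capture under Poisson occupancy
#'
#' Reconstitution distributes active-protein copies over an ensemble of
#' identical vesicles following Poisson statistics with mean \code{lambda}.
#' Vesicles with at least one copy (probability \code{1 - exp(-lambda)})
#' scramble their inner-leaflet reporter pool to the outer leaflet where it
#' is captured; unoccupied vesicles expose only the outer-leaflet pool
#' \code{f_out}. The expected captured percentage is
#' \deqn{100 [f_{out} + (1 - f_{out})(1 - e^{-\lambda})]}
#' ranging from \code{100 * f_out} (protein-free liposomes, 50% for
#' symmetric vesicles) to 100% at saturating occupancy.
#'
#' @param lambda mean active copies per vesicle (>= 0); vectorised
#' @param f_out outer-leaflet reporter fraction (default 0.5)
#' @return expected capture percentage; strictly increasing in
#'   \code{lambda}
#' @export
expected_capture <- function(lambda, f_out = 0.5) {
  if (any(lambda < 0)) stop("'lambda' must be >= 0", call. = FALSE)
  if (f_out < 0 || f_out > 1) stop("'f_out' must lie in [0, 1]", call. = FALSE)
  100 * (f_out + (1 - f_out) * (1 - exp(-lambda)))
}

#' Expected flipping percentage under Poisson occupancy
#'
#' The flipping statistic of the ideal assay triplet equals the occupied
#' vesicle fraction: \code{100 * (1 - exp(-lambda))}.
#'
#' @inheritParams expected_capture
#' @return expected flipping percentage
#' @export
expected_flipping <- function(lambda) {
  if (any(lambda < 0)) stop("'lambda' must be >= 0", call. = FALSE)
  100 * (1 - exp(-lambda))
}

#' Poisson mean achieving a target capture percentage
#'
#' Inverts \code{\link{expected_capture}}; e.g. the design rule that the
#' peak fraction should report ~70% capture corresponds to an occupied
#' vesicle fraction of 0.4, i.e. \code{lambda = ln(5/3)}.
#'
#' @param capture target capture percentage, in
#'   \code{(100 * f_out, 100)}
#' @param f_out outer-leaflet reporter fraction
#' @return Poisson mean lambda
#' @export
lambda_for_capture <- function(capture, f_out = 0.5) {
  occ <- (capture / 100 - f_out) / (1 - f_out)
  if (any(occ < 0) || any(occ >= 1))
    stop("'capture' must lie in [100 * f_out, 100)", call. = FALSE)
  -log(1 - occ)
}

#' Calibrate the occupancy scale against a target peak capture
#'
#' Chooses \code{occupancy_scale} so that the fraction with the largest
#' reconstituted active amount reports the target capture percentage — the
#' design rule of reconstituting just enough protein that the peak fraction
#' reads ~70%, keeping the assay inside its dynamic range.
#'
#' @param amounts per-fraction active-protein amounts (>= 0, max > 0)
#' @param params a \code{recon_params}
#' @param target_capture target capture percentage at the peak fraction
#' @return a \code{recon_params} with calibrated \code{occupancy_scale}
#' @export
calibrate_occupancy <- function(amounts, params = recon_params(),
                                target_capture = 70) {
  peak <- max(amounts)
  if (peak <= 0) stop("no active amount to calibrate against", call. = FALSE)
  lam <- lambda_for_capture(target_capture, params$f_out)
  params$occupancy_scale <- lam / (params$reconstituted_share * peak)
  params
}

#' Simulated per-fraction activity profile
#'
#' Converts per-fraction active-protein amounts into the assay readout:
#' \code{lambda_j = occupancy_scale * reconstituted_share * amount_j}, then
#' \code{\link{expected_capture}} (or \code{\link{expected_flipping}}).
#' Optional multiplicative measurement noise produces duplicate readouts.
#'
#' @param amounts per-fraction active amounts (named or indexed by
#'   \code{fractions})
#' @param fractions fraction indices matching \code{amounts}
#' @param params a \code{recon_params}
#' @param readout \code{"capture"} or \code{"flipping"}
#' @param n_measurements readouts per fraction (2 = duplicates)
#' @param noise_cv coefficient of variation of measurement noise (0 = none)
#' @param seed integer seed (used only when \code{noise_cv > 0})
#' @return an \code{activity_profile}: data.frame with columns
#'   \code{fraction}, \code{replicate}, \code{value}, \code{readout}
#' @export
activity_profile <- function(amounts, fractions = seq_along(amounts),
                             params = recon_params(),
                             readout = c("capture", "flipping"),
                             n_measurements = 1L, noise_cv = 0, seed = 1L) {
  readout <- match.arg(readout)
  if (any(amounts < 0)) stop("'amounts' must be >= 0", call. = FALSE)
  if (length(amounts) != length(fractions))
    stop("'fractions' must match 'amounts'", call. = FALSE)
  lam <- params$occupancy_scale * params$reconstituted_share * amounts
  ideal <- if (readout == "capture") expected_capture(lam, params$f_out)
           else expected_flipping(lam)
  vals <- with_seed(seed, {
    lapply(seq_len(n_measurements), function(m) {
      if (noise_cv > 0) {
        sigma <- sqrt(log(1 + noise_cv^2))
        ideal * exp(stats::rnorm(length(ideal), 0, sigma))
      } else ideal
    })
  })
  out <- data.frame(
    fraction = rep(as.integer(fractions), times = n_measurements),
    replicate = rep(seq_len(n_measurements), each = length(fractions)),
    value = unlist(vals),
    readout = readout,
    stringsAsFactors = FALSE)
  class(out) <- c("activity_profile", "data.frame")
  out
}

#' Average duplicate activity measurements per fraction
#'
#' @param activity an \code{activity_profile}
#' @return data.frame with one averaged \code{value} per \code{fraction}
#' @export
average_activity <- function(activity) {
  stopifnot(is.data.frame(activity),
            all(c("fraction", "value") %in% names(activity)))
  agg <- stats::aggregate(value ~ fraction, data = activity, FUN = mean)
  agg[order(agg$fraction), , drop = FALSE]
}

#' In-silico immunodepletion experiment
#'
#' Models removing target proteins from the extract before reconstitution,
#' at a grid of protein-to-phospholipid ratios. Equivalent total amounts of
#' mock-treated and depleted extract are reconstituted, so the Poisson mean
#' scales with the surviving active share:
#' \code{lambda(ppr) = occupancy_scale * ppr * active_share}, with
#' \code{active_share} the surviving active abundance relative to the total
#' extract abundance. Removing species that contribute a fraction q of the
#' active copies multiplies lambda by (1 - q): a complete loss of readout if
#' the sole active species is removed, and (in the small-lambda regime) a
#' readout lowered by q when one of several redundant active species is
#' removed.
#'
#' @param pool a \code{species_pool} describing the extract
#' @param removed_ids character ids to deplete (must exist in the pool)
#' @param ppr_grid protein-to-phospholipid ratios (e.g. 25-125 g/mol)
#' @param params a \code{recon_params}; \code{occupancy_scale} is per unit
#'   of (ppr x active share)
#' @return data.frame with columns \code{ppr}, \code{flipping_mock},
#'   \code{flipping_depleted}
#' @export
depletion_readout <- function(pool, removed_ids, ppr_grid,
                              params = recon_params()) {
  stopifnot(inherits(pool, "species_pool"))
  if (length(ppr_grid) == 0L)
    stop("'ppr_grid' must be nonempty", call. = FALSE)
  removed_ids <- as.character(removed_ids)
  if (!all(removed_ids %in% pool$id))
    stop("unknown ids in 'removed_ids'", call. = FALSE)
  total <- sum(pool$abundance)
  active_mock <- sum(pool$abundance[pool$is_active])
  keep <- !(pool$id %in% removed_ids)
  active_depl <- sum(pool$abundance[pool$is_active & keep])
  lam_mock <- params$occupancy_scale * ppr_grid * active_mock / total
  lam_depl <- params$occupancy_scale * ppr_grid * active_depl / total
  data.frame(ppr = ppr_grid,
             flipping_mock = expected_flipping(lam_mock),
             flipping_depleted = expected_flipping(lam_depl))
}
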