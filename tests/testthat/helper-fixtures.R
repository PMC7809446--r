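# Shared fixtures, built in code.

default_gradient <- gradient_spec()
default_cal <- calibrate_gradient()

# a small single-active-species pool at the nominal activity-peak S
peak_pool <- function(active_s = 6.5, abundance = 100) {
  species_pool("act", mass_from_s(active_s), abundance, TRUE,
               s_value = active_s)
}

# independent textbook Pearson correlation: explicit covariance sums,
# no calls into the code path under test
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# deterministic pseudo-annotations for a species pool: the active species
# matches the curation hypothesis (essential, polytopic, ER); decoys get
# plausible random annotations
make_annotations <- function(pool, seed = 42L,
                             p_essential = 0.18, p_er = 0.25) {
  set.seed(seed)
  n <- nrow(pool)
  locs <- sample(c("ER", "Golgi", "PM", "mito", "unknown"), n, TRUE,
                 prob = c(p_er, 0.15, 0.15, 0.15, 1 - p_er - 0.45))
  ann <- annotation_table(data.frame(
    protein_id = pool$id,
    essential = stats::runif(n) < p_essential,
    tm_spans = stats::rpois(n, 2),
    localization = locs,
    stringsAsFactors = FALSE))
  act <- pool$is_active
  ann$essential[act] <- TRUE
  ann$tm_spans[act] <- 10L
  ann$localization[act] <- "ER"
  ann
}

# ideal assay-count triplet realizing a given Poisson occupancy
triplet_for_lambda <- function(lambda, total = 20000) {
  r_cona <- expected_capture(lambda)
  list(buffer = list(P = total / 2, S = total / 2),
       conA = list(P = total * r_cona / 100,
                   S = total * (1 - r_cona / 100)),
       conA_TX = list(P = total, S = 0))
}
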