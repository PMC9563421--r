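#' Configuration of the synthetic-data generator
#'
#' The generator emulates the statistical structure the analysis assumes,
#' so every stage can be exercised against known truth: a saturating DH
#' trajectory, per-compound relative-content trajectories drawn from five
#' shape archetypes with multiplicative lognormal noise, and odor thresholds
#' spanning several orders of magnitude with one designated low-threshold
#' reference compound.
#'
#' Defaults are calibrated to the study conditions: five sampling times over
#' 0-8 h, 30 compounds, DH kinetics matching the least-squares fit of the
#' saturating model to the measured series (plateau 15.06 %, rate 0.455/h),
#' 5 % multiplicative noise (replicate SDs scale roughly with means), and
#' thresholds log-uniform over 1e-5 to 1e-1 ug/kg.
#'
#' @param seed integer RNG seed.
#' @param n_compounds number of volatiles.
#' @param time_points increasing sampling times, hours.
#' @param dh_max DH plateau, percent.
#' @param dh_rate DH rate constant, 1/h; > 0.
#' @param archetype_mix named proportions over `monotone_up`,
#'   `monotone_down`, `unimodal`, `oscillatory`, `constant`; must sum to 1.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise; >= 0.
#' @param threshold_log10_range log10 bounds of the threshold distribution.
#' @return a list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L, n_compounds = 30L,
                             time_points = c(0, 2, 4, 6, 8),
                             dh_max = 15.06, dh_rate = 0.455,
                             archetype_mix = c(monotone_up = 0.30,
                                               monotone_down = 0.15,
                                               unimodal = 0.20,
                                               oscillatory = 0.25,
                                               constant = 0.10),
                             noise_cv = 0.05,
                             threshold_log10_range = c(-5, -1)) {
  assert_that(is_number(seed), "seed must be a number")
  assert_that(is_number(n_compounds) && n_compounds >= 1,
              "n_compounds must be >= 1")
  assert_that(is.numeric(time_points) && length(time_points) >= 2 &&
                all(diff(time_points) > 0),
              "time_points must be increasing, length >= 2")
  assert_that(is_number(dh_max) && dh_max > 0, "dh_max must be > 0")
  assert_that(is_number(dh_rate) && dh_rate > 0, "dh_rate must be > 0")
  kinds <- c("monotone_up", "monotone_down", "unimodal", "oscillatory",
             "constant")
  assert_that(is.numeric(archetype_mix) &&
                all(names(archetype_mix) %in% kinds) &&
                all(archetype_mix >= 0) &&
                abs(sum(archetype_mix) - 1) < 1e-9,
              "archetype_mix must be named proportions summing to 1")
  assert_that(is_number(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  assert_that(is.numeric(threshold_log10_range) &&
                length(threshold_log10_range) == 2 &&
                diff(threshold_log10_range) >= 0,
              "threshold_log10_range must be increasing bounds")
  structure(list(seed = as.integer(seed),
                 n_compounds = as.integer(n_compounds),
                 time_points = as.numeric(time_points), dh_max = dh_max,
                 dh_rate = dh_rate, archetype_mix = archetype_mix,
                 noise_cv = noise_cv,
                 threshold_log10_range = threshold_log10_range),
            class = "synthetic_config")
}

#' Generate a saturating DH trajectory
#'
#' `DH(t) = dh_max * (1 - exp(-dh_rate * t))`, optionally with additive
#' Gaussian measurement noise (never applied at t = 0, where DH is 0 by
#' definition).
#'
#' @param cfg a [synthetic_config()].
#' @param noise_sd SD of additive noise in DH percent; default 0.
#' @return `data.frame` with columns `time` and `dh`.
#' @export
generate_dh_trajectory <- function(cfg, noise_sd = 0) {
  stopifnot(inherits(cfg, "synthetic_config"))
  assert_that(is_number(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  dh <- dh_saturating(cfg$time_points, cfg$dh_max, cfg$dh_rate)
  if (noise_sd > 0) {
    eps <- with_seed(cfg$seed, stats::rnorm(length(dh), 0, noise_sd))
    dh <- pmax(dh + eps, 0)
    dh[cfg$time_points == 0] <- 0
  }
  data.frame(time = cfg$time_points, dh = dh)
}

#' Titration specs that reproduce a DH series
#'
#' Inverts the DH formula for each target value and packages full
#' [titration_spec()] quantities, so the forward computation round-trips the
#' series exactly.
#'
#' @param dh numeric vector of target DH values (percent, >= 0).
#' @param naoh_conc,volume,mass,protein_fraction titration conditions.
#' @param v2 water-blank NaOH volume, mL.
#' @return list of [titration_spec()], one per DH value.
#' @export
generate_titration_specs <- function(dh, naoh_conc = 0.05, volume = 25,
                                     mass = 5, protein_fraction = 0.69,
                                     v2 = 0.5) {
  diffs <- invert_dh(dh, naoh_conc, volume, mass, protein_fraction)
  lapply(diffs, function(d) {
    titration_spec(naoh_conc, v2 + d, v2, volume, mass, protein_fraction)
  })
}

# Archetype parameter draws. Amplitude ranges keep individual contents in
# (0, 10]% and 30-compound sample totals well below the 100% share bound;
# `scale` shrinks curves further when more compounds share the total.
draw_truth_curve <- function(kind, span, scale = 1) {
  f <- switch(kind,
    monotone_up = {
      c0 <- stats::runif(1, 0.1, 1)
      amp <- stats::runif(1, 0.5, 3)
      r <- stats::runif(1, 1, 3) / span
      function(t) c0 + amp * (1 - exp(-r * t))
    },
    monotone_down = {
      c0 <- stats::runif(1, 0.1, 1)
      amp <- stats::runif(1, 0.5, 3)
      r <- stats::runif(1, 1, 3) / span
      function(t) c0 + amp * exp(-r * t)
    },
    unimodal = {
      c0 <- stats::runif(1, 0.1, 1)
      amp <- stats::runif(1, 0.5, 3)
      mu <- stats::runif(1, 0.25, 0.75) * span
      sig <- stats::runif(1, 0.1, 0.25) * span
      function(t) c0 + amp * exp(-(t - mu)^2 / (2 * sig^2))
    },
    oscillatory = {
      a <- stats::runif(1, 0.5, 3)
      b <- stats::runif(1, 0.3, 0.8) * a
      w <- stats::runif(1, 2 * pi / (2 * span), 4 * pi / span)
      ph <- stats::runif(1, 0, 2 * pi)
      function(t) a + b * sin(w * t + ph)
    },
    constant = {
      c0 <- stats::runif(1, 0.1, 3)
      function(t) rep(c0, length(t))
    })
  function(t) scale * f(t)
}

#' Generate synthetic volatile-content trajectories
#'
#' Per compound: draw a shape archetype from the configured mix, draw a
#' smooth positive base curve of that shape, evaluate it at the sampling
#' points, and apply multiplicative lognormal noise with the configured
#' coefficient of variation (unit mean). Contents are generated directly as
#' percent shares; nothing is renormalised. The noise-free truth is returned
#' alongside the observations so estimator error can be measured without
#' re-deriving it. Deterministic given the seed.
#'
#' @param cfg a [synthetic_config()].
#' @param x optional abscissa overriding `cfg$time_points` (e.g. the DH
#'   values reached at the sampling times, for fits over the DH axis).
#' @return list with `content` (a [content_matrix()] of noisy observations),
#'   `truth` (noise-free matrix, same shape), `truth_fns` (list of base-curve
#'   functions), `archetypes` (character vector), `x` (abscissa used).
#' @export
generate_volatile_trajectories <- function(cfg, x = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (is.null(x)) x <- cfg$time_points
  assert_that(is.numeric(x) && all(diff(x) > 0),
              "x must be strictly increasing")
  span <- diff(range(x))
  mix <- cfg$archetype_mix
  scale <- min(1, 30 / cfg$n_compounds)  # keep per-sample totals below 100%
  with_seed(cfg$seed, {
    kinds <- sample(names(mix), cfg$n_compounds, replace = TRUE, prob = mix)
    fns <- lapply(kinds, draw_truth_curve, span = span, scale = scale)
    truth <- vapply(fns, function(f) f(x), numeric(length(x)))
    sdlog <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- if (cfg$noise_cv > 0) {
      matrix(stats::rlnorm(length(truth), -sdlog^2 / 2, sdlog), nrow(truth))
    } else {
      matrix(1, nrow(truth), ncol(truth))
    }
    obs <- truth * noise
    ids <- sprintf("cmpd_%02d", seq_len(cfg$n_compounds))
    dimnames(truth) <- dimnames(obs) <-
      list(sprintf("x_%g", x), ids)
    names(fns) <- names(kinds) <- ids
    list(content = content_matrix(obs), truth = truth, truth_fns = fns,
         archetypes = kinds, x = x)
  })
}

#' Generate a synthetic odor-threshold table
#'
#' Thresholds are drawn log-uniformly over the configured log10 range; the
#' first compound is the designated reference and receives the range's lower
#' bound, so it carries the minimum threshold (emulating a trace pyrazine
#' that dominates flavor contribution).
#'
#' @param cfg a [synthetic_config()].
#' @return named numeric vector of thresholds (ug/kg); the designated
#'   reference compound's name is in `attr(, "reference")`.
#' @export
generate_threshold_table <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  lo <- cfg$threshold_log10_range[1]
  hi <- cfg$threshold_log10_range[2]
  thr <- with_seed(cfg$seed + 1L,
                   10^stats::runif(cfg$n_compounds, lo, hi))
  thr[1] <- 10^lo
  names(thr) <- sprintf("cmpd_%02d", seq_len(cfg$n_compounds))
  attr(thr, "reference") <- names(thr)[1]
  thr
}
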