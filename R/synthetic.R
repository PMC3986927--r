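#' Default synthetic stress-condition panel
#'
#' One glucose control at 30 degrees plus nine stress conditions mirroring
#' a lignocellulosic-fermentation panel: osmotic (sorbitol), ethanol,
#' elevated temperature (35 and 40 degrees), weak acids (acetic, formic),
#' furans (furfural, HMF) and a phenolic (vanillin). Runs last 96 h at
#' 15-min sampling except the 40 degree assay, truncated at 24 h; %RSI
#' endpoints are 50 h (24 h at 40 degrees).
#'
#' @return A `pm_conditions` table with an extra `run_hours` column used by
#'   the simulator.
#' @export
default_conditions <- function() {
  df <- data.frame(
    condition_id = c("ctrl30", "sorb10", "eth10", "temp35", "heat40",
                     "acetic25", "formic10", "furf10", "hmf10", "van10"),
    stressor = c("glucose", "sorbitol", "ethanol", "temperature",
                 "temperature", "acetic acid", "formic acid", "furfural",
                 "HMF", "vanillin"),
    dose = c(6, 10, 10, 0, 0, 25, 10, 10, 10, 10),
    unit = c("%w/v", "%w/v", "%v/v", "", "", "mM", "mM", "mM", "mM", "mM"),
    temperature_C = c(30, 30, 30, 35, 40, 30, 30, 30, 30, 30),
    endpoint_hours = c(50, 50, 50, 50, 24, 50, 50, 50, 50, 50),
    control_id = c("", rep("ctrl30", 9L)),
    stringsAsFactors = FALSE)
  df$run_hours <- ifelse(df$temperature_C == 40, 24, 96)
  as_pm_conditions(df)
}

#' Specify a synthetic phenotypic-microarray study
#'
#' Defines the generative model for a study with known ground truth: each
#' curve is a logistic redox-accumulation curve
#' S(t) = b + theta * A / (1 + exp(-r (t - t_m - delta))) + noise,
#' floored at 0, on a 0.25 h grid. `A` is drawn once per strain from
#' `amplitude_range` (the control endpoint spread seen across strains);
#' `theta` in [0, 1] is the per-strain-per-stress amplitude multiplier
#' carrying the planted tolerance structure; `delta` is a lag delay in
#' hours. Per stress condition a tolerant block draws theta from
#' `theta_tolerant` and a sensitive block from `theta_sensitive`; controls
#' have theta = 1, delta = 0.
#'
#' @param n_strains Number of strains (first is the reference).
#' @param conditions Condition table (with `run_hours`); see
#'   [default_conditions()].
#' @param replicates Replicates per strain x condition (>= 1).
#' @param n_tolerant,n_sensitive Planted block sizes.
#' @param amplitude_range Range of the per-strain logistic amplitude A
#'   (signal units).
#' @param rate Logistic rate r (per hour).
#' @param midpoint_h Logistic midpoint t_m (hours).
#' @param baseline Baseline signal b (units).
#' @param theta_tolerant,theta_sensitive,theta_intermediate Uniform ranges
#'   for theta by planted class.
#' @param noise_sd Additive Gaussian noise sd (signal units).
#' @param reference_id Reference strain id.
#' @param seed Integer seed; the study is fully reproducible from it.
#' @return A `pm_synth_spec` list.
#' @export
synthetic_spec <- function(n_strains = 90L,
                           conditions = default_conditions(),
                           replicates = 3L,
                           n_tolerant = 10L,
                           n_sensitive = 5L,
                           amplitude_range = c(35, 75),
                           rate = 0.3,
                           midpoint_h = 20,
                           baseline = 5,
                           theta_tolerant = c(0.8, 1.0),
                           theta_sensitive = c(0.1, 0.3),
                           theta_intermediate = c(0.35, 0.75),
                           noise_sd = 2,
                           reference_id = "S288C",
                           seed = 1L) {
  stopifnot(n_strains >= 2L, replicates >= 1L,
            n_tolerant + n_sensitive <= n_strains - 1L,
            all(amplitude_range > 0), rate > 0, midpoint_h > 0,
            baseline >= 0, noise_sd >= 0)
  if (!"run_hours" %in% names(conditions))
    conditions$run_hours <- ifelse(conditions$temperature_C == 40, 24, 96)
  structure(list(n_strains = as.integer(n_strains), conditions = conditions,
                 replicates = as.integer(replicates),
                 n_tolerant = as.integer(n_tolerant),
                 n_sensitive = as.integer(n_sensitive),
                 amplitude_range = amplitude_range, rate = rate,
                 midpoint_h = midpoint_h, baseline = baseline,
                 theta_tolerant = theta_tolerant,
                 theta_sensitive = theta_sensitive,
                 theta_intermediate = theta_intermediate,
                 noise_sd = noise_sd, reference_id = reference_id,
                 seed = as.integer(seed)),
            class = "pm_synth_spec")
}

# deterministic per-curve substream seed; stays below 2^31 - 1
derive_seed <- function(seed, strain_idx, cond_idx, replicate) {
  h <- (as.numeric(seed) %% 2147483647) * 48271 +
    strain_idx * 1299709 + cond_idx * 104729 + replicate * 7919
  as.integer(h %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit(if (had) assign(".Random.seed", old, envir = .GlobalEnv)
          else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
            rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulate a single redox kinetic curve
#'
#' Logistic curve with additive Gaussian noise, floored at zero, sampled on
#' a uniform grid (default 0.25 h, the 15-min plate-photography interval).
#' A 96 h run yields 385 points, a 24 h run 97. Identical seeds give
#' bitwise-identical series.
#'
#' @param strain_id,condition_id,replicate Series identity.
#' @param run_hours Run length in hours.
#' @param A,rate,midpoint_h,baseline Logistic parameters (amplitude, rate
#'   per hour, midpoint hours, baseline units).
#' @param theta Amplitude multiplier in [0, 1].
#' @param delta Lag delay in hours (>= 0).
#' @param noise_sd Gaussian noise sd (units); 0 for a noiseless curve.
#' @param step Grid step in hours.
#' @param seed Optional integer seed for the noise draw.
#' @return A [pm_series].
#' @export
simulate_curve <- function(strain_id, condition_id, replicate,
                           run_hours = 96, A = 60, rate = 0.3,
                           midpoint_h = 20, baseline = 5, theta = 1,
                           delta = 0, noise_sd = 0, step = 0.25,
                           seed = NULL) {
  stopifnot(A > 0, rate > 0, midpoint_h > 0, theta >= 0, theta <= 1,
            delta >= 0, noise_sd >= 0, run_hours > 0)
  times <- seq(0, run_hours, by = step)
  mu <- baseline + theta * A / (1 + exp(-rate * (times - midpoint_h - delta)))
  sig <- if (noise_sd > 0) {
    draw <- function() mu + stats::rnorm(length(mu), 0, noise_sd)
    if (is.null(seed)) draw() else with_seed(seed, draw())
  } else mu
  pm_series(strain_id, condition_id, replicate, times, pmax(sig, 0))
}

#' Simulate a complete phenotypic-microarray study with ground truth
#'
#' Draws per-strain amplitudes and per-strain-per-condition tolerance
#' multipliers according to the planted block structure, then generates
#' every (strain, condition, replicate) curve from a deterministic
#' per-curve substream of the study seed.
#'
#' @param spec A `pm_synth_spec` from [synthetic_spec()].
#' @return A list of class `pm_synth_study`: `curves` (named list of
#'   [pm_series]), `truth` (data frame strain_id, condition_id, theta,
#'   delta, class), `strains` (data frame strain_id, class), `spec`.
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "pm_synth_spec"))
  n <- spec$n_strains
  ids <- c(spec$reference_id,
           sprintf("SYN%03d", seq_len(n - 1L)))
  cls <- rep("intermediate", n)
  # reference stays intermediate; blocks fill the following slots
  if (spec$n_tolerant > 0) cls[1L + seq_len(spec$n_tolerant)] <- "tolerant"
  if (spec$n_sensitive > 0)
    cls[1L + spec$n_tolerant + seq_len(spec$n_sensitive)] <- "sensitive"
  conds <- spec$conditions
  is_stress <- nzchar(conds$control_id)
  truth <- list()
  curves <- list()
  study <- with_seed(spec$seed, {
    A <- stats::runif(n, spec$amplitude_range[1L], spec$amplitude_range[2L])
    theta <- matrix(1, n, nrow(conds),
                    dimnames = list(ids, conds$condition_id))
    for (j in which(is_stress)) {
      rng <- function(cl) switch(cl,
        tolerant = spec$theta_tolerant,
        sensitive = spec$theta_sensitive,
        spec$theta_intermediate)
      for (i in seq_len(n)) {
        r <- rng(cls[i])
        theta[i, j] <- stats::runif(1L, r[1L], r[2L])
      }
    }
    list(A = A, theta = theta)
  })
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(conds))) {
      truth[[length(truth) + 1L]] <- data.frame(
        strain_id = ids[i], condition_id = conds$condition_id[j],
        theta = study$theta[i, j], delta = 0,
        class = if (is_stress[j]) cls[i] else "control",
        stringsAsFactors = FALSE)
      for (r in seq_len(spec$replicates)) {
        s <- simulate_curve(ids[i], conds$condition_id[j], r,
                            run_hours = conds$run_hours[j],
                            A = study$A[i], rate = spec$rate,
                            midpoint_h = spec$midpoint_h,
                            baseline = spec$baseline,
                            theta = study$theta[i, j], delta = 0,
                            noise_sd = spec$noise_sd, step = 0.25,
                            seed = derive_seed(spec$seed, i, j, r))
        curves[[series_key(s)]] <- s
      }
    }
  }
  structure(list(curves = curves,
                 truth = do.call(rbind, truth),
                 strains = data.frame(strain_id = ids, class = cls,
                                      amplitude = study$A,
                                      stringsAsFactors = FALSE),
                 spec = spec),
            class = "pm_synth_study")
}

#' Simulate a log-ratio matrix with two planted strain blocks
#'
#' Direct generator for clustering validation: two blocks of strains with
#' opposite condition profiles (an alternating +/- effect pattern and its
#' negation) plus Gaussian noise on the log2 scale, clipped to the heat-map
#' range.
#'
#' @param n_strains Total strains (split as evenly as possible).
#' @param condition_ids Condition (column) names.
#' @param effect Absolute block effect on the log2 scale (default 1).
#' @param noise_sd Log2-scale noise sd (default 0.3).
#' @param clip Clipping bound (default 3).
#' @param seed Integer seed.
#' @return List with `matrix` (strains x conditions) and `blocks` (named
#'   integer vector, 1 or 2).
#' @export
simulate_logratio_blocks <- function(n_strains = 90L,
                                     condition_ids = sprintf("cond%02d", 1:9),
                                     effect = 1, noise_sd = 0.3, clip = 3,
                                     seed = 1L) {
  stopifnot(n_strains >= 4L, length(condition_ids) >= 2L, noise_sd >= 0)
  n1 <- n_strains %/% 2L
  blocks <- c(rep(1L, n1), rep(2L, n_strains - n1))
  ids <- sprintf("STR%03d", seq_len(n_strains))
  names(blocks) <- ids
  pattern <- effect * rep_len(c(1, -1), length(condition_ids))
  mu <- outer(ifelse(blocks == 1L, 1, -1), pattern)
  mat <- with_seed(seed,
    mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu)))
  mat <- pmin(pmax(mat, -clip), clip)
  dimnames(mat) <- list(ids, condition_ids)
  list(matrix = mat, blocks = blocks)
}
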