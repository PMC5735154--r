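#' Reference utility configuration
#'
#' Evenly spaced utilities used as the package's reference configuration for
#' the noise sweep and the synthetic cohorts. The spacing (set by
#' `range_max`) fixes the units of the deterministic utility relative to the
#' standard-normal error term, and therefore the shape of the alpha ->
#' intransitivity curve. The default `range_max` is calibrated once so that
#' a noise fraction of alpha = 0.3 produces a mean intransitivity near 6%,
#' the regime reported for hippocampal-lesion patients; see the package
#' vignette.
#'
#' @param n_items number of items.
#' @param range_max top of the utility range; utilities are evenly spaced on
#'   `[0, range_max]`. Together with the reference error scale (6, see
#'   [simulation_config()]) this places the noise sweep in the empirically
#'   observed 1-25% intransitivity range.
#' @return Numeric vector of length `n_items`.
#' @export
reference_utilities <- function(n_items = 20, range_max = 16) {
  seq(0, range_max, length.out = n_items)
}

#' Simulation configuration for the random-utility choice model
#'
#' @param n_items number of items in the choice set.
#' @param utilities numeric utility vector of length `n_items`; defaults to
#'   [reference_utilities()].
#' @param alpha noise fraction in `[0, 1]`: the proportion of the effective
#'   utility attributable to random error (0 = noiseless preference, 1 =
#'   pure random choice).
#' @param error_spec list with `family` (`"normal"`, `"logistic"` or
#'   `"uniform"`) and `scale` for the error draws; all families are centred
#'   at zero and symmetric, so alpha = 1 always yields fair-coin choices.
#' @param seed master RNG seed.
#' @param n_replicates default number of simulated subjects per condition.
#' @param shared_error if `TRUE`, a single error draw is used for both
#'   options of a trial; the error terms then cancel in the choice
#'   probability and the model reduces to an alpha-scaled deterministic
#'   logistic choice. Provided for documentation of that algebraic reading;
#'   the default (`FALSE`) draws independent errors per option, the standard
#'   random-utility formulation.
#' @param drift_sd per-trial standard deviation of an independent Gaussian
#'   random walk added to each item's utility across the session (0 =
#'   stable utilities). Positive values make choices far apart in the
#'   session less consistent with each other.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_items = 20, utilities = NULL, alpha = 0,
                              error_spec = list(family = "normal", scale = 6),
                              seed = 1L, n_replicates = 1000L,
                              shared_error = FALSE, drift_sd = 0) {
  n_items <- as.integer(n_items)
  if (n_items < 2) stop("n_items must be >= 2", call. = FALSE)
  if (is.null(utilities)) {
    utilities <- reference_utilities(n_items)
  }
  if (length(utilities) != n_items || any(!is.finite(utilities))) {
    stop("utilities must be a finite vector of length n_items", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  if (!error_spec$family %in% c("normal", "logistic", "uniform")) {
    stop("error family must be normal, logistic or uniform", call. = FALSE)
  }
  if (drift_sd < 0) stop("drift_sd must be >= 0", call. = FALSE)
  structure(list(n_items = n_items, utilities = utilities, alpha = alpha,
                 error_spec = error_spec, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 shared_error = isTRUE(shared_error), drift_sd = drift_sd),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "<simulation_config> %d items, alpha = %.3f, error = %s(scale %.3g), drift_sd = %.3g\n",
    x$n_items, x$alpha, x$error_spec$family, x$error_spec$scale, x$drift_sd))
  invisible(x)
}

.draw_errors <- function(n, error_spec) {
  switch(error_spec$family,
         normal = stats::rnorm(n, 0, error_spec$scale),
         logistic = stats::rlogis(n, 0, error_spec$scale),
         uniform = stats::runif(n, -error_spec$scale, error_spec$scale))
}

#' Probability of choosing option A under the noisy random-utility model
#'
#' The effective utility of each option is the convex combination
#' `(1 - alpha) * u + alpha * eps` of its deterministic utility and an error
#' draw; the choice probability is the logistic function of the effective
#' utility difference:
#' `p(A) = 1 / (1 + exp(((1-alpha) u_b + alpha eps_b) - ((1-alpha) u_a + alpha eps_a)))`.
#'
#' @param u_a,u_b deterministic utilities of options A and B.
#' @param alpha noise fraction in `[0, 1]`.
#' @param eps_a,eps_b realised error draws for A and B.
#' @param shared_error if `TRUE`, `eps_b` is ignored and `eps_a` is used for
#'   both options (the errors then cancel).
#' @return Probability of choosing A, in (0, 1). Vectorised over all
#'   arguments.
#' @export
choice_probability <- function(u_a, u_b, alpha, eps_a, eps_b,
                               shared_error = FALSE) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  stopifnot(all(is.finite(u_a)), all(is.finite(u_b)))
  if (shared_error) eps_b <- eps_a
  v_a <- (1 - alpha) * u_a + alpha * eps_a
  v_b <- (1 - alpha) * u_b + alpha * eps_b
  stats::plogis(v_a - v_b)
}

# One subject's trials under the model: every pair once, seeded random
# presentation order, independent error draws per option per trial, binary
# choice drawn from the logistic probability. Returns a tibble of trials
# (rt left NA; the cohort generator adds its own response-time model).
.simulate_trials <- function(cfg) {
  n <- cfg$n_items
  pairs <- enumerate_pairs(n)
  n_trials <- nrow(pairs)
  ord <- sample.int(n_trials)
  a <- pairs[ord, 1]; b <- pairs[ord, 2]
  u_a <- cfg$utilities[a]; u_b <- cfg$utilities[b]
  if (cfg$drift_sd > 0) {
    # per-item random walk over the session, indexed by presentation time
    steps <- matrix(stats::rnorm(n * n_trials, 0, cfg$drift_sd), n, n_trials)
    walk <- t(apply(steps, 1, cumsum))
    tt <- seq_len(n_trials)
    u_a <- u_a + walk[cbind(a, tt)]
    u_b <- u_b + walk[cbind(b, tt)]
  }
  eps_a <- .draw_errors(n_trials, cfg$error_spec)
  eps_b <- .draw_errors(n_trials, cfg$error_spec)
  p_a <- choice_probability(u_a, u_b, cfg$alpha, eps_a, eps_b,
                            cfg$shared_error)
  take_a <- stats::runif(n_trials) < p_a
  tibble::new_tibble(list(
    trial_index = seq_len(n_trials),
    item_a = a, item_b = b,
    choice = ifelse(take_a, a, b),
    rt = rep(NA_real_, n_trials)
  ), nrow = n_trials)
}

#' Simulate one subject's complete pairwise-choice session
#'
#' Presents every unordered pair of items once in a seeded random order and
#' draws each choice from [choice_probability()] with fresh independent
#' error draws per option per trial. Fully reproducible given
#' `(cfg$seed, subject_id)`.
#'
#' @param cfg a [simulation_config()].
#' @param subject_id subject identifier for the output table.
#' @param seed optional explicit seed; by default derived from `cfg$seed`
#'   and `subject_id`.
#' @param group,task labels for the output table.
#' @return A [choice_dataset()] with one subject and
#'   `choose(n_items, 2)` trials.
#' @export
simulate_subject <- function(cfg, subject_id = "sim01", seed = NULL,
                             group = "CON", task = "preference") {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(seed)) seed <- derive_seed(cfg$seed, .string_seed(subject_id))
  set.seed(seed)
  tr <- .simulate_trials(cfg)
  tr$subject_id <- subject_id
  tr$group <- group
  tr$task <- task
  choice_dataset(tr, n_items = cfg$n_items)
}

# Fast replicate: simulate one subject and return the intransitivity
# percentage via the tournament score-sequence identity
# (#cyclic = C(n,3) - sum_i C(wins_i, 2)); equality with score_subject on
# full triplet records is asserted in the test-suite.
.simulate_pct <- function(cfg, seed) {
  set.seed(seed)
  tr <- .simulate_trials(cfg)
  wins <- tabulate(tr$choice, nbins = cfg$n_items)
  100 * .count_cyclic(wins) / choose(cfg$n_items, 3)
}

#' Sweep the noise fraction and measure mean intransitivity
#'
#' For every alpha on the grid, simulates `n_replicates` independent
#' subjects under the configuration, scores each subject's intransitivity
#' percentage over all triplets, and records the mean and standard error.
#' Sub-seeds are derived deterministically from `(seed, round(alpha * 1e6),
#' replicate)`, so adding grid points does not perturb existing replicates.
#'
#' @param cfg_base a [simulation_config()]; its `alpha` is overridden by the
#'   grid values.
#' @param alpha_grid strictly increasing vector of noise fractions in
#'   `[0, 1]`.
#' @param n_replicates simulated subjects per grid point (default from
#'   `cfg_base`).
#' @param seed master seed (default from `cfg_base`).
#' @return An object of class `sweep_result`: a list with `table` (tibble:
#'   alpha, mean_pct, se_pct, n_replicates), `n_replicates` and `config`.
#' @examples
#' cfg <- simulation_config(n_items = 8, seed = 1)
#' sw <- sweep_alpha(cfg, c(0, 0.5, 1), n_replicates = 50)
#' sw$table
#' invert_alpha(sw$table$mean_pct[2], sw)$alpha
#' @export
sweep_alpha <- function(cfg_base, alpha_grid, n_replicates = NULL, seed = NULL) {
  stopifnot(inherits(cfg_base, "simulation_config"))
  if (length(alpha_grid) == 0) stop("alpha_grid must be non-empty", call. = FALSE)
  if (any(alpha_grid < 0 | alpha_grid > 1)) {
    stop("alpha_grid values must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(alpha_grid, strictly = TRUE)) {
    stop("alpha_grid must be strictly increasing", call. = FALSE)
  }
  if (is.null(n_replicates)) n_replicates <- cfg_base$n_replicates
  if (is.null(seed)) seed <- cfg_base$seed
  rows <- lapply(alpha_grid, function(a) {
    cfg <- cfg_base
    cfg$alpha <- a
    pct <- vapply(seq_len(n_replicates), function(r) {
      .simulate_pct(cfg, derive_seed(seed, round(a * 1e6), r))
    }, numeric(1))
    tibble::tibble(alpha = a, mean_pct = mean(pct),
                   se_pct = stats::sd(pct) / sqrt(n_replicates),
                   n_replicates = n_replicates)
  })
  structure(list(table = dplyr::bind_rows(rows),
                 n_replicates = n_replicates, config = cfg_base),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d grid points, %d replicates each\n",
              nrow(x$table), x$n_replicates))
  print(x$table)
  invisible(x)
}

#' Invert an observed intransitivity percentage to a noise fraction
#'
#' Interpolates the isotonic (monotone non-decreasing) fit of the sweep's
#' (alpha, mean intransitivity) curve to find the noise fraction alpha*
#' whose expected intransitivity matches the observation. The uncertainty
#' interval inverts the mean +/- SE curves the same way.
#'
#' @param observed_pct observed intransitivity percentage (0-100 scale).
#' @param sweep a [sweep_alpha()] result whose mean curve brackets
#'   `observed_pct`.
#' @return A list with `alpha` (the estimate), `lower`, `upper` (interval
#'   endpoints from the +/- SE curves, clamped to the grid range) and
#'   `flag` (`"ok"` or `"below_range"`). An observation above the curve's
#'   maximum is an error (the sweep does not bracket it).
#' @export
invert_alpha <- function(observed_pct, sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  tab <- sweep$table
  if (nrow(tab) < 2) stop("sweep needs at least two grid points", call. = FALSE)
  fit_mid <- stats::isoreg(tab$alpha, tab$mean_pct)$yf
  inv <- function(curve, y) {
    if (y <= curve[1]) return(tab$alpha[1])
    if (y > max(curve)) return(NA_real_)
    stats::approx(x = curve, y = tab$alpha, xout = y, ties = "ordered")$y
  }
  top_slack <- 3 * tab$se_pct[nrow(tab)]
  if (observed_pct > max(fit_mid) + top_slack) {
    stop(sprintf(
      "observed percentage %.3f exceeds the sweep curve maximum %.3f; extend the grid or increase replicates",
      observed_pct, max(fit_mid)), call. = FALSE)
  }
  flag <- "ok"
  if (observed_pct > max(fit_mid)) {
    # within sampling noise of the curve ceiling: saturate at the top alpha
    return(list(alpha = tab$alpha[nrow(tab)], lower = NA_real_,
                upper = tab$alpha[nrow(tab)], flag = "at_ceiling"))
  }
  if (observed_pct < fit_mid[1]) flag <- "below_range"
  # a flat isotonic segment at the observation means the grid cannot resolve
  # alpha there
  at <- findInterval(observed_pct, fit_mid)
  if (flag == "ok" && at >= 1 && at < length(fit_mid) &&
      fit_mid[at] == fit_mid[at + 1] && observed_pct > fit_mid[1]) {
    seg <- which(fit_mid == fit_mid[at])
    if (length(seg) > 2) {
      stop("sweep curve is flat at the observed percentage; use a denser grid or more replicates",
           call. = FALSE)
    }
  }
  alpha_hat <- inv(fit_mid, observed_pct)
  fit_hi <- stats::isoreg(tab$alpha, tab$mean_pct + tab$se_pct)$yf
  fit_lo <- stats::isoreg(tab$alpha, pmax(tab$mean_pct - tab$se_pct, 0))$yf
  lower <- inv(fit_hi, observed_pct)
  upper <- inv(fit_lo, observed_pct)
  if (is.na(upper)) upper <- tab$alpha[nrow(tab)]
  list(alpha = alpha_hat, lower = lower, upper = upper, flag = flag)
}
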