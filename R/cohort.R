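#' Specification of a synthetic three-group cohort
#'
#' Describes a cohort emulating a clinical lesion study: three groups
#' (healthy controls CON, extratemporal-lobe patients ETL,
#' mediotemporal-lobe patients MTL) each performing a complete
#' pairwise preference task over `n_items` items and a matched
#' number-comparison control task. Preference choices come from the
#' random-utility simulator at a subject-specific noise fraction drawn
#' around the group value; control choices are the objectively correct
#' larger-number response flipped with a small group-specific lapse
#' probability. Response times are lognormal with an
#' involvement-linked slowdown; lesion records for a subset of MTL
#' subjects carry a lateral damage index monotonically linked to the
#' subject's noise level plus noise.
#'
#' The default group noise fractions and lapse rates are calibrated so
#' that group mean intransitivity percentages land near 2.75 / 3.37 /
#' 6.07 (preference) and 0.14 / 1.00 / 0.50 (control) for CON / ETL /
#' MTL, the regime of the lesion study the pipeline is designed around;
#' the lapse calibration is the closed form `lapse * (1 - lapse) =
#' proportion`. See the package vignette for how each default was fixed.
#'
#' @param n_per_group named integer vector: subjects per group.
#' @param alpha named numeric vector: group-level noise fractions for the
#'   preference task.
#' @param alpha_sd sd of the truncated-normal subject-level jitter around
#'   the group noise fraction.
#' @param lapse named numeric vector: group-level base lapse probabilities
#'   for the control task (the flip probability for adjacent numbers), each
#'   in `[0, 0.5]`.
#' @param lapse_tau decay constant of the numerical distance effect: the
#'   flip probability for a pair at numerical distance `d` is
#'   `lapse * exp(-(d - 1) / lapse_tau)` (capped at 1/2). `Inf` gives a
#'   uniform lapse on every pair.
#' @param n_items items per task.
#' @param utilities preference-task utility vector (fixed per cohort).
#' @param utility_shuffle if `TRUE`, each subject receives a fresh random
#'   assignment of the utility values to item codes. This makes items
#'   exchangeable across subjects (no idiosyncratic item effects), which is
#'   the null hypothesis of the item-heterogeneity test; with a shared
#'   assignment (default) middling-utility items genuinely participate in
#'   more cycles.
#' @param error_spec error distribution for the preference simulator.
#' @param drift_sd per-trial sd of the utility random walk (injects the
#'   trial-spacing effect: choices further apart are less consistent).
#' @param rt list of response-time parameters: `meanlog`, `sdlog`
#'   (lognormal, seconds), `subject_sd` (subject-level meanlog jitter),
#'   `slowdown` (meanlog increment on trials involved in intransitive
#'   triplets), `mtl_shift` (meanlog increment for MTL subjects).
#' @param lesion list: `n` (MTL subjects with lesion records), `center`,
#'   `rate`, `scale`, `floor` (logistic link from subject noise fraction to
#'   the lateral damage index), `noise_sd` (link noise), `total_volume`
#'   (left + right volume used to synthesise the volume table).
#' @param seed master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(CON = 30L, ETL = 30L, MTL = 31L),
                        alpha = c(CON = 0.09, ETL = 0.14, MTL = 0.27),
                        alpha_sd = 0.05,
                        lapse = c(CON = 0.0446, ETL = 0.2838, MTL = 0.1524),
                        lapse_tau = 1.5,
                        n_items = 20L,
                        utilities = NULL,
                        utility_shuffle = FALSE,
                        error_spec = list(family = "normal", scale = 6),
                        drift_sd = 0.25,
                        rt = list(meanlog = 0.4, sdlog = 0.35,
                                  subject_sd = 0.15, slowdown = 0.15,
                                  mtl_shift = 0.12),
                        lesion = list(n = 16L, center = 0.27, rate = 16,
                                      scale = 0.55, floor = 0.05,
                                      noise_sd = 0.01, total_volume = 8),
                        seed = 1L) {
  stopifnot(setequal(names(n_per_group), .groups),
            setequal(names(alpha), .groups),
            setequal(names(lapse), .groups))
  if (any(n_per_group < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (any(lapse < 0 | lapse > 0.5)) stop("lapse must lie in [0, 0.5]", call. = FALSE)
  if (!(lapse_tau > 0)) stop("lapse_tau must be positive", call. = FALSE)
  if (alpha_sd < 0 || drift_sd < 0) stop("sd parameters must be >= 0", call. = FALSE)
  if (rt$sdlog <= 0) stop("rt$sdlog must be positive", call. = FALSE)
  if (is.null(utilities)) utilities <- reference_utilities(n_items)
  if (length(utilities) != n_items) {
    stop("utilities must have length n_items", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group[.groups], alpha = alpha[.groups],
                 alpha_sd = alpha_sd, lapse = lapse[.groups], lapse_tau = lapse_tau,
                 n_items = as.integer(n_items), utilities = utilities,
                 utility_shuffle = isTRUE(utility_shuffle),
                 error_spec = error_spec, drift_sd = drift_sd, rt = rt,
                 lesion = lesion, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> n = %s | alpha = %s | lapse = %s | %d items, seed %d\n",
    paste(x$n_per_group, collapse = "/"),
    paste(sprintf("%.3f", x$alpha), collapse = "/"),
    paste(sprintf("%.4f", x$lapse), collapse = "/"),
    x$n_items, x$seed))
  invisible(x)
}

# truncated-normal draw on [0, 1] by rejection
.rtrunc01 <- function(mean, sd) {
  if (sd == 0) return(min(max(mean, 0), 1))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0 && x <= 1) return(x)
  }
}

.simulate_number_task <- function(n_items, lapse, lapse_tau = 1.5) {
  pairs <- enumerate_pairs(n_items)
  n_trials <- nrow(pairs)
  ord <- sample.int(n_trials)
  a <- pairs[ord, 1]; b <- pairs[ord, 2]
  correct <- pmax(a, b)
  wrong <- pmin(a, b)
  # numerical distance effect: lapses concentrate on close number pairs
  dist <- correct - wrong
  q <- if (is.finite(lapse_tau)) {
    pmin(lapse * exp(-(dist - 1) / lapse_tau), 0.5)
  } else {
    rep(min(lapse, 0.5), n_trials)
  }
  flip <- stats::runif(n_trials) < q
  tibble::new_tibble(list(trial_index = seq_len(n_trials), item_a = a,
                          item_b = b, choice = ifelse(flip, wrong, correct),
                          rt = rep(NA_real_, n_trials)), nrow = n_trials)
}

#' Generate a complete synthetic cohort
#'
#' Generates every subject's preference and control sessions, response
#' times, and the MTL lesion records, exactly as described in
#' [cohort_spec()]. The output is a pure function of the spec (including
#' its seed): the same spec gives a bitwise-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `dataset` (a
#'   [choice_dataset()] covering both tasks), `subjects` (tibble:
#'   subject_id, group, alpha_true, lapse, rt_meanlog), `lesions` (tibble:
#'   subject_id, vol_left, vol_right, ldi_true for the MTL lesion subset;
#'   all values synthetic), `scores` and `triplets` (the scored dataset, as
#'   from [score_all()]), and `spec`.
#' @examples
#' spec <- cohort_spec(n_per_group = c(CON = 2L, ETL = 2L, MTL = 2L),
#'                     n_items = 8L, seed = 1)
#' co <- generate_cohort(spec)
#' co$scores
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subj_rows <- list(); trial_rows <- list()
  trip_rows <- list(); score_rows <- list()
  trip_template <- enumerate_triplets(spec$n_items)

  for (g in .groups) {
    for (s in seq_len(spec$n_per_group[[g]])) {
      sid <- sprintf("%s%02d", g, s)
      set.seed(derive_seed(spec$seed, .string_seed(sid)))
      alpha_i <- .rtrunc01(spec$alpha[[g]], spec$alpha_sd)
      meanlog_i <- spec$rt$meanlog + spec$rt$subject_sd * stats::rnorm(1) +
        (g == "MTL") * spec$rt$mtl_shift

      u_i <- if (spec$utility_shuffle) sample(spec$utilities) else spec$utilities
      cfg <- simulation_config(
        n_items = spec$n_items, utilities = u_i, alpha = alpha_i,
        error_spec = spec$error_spec, seed = spec$seed,
        drift_sd = spec$drift_sd)
      pref <- .simulate_trials(cfg)
      pref$task <- "preference"
      ctrl <- .simulate_number_task(spec$n_items, spec$lapse[[g]], spec$lapse_tau)
      ctrl$task <- "number"

      for (task_tbl in list("preference", "number")) {
        tbl <- if (task_tbl == "preference") pref else ctrl
        n_tr <- nrow(tbl)
        tbl$rt <- stats::rlnorm(n_tr, meanlog_i, spec$rt$sdlog)
        # score, flag involvement, regenerate flagged trials' rts slower
        mats <- .subject_matrices(tbl, spec$n_items)
        tt <- .triplet_table(mats, trip_template)
        tt <- tt[tt$observed, names(tt) != "observed"]
        tbl <- trial_involvement(tt, tbl)
        if (spec$rt$slowdown != 0 && any(tbl$involved)) {
          idx <- which(tbl$involved)
          tbl$rt[idx] <- stats::rlnorm(length(idx),
                                       meanlog_i + spec$rt$slowdown,
                                       spec$rt$sdlog)
        }
        tbl$subject_id <- sid; tbl$group <- g
        if (task_tbl == "preference") pref <- tbl else ctrl <- tbl
        tt$subject_id <- rep(sid, nrow(tt)); tt$group <- rep(g, nrow(tt))
        tt$task <- rep(task_tbl, nrow(tt))
        trip_rows[[paste(sid, task_tbl)]] <- tt
        n_intr <- sum(tt$is_intransitive)
        score_rows[[paste(sid, task_tbl)]] <- list(
          subject_id = sid, group = g, task = task_tbl,
          n_triplets = nrow(tt), n_intransitive = n_intr,
          pct_intransitive = 100 * n_intr / nrow(tt), n_excluded = 0L)
      }
      trial_rows[[sid]] <- dplyr::bind_rows(pref, ctrl)
      subj_rows[[sid]] <- list(
        subject_id = sid, group = g, alpha_true = alpha_i,
        lapse = spec$lapse[[g]], rt_meanlog = meanlog_i)
    }
  }
  subjects <- dplyr::bind_rows(lapply(subj_rows, tibble::as_tibble))
  trials <- dplyr::bind_rows(trial_rows)
  ds <- choice_dataset(trials, n_items = spec$n_items)

  # lesion records for a seeded random subset of MTL subjects: ldi is a
  # logistic function of the subject's true noise fraction plus noise
  set.seed(derive_seed(spec$seed, 777001L))
  mtl <- subjects[subjects$group == "MTL", ]
  n_les <- min(spec$lesion$n, nrow(mtl))
  picked <- mtl[sample.int(nrow(mtl), n_les), ]
  ldi_true <- spec$lesion$floor + spec$lesion$scale *
    stats::plogis(spec$lesion$rate * (picked$alpha_true - spec$lesion$center))
  ldi_obs <- pmin(pmax(ldi_true + stats::rnorm(n_les, 0, spec$lesion$noise_sd),
                       0.001), 0.97)
  side_left <- stats::runif(n_les) < 0.5
  tot <- spec$lesion$total_volume
  intact <- tot * (1 + ldi_obs) / 2
  damaged <- tot * (1 - ldi_obs) / 2
  lesions <- tibble::tibble(
    subject_id = picked$subject_id,
    vol_left = ifelse(side_left, damaged, intact),
    vol_right = ifelse(side_left, intact, damaged),
    ldi_true = ldi_true)
  lesions <- lesions[order(lesions$subject_id), ]

  structure(list(dataset = ds, subjects = subjects, lesions = lesions,
                 scores = dplyr::bind_rows(lapply(score_rows, tibble::as_tibble)),
                 triplets = dplyr::bind_rows(trip_rows), spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d trials, %d lesion records\n",
              nrow(x$subjects), nrow(x$dataset$trials), nrow(x$lesions)))
  invisible(x)
}

#' Spec for a group-exchangeable null cohort
#'
#' All group parameters are equalised, the injected effects (utility
#' drift, involvement slowdown, MTL response-time shift) are switched off,
#' and utility-to-item assignment is shuffled per subject so items are
#' exchangeable. Every group-difference, trial-position and item statistic
#' is then null by construction. Used for type-I-error calibration.
#'
#' @param spec base [cohort_spec()] supplying sizes, seed and the common
#'   parameter values.
#' @param alpha common noise fraction (default: mean of the base spec's
#'   group values).
#' @param lapse common lapse rate (default: mean of the base spec's).
#' @return A [cohort_spec()].
#' @export
null_cohort_spec <- function(spec = cohort_spec(), alpha = NULL, lapse = NULL) {
  if (is.null(alpha)) alpha <- mean(spec$alpha)
  if (is.null(lapse)) lapse <- mean(spec$lapse)
  spec$alpha[] <- alpha
  spec$lapse[] <- lapse
  spec$drift_sd <- 0
  spec$rt$slowdown <- 0
  spec$rt$mtl_shift <- 0
  spec$utility_shuffle <- TRUE
  spec
}

#' Generate a null cohort
#'
#' @param spec base [cohort_spec()]; see [null_cohort_spec()].
#' @param ... passed to [null_cohort_spec()].
#' @return A `synthetic_cohort` (see [generate_cohort()]).
#' @export
generate_null_cohort <- function(spec = cohort_spec(), ...) {
  generate_cohort(null_cohort_spec(spec, ...))
}
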