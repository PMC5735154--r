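#' @importFrom lmerTest lmer
NULL

.model_result <- function(tidy, description, fit = NULL) {
  structure(list(tidy = tidy, description = description, fit = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result>", x$description, "\n")
  print(x$tidy)
  invisible(x)
}

.tidy_coeftest <- function(ct) {
  tibble::tibble(
    term = rownames(ct),
    estimate = ct[, 1], std_error = ct[, 2],
    statistic = ct[, 3], p_value = ct[, 4]
  )
}

#' Log-transform intransitivity percentages
#'
#' Applies `log(pct + offset)`. The purpose of the transform is to remove
#' the right skew and the gross variance inequality between the preference
#' and the near-ceiling control task, so the default offset policy
#' (`"stabilize"`) chooses the offset that minimises the Bartlett
#' between-task variance statistic of the transformed values — the
#' transform's own success criterion — over
#' `[100 / (2 * n_triplets), 5]` percentage points. The lower end of that
#' range, half the percentage value of a single triplet (the smallest
#' meaningful resolution of the statistic), is available as the fixed
#' `"half_triplet"` policy. The offset actually used is recorded as the
#' `"offset"` attribute of the result.
#'
#' @param scores subject-score tibble with `pct_intransitive`,
#'   `n_triplets` and (for the default policy) `task`.
#' @param offset optional explicit offset in percentage points; overrides
#'   the policy.
#' @param offset_policy `"stabilize"` (default) or `"half_triplet"`.
#' @return `scores` with an added `log_pct` column; the offset is stored in
#'   `attr(, "offset")` and the policy in `attr(, "offset_policy")`.
#' @export
log_transform_scores <- function(scores, offset = NULL,
                                 offset_policy = c("stabilize", "half_triplet")) {
  offset_policy <- match.arg(offset_policy)
  if (any(scores$pct_intransitive < 0, na.rm = TRUE)) {
    stop("percentages must be nonnegative", call. = FALSE)
  }
  half_triplet <- 100 / (2 * max(scores$n_triplets))
  if (!is.null(offset)) {
    offset_policy <- "fixed"
  } else if (offset_policy == "half_triplet" || is.null(scores$task) ||
             length(unique(scores$task)) < 2) {
    offset <- half_triplet
  } else {
    k2 <- function(log_c) {
      v <- split(log(scores$pct_intransitive + exp(log_c)), scores$task)
      tryCatch(variance_homogeneity_check(v)$statistic,
               error = function(e) Inf)
    }
    opt <- stats::optimize(k2, c(log(half_triplet), log(5)))
    offset <- exp(opt$minimum)
  }
  scores$log_pct <- log(scores$pct_intransitive + offset)
  attr(scores, "offset") <- offset
  attr(scores, "offset_policy") <- offset_policy
  scores
}

#' Bartlett test of variance homogeneity between tasks (or groups)
#'
#' @param values_by_task named list of numeric vectors, one per task or
#'   group (at least 2 groups of at least 2 values).
#' @return A list with `statistic` (Bartlett's K-squared), `df` (number of
#'   groups minus 1) and `p`.
#' @export
variance_homogeneity_check <- function(values_by_task) {
  if (length(values_by_task) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(values_by_task))) {
    names(values_by_task) <- paste0("group", seq_along(values_by_task))
  }
  for (nm in names(values_by_task)) {
    v <- values_by_task[[nm]]
    if (length(v) < 2) stop("group '", nm, "' has fewer than 2 values", call. = FALSE)
    if (stats::var(v) == 0) {
      stop("group '", nm, "' has zero variance; Bartlett statistic undefined",
           call. = FALSE)
    }
  }
  bt <- stats::bartlett.test(values_by_task)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p = bt$p.value)
}

#' Orthogonal group contrasts for the three-group design
#'
#' Contrast 1 compares the extratemporal patients to healthy controls
#' (CON -1, ETL +1, MTL 0); contrast 2 compares the mediotemporal patients
#' to the mean of both control groups (CON -1/2, ETL -1/2, MTL +1). Both
#' sum to zero over groups and are mutually orthogonal.
#'
#' @param groups group labels; must be exactly CON, ETL, MTL (any order).
#' @return A list of class `contrast_scheme` with `codes` (3 x 2 matrix,
#'   rows CON/ETL/MTL, columns `etl_vs_con`, `mtl_vs_controls`) and
#'   `description`.
#' @export
build_contrasts <- function(groups = c("CON", "ETL", "MTL")) {
  if (!setequal(groups, .groups) || length(groups) != 3) {
    stop("groups must be exactly CON, ETL, MTL", call. = FALSE)
  }
  codes <- cbind(
    etl_vs_con = c(CON = -1, ETL = 1, MTL = 0),
    mtl_vs_controls = c(CON = -0.5, ETL = -0.5, MTL = 1)
  )
  structure(list(
    codes = codes,
    description = c(
      etl_vs_con = "extratemporal patients vs healthy controls",
      mtl_vs_controls = "mediotemporal patients vs mean of both control groups")
  ), class = "contrast_scheme")
}

#' Build the fixed-effects design columns for the group-by-task model
#'
#' Adds the two orthogonal group-contrast columns and a centred task code
#' (+1/2 preference, -1/2 number) to a scores table. Kept separate from the
#' fitter so the design construction can be verified on its own.
#'
#' @param scores tibble with `group` and `task` columns.
#' @param scheme a [build_contrasts()] scheme.
#' @return `scores` with added numeric columns `c_etl`, `c_mtl`, `task_c`.
#' @export
build_group_task_design <- function(scores, scheme = build_contrasts()) {
  bad <- setdiff(unique(scores$group), rownames(scheme$codes))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  scores$c_etl <- unname(scheme$codes[scores$group, "etl_vs_con"])
  scores$c_mtl <- unname(scheme$codes[scores$group, "mtl_vs_controls"])
  scores$task_c <- ifelse(scores$task == "preference", 0.5, -0.5)
  scores
}

#' Mixed-effects group-by-task analysis of log intransitivity
#'
#' Fits a linear mixed model regressing log-transformed intransitivity
#' percentages from both tasks on the interaction of the orthogonal group
#' contrasts with task, with a random intercept per subject:
#' `log_pct ~ (c_etl + c_mtl) * task_c + (1 | subject_id)`. The key term is
#' the `c_mtl:task_c` interaction — whether the preference/control gap in
#' inconsistency is larger for the mediotemporal group than for both
#' control groups together.
#'
#' @param scores tibble with `subject_id`, `group`, `task` and `log_pct`
#'   (see [log_transform_scores()]); every subject must contribute both
#'   tasks.
#' @return A `model_result` whose `tidy` table has one row per fixed-effect
#'   term (estimate, standard error, t statistic, Satterthwaite df,
#'   p-value).
#' @export
fit_group_task_model <- function(scores) {
  if (length(unique(scores$task)) < 2) {
    stop("singular design: both tasks are required to estimate the ",
         "group-by-task interaction", call. = FALSE)
  }
  tab <- table(scores$group, scores$task)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)
    stop("singular design: no observations for group ",
         rownames(tab)[bad[1, 1]], ", task ", colnames(tab)[bad[1, 2]],
         call. = FALSE)
  }
  per_subject <- table(scores$subject_id)
  if (any(per_subject < 2)) {
    stop("every subject must contribute both tasks; incomplete: ",
         paste(utils::head(names(per_subject)[per_subject < 2], 5),
               collapse = ", "), call. = FALSE)
  }
  d <- build_group_task_design(scores)
  fit <- lmerTest::lmer(log_pct ~ (c_etl + c_mtl) * task_c + (1 | subject_id),
                        data = d, REML = TRUE)
  sm <- stats::coef(summary(fit))
  tidy <- tibble::tibble(
    term = rownames(sm), estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"], statistic = sm[, "t value"],
    df = sm[, "df"], p_value = sm[, "Pr(>|t|)"]
  )
  .model_result(
    tidy,
    "linear mixed model, random intercept per subject, Satterthwaite df; task coded -1/2 (number) / +1/2 (preference)",
    fit)
}

.zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

.robust_logistic <- function(formula, data, cluster, description) {
  fit <- stats::glm(formula, data = data, family = stats::binomial())
  vc <- sandwich::vcovCL(fit, cluster = cluster)
  ct <- lmtest::coeftest(fit, vcov. = vc)
  .model_result(.tidy_coeftest(ct), description, fit)
}

#' Trial-position regressions of triplet intransitivity
#'
#' Two logistic regressions at the triplet level, each with a
#' mediotemporal-group interaction and cluster-robust (by subject)
#' standard errors: (a) intransitivity on the (standardised) trial index of
#' the last-seen constituent trial — tests whether inconsistency declines
#' as earlier choices could be remembered; (b) intransitivity on the
#' (standardised) variance of the three constituent trial indices — tests
#' whether choices made further apart in the session are less mutually
#' consistent. Predictor standardisation (mean, sd) is recorded in the
#' result's `scaling` element.
#'
#' @param triplets triplet records with `is_intransitive`,
#'   `last_trial_index`, `trial_index_variance`, `group`, `subject_id`
#'   (typically [score_all()]'s `triplets` for the preference task).
#' @return A list with `last_trial` and `trial_variance` `model_result`s
#'   and `scaling` (means/sds used for the z-scores).
#' @export
triplet_level_regressions <- function(triplets) {
  y <- triplets$is_intransitive
  if (all(y) || all(!y)) {
    stop("all triplets have the same class; the logistic regression is ",
         "separated. Use data with both transitive and intransitive triplets.",
         call. = FALSE)
  }
  d <- tibble::tibble(
    y = as.integer(y),
    mtl = as.integer(triplets$group == "MTL"),
    subject_id = triplets$subject_id
  )
  scaling <- list(
    last_trial = c(mean = mean(triplets$last_trial_index),
                   sd = stats::sd(triplets$last_trial_index)),
    trial_variance = c(mean = mean(triplets$trial_index_variance),
                       sd = stats::sd(triplets$trial_index_variance))
  )
  d$z_last <- (triplets$last_trial_index - scaling$last_trial["mean"]) /
    scaling$last_trial["sd"]
  d$z_var <- (triplets$trial_index_variance - scaling$trial_variance["mean"]) /
    scaling$trial_variance["sd"]
  list(
    last_trial = .robust_logistic(
      y ~ z_last * mtl, d, d$subject_id,
      "logistic regression of triplet intransitivity on standardised last-trial index, MTL interaction, cluster-robust (subject) SE"),
    trial_variance = .robust_logistic(
      y ~ z_var * mtl, d, d$subject_id,
      "logistic regression of triplet intransitivity on standardised trial-index variance, MTL interaction, cluster-robust (subject) SE"),
    scaling = scaling
  )
}

#' Response-time analyses
#'
#' (a) Logistic regression of a trial's involvement in intransitive
#' triplets on its standardised response time (with a quadratic term and a
#' mediotemporal interaction, cluster-robust by subject) — a positive
#' linear coefficient means slower, not faster, trials are the inconsistent
#' ones, contradicting a speed-accuracy-tradeoff account. (b) Linear model
#' of subject mean response time on the orthogonal group contrasts — tests
#' whether the mediotemporal group responds slower overall.
#'
#' @param trials trial table with `involved` (see [trial_involvement()]),
#'   `rt`, `group`, `subject_id`.
#' @return A list with `involvement` and `group_rt` `model_result`s and
#'   `n_excluded_rt` (trials dropped for missing response times).
#' @export
rt_analyses <- function(trials) {
  n_excluded <- sum(is.na(trials$rt))
  if (n_excluded > 0) {
    message(n_excluded, " trial(s) excluded for missing response times")
    trials <- trials[!is.na(trials$rt), ]
  }
  if (nrow(trials) == 0) stop("no trials with response times", call. = FALSE)
  z_rt <- .zscore(trials$rt)
  if (is.null(z_rt)) {
    warning("response times are constant; rt coefficients degenerate (reported as 0)")
    tidy <- tibble::tibble(term = c("z_rt", "I(z_rt^2)", "z_rt:mtl"),
                           estimate = 0, std_error = NA_real_,
                           statistic = NA_real_, p_value = NA_real_)
    involvement <- .model_result(tidy, "degenerate: constant response times")
  } else {
    d <- tibble::tibble(y = as.integer(trials$involved), z_rt = z_rt,
                        mtl = as.integer(trials$group == "MTL"),
                        subject_id = trials$subject_id)
    involvement <- .robust_logistic(
      y ~ z_rt + I(z_rt^2) + z_rt:mtl + mtl, d, d$subject_id,
      "logistic regression of intransitive-triplet involvement on standardised rt (+ quadratic), MTL interaction, cluster-robust (subject) SE")
  }
  subj <- dplyr::summarise(
    dplyr::group_by(trials, .data$subject_id, .data$group),
    mean_rt = mean(.data$rt), .groups = "drop")
  subj <- build_group_task_design(
    tibble::tibble(subject_id = subj$subject_id, group = subj$group,
                   task = "preference", mean_rt = subj$mean_rt))
  fit <- stats::lm(mean_rt ~ c_etl + c_mtl, data = subj)
  sm <- stats::coef(summary(fit))
  group_rt <- .model_result(
    tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                   std_error = sm[, 2], statistic = sm[, 3],
                   df = fit$df.residual, p_value = sm[, 4]),
    "linear model of subject mean rt on orthogonal group contrasts")
  list(involvement = involvement, group_rt = group_rt,
       n_excluded_rt = n_excluded)
}

#' Test for item heterogeneity in intransitive-triplet involvement
#'
#' Asks whether specific items are disproportionately involved in
#' intransitive triplets. Counts per subject x item are analysed with a
#' two-way ANOVA with subject as a blocking factor; the F statistic for the
#' item factor has `n_items - 1` and `(n_subjects - 1) * (n_items - 1)`
#' degrees of freedom.
#'
#' @param counts tibble with `subject_id`, `item`, `count` (how many
#'   intransitive triplets of that subject contain that item).
#' @return A list with `statistic` (F), `df1`, `df2`, `p` and `description`.
#' @export
item_involvement_test <- function(counts) {
  if (length(unique(counts$item)) < 2) {
    stop("need at least 2 items", call. = FALSE)
  }
  counts$item <- factor(counts$item)
  counts$subject_id <- factor(counts$subject_id)
  fit <- stats::aov(count ~ item + subject_id, data = counts)
  an <- summary(fit)[[1]]
  row <- grep("^item", rownames(an))
  list(statistic = an[row, "F value"], df1 = an[row, "Df"],
       df2 = an["Residuals", "Df"], p = an[row, "Pr(>F)"],
       description = "two-way ANOVA of involvement counts, item factor with subject blocks")
}

#' Per-subject item involvement counts for a scored dataset
#'
#' @param triplets triplet records for one task across subjects.
#' @param n_items number of items.
#' @return Tibble `subject_id`, `item`, `count`.
#' @export
item_involvement_counts <- function(triplets, n_items) {
  subjects <- unique(triplets$subject_id)
  rows <- lapply(subjects, function(s) {
    tibble::tibble(
      subject_id = s, item = seq_len(n_items),
      count = item_involvement(triplets[triplets$subject_id == s, ], n_items))
  })
  dplyr::bind_rows(rows)
}
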