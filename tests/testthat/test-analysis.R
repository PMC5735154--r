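test_that("the lateral damage index follows its defining formula", {
  expect_equal(compute_ldi(3.1, 3.1), 0)
  expect_equal(compute_ldi(0.62, 0.38), 0.24)
  # symmetric under side swap, bounded in [0, 1)
  set.seed(8)
  vl <- runif(200, 0.01, 10); vr <- runif(200, 0.01, 10)
  expect_equal(compute_ldi(vl, vr), compute_ldi(vr, vl))
  expect_true(all(compute_ldi(vl, vr) >= 0 & compute_ldi(vl, vr) < 1))
  expect_equal(compute_ldi(vl, vr) == 0, vl == vr)
  # one-sided atrophy approaches (but never reaches) 1
  expect_gt(compute_ldi(1, 1e-9), 0.999)
  expect_error(compute_ldi(0, 1), "strictly positive")
  expect_error(compute_ldi(1, -2), "strictly positive")
})

test_that("lesion-behaviour correlation is a midrank Spearman with matching", {
  recs <- tibble::tibble(subject_id = paste0("m", 1:8),
                         vol_left = seq(2, 4.8, by = 0.4), vol_right = 5)
  recs <- lesion_records(recs)
  scores <- tibble::tibble(subject_id = paste0("m", 1:8),
                           pct_intransitive = sort(runif(8)) * 10)
  # ldi decreases with vol_left here; pct increases -> perfectly monotone
  res <- ldi_behavior_correlation(recs, scores)
  expect_equal(res$rho, -1)
  res2 <- ldi_behavior_correlation(recs, scores[8:1, ])  # order irrelevant
  expect_equal(res2$rho, -1)
  scores$pct_intransitive <- rev(scores$pct_intransitive)
  expect_equal(ldi_behavior_correlation(recs, scores)$rho, 1)
  expect_error(ldi_behavior_correlation(recs, scores[1:5, ]), "no scores")

  # oracle: rank-then-Pearson with midranks
  set.seed(3)
  scores$pct_intransitive <- round(runif(8), 1)  # ties likely
  res3 <- ldi_behavior_correlation(recs, scores)
  expect_equal(res3$rho,
               stats::cor(rank(recs$ldi), rank(scores$pct_intransitive)))
  expect_equal(res3$n, 8)
})

test_that("Bartlett wrapper matches the closed-form statistic", {
  # 6-value fixture, two groups of 3; closed form computed explicitly
  g1 <- c(1, 2, 3); g2 <- c(2, 6, 10)  # 4x the sd -> 16x the variance
  n <- c(3, 3); N <- 6; k <- 2
  s2 <- c(var(g1), var(g2))
  sp2 <- sum((n - 1) * s2) / (N - k)
  corr <- 1 + (sum(1 / (n - 1)) - 1 / (N - k)) / (3 * (k - 1))
  k2_hand <- ((N - k) * log(sp2) - sum((n - 1) * log(s2))) / corr
  res <- variance_homogeneity_check(list(a = g1, b = g2))
  expect_equal(res$statistic, k2_hand)
  expect_equal(res$df, 1)
  expect_gt(res$statistic, 0)
  expect_true(res$p > 0 && res$p < 1)

  # equal variances: statistic at (numerically) zero
  expect_lt(variance_homogeneity_check(list(g1, g1 + 5))$statistic, 1e-10)
  # invariant to permutation within groups
  expect_equal(variance_homogeneity_check(list(a = g1, b = rev(g2)))$statistic,
               res$statistic)
  expect_error(variance_homogeneity_check(list(g1)), "at least 2")
  expect_error(variance_homogeneity_check(list(a = g1, b = c(1, 1, 1))),
               "zero variance")
})

test_that("log transform keeps zeros finite and preserves order", {
  sc <- tibble::tibble(
    subject_id = paste0("s", 1:6), group = "CON",
    task = rep(c("preference", "number"), each = 3),
    n_triplets = 1140L,
    pct_intransitive = c(2.5, 2.5, 7, 0, 0.5, 1))
  out <- log_transform_scores(sc, offset_policy = "half_triplet")
  expect_equal(attr(out, "offset"), 100 / 2280)
  expect_true(all(is.finite(out$log_pct)))
  expect_equal(out$log_pct[4], log(100 / 2280))
  expect_equal(out$log_pct[1], out$log_pct[2])
  expect_true(all(diff(out$log_pct[order(sc$pct_intransitive)]) >= 0))
  expect_error(log_transform_scores(dplyr::mutate(sc, pct_intransitive = -1)),
               "nonnegative")
})

test_that("the variance-stabilising offset reduces the between-task Bartlett statistic", {
  co <- generate_cohort(cohort_spec(seed = 21))
  pre <- variance_homogeneity_check(
    split(co$scores$pct_intransitive, co$scores$task))
  st <- log_transform_scores(co$scores)
  post <- variance_homogeneity_check(split(st$log_pct, st$task))
  expect_lt(post$statistic, pre$statistic)
  expect_gt(attr(st, "offset"), 100 / 2280)  # the chosen offset is recorded
  # and the chosen offset homogenises better than the fixed half-triplet one
  st2 <- log_transform_scores(co$scores, offset_policy = "half_triplet")
  post2 <- variance_homogeneity_check(split(st2$log_pct, st2$task))
  expect_lte(post$statistic, post2$statistic)
})

test_that("the contrast scheme encodes the two planned comparisons orthogonally", {
  sch <- build_contrasts()
  expect_equal(colSums(sch$codes), c(etl_vs_con = 0, mtl_vs_controls = 0))
  expect_equal(sum(sch$codes[, 1] * sch$codes[, 2]), 0)
  expect_equal(unname(sch$codes["MTL", ]), c(0, 1))
  # applied to the observed group means, the second contrast is the
  # mediotemporal excess over the pooled controls
  means <- c(CON = 2.75, ETL = 3.37, MTL = 6.07)
  expect_equal(sum(sch$codes[, "mtl_vs_controls"] * means), 3.01)
  expect_equal(sum(sch$codes[, "etl_vs_con"] * means), 0.62)
  expect_error(build_contrasts(c("CON", "ETL", "XXX")), "exactly CON, ETL, MTL")
})

test_that("the group-task design matrix is built as specified", {
  sc <- tidyr::expand_grid(group = c("CON", "ETL", "MTL"),
                           task = c("preference", "number"))
  d <- build_group_task_design(sc)
  expect_equal(d$c_etl, rep(c(-1, 1, 0), each = 2))
  expect_equal(d$c_mtl, rep(c(-0.5, -0.5, 1), each = 2))
  expect_equal(d$task_c, rep(c(0.5, -0.5), 3))
  expect_error(build_group_task_design(tibble::tibble(group = "HC", task = "a")),
               "unknown group")
})

test_that("the mixed model reports the planned terms and rejects singular designs", {
  co <- generate_cohort(small_spec(seed = 31))
  st <- log_transform_scores(co$scores)
  res <- suppressMessages(fit_group_task_model(st))
  expect_setequal(res$tidy$term,
                  c("(Intercept)", "c_etl", "c_mtl", "task_c",
                    "c_etl:task_c", "c_mtl:task_c"))
  expect_true(all(res$tidy$p_value >= 0 & res$tidy$p_value <= 1))

  # shifting all responses by a constant moves only the intercept
  st2 <- st; st2$log_pct <- st2$log_pct + 2
  res2 <- suppressMessages(fit_group_task_model(st2))
  expect_equal(res$tidy$estimate[-1], res2$tidy$estimate[-1], tolerance = 1e-6)
  expect_equal(unname(res2$tidy$estimate[1] - res$tidy$estimate[1]), 2,
               tolerance = 1e-6)

  expect_error(fit_group_task_model(st[st$task == "preference", ]),
               "singular design")
  expect_error(fit_group_task_model(st[-1, ]), "both tasks")
})

test_that("triplet-level regressions separate cleanly and standardise predictors", {
  co <- generate_cohort(small_spec(seed = 41))
  trip <- co$triplets[co$triplets$task == "preference", ]
  res <- triplet_level_regressions(trip)
  expect_setequal(names(res), c("last_trial", "trial_variance", "scaling"))
  expect_true("z_var" %in% res$trial_variance$tidy$term)
  expect_equal(unname(res$scaling$last_trial["mean"]),
               mean(trip$last_trial_index))

  all_trans <- trip
  all_trans$is_intransitive <- FALSE
  expect_error(triplet_level_regressions(all_trans), "separated")
})

test_that("shuffling trial order destroys the trial-spacing effect", {
  # pooled drifted cohorts give a clear positive spacing coefficient;
  # re-indexing trials at random breaks the generative link
  co <- generate_cohort(cohort_spec(seed = 51))
  trip <- co$triplets[co$triplets$task == "preference", ]
  z_obs <- triplet_level_regressions(trip)$trial_variance$tidy
  z_obs <- z_obs$statistic[z_obs$term == "z_var"]
  expect_gt(z_obs, 2)

  tr <- co$dataset$trials
  set.seed(1)
  shuffled <- dplyr::group_by(tr, subject_id, task)
  shuffled <- dplyr::mutate(shuffled, trial_index = sample(trial_index))
  ds2 <- choice_dataset(dplyr::ungroup(shuffled), co$dataset$n_items)
  trip2 <- score_all(ds2)$triplets
  trip2 <- trip2[trip2$task == "preference", ]
  z_shuf <- triplet_level_regressions(trip2)$trial_variance$tidy
  z_shuf <- z_shuf$statistic[z_shuf$term == "z_var"]
  expect_lt(abs(z_shuf), 2.5)
  expect_lt(abs(z_shuf), z_obs)
})

test_that("rt analyses flag degenerate inputs and report exclusions", {
  co <- generate_cohort(small_spec(seed = 61))
  pref <- co$dataset$trials[co$dataset$trials$task == "preference", ]
  trip <- co$triplets[co$triplets$task == "preference", ]
  ann <- dplyr::bind_rows(lapply(unique(pref$subject_id), function(s) {
    trial_involvement(trip[trip$subject_id == s, ], pref[pref$subject_id == s, ])
  }))

  res <- rt_analyses(ann)
  expect_equal(res$n_excluded_rt, 0)
  expect_true("z_rt" %in% res$involvement$tidy$term)
  expect_setequal(res$group_rt$tidy$term, c("(Intercept)", "c_etl", "c_mtl"))

  ann2 <- ann; ann2$rt[1:10] <- NA
  expect_message(res2 <- rt_analyses(ann2), "10 trial\\(s\\) excluded")
  expect_equal(res2$n_excluded_rt, 10)

  ann3 <- ann; ann3$rt <- 1.5
  w <- testthat::capture_warnings(res3 <- rt_analyses(ann3))
  expect_true(any(grepl("constant", w)))
  expect_equal(res3$involvement$tidy$estimate[res3$involvement$tidy$term == "z_rt"], 0)
})

test_that("rt slowdown and group shift injected by the generator are recovered", {
  spec <- small_spec(seed = 71)
  spec$rt$slowdown <- 0.4
  spec$rt$mtl_shift <- 0.5
  co <- generate_cohort(spec)
  pref <- co$dataset$trials[co$dataset$trials$task == "preference", ]
  trip <- co$triplets[co$triplets$task == "preference", ]
  ann <- dplyr::bind_rows(lapply(unique(pref$subject_id), function(s) {
    trial_involvement(trip[trip$subject_id == s, ], pref[pref$subject_id == s, ])
  }))
  res <- rt_analyses(ann)
  expect_gt(res$involvement$tidy$estimate[res$involvement$tidy$term == "z_rt"], 0)
  expect_gt(res$group_rt$tidy$estimate[res$group_rt$tidy$term == "c_mtl"], 0)
})

test_that("item involvement test detects heterogeneity and only heterogeneity", {
  # no item effect at all: between-item sum of squares is exactly zero
  flat <- tidyr::expand_grid(subject_id = c("a", "b"), item = 1:3)
  flat$count <- c(1, 2, 3, 3, 2, 1)  # item means all equal
  res <- item_involvement_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$df1, 2)

  # an inflated item is detected
  set.seed(5)
  counts <- tidyr::expand_grid(subject_id = paste0("s", 1:12), item = 1:8)
  counts$count <- rpois(nrow(counts), 3) + ifelse(counts$item == 4, 6, 0)
  res2 <- item_involvement_test(counts)
  expect_lt(res2$p, 0.01)
  expect_equal(res2$df1, 7)

  expect_error(item_involvement_test(dplyr::filter(counts, item == 1)),
               "at least 2 items")
})

test_that("per-subject item counts feed the heterogeneity test", {
  co <- generate_cohort(small_spec(seed = 81))
  trip <- co$triplets[co$triplets$task == "preference", ]
  counts <- item_involvement_counts(trip, 10)
  expect_equal(nrow(counts), 15 * 10)
  # conservation per subject: 3 intransitive-triplet slots per cycle
  tot <- stats::aggregate(count ~ subject_id, counts, sum)
  sc <- co$scores[co$scores$task == "preference", ]
  expect_equal(tot$count[match(sc$subject_id, tot$subject_id)],
               3 * sc$n_intransitive)
})
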