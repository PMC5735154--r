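test_that("choice_dataset enforces trial invariants", {
  tr <- tibble::tibble(subject_id = "s1", group = "CON", task = "preference",
                       trial_index = 1L, item_a = 1L, item_b = 2L,
                       choice = 1L, rt = 0.8)
  expect_s3_class(choice_dataset(tr, 3), "choice_dataset")

  bad <- tr; bad$item_b <- 1L
  expect_error(choice_dataset(bad, 3), "item_a equals item_b")
  bad <- tr; bad$choice <- 3L
  expect_error(choice_dataset(bad, 3), "not a member of its pair")
  bad <- tr; bad$item_b <- 9L
  expect_error(choice_dataset(bad, 3), "outside 1..n_items")
  bad <- tr; bad$rt <- -1
  expect_error(choice_dataset(bad, 3), "negative response times")
  expect_error(choice_dataset(tr[, -1], 3), "subject_id")
})

test_that("a toy multi-subject file reads with normalised item codes", {
  # 3 subjects x 3 items x 3 trials, with item codes 10/20/30 to exercise
  # normalisation
  rows <- expand.grid(subject_id = c("a", "b", "c"), pair = 1:3)
  pair_map <- rbind(c(10, 20), c(20, 30), c(10, 30))
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(subject_id = rows$subject_id, group = "CON",
                   task = "preference", trial_index = rows$pair,
                   item_a = pair_map[rows$pair, 1],
                   item_b = pair_map[rows$pair, 2],
                   choice = pair_map[rows$pair, 1], rt = 0.5)
  utils::write.csv(df, f, row.names = FALSE)
  ds <- read_choice_table(f)
  expect_equal(nrow(ds$trials), 9)
  expect_equal(ds$n_items, 3)
  expect_setequal(unique(c(ds$trials$item_a, ds$trials$item_b)), 1:3)
  expect_equal(unname(ds$item_labels), c("10", "20", "30"))
})

test_that("reader reports missing columns and unparseable rows by position", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,task,trial_index,item_a,item_b,rt",
               "s1,CON,preference,1,1,2,0.5"), f)
  expect_error(read_choice_table(f), "missing required column 'choice'")

  writeLines(c("subject_id,group,task,trial_index,item_a,item_b,choice,rt",
               "s1,CON,preference,1,1,2,1,0.5",
               "s1,CON,preference,oops,1,3,1,0.5"), f)
  expect_error(read_choice_table(f), "line\\(s\\): 3")
})

test_that("dialect remaps column names and converts ms to seconds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subj\tgrp\ttask\ttrial_index\titem_a\titem_b\tchoice\tlatency",
               "s1\tCON\tpreference\t1\t1\t2\t2\t800"), f)
  ds <- read_choice_table(f, choice_dialect(
    sep = "\t", columns = c(subject_id = "subj", group = "grp",
                            rt = "latency"), rt_unit = "ms"))
  expect_equal(ds$trials$rt, 0.8)
  expect_equal(ds$trials$choice, 2L)
})

test_that("write then read is the identity on a generated cohort", {
  co <- generate_cohort(small_spec(seed = 7))
  f <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(co$dataset, f)
  back <- read_choice_table(f, n_items = co$dataset$n_items)
  tr1 <- co$dataset$trials[order(co$dataset$trials$subject_id,
                                 co$dataset$trials$task,
                                 co$dataset$trials$trial_index), ]
  expect_equal(as.data.frame(back$trials), as.data.frame(tr1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$n_items, co$dataset$n_items)
})

test_that("writing an empty dataset yields a header-only file", {
  tr <- tibble::tibble(subject_id = character(), group = character(),
                       task = character(), trial_index = integer(),
                       item_a = integer(), item_b = integer(),
                       choice = integer(), rt = numeric())
  ds <- choice_dataset(tr, 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(ds, f)
  expect_length(readLines(f), 1)
})

test_that("a single-subject 190-trial file has 190 data rows", {
  ds <- simulate_subject(simulation_config(alpha = 0.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(ds, f)
  expect_length(readLines(f), 191)
})

test_that("validate_design accepts the complete 190-trial design", {
  ds <- simulate_subject(simulation_config(alpha = 0.3), "p01")
  expect_equal(nrow(ds$trials), 190)
  rep <- validate_design(ds)
  expect_true(rep$is_complete)
  expect_equal(nrow(rep$missing_pairs), 0)
})

test_that("validate_design localises missing, duplicated and missing-choice defects", {
  ds <- simulate_subject(simulation_config(alpha = 0.3), "p01")
  # drop one trial -> exactly one missing pair
  short <- choice_dataset(ds$trials[-10, ], ds$n_items)
  rep <- validate_design(short)
  expect_false(rep$is_complete)
  expect_equal(nrow(rep$missing_pairs), 1)
  gone <- ds$trials[10, ]
  expect_equal(rep$missing_pairs$pair,
               paste(min(gone$item_a, gone$item_b),
                     max(gone$item_a, gone$item_b), sep = "-"))

  # replace one pair's trial with a repeat of another -> 1 duplicate + 1 missing
  tr <- ds$trials
  tr[10, c("item_a", "item_b", "choice")] <- tr[11, c("item_a", "item_b", "choice")]
  rep2 <- validate_design(choice_dataset(tr, ds$n_items))
  expect_equal(nrow(rep2$duplicate_pairs), 1)
  expect_equal(nrow(rep2$missing_pairs), 1)

  # a missing response is irregular but not an error
  tr <- ds$trials
  tr$choice[5] <- NA_integer_
  rep3 <- validate_design(choice_dataset(tr, ds$n_items))
  expect_false(rep3$is_complete)
  expect_match(rep3$irregular_trials$issue, "missing choice")
})

test_that("a file with a duplicated pair loads and is flagged", {
  ds <- simulate_subject(simulation_config(n_items = 5, alpha = 0.5))
  tr <- ds$trials
  tr[1, c("item_a", "item_b", "choice")] <- tr[2, c("item_a", "item_b", "choice")]
  f <- withr::local_tempfile(fileext = ".csv")
  write_choice_table(choice_dataset(tr, 5), f)
  back <- read_choice_table(f, n_items = 5)
  rep <- validate_design(back)
  expect_equal(nrow(rep$duplicate_pairs), 1)
})
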