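#' Enumerate all unordered pairs of items
#'
#' @param n_items number of items (>= 2).
#' @return Integer matrix with columns `item_a < item_b`, one row per pair;
#'   `choose(n_items, 2)` rows.
#' @export
enumerate_pairs <- function(n_items) {
  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 2) stop("n_items must be >= 2", call. = FALSE)
  m <- t(utils::combn(n_items, 2))
  colnames(m) <- c("item_a", "item_b")
  m
}

#' Enumerate all unordered triples of items
#'
#' @param n_items number of items (>= 3).
#' @return Integer matrix with columns `i < j < k`, `choose(n_items, 3)` rows.
#' @export
enumerate_triplets <- function(n_items) {
  n_items <- as.integer(n_items)
  if (is.na(n_items) || n_items < 3) stop("n_items must be >= 3", call. = FALSE)
  m <- t(utils::combn(n_items, 3))
  colnames(m) <- c("i", "j", "k")
  m
}

#' Classify one triplet of pairwise choices
#'
#' Given the three pairwise winners among items `(i, j, k)`, decides whether
#' the choices form a transitive order or a directed 3-cycle. A triplet is
#' intransitive exactly when no item wins both of its two comparisons, which
#' happens for 2 of the 8 possible orientation patterns.
#'
#' @param items integer vector `c(i, j, k)` of three distinct item codes.
#' @param winners integer vector `c(w_ij, w_jk, w_ik)`: the winner of the
#'   (i, j), (j, k) and (i, k) comparisons respectively.
#' @return `"transitive"` or `"intransitive"`.
#' @export
classify_triplet <- function(items, winners) {
  stopifnot(length(items) == 3, length(winners) == 3)
  if (length(unique(items)) != 3) stop("items must be distinct", call. = FALSE)
  i <- items[1]; j <- items[2]; k <- items[3]
  pairs <- list(c(i, j), c(j, k), c(i, k))
  for (p in seq_len(3)) {
    if (!winners[p] %in% pairs[[p]]) {
      stop(sprintf("winner %s is not a member of pair (%s, %s)",
                   winners[p], pairs[[p]][1], pairs[[p]][2]), call. = FALSE)
    }
  }
  wins <- c(sum(winners == i), sum(winners == j), sum(winners == k))
  if (max(wins) == 2) "transitive" else "intransitive"
}

# Per-subject structures: a logical "beat" matrix B[a, b] = TRUE if a was
# chosen over b (canonical orientation a < b is stored; B[b, a] is implied),
# and the trial index of each canonical pair.
.subject_matrices <- function(trials, n_items) {
  B <- matrix(NA, n_items, n_items)
  TI <- matrix(NA_integer_, n_items, n_items)
  lo <- pmin(trials$item_a, trials$item_b)
  hi <- pmax(trials$item_a, trials$item_b)
  B[cbind(lo, hi)] <- trials$choice == lo
  TI[cbind(lo, hi)] <- trials$trial_index
  list(beat = B, trial_of = TI)
}

# Vectorised triplet table from the beat/trial matrices. trip is the output
# of enumerate_triplets(n_items).
.triplet_table <- function(mats, trip) {
  i <- trip[, 1]; j <- trip[, 2]; k <- trip[, 3]
  a_ij <- mats$beat[cbind(i, j)]
  a_jk <- mats$beat[cbind(j, k)]
  a_ik <- mats$beat[cbind(i, k)]
  t_ij <- mats$trial_of[cbind(i, j)]
  t_jk <- mats$trial_of[cbind(j, k)]
  t_ik <- mats$trial_of[cbind(i, k)]
  observed <- !is.na(a_ij) & !is.na(a_jk) & !is.na(a_ik)
  is_intr <- (a_ij & a_jk & !a_ik) | (!a_ij & !a_jk & a_ik)
  tibble::new_tibble(list(
    i = i, j = j, k = k,
    w_ij = ifelse(a_ij, i, j), w_jk = ifelse(a_jk, j, k),
    w_ik = ifelse(a_ik, i, k),
    is_intransitive = is_intr,
    t_ij = t_ij, t_jk = t_jk, t_ik = t_ik,
    last_trial_index = pmax(t_ij, t_jk, t_ik),
    trial_index_variance = .var3(t_ij, t_jk, t_ik),
    observed = observed
  ), nrow = length(i))
}

#' Score one subject's intransitivity on one task
#'
#' Enumerates all `choose(n_items, 3)` item triplets for the given subject
#' and task, classifies each as transitive or intransitive, and returns the
#' subject-level score together with the triplet-level records used by the
#' trial-position analyses. Triplets with a missing constituent choice are
#' excluded from numerator and denominator and counted in `n_excluded`.
#'
#' @param ds a [choice_dataset()].
#' @param subject_id subject identifier present in `ds`.
#' @param task task label present for that subject.
#' @return A list with `score` (one-row tibble: subject_id, group, task,
#'   n_triplets, n_intransitive, pct_intransitive, n_excluded) and
#'   `triplets` (tibble of fully observed triplet records with the three
#'   pairwise winners, the intransitivity flag, the three trial indices,
#'   `last_trial_index` and `trial_index_variance`).
#' @examples
#' path <- system.file("extdata", "example_choices.csv", package = "intrans")
#' ds <- read_choice_table(path)
#' score_subject(ds, "demo01", "preference")$score
#' @export
score_subject <- function(ds, subject_id, task) {
  stopifnot(inherits(ds, "choice_dataset"))
  sel <- ds$trials$subject_id == subject_id & ds$trials$task == task
  if (!any(sel)) {
    stop(sprintf("no trials for subject '%s', task '%s'", subject_id, task),
         call. = FALSE)
  }
  trials <- ds$trials[sel & !is.na(ds$trials$choice), ]
  mats <- .subject_matrices(trials, ds$n_items)
  trip <- enumerate_triplets(ds$n_items)
  tt <- .triplet_table(mats, trip)
  n_excluded <- sum(!tt$observed)
  tt <- tt[tt$observed, names(tt) != "observed"]
  n_triplets <- nrow(tt)
  n_intr <- sum(tt$is_intransitive)
  score <- tibble::tibble(
    subject_id = subject_id,
    group = trials$group[1],
    task = task,
    n_triplets = n_triplets,
    n_intransitive = n_intr,
    pct_intransitive = if (n_triplets > 0) 100 * n_intr / n_triplets else NA_real_,
    n_excluded = n_excluded
  )
  tt$subject_id <- subject_id
  tt$group <- trials$group[1]
  tt$task <- task
  list(score = score, triplets = tt)
}

#' Score every subject and task in a dataset
#'
#' @param ds a [choice_dataset()].
#' @return A list with `scores` (one row per subject x task) and `triplets`
#'   (all triplet records, stacked).
#' @export
score_all <- function(ds) {
  stopifnot(inherits(ds, "choice_dataset"))
  keys <- unique(ds$trials[c("subject_id", "task")])
  res <- lapply(seq_len(nrow(keys)), function(r) {
    score_subject(ds, keys$subject_id[r], keys$task[r])
  })
  list(
    scores = dplyr::bind_rows(lapply(res, `[[`, "score")),
    triplets = dplyr::bind_rows(lapply(res, `[[`, "triplets"))
  )
}

#' Count how many intransitive triplets each item participates in
#'
#' Each directed 3-cycle touches exactly three items, so the counts sum to
#' three times the number of intransitive triplets.
#'
#' @param triplets triplet records as returned by [score_subject()].
#' @param n_items number of items.
#' @return Integer vector of length `n_items`.
#' @export
item_involvement <- function(triplets, n_items) {
  idx <- c(triplets$i[triplets$is_intransitive],
           triplets$j[triplets$is_intransitive],
           triplets$k[triplets$is_intransitive])
  tabulate(idx, nbins = n_items)
}

#' Annotate trials with their membership in intransitive triplets
#'
#' Each triplet is built from three trials (one per constituent pair); a
#' trial is "involved" if at least one intransitive triplet uses it.
#'
#' @param triplets triplet records for one subject x task
#'   (see [score_subject()]).
#' @param trials the matching trials (rows of a [choice_dataset()]'s
#'   `trials` for that subject and task).
#' @return `trials` with two extra columns: `n_intransitive_triplets`
#'   (count of intransitive triplets using the trial) and `involved`
#'   (logical flag).
#' @export
trial_involvement <- function(triplets, trials) {
  ti <- c(triplets$t_ij, triplets$t_jk, triplets$t_ik)
  flag <- rep(triplets$is_intransitive, 3)
  counts <- tapply(as.integer(flag), factor(ti, levels = trials$trial_index),
                   sum, default = 0L)
  trials$n_intransitive_triplets <- as.integer(counts[as.character(trials$trial_index)])
  trials$n_intransitive_triplets[is.na(trials$n_intransitive_triplets)] <- 0L
  trials$involved <- trials$n_intransitive_triplets > 0L
  trials
}

#' Expected intransitivity probability under symmetric random choice
#'
#' Enumerates the 8 equally likely orientation patterns of one triplet under
#' independent fair-coin pairwise choices via [classify_triplet()] and
#' returns the proportion that are cyclic. This is the per-triplet
#' intransitivity probability of a purely random responder, and the maximum
#' of the expected proportion over symmetric choice probabilities.
#'
#' @return A single proportion.
#' @export
random_choice_intransitivity <- function() {
  patterns <- expand.grid(a_ij = c(TRUE, FALSE), a_jk = c(TRUE, FALSE),
                          a_ik = c(TRUE, FALSE))
  cls <- apply(patterns, 1, function(p) {
    classify_triplet(
      items = c(1L, 2L, 3L),
      winners = c(if (p[["a_ij"]]) 1L else 2L,
                  if (p[["a_jk"]]) 2L else 3L,
                  if (p[["a_ik"]]) 1L else 3L))
  })
  mean(cls == "intransitive")
}

# Fast cyclic-triple count from the win tally of a complete tournament:
# number of cyclic triangles = C(n,3) - sum_i C(wins_i, 2).
.count_cyclic <- function(wins) {
  n <- length(wins)
  choose(n, 3) - sum(choose(wins, 2))
}
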