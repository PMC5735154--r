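# Shared fixtures and independent oracles.

# A trials tibble for one subject/task from an explicit winner list.
# pairs: matrix (item_a, item_b); winners: chosen item per pair.
trials_from_winners <- function(pairs, winners, subject_id = "s1",
                                group = "CON", task = "preference",
                                order = seq_len(nrow(pairs))) {
  tibble::tibble(
    subject_id = subject_id, group = group, task = task,
    trial_index = order,
    item_a = pairs[, 1], item_b = pairs[, 2],
    choice = winners, rt = NA_real_)
}

# Complete single-subject dataset with choices following a strict ranking
# (item with the higher rank value always wins).
ranked_dataset <- function(n_items, ranking = seq_len(n_items),
                           seed = 1, ...) {
  set.seed(seed)
  pairs <- enumerate_pairs(n_items)
  winners <- ifelse(ranking[pairs[, 1]] > ranking[pairs[, 2]],
                    pairs[, 1], pairs[, 2])
  tr <- trials_from_winners(pairs, winners, order = sample.int(nrow(pairs)), ...)
  choice_dataset(tr, n_items = n_items)
}

# Complete single-subject dataset with independent fair-coin choices.
coinflip_dataset <- function(n_items, seed, ...) {
  set.seed(seed)
  pairs <- enumerate_pairs(n_items)
  winners <- ifelse(stats::runif(nrow(pairs)) < 0.5, pairs[, 1], pairs[, 2])
  tr <- trials_from_winners(pairs, winners, order = sample.int(nrow(pairs)), ...)
  choice_dataset(tr, n_items = n_items)
}

# Independent oracle: count intransitive triples by an explicit triple loop
# over the raw trial table, re-deriving each pair's winner by lookup. A
# triple is cyclic iff each of its three items wins exactly one of its two
# comparisons.
brute_force_intransitive <- function(trials, n_items) {
  winner_of <- function(x, y) {
    row <- which((trials$item_a == x & trials$item_b == y) |
                   (trials$item_a == y & trials$item_b == x))
    stopifnot(length(row) == 1)
    trials$choice[row]
  }
  count <- 0L
  for (i in seq_len(n_items - 2)) {
    for (j in seq(i + 1, n_items - 1)) {
      for (k in seq(j + 1, n_items)) {
        w <- c(winner_of(i, j), winner_of(j, k), winner_of(i, k))
        n_wins <- c(sum(w == i), sum(w == j), sum(w == k))
        if (all(n_wins == 1)) count <- count + 1L
      }
    }
  }
  count
}

# The 4-item worked example: A>B, B>C, C>A (a cycle) and D loses to all.
# Items A=1, B=2, C=3, D=4; exactly 1 of the 4 triples is cyclic.
four_item_cycle_dataset <- function() {
  pairs <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  winners <- c(1, 2, 3, 1, 2, 3)  # A>B, B>C, C>A, A>D, B>D, C>D
  tr <- trials_from_winners(pairs, winners)
  choice_dataset(tr, n_items = 4)
}

# Small cohort spec for fast end-to-end tests.
small_spec <- function(seed = 1, ...) {
  cohort_spec(n_per_group = c(CON = 5L, ETL = 5L, MTL = 5L),
              n_items = 10L, seed = seed, ...)
}
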