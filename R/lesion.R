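#' Lateral damage index of a paired structure
#'
#' The LDI expresses unilateral damage as the absolute normalised asymmetry
#' of the left and right structure volumes,
#' `|V_L - V_R| / (V_L + V_R)`. It is dimensionless, lies in `[0, 1)`,
#' is symmetric under swapping sides, and equals 0 exactly when the two
#' volumes are equal.
#'
#' @param vol_left,vol_right left and right volumes in the same (arbitrary)
#'   unit; both strictly positive. Vectorised.
#' @return Numeric vector of LDI values.
#' @examples
#' compute_ldi(2.91, 4.07)   # right-larger asymmetry, ~0.17
#' compute_ldi(3.5, 3.5)     # symmetric volumes -> 0
#' @export
compute_ldi <- function(vol_left, vol_right) {
  if (any(!is.finite(vol_left)) || any(!is.finite(vol_right)) ||
      any(vol_left <= 0) || any(vol_right <= 0)) {
    stop("volumes must be finite and strictly positive", call. = FALSE)
  }
  abs((vol_left - vol_right) / (vol_left + vol_right))
}

#' Build lesion records from a volumes table
#'
#' @param volumes data frame with columns `subject_id`, `vol_left`,
#'   `vol_right`.
#' @return Tibble with the input columns plus `ldi` (see [compute_ldi()]).
#' @export
lesion_records <- function(volumes) {
  required <- c("subject_id", "vol_left", "vol_right")
  missing_cols <- setdiff(required, names(volumes))
  if (length(missing_cols) > 0) {
    stop("volumes table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(volumes)[required]
  out$ldi <- compute_ldi(out$vol_left, out$vol_right)
  out
}

#' Rank correlation between lesion extent and choice inconsistency
#'
#' Spearman rank correlation (midranks for ties, two-tailed test) between
#' subjects' lateral damage index and their intransitivity percentage.
#'
#' @param records lesion records (see [lesion_records()]): `subject_id`,
#'   `ldi`.
#' @param scores subject scores with `subject_id` and `pct_intransitive`
#'   (one task only).
#' @return A list with `rho`, `statistic` (the Spearman S statistic), `p`,
#'   and `n` (matched subjects).
#' @export
ldi_behavior_correlation <- function(records, scores) {
  orphans <- setdiff(records$subject_id, scores$subject_id)
  if (length(orphans) > 0) {
    stop("no scores for lesion subject(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  m <- merge(records[c("subject_id", "ldi")],
             scores[c("subject_id", "pct_intransitive")], by = "subject_id")
  if (nrow(m) < 4) stop("need at least 4 matched subjects", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(m$ldi, m$pct_intransitive, method = "spearman",
                    alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), statistic = unname(ct$statistic),
       p = ct$p.value, n = nrow(m))
}
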