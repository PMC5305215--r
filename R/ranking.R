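#' Aggregate per-replicate Z-scores per protein
#'
#' Collects each protein's Z-scores across the replicate ratio tables and
#' derives the order statistics used for ranking: the second-largest Z
#' (the lower of two or the middle of three) for every protein quantified
#' in at least two replicates, and the third-largest (minimum of three) for
#' proteins quantified in all three. Proteins with a single +NTR/Ctl value
#' are excluded entirely — one high value may still be a cargo, but it
#' cannot be corroborated.
#'
#' @param records Ratio-record tibble from [ratio_records()] (2 or 3
#'   replicates bound together), or a list of per-replicate tibbles.
#' @return A tibble with columns `accession`, `z1`, `z2`, `z3` (Z-score in
#'   replicate 1..3, `NA` where unquantified), `n_values`, `second_z`,
#'   `third_z` (`NA` unless `n_values == 3`).
#' @export
assemble_ranking_input <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- bind_rows(records)
  }
  reps <- sort(unique(records$replicate))
  if (length(reps) < 2L) {
    stop_silactp("need ratio records from at least 2 replicates",
                 "silactp_usage_error")
  }
  if (length(reps) > 3L) {
    stop_silactp("more than 3 replicates supplied", "silactp_usage_error")
  }
  wide <- records %>%
    select("accession", "replicate", "z") %>%
    tidyr::pivot_wider(names_from = "replicate", values_from = "z",
                       names_prefix = "z")
  for (nm in paste0("z", 1:3)) if (!nm %in% names(wide)) wide[[nm]] <- NA_real_
  zmat <- as.matrix(wide[, c("z1", "z2", "z3")])
  n_values <- rowSums(!is.na(zmat))
  wide %>%
    mutate(n_values = as.integer(n_values),
           second_z = apply(zmat, 1L, order_statistic, k = 2L),
           third_z = apply(zmat, 1L, order_statistic, k = 3L)) %>%
    dplyr::filter(.data$n_values >= 2L) %>%
    select("accession", "z1", "z2", "z3", "n_values", "second_z", "third_z")
}

#' k-th largest of a protein's replicate Z-scores
#'
#' @param z_values Numeric vector (NAs ignored) of 2-3 Z-scores.
#' @param k 2 for the second-largest (lower of two, middle of three), 3 for
#'   the third-largest (minimum of three).
#' @return The k-th largest value, or `NA` if fewer than `k` values.
#' @export
#' @examples
#' order_statistic(c(2.0, 0.5, 1.0), k = 2)  # 1.0
order_statistic <- function(z_values, k) {
  stopifnot(k %in% c(2L, 3L))
  z <- z_values[!is.na(z_values)]
  if (length(z) < k) return(NA_real_)
  sort(z, decreasing = TRUE)[k]
}

#' Rank proteins by an order-statistic of their replicate Z-scores
#'
#' Descending by the chosen statistic. The 2nd-Z ranking contains every
#' protein with >= 2 replicate values; the 3rd-Z ranking only proteins with
#' all three. Ties are broken deterministically: first by the larger sum of
#' the remaining (unused) order statistics, then lexicographically by
#' accession, so output is byte-stable across runs — documented because a
#' boundary tie can move a protein across a percentile cutoff.
#'
#' @param entries Tibble from [assemble_ranking_input()].
#' @param statistic `"second_z"` or `"third_z"`.
#' @return A `silac_ranking` tibble: `rank`, `accession`, `statistic`
#'   (value), `z1`, `z2`, `z3`, `n_values`, `percentile`.
#' @export
rank_proteins <- function(entries, statistic = c("second_z", "third_z")) {
  statistic <- match.arg(statistic)
  pool <- if (statistic == "third_z") {
    dplyr::filter(entries, .data$n_values == 3L)
  } else {
    entries
  }
  if (nrow(pool) == 0) {
    stop_silactp("no proteins eligible for this ranking",
                 "silactp_usage_error")
  }
  zmat <- as.matrix(pool[, c("z1", "z2", "z3")])
  stat <- pool[[statistic]]
  rest <- rowSums(zmat, na.rm = TRUE) - stat
  ord <- order(-stat, -rest, pool$accession)
  out <- pool[ord, ] %>%
    mutate(statistic = stat[ord], rank = seq_len(nrow(pool)),
           percentile = 100 * .data$rank / nrow(pool)) %>%
    select("rank", "accession", "statistic", "z1", "z2", "z3",
           "n_values", "percentile")
  class(out) <- c("silac_ranking", class(out))
  attr(out, "statistic") <- statistic
  out
}

#' Number of proteins in the top pct% of a ranking
#'
#' The floor rule `floor(N * pct / 100)`: the top 15% of 1649 proteins is
#' 247, of 2060 is 309; the top 4% of 1235 is 49, of 1671 is 66. A small
#' epsilon guards against binary floating-point representation of the
#' product sitting just below an integer.
#'
#' @param N Ranking size (positive integer).
#' @param pct Percent cutoff in (0, 100].
#' @return Non-negative integer count.
#' @export
cutoff_count <- function(N, pct) {
  stopifnot(N >= 1, pct > 0, pct <= 100)
  as.integer(floor(N * pct / 100 + 1e-9))
}

#' Call a candidate cargo set from a ranking
#'
#' The two published criteria are the high-sensitivity call — the top 15%
#' of the 2nd-Z ranking — and the high-specificity call — the top 4% of the
#' 3rd-Z ranking. Any percentage can be supplied, and the member count can
#' be overridden outright (e.g. to reproduce a hand-curated set size).
#'
#' @param ranking A `silac_ranking` tibble.
#' @param criterion `"second_z_15"` or `"third_z_4"`; ignored when `pct`
#'   is given.
#' @param pct Optional percent cutoff overriding the criterion's.
#' @param n_members Optional member-count override.
#' @param receptor Optional receptor name stored on the result.
#' @return A `cargo_set` tibble with columns `rank`, `accession` (top of
#'   the ranking, in rank order) and attributes `criterion`, `receptor`.
#' @export
call_cargo_set <- function(ranking, criterion = c("second_z_15", "third_z_4"),
                           pct = NULL, n_members = NULL,
                           receptor = NA_character_) {
  criterion <- match.arg(criterion)
  if (nrow(ranking) == 0) {
    stop_silactp("empty ranking", "silactp_usage_error")
  }
  expected <- c(second_z_15 = "second_z", third_z_4 = "third_z")[[criterion]]
  if (is.null(pct) && !is.null(attr(ranking, "statistic")) &&
      !identical(attr(ranking, "statistic"), expected)) {
    stop_silactp(paste0("criterion ", criterion, " expects a ", expected,
                        " ranking"), "silactp_usage_error")
  }
  pct <- pct %||% c(second_z_15 = 15, third_z_4 = 4)[[criterion]]
  k <- n_members %||% cutoff_count(nrow(ranking), pct)
  out <- head(select(as_tibble(ranking), "rank", "accession"), k)
  class(out) <- c("cargo_set", class(out))
  attr(out, "criterion") <- criterion
  attr(out, "receptor") <- receptor
  out
}
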