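#' One-sided Fisher exact enrichment p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`: the chance that drawing `n` of `N`
#' proteins yields at least `k` of the `K` annotated ones. This equals the
#' one-sided (enrichment) Fisher exact p-value of the 2x2 table
#' `[[k, n - k], [K - k, N - n - K + k]]`. Terms are accumulated in
#' log-space via `lgamma` so p-values far below double underflow of any
#' single naive factorial are still exact; no continuity correction or
#' mid-p adjustment is applied.
#'
#' @param k Annotated proteins in the drawn set (top slice).
#' @param K Annotated proteins in the universe.
#' @param n Size of the drawn set.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_enrichment_p(17, 25, 37, 1235)  # 1.67e-22
fisher_enrichment_p <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  ok <- k >= 0 && K >= 0 && n >= 0 && N >= 0 && K <= N && n <= N &&
    k <= min(K, n) && k >= max(0, n + K - N)
  if (!ok) {
    stop_silactp("inconsistent contingency arguments (need 0 <= k <= min(K, n), K <= N, n <= N, k >= n + K - N)",
                 "silactp_domain_error")
  }
  if (k == 0) return(1)
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  kk <- k:min(K, n)
  terms <- lchoose_(K, kk) + lchoose_(N - K, n - kk) - lchoose_(N, n)
  m <- max(terms)
  exp(m + log(sum(exp(terms - m))))
}

#' Reported-cargo rate and recall at a cutoff
#'
#' The reported-cargo rate `p(i) / [p(i) + n(i)]` is a lower bound on the
#' precision at cutoff i (unreported true cargoes count against it); recall
#' is `p(i) / P` over the `P` reported cargoes in the ranking.
#'
#' @param p_i Reported cargoes in the top i%.
#' @param n_i Negative examples in the top i%.
#' @param P_total Total reported cargoes in the ranking.
#' @return A tibble with columns `rate` (NA when `p_i + n_i == 0`) and
#'   `recall`.
#' @export
rate_and_recall <- function(p_i, n_i, P_total) {
  stopifnot(all(P_total >= 1), all(p_i <= P_total), all(p_i >= 0),
            all(n_i >= 0))
  tibble(rate = ifelse(p_i + n_i > 0, p_i / (p_i + n_i), NA_real_),
         recall = p_i / P_total)
}

#' Sweep percentile cutoffs against reported-cargo annotation
#'
#' For each cutoff i (default 1%, 2%, ..., 100%) counts the reported
#' cargoes and negative examples in the top i% of the ranking and computes
#' the reported-cargo rate, recall and one-sided Fisher exact enrichment
#' p-value. Two negative-example definitions are supported:
#' `all_unreported` treats every unreported protein as negative (rate is
#' then a lower bound on precision); `non_nuclear_only` treats only
#' unreported proteins with non-nuclear localization as negative and
#' excludes the rest from the evaluation universe entirely (neither
#' positive nor negative). Cutoff sizes are always computed on the full
#' ranking first; the exclusion is applied inside each top-i% slice.
#' Recall always uses the full positive set in the ranking, so it is
#' unaffected by the negative definition.
#'
#' @param ranking A `silac_ranking` tibble.
#' @param annotations A `silac_annotations` list ([read_annotations()] or
#'   [generate_silac_data()]).
#' @param receptor Receptor whose reported cargoes are the positives.
#' @param neg_def `"all_unreported"` or `"non_nuclear_only"`.
#' @param increment Cutoff step in percent (default 1).
#' @param max_pct Largest cutoff (default 100).
#' @return A `silac_evaluation` tibble: `cutoff_pct`, `n_top`, `p_i`,
#'   `n_i`, `P_total`, `N_eval`, `rate`, `recall`, `fisher_p`.
#' @export
evaluate_cutoffs <- function(ranking, annotations, receptor,
                             neg_def = c("all_unreported", "non_nuclear_only"),
                             increment = 1L, max_pct = 100L) {
  neg_def <- match.arg(neg_def)
  stopifnot(nrow(ranking) > 0, increment >= 1, max_pct <= 100)
  reported <- annotations$reported$accession[
    annotations$reported$receptor == receptor]
  is_pos <- ranking$accession %in% reported
  P_total <- sum(is_pos)
  if (P_total == 0) {
    stop_silactp(paste0("no reported cargo of ", receptor,
                        " present in the ranking"), "silactp_usage_error")
  }
  in_universe <- if (neg_def == "all_unreported") {
    rep(TRUE, nrow(ranking))
  } else {
    cls <- localization_class(annotations, ranking$accession)
    is_pos | (cls == "non_nuclear")
  }
  N_eval <- sum(in_universe)
  K <- P_total
  cutoffs <- seq(increment, max_pct, by = increment)
  # cumulative counts down the ranking make the sweep O(N + cutoffs)
  cum_pos <- cumsum(is_pos & in_universe)
  cum_eval <- cumsum(in_universe)
  out <- purrr::map_dfr(cutoffs, function(i) {
    n_top <- cutoff_count(nrow(ranking), i)
    p_i <- if (n_top > 0) cum_pos[n_top] else 0L
    n_eval_top <- if (n_top > 0) cum_eval[n_top] else 0L
    n_i <- n_eval_top - p_i
    tibble(cutoff_pct = i, n_top = n_top, p_i = as.integer(p_i),
           n_i = as.integer(n_i), P_total = P_total, N_eval = N_eval,
           fisher_p = fisher_enrichment_p(p_i, K, n_eval_top, N_eval))
  }) %>%
    mutate(rate_and_recall(.data$p_i, .data$n_i, P_total)) %>%
    select("cutoff_pct", "n_top", "p_i", "n_i", "P_total", "N_eval",
           "rate", "recall", "fisher_p")
  class(out) <- c("silac_evaluation", class(out))
  attr(out, "receptor") <- receptor
  attr(out, "neg_def") <- neg_def
  out
}
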