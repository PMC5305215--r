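#' Pair +NTR and control quantifications of one replicate
#'
#' The import index of a protein needs its L/H ratio in both the +NTR and
#' the control reaction of the same replicate; +NTR values lacking the
#' counterpart control value are discarded (and vice versa), so the result
#' contains exactly the proteins quantified in both runs.
#'
#' @param ntr_run,ctl_run Quantification tibbles from [read_quant_table()]
#'   (or one receptor/replicate slice of [generate_silac_data()] output),
#'   with `condition` `"ntr"` and `"ctl"` respectively.
#' @return A tibble with columns `accession`, `replicate`, `lh_ntr`,
#'   `lh_ctl`, one row per protein quantified in both runs.
#' @export
pair_ratios <- function(ntr_run, ctl_run) {
  rep_ntr <- unique(ntr_run$replicate)
  rep_ctl <- unique(ctl_run$replicate)
  if (length(rep_ntr) != 1L || length(rep_ctl) != 1L || rep_ntr != rep_ctl) {
    stop_silactp("`ntr_run` and `ctl_run` must come from the same replicate",
                 "silactp_usage_error")
  }
  if (!all(ntr_run$condition == "ntr") || !all(ctl_run$condition == "ctl")) {
    stop_silactp("conditions must be ntr / ctl respectively",
                 "silactp_usage_error")
  }
  inner_join(
    select(ntr_run, "accession", "replicate", lh_ntr = "lh_ratio"),
    select(ctl_run, "accession", lh_ctl = "lh_ratio"),
    by = "accession"
  )
}

#' Import index and its log2
#'
#' The +NTR/Ctl import index of a protein is the quotient of its L/H ratios
#' with and without the receptor; candidate cargoes are enriched in the
#' light (imported) channel only when the receptor is present, raising the
#' index above 1.
#'
#' @param lh_ntr,lh_ctl Positive numeric vectors of L/H ratios.
#' @return A tibble with columns `index` (`lh_ntr / lh_ctl`) and `x`
#'   (`log2(index)`).
#' @export
#' @examples
#' log2_index(2, 0.5)   # index 4, x 2
log2_index <- function(lh_ntr, lh_ctl) {
  if (any(!is.finite(lh_ntr) | lh_ntr <= 0) ||
      any(!is.finite(lh_ctl) | lh_ctl <= 0)) {
    stop_silactp("L/H ratios must be finite and positive",
                 "silactp_domain_error")
  }
  idx <- lh_ntr / lh_ctl
  tibble(index = idx, x = log2(idx))
}

#' Z-normalize log2 import indices within one replicate
#'
#' Centering and scaling by the replicate-wide mean and standard deviation
#' makes the three replicates' index distributions comparable before
#' order-statistic aggregation. The sample (n-1) standard deviation is used;
#' with thousands of proteins per replicate the convention is numerically
#' negligible but it is fixed for reproducibility.
#'
#' @param xs Numeric vector of log2 import indices (length >= 2, not
#'   constant).
#' @return Numeric vector of Z-scores, mean 0 and sd 1.
#' @export
zscore_within_replicate <- function(xs) {
  if (length(xs) < 2L) {
    stop_silactp("need at least 2 values to Z-normalize",
                 "silactp_usage_error")
  }
  s <- sd(xs)
  if (!is.finite(s) || s == 0) {
    stop_silactp("constant input: standard deviation is zero",
                 "silactp_degenerate_error")
  }
  (xs - mean(xs)) / s
}

#' Per-replicate ratio records for one receptor
#'
#' Runs the full quantification model for every replicate of one receptor:
#' pairs the +NTR and control runs, computes the +NTR/Ctl index and its
#' log2 (`x`), and Z-normalizes `x` over all paired proteins within each
#' replicate.
#'
#' @param quant A long quantification tibble covering the receptor's +NTR
#'   runs and their controls (columns `receptor`, `condition`, `replicate`,
#'   `accession`, `lh_ratio`, `lh_count`). Control rows are matched by
#'   `replicate`; their `receptor` tag, used only for bookkeeping, may be
#'   the paired receptor's name or `NA`.
#' @param receptor Receptor name to analyse.
#' @return A tibble of ratio records: `accession`, `replicate`, `lh_ntr`,
#'   `lh_ctl`, `index`, `x`, `z`.
#' @export
ratio_records <- function(quant, receptor) {
  ntr <- dplyr::filter(quant, .data$condition == "ntr",
                       .data$receptor == !!receptor)
  ctl <- dplyr::filter(quant, .data$condition == "ctl",
                       is.na(.data$receptor) | .data$receptor == !!receptor)
  if (nrow(ntr) == 0) {
    stop_silactp(paste0("no +NTR runs for receptor ", receptor),
                 "silactp_usage_error")
  }
  reps <- sort(unique(ntr$replicate))
  purrr::map_dfr(reps, function(r) {
    paired <- pair_ratios(dplyr::filter(ntr, .data$replicate == r),
                          dplyr::filter(ctl, .data$replicate == r))
    paired %>%
      mutate(log2_index(.data$lh_ntr, .data$lh_ctl),
             z = zscore_within_replicate(.data$x))
  })
}
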