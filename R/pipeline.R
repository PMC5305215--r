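#' Rank one receptor's candidate cargoes from quantification tables
#'
#' Convenience wrapper chaining the quantification model: pair each
#' replicate's +NTR and control runs, compute log2 import indices,
#' Z-normalize within replicates, aggregate per protein, and rank by the
#' requested order statistic.
#'
#' @inheritParams ratio_records
#' @param statistic `"second_z"` (proteins with >= 2 replicate values) or
#'   `"third_z"` (all three).
#' @return A `silac_ranking` tibble (see [rank_proteins()]).
#' @export
#' @examples
#' sim <- generate_silac_data(simulation_config(n_proteins = 300,
#'   receptors = "Trn-1", seed = 7))
#' rank_receptor(sim$quant, "Trn-1") |> head()
rank_receptor <- function(quant, receptor,
                          statistic = c("second_z", "third_z")) {
  statistic <- match.arg(statistic)
  quant %>%
    ratio_records(receptor) %>%
    assemble_ranking_input() %>%
    rank_proteins(statistic)
}

#' Call candidate cargo sets for every receptor in a dataset
#'
#' Runs [rank_receptor()] and [call_cargo_set()] for each receptor,
#' returning all called sets in one long tibble ready for
#' [sharing_summary()], [build_profile_matrix()] or [recovery_report()].
#'
#' @param quant Long quantification tibble covering several receptors.
#' @param receptors Receptor names (default: all with +NTR runs).
#' @param criterion `"second_z_15"` or `"third_z_4"`.
#' @param pct Optional percent-cutoff override.
#' @return A tibble: `receptor`, `rank`, `accession`.
#' @export
call_all_cargo_sets <- function(quant, receptors = NULL,
                                criterion = c("second_z_15", "third_z_4"),
                                pct = NULL) {
  criterion <- match.arg(criterion)
  statistic <- c(second_z_15 = "second_z", third_z_4 = "third_z")[[criterion]]
  receptors <- receptors %||%
    unique(quant$receptor[quant$condition == "ntr"])
  purrr::map_dfr(receptors, function(r) {
    set <- quant %>%
      rank_receptor(r, statistic) %>%
      call_cargo_set(criterion, pct = pct, receptor = r)
    mutate(as_tibble(set), receptor = r, .before = 1)
  })
}
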