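small_cfg <- function(...) {
  simulation_config(n_proteins = 300, receptors = "Trn-1", ...)
}

test_that("config validation names every offending field", {
  expect_error(simulation_config(cargo_fraction = 1.5, dropout = -0.1),
               "cargo_fraction.*dropout|dropout.*cargo_fraction",
               class = "silactp_validation_error")
  expect_error(simulation_config(n_replicates = 4),
               class = "silactp_validation_error")
  expect_error(simulation_config(sharing_design = tibble::tibble(
    receptor_a = "NoSuch", receptor_b = "Trn-1", fraction = 0.5)),
    class = "silactp_validation_error")
})

test_that("a fixed seed gives identical tables and does not leak RNG state", {
  cfg <- small_cfg(seed = 101)
  s1 <- generate_silac_data(cfg)
  set.seed(777)
  expected_next <- rnorm(1)
  set.seed(777)
  s2 <- generate_silac_data(cfg)
  expect_identical(s1$quant, s2$quant)
  expect_identical(s1$truth$cargo, s2$truth$cargo)
  expect_identical(s1$annotations$reported, s2$annotations$reported)
  # caller's RNG stream is untouched by the generator
  expect_identical(rnorm(1), expected_next)

  s3 <- generate_silac_data(small_cfg(seed = 102))
  expect_false(identical(s1$quant$lh_ratio, s3$quant$lh_ratio))
})

test_that("without missingness every protein appears in every run", {
  cfg <- small_cfg(dropout = 0, count_mean = 1e6, seed = 5)
  sim <- generate_silac_data(cfg)
  runs <- dplyr::count(sim$quant, condition, replicate)
  expect_true(all(runs$n == 300))
  entries <- assemble_ranking_input(ratio_records(sim$quant, "Trn-1"))
  expect_true(all(entries$n_values == 3L))
  # the 3rd-Z population equals the 2nd-Z population
  expect_setequal(rank_proteins(entries, "third_z")$accession,
                  rank_proteins(entries, "second_z")$accession)
})

test_that("replicate presence counts respond to dropout as expectation predicts", {
  # with count_mean large, absence is driven by dropout alone; a protein
  # enters a replicate's ratio table iff present in both runs, so
  # P(3 values) averages E[(1-p)^6] over proteins
  cfg <- small_cfg(dropout = 0.15, count_mean = 1e6, seed = 33)
  sim <- generate_silac_data(cfg)
  p <- pmin(1, 2 * 0.15 * (1 - rank(sim$truth$proteins$abundance) / 301))
  expected3 <- sum(((1 - p)^2)^3)
  entries <- assemble_ranking_input(ratio_records(sim$quant, "Trn-1"))
  observed3 <- sum(entries$n_values == 3L)
  expect_lt(abs(observed3 - expected3) / expected3, 0.15)

  # fewer proteins survive all three replicates than under less dropout
  low <- generate_silac_data(small_cfg(dropout = 0.02, count_mean = 1e6,
                                       seed = 33))
  low3 <- sum(assemble_ranking_input(
    ratio_records(low$quant, "Trn-1"))$n_values == 3L)
  expect_gt(low3, observed3)
})

test_that("reported labels are drawn from planted cargoes only", {
  sim <- generate_silac_data(small_cfg(seed = 19, reported_fraction = 0.2))
  expect_true(all(sim$annotations$reported$accession %in%
                    sim$truth$cargo$accession))
  expect_true(all(sim$truth$cargo$delta >= 0.3))
  loc <- sim$truth$proteins$localization
  expect_true(all(loc[sim$truth$proteins$accession %in%
                        sim$truth$cargo$accession] == "nuclear"))
})

test_that("recovery report computes recall and precision against the truth", {
  sim <- generate_silac_data(small_cfg(seed = 3))
  planted <- sim$truth$cargo$accession[sim$truth$cargo$receptor == "Trn-1"]
  perfect <- recovery_report(sim$truth, list(`Trn-1` = planted))
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)

  half <- recovery_report(sim$truth,
                          list(`Trn-1` = c(planted[1:10], "SYN99999")))
  expect_equal(half$n_recovered, 10L)
  expect_equal(half$precision, 10 / 11)
  expect_error(recovery_report(sim$truth, list(Nope = "X")),
               class = "silactp_usage_error")
})

test_that("stronger planted effects do not reduce planted-cargo recall", {
  mean_recall <- function(effect_mean, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- generate_silac_data(simulation_config(
        n_proteins = 250, receptors = "Trn-1", effect_mean = effect_mean,
        effect_sd = 0.2, seed = s))
      sets <- call_all_cargo_sets(sim$quant, criterion = "second_z_15")
      recovery_report(sim$truth, sets)$recall
    }, numeric(1)))
  }
  seeds <- 1:12
  grid <- vapply(c(0.5, 1.5, 3), mean_recall, numeric(1), seeds = seeds)
  expect_true(all(diff(grid) >= 0))
})

test_that("a per-replicate global shift is absorbed by the Z-normalization", {
  base <- generate_silac_data(small_cfg(seed = 55))
  shifted <- generate_silac_data(small_cfg(seed = 55,
                                           replicate_shift_sd = 2))
  rb <- rank_receptor(base$quant, "Trn-1")
  rs <- rank_receptor(shifted$quant, "Trn-1")
  # different raw ratios, but replicate-wise standardization keeps
  # recovery comparable
  expect_false(identical(base$quant$lh_ratio, shifted$quant$lh_ratio))
  recall_b <- recovery_report(
    base$truth, list(`Trn-1` = call_cargo_set(rb, "second_z_15")$accession))
  recall_s <- recovery_report(
    shifted$truth, list(`Trn-1` = call_cargo_set(rs, "second_z_15")$accession))
  expect_lt(abs(recall_b$recall - recall_s$recall), 0.2)
})
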