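# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic SILAC transport simulator
#'
#' Defines the generative model for replicate protein-level quantification
#' tables with planted cargo structure. Proteins get log-normal abundances;
#' each run measures a protein's log2 L/H as a protein-specific baseline
#' plus independent Gaussian measurement noise, and planted cargoes of the
#' run's receptor additionally gain their import effect `delta` (log2
#' units) in the +NTR condition only. L/H counts are Poisson in abundance,
#' and a protein is absent from a run when its drawn count is 0 or it is
#' dropped out (dropout probability decreases with abundance). Defaults
#' emulate the scale of the real experiments: ~2000 quantified proteins per
#' run, 12 receptors, 3 replicates.
#'
#' @param n_proteins Number of proteins in the proteome (default 2000,
#'   the scale of quantified proteins per run in the real assays).
#' @param receptors Character vector of receptor names (default the 12
#'   importin-family import/bi-directional receptors).
#' @param n_replicates 2 or 3 (default 3).
#' @param cargo_fraction Fraction of the proteome planted as cargo per
#'   receptor (default 0.08).
#' @param sharing_design Optional tibble (`receptor_a`, `receptor_b`,
#'   `fraction`) forcing receptor_b's cargo set to share `fraction` of its
#'   size with receptor_a's; unlisted pairs overlap only by chance.
#' @param effect_mean,effect_sd,effect_min Planted log2 import effect:
#'   Normal(`effect_mean`, `effect_sd`) truncated at `effect_min`
#'   (defaults 1.5, 0.5, 0.3). Set all three to 0 for a null simulation.
#' @param noise_log2 SD of the per-run Gaussian noise on log2 L/H
#'   (default 0.6).
#' @param baseline_sd SD of the per-protein baseline log2 L/H
#'   (default 0.5).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters (defaults 0, 1).
#' @param count_mean Expected L/H count of a protein of mean abundance;
#'   per-protein Poisson mean scales linearly with abundance (default 8).
#' @param dropout Mean dropout probability; per protein it is
#'   `min(1, 2 * dropout * (1 - F))` with `F` the protein's abundance
#'   percentile, so low-abundance proteins drop out more (default 0.1).
#' @param replicate_shift_sd SD of an optional per-replicate global shift
#'   added to the +NTR runs' log2 L/H, exercising the within-replicate
#'   Z-normalization (default 0, off).
#' @param reported_fraction Fraction of planted cargoes labeled as
#'   previously reported (default 0.1). Reported labels are drawn from
#'   planted cargoes only, so evaluation positives are true by
#'   construction.
#' @param nonnuclear_fraction Fraction of non-cargo proteins annotated
#'   non-nuclear (default 0.15).
#' @param seed Integer RNG seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 2000L,
                              receptors = c("Imp-beta", "Trn-1", "Trn-2",
                                            "Trn-SR", "Imp-4", "Imp-5",
                                            "Imp-7", "Imp-8", "Imp-9",
                                            "Imp-11", "Imp-13", "Exp-4"),
                              n_replicates = 3L,
                              cargo_fraction = 0.08,
                              sharing_design = NULL,
                              effect_mean = 1.5, effect_sd = 0.5,
                              effect_min = 0.3,
                              noise_log2 = 0.6, baseline_sd = 0.5,
                              abundance_meanlog = 0, abundance_sdlog = 1,
                              count_mean = 8, dropout = 0.1,
                              replicate_shift_sd = 0,
                              reported_fraction = 0.1,
                              nonnuclear_fraction = 0.15,
                              seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), receptors = receptors,
              n_replicates = as.integer(n_replicates),
              cargo_fraction = cargo_fraction,
              sharing_design = sharing_design,
              effect_mean = effect_mean, effect_sd = effect_sd,
              effect_min = effect_min, noise_log2 = noise_log2,
              baseline_sd = baseline_sd,
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              count_mean = count_mean, dropout = dropout,
              replicate_shift_sd = replicate_shift_sd,
              reported_fraction = reported_fraction,
              nonnuclear_fraction = nonnuclear_fraction,
              seed = as.integer(seed))
  bad <- character()
  if (cfg$n_proteins < 10) bad <- c(bad, "n_proteins (< 10)")
  if (length(cfg$receptors) < 1 || anyDuplicated(cfg$receptors)) {
    bad <- c(bad, "receptors (empty or duplicated)")
  }
  if (!cfg$n_replicates %in% 2:3) bad <- c(bad, "n_replicates (not 2 or 3)")
  for (fr in c("cargo_fraction", "dropout", "reported_fraction",
               "nonnuclear_fraction")) {
    if (cfg[[fr]] < 0 || cfg[[fr]] > 1) bad <- c(bad, paste0(fr, " (not in [0,1])"))
  }
  for (pos in c("effect_sd", "noise_log2", "baseline_sd", "abundance_sdlog",
                "count_mean", "replicate_shift_sd")) {
    if (cfg[[pos]] < 0) bad <- c(bad, paste0(pos, " (negative)"))
  }
  if (!is.null(sharing_design)) {
    if (!all(c("receptor_a", "receptor_b", "fraction") %in%
             names(sharing_design)) ||
        !all(unlist(sharing_design[c("receptor_a", "receptor_b")]) %in%
             cfg$receptors) ||
        any(sharing_design$fraction < 0 | sharing_design$fraction > 1)) {
      bad <- c(bad, "sharing_design (unknown receptor or fraction outside [0,1])")
    }
  }
  if (length(bad) > 0) {
    stop_silactp(paste0("invalid simulation config: ",
                        paste(bad, collapse = "; ")),
                 "silactp_validation_error")
  }
  structure(cfg, class = "simulation_config")
}

#' Null configuration (no planted import effects)
#'
#' All effect parameters 0, so every protein's +NTR and control runs share
#' one distribution and rankings order proteins by noise alone.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
null_config <- function(...) {
  simulation_config(effect_mean = 0, effect_sd = 0, effect_min = 0, ...)
}

rtrunc_normal <- function(n, mean, sd, lower) {
  if (sd == 0) return(pmax(rep(mean, n), lower))
  u <- runif(n, pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

#' Generate synthetic replicate SILAC quantification tables
#'
#' Draws the full study design from a [simulation_config()]: paired +NTR
#' and control quantification runs for every receptor and replicate, the
#' ground truth (planted cargo sets with per-cargo effects, per-protein
#' abundance and labels), and an annotation set compatible with
#' [evaluate_cutoffs()]. Identical seed, identical output.
#'
#' @param config A `simulation_config`.
#' @return A list with elements:
#'   * `quant`: tibble of all runs (`receptor`, `condition`, `replicate`,
#'     `accession`, `lh_ratio`, `lh_count`); control runs carry the paired
#'     receptor's name with `condition == "ctl"`;
#'   * `truth`: list(`cargo` = tibble(receptor, accession, delta),
#'     `proteins` = tibble(accession, abundance, localization, reported),
#'     `seed`, `config`);
#'   * `annotations`: `silac_annotations` list.
#' @export
generate_silac_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_proteins
    acc <- sprintf("SYN%05d", seq_len(n))
    abundance <- stats::rlnorm(n, config$abundance_meanlog,
                               config$abundance_sdlog)
    baseline <- rnorm(n, 0, config$baseline_sd)
    lambda <- config$count_mean * abundance / mean(abundance)
    p_drop <- pmin(1, 2 * config$dropout * (1 - rank(abundance) / (n + 1)))

    # planted cargo sets, honoring any designed pairwise sharing
    n_cargo <- max(1L, round(config$cargo_fraction * n))
    sets <- list()
    for (r in config$receptors) {
      forced <- character()
      if (!is.null(config$sharing_design)) {
        des <- config$sharing_design[config$sharing_design$receptor_b == r, ]
        for (i in seq_len(nrow(des))) {
          partner <- sets[[des$receptor_a[i]]]
          if (!is.null(partner)) {
            k <- min(length(partner), round(des$fraction[i] * n_cargo))
            forced <- union(forced, sample(partner, k))
          }
        }
      }
      rest <- sample(setdiff(acc, forced), n_cargo - length(forced))
      sets[[r]] <- c(forced, rest)
    }
    cargo <- purrr::map_dfr(config$receptors, function(r) {
      tibble(receptor = r, accession = sets[[r]],
             delta = rtrunc_normal(length(sets[[r]]), config$effect_mean,
                                   config$effect_sd, config$effect_min))
    })

    is_cargo <- acc %in% cargo$accession
    loc <- character(n)
    loc[is_cargo] <- "nuclear"
    n_non <- sum(!is_cargo)
    loc[!is_cargo] <- sample(
      c("non_nuclear", "nuclear", "undetermined"), n_non, replace = TRUE,
      prob = c(config$nonnuclear_fraction, 0.35,
               max(0, 1 - config$nonnuclear_fraction - 0.35)))
    reported <- cargo %>%
      group_by(.data$receptor) %>%
      dplyr::slice_sample(prop = config$reported_fraction) %>%
      ungroup() %>%
      select("receptor", "accession")

    runs <- tidyr::expand_grid(receptor = config$receptors,
                               condition = c("ctl", "ntr"),
                               replicate = seq_len(config$n_replicates))
    shift <- array(rnorm(length(config$receptors) * config$n_replicates,
                         0, config$replicate_shift_sd),
                   dim = c(length(config$receptors), config$n_replicates),
                   dimnames = list(config$receptors, NULL))
    quant <- purrr::pmap_dfr(runs, function(receptor, condition, replicate) {
      counts <- rpois(n, lambda)
      present <- counts >= 1L & runif(n) >= p_drop
      log2lh <- baseline + rnorm(n, 0, config$noise_log2)
      if (condition == "ntr") {
        log2lh <- log2lh + shift[receptor, replicate]
        rc <- cargo[cargo$receptor == receptor, ]
        d <- numeric(n)
        d[match(rc$accession, acc)] <- rc$delta
        log2lh <- log2lh + d
      }
      tibble(receptor = receptor, condition = condition,
             replicate = as.integer(replicate),
             accession = acc[present],
             lh_ratio = 2^log2lh[present],
             lh_count = as.integer(counts[present]))
    })

    annotations <- structure(list(
      reported = reported,
      localization = tibble(accession = acc, class = loc)
    ), class = "silac_annotations")

    list(quant = quant,
         truth = list(cargo = cargo,
                      proteins = tibble(accession = acc,
                                        abundance = abundance,
                                        localization = loc,
                                        reported = acc %in%
                                          reported$accession),
                      seed = config$seed, config = config),
         annotations = annotations)
  })
}

#' Recovery of planted cargoes by called cargo sets
#'
#' Compares called candidate-cargo sets against the simulator's ground
#' truth: per receptor, recall is the fraction of planted cargoes called
#' and precision the fraction of called proteins that were planted.
#'
#' @param truth The `truth` element of [generate_silac_data()] output.
#' @param cargo_sets A tibble (`receptor`, `accession`) or named list of
#'   accession vectors of called sets.
#' @return A tibble: `receptor`, `n_planted`, `n_called`, `n_recovered`,
#'   `recall`, `precision`.
#' @export
recovery_report <- function(truth, cargo_sets) {
  sets <- as_cargo_list(cargo_sets)
  unknown <- setdiff(names(sets), unique(truth$cargo$receptor))
  if (length(unknown) > 0) {
    stop_silactp(paste0("called sets name receptors absent from the truth: ",
                        paste(unknown, collapse = ", ")),
                 "silactp_usage_error")
  }
  purrr::map_dfr(names(sets), function(r) {
    planted <- truth$cargo$accession[truth$cargo$receptor == r]
    called <- sets[[r]]
    hit <- length(intersect(called, planted))
    tibble(receptor = r, n_planted = length(planted),
           n_called = length(called), n_recovered = hit,
           recall = hit / length(planted),
           precision = if (length(called) > 0) hit / length(called)
                       else NA_real_)
  })
}
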