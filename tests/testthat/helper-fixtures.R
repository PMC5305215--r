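# Shared fixture builders: everything is generated in code at test time.

write_quant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path)
  path
}

# A minimal one-replicate quant pair with known ratios.
toy_run <- function(accs, ratios, condition, replicate = 1L,
                    receptor = "Trn-1", counts = 2L) {
  tibble::tibble(receptor = receptor, condition = condition,
                 replicate = as.integer(replicate), accession = accs,
                 lh_ratio = ratios,
                 lh_count = as.integer(rep_len(counts, length(accs))))
}

# A hand-built ranking of size n with reported positives at given ranks.
# Only the fields the evaluation module reads are meaningful.
fixture_ranking <- function(n, positive_ranks, receptor = "Trn-1",
                            statistic = "second_z") {
  acc <- sprintf("P%05d", seq_len(n))
  rk <- tibble::tibble(
    rank = seq_len(n), accession = acc,
    statistic = seq(5, -5, length.out = n),
    z1 = NA_real_, z2 = NA_real_, z3 = NA_real_,
    n_values = 3L, percentile = 100 * seq_len(n) / n)
  class(rk) <- c("silac_ranking", class(rk))
  attr(rk, "statistic") <- statistic
  ann <- structure(list(
    reported = tibble::tibble(receptor = receptor,
                              accession = acc[positive_ranks]),
    localization = tibble::tibble(accession = character(),
                                  class = character())
  ), class = "silac_annotations")
  list(ranking = rk, annotations = ann, accessions = acc)
}

# Trn-1 evaluation fixture mirroring the printed contingency structure:
# 1649 ranked proteins, 27 reported cargoes, exactly 20 of them inside the
# top 247 ranks.
trn1_fixture <- function() {
  fixture_ranking(1649, c(seq(10, 200, by = 10),
                          c(300, 500, 700, 900, 1100, 1300, 1500)))
}

# Size-safe single draw (sample() treats a scalar as 1:n).
sample1 <- function(x) x[sample.int(length(x), 1L)]

# Brute-force upper-tail hypergeometric probability by full enumeration of
# the pmf (independent of the package's log-space route).
enum_hyper_upper <- function(k, K, n, N) {
  kk <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

# Naive sliding-window motif oracle for the default hydrophobic PY-NLS:
# tries every (start, linker, spacer) combination explicitly.
naive_hydrophobic_pynls <- function(seq, linker_max = 15) {
  res <- strsplit(seq, "")[[1]]
  phi <- strsplit("WFYLIVM", "")[[1]]
  hits <- integer()
  for (s in seq_along(res)) {
    if (s + 3 > length(res)) break
    if (!(res[s] %in% phi && res[s + 1] %in% c("G", "A", "S") &&
          res[s + 2] %in% phi && res[s + 3] %in% phi)) next
    for (g in 0:linker_max) {
      r_pos <- s + 4 + g
      for (x in 2:5) {
        p_pos <- r_pos + 1 + x
        if (p_pos + 1 > length(res)) next
        if (res[r_pos] %in% c("R", "K", "H") && res[p_pos] == "P" &&
            res[p_pos + 1] == "Y") {
          hits <- c(hits, s)
        }
      }
    }
  }
  unique(hits)
}
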