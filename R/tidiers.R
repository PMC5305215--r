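#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cargo-profile dendrogram
#'
#' One row per agglomeration step, broom-style: the merge height and the
#' receptors contained in the newly formed cluster.
#'
#' @param x A `cargo_dendrogram` from [ward_cluster()].
#' @param ... Unused.
#' @return A tibble: `step`, `height`, `n_members`, `members`
#'   (comma-separated receptor names).
#' @export
tidy.cargo_dendrogram <- function(x, ...) {
  hc <- x$hclust
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) hc$labels[-k] else members[[k]]
    }))
  }
  tibble(step = seq_len(nrow(hc$merge)), height = hc$height,
         n_members = lengths(members),
         members = vapply(members, function(m) paste(sort(m), collapse = ","),
                          ""))
}

#' @rdname tidy.cargo_dendrogram
#' @export
glance.cargo_dendrogram <- function(x, ...) {
  tibble(n_leaves = length(x$hclust$labels),
         n_merges = length(x$hclust$height),
         max_height = max(x$hclust$height),
         method = x$method)
}

#' Tidy / summarise an evaluation sweep
#'
#' `tidy()` returns the sweep as a plain tibble; `glance()` condenses it to
#' one row: the most enriched cutoff, its Fisher p-value, and the
#' rate/recall trade-off there.
#'
#' @param x A `silac_evaluation` tibble from [evaluate_cutoffs()].
#' @param ... Unused.
#' @export
tidy.silac_evaluation <- function(x, ...) {
  class(x) <- setdiff(class(x), "silac_evaluation")
  as_tibble(x)
}

#' @rdname tidy.silac_evaluation
#' @export
glance.silac_evaluation <- function(x, ...) {
  best <- which.min(x$fisher_p)
  tibble(receptor = attr(x, "receptor") %||% NA_character_,
         neg_def = attr(x, "neg_def") %||% NA_character_,
         best_cutoff_pct = x$cutoff_pct[best],
         best_fisher_p = x$fisher_p[best],
         rate_at_best = x$rate[best],
         recall_at_best = x$recall[best])
}

#' Tidy a sharing summary
#'
#' Long pairwise form: one row per unordered receptor pair with the shared
#' cargo count.
#'
#' @param x A `sharing_summary` from [sharing_summary()].
#' @param ... Unused.
#' @export
tidy.sharing_summary <- function(x, ...) {
  recs <- rownames(x$pairwise)
  pairs <- utils::combn(seq_along(recs), 2)
  tibble(receptor_a = recs[pairs[1, ]], receptor_b = recs[pairs[2, ]],
         shared = x$pairwise[t(pairs)])
}

#' @rdname tidy.sharing_summary
#' @export
glance.sharing_summary <- function(x, ...) {
  tibble(n_receptors = nrow(x$pairwise),
         total_cargoes = x$total_cargoes,
         unique_cargoes = sum(x$unique_counts),
         mean_pairwise = x$mean_pairwise)
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat("Cargo sharing across", nrow(x$pairwise), "receptors:",
      x$total_cargoes, "cargoes,", sum(x$unique_counts),
      "unique to one receptor, mean pairwise sharing",
      format(x$mean_pairwise, digits = 3), "\n")
  invisible(x)
}

#' @export
print.cargo_dendrogram <- function(x, ...) {
  cat("Cargo-profile dendrogram (", x$method, " on Euclidean distances), ",
      length(x$hclust$labels), " receptors\n", sep = "")
  invisible(x)
}
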