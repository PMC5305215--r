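# Normalize cargo-set input: a tibble (receptor, accession) or a named list
# of accession vectors -> named list, preserving receptor order.
as_cargo_list <- function(cargo_sets) {
  if (is.data.frame(cargo_sets)) {
    stopifnot(all(c("receptor", "accession") %in% names(cargo_sets)))
    recs <- unique(cargo_sets$receptor)
    sets <- lapply(recs, function(r) {
      unique(cargo_sets$accession[cargo_sets$receptor == r])
    })
    return(setNames(sets, recs))
  }
  if (is.list(cargo_sets)) {
    if (is.null(names(cargo_sets)) || anyDuplicated(names(cargo_sets))) {
      stop_silactp("cargo sets need unique receptor names",
                   "silactp_usage_error")
    }
    return(lapply(cargo_sets, function(x) unique(as.character(x))))
  }
  stop_silactp("cargo_sets must be a tibble or named list",
               "silactp_usage_error")
}

#' Cargo sharing statistics between receptors
#'
#' How redundantly the import pathways cover the proteome: the pairwise
#' shared-cargo counts between receptors, the number of cargoes unique to
#' a single receptor, the total distinct cargoes, and the mean pairwise
#' sharing over unordered receptor pairs.
#'
#' @param cargo_sets A tibble with columns `receptor`, `accession`, or a
#'   named list of accession vectors (>= 2 receptors).
#' @return A `sharing_summary` list: `pairwise` (symmetric integer matrix,
#'   diagonal = set sizes), `unique_counts` (named vector), `total_cargoes`,
#'   `mean_pairwise`, and `per_cargo_receptors` (tibble: accession,
#'   n_receptors).
#' @export
sharing_summary <- function(cargo_sets) {
  sets <- as_cargo_list(cargo_sets)
  if (length(sets) < 2L) {
    stop_silactp("need at least 2 cargo sets", "silactp_usage_error")
  }
  recs <- names(sets)
  universe <- sort(unique(unlist(sets)))
  mat <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  storage.mode(mat) <- "integer"          # universe x receptors
  pairwise <- crossprod(mat)
  dimnames(pairwise) <- list(recs, recs)
  membership <- rowSums(mat)
  uniq <- vapply(seq_along(sets), function(j) {
    sum(mat[, j] == 1L & membership == 1L)
  }, integer(1))
  off <- pairwise[upper.tri(pairwise)]
  structure(list(
    pairwise = pairwise,
    unique_counts = setNames(as.integer(uniq), recs),
    total_cargoes = length(universe),
    mean_pairwise = mean(off),
    per_cargo_receptors = tibble(accession = universe,
                                 n_receptors = as.integer(membership))
  ), class = "sharing_summary")
}

#' Binary receptor-by-cargo profile matrix
#'
#' Each receptor's cargo profile is a binary vector over the union of all
#' input cargo sets: 1 where the protein is in that receptor's set. Rows
#' follow input receptor order; columns are the lexicographically sorted
#' cargo universe. Receptors whose candidate sets are dominated by
#' adapter-mediated indirect cargoes (Imp-beta via Imp-alpha) are best
#' excluded by the caller before profiling.
#'
#' @inheritParams sharing_summary
#' @return An integer matrix (receptors x cargo universe) with dimnames.
#' @export
build_profile_matrix <- function(cargo_sets) {
  sets <- as_cargo_list(cargo_sets)
  if (length(sets) < 2L) {
    stop_silactp("need at least 2 cargo sets", "silactp_usage_error")
  }
  universe <- sort(unique(unlist(sets)))
  mat <- t(vapply(sets, function(s) as.integer(universe %in% s),
                  integer(length(universe))))
  dimnames(mat) <- list(names(sets), universe)
  mat
}

#' Ward hierarchical clustering of cargo profiles
#'
#' Agglomerative clustering of the binary profile rows on Euclidean
#' distance with Ward linkage. `"ward.D2"` (the default) applies the Ward
#' criterion to the distances themselves; `"ward.D"` is the historical R
#' dialect that applies the update to unsquared distances — both are
#' exposed because published analyses of this era used either. Receptors
#' with identical profiles merge at height 0.
#'
#' @param mat Profile matrix from [build_profile_matrix()] (>= 2 rows).
#' @param method `"ward.D2"` or `"ward.D"`.
#' @return A `cargo_dendrogram` object wrapping the `hclust` tree
#'   (elements `hclust`, `dist`, `method`).
#' @export
ward_cluster <- function(mat, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  if (is.null(dim(mat)) || nrow(mat) < 2L) {
    stop_silactp("need at least 2 profile rows to cluster",
                 "silactp_usage_error")
  }
  d <- dist(mat, method = "euclidean")
  hc <- hclust(d, method = method)
  structure(list(hclust = hc, dist = d, method = method),
            class = "cargo_dendrogram")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from the merge heights (each branch spans the
#' height difference between a node and its parent), so the tree
#' round-trips through any standard Newick parser with the same topology.
#'
#' @param dend A `cargo_dendrogram` from [ward_cluster()].
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(dend, path = NULL) {
  phy <- ape::as.phylo(dend$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Sibling pairs in a dendrogram
#'
#' Receptor pairs that merge directly with each other (both children of a
#' merge node are leaves) — e.g. receptor paralogs whose cargo cohorts
#' largely coincide.
#'
#' @param dend A `cargo_dendrogram`.
#' @return A tibble: `receptor_a`, `receptor_b`, `height`.
#' @export
sibling_pairs <- function(dend) {
  hc <- dend$hclust
  leaf_pairs <- which(hc$merge[, 1] < 0 & hc$merge[, 2] < 0)
  purrr::map_dfr(leaf_pairs, function(i) {
    ab <- sort(hc$labels[-hc$merge[i, ]])
    tibble(receptor_a = ab[1], receptor_b = ab[2], height = hc$height[i])
  })
}
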