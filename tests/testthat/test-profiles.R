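test_that("sharing statistics match hand counts", {
  ss <- sharing_summary(list(R1 = c("A", "B", "C"), R2 = c("B", "C", "D")))
  expect_equal(ss$pairwise["R1", "R2"], 2L)
  expect_equal(ss$pairwise["R1", "R1"], 3L)
  expect_equal(unname(ss$unique_counts), c(1L, 1L))
  expect_equal(ss$total_cargoes, 4L)
  expect_equal(ss$mean_pairwise, 2)

  same <- sharing_summary(list(R1 = c("A", "B"), R2 = c("A", "B")))
  expect_equal(same$pairwise["R1", "R2"], 2L)
  expect_equal(sum(same$unique_counts), 0L)

  expect_error(sharing_summary(list(R1 = "A")), class = "silactp_usage_error")
  expect_error(sharing_summary(setNames(list("A", "B"), c("R", "R"))),
               class = "silactp_usage_error")
})

test_that("sharing summary equals a brute-force set-algebra oracle on synthetic truth", {
  design <- tibble::tibble(receptor_a = c("Trn-1", "Imp-7"),
                           receptor_b = c("Trn-2", "Imp-8"),
                           fraction = c(0.6, 0.4))
  sim <- generate_silac_data(simulation_config(
    n_proteins = 600, sharing_design = design, seed = 9))
  sets <- split(sim$truth$cargo$accession, sim$truth$cargo$receptor)
  sets <- sets[unique(sim$truth$cargo$receptor)]
  ss <- sharing_summary(sets)

  recs <- names(sets)
  for (a in recs) for (b in recs) {
    expect_equal(ss$pairwise[a, b], length(intersect(sets[[a]], sets[[b]])))
  }
  all_acc <- unlist(sets)
  for (a in recs) {
    others <- unlist(sets[setdiff(recs, a)])
    expect_equal(unname(ss$unique_counts[a]),
                 length(setdiff(sets[[a]], others)))
    # unique + shared-with-at-least-one-other = set size
    expect_equal(unname(ss$unique_counts[a]) +
                   length(intersect(sets[[a]], others)),
                 length(sets[[a]]))
  }
  expect_equal(ss$total_cargoes, length(unique(all_acc)))
  expect_equal(ss$mean_pairwise,
               mean(utils::combn(recs, 2, function(p) {
                 length(intersect(sets[[p[1]]], sets[[p[2]]]))
               })))
  # designed pair shares more than undesigned pairs on average
  expect_gt(ss$pairwise["Trn-1", "Trn-2"], ss$mean_pairwise)
})

test_that("profile matrices are deterministic binary receptor-by-universe tables", {
  mat <- build_profile_matrix(list(R1 = c("C", "A"), R2 = c("A", "B")))
  expect_equal(dim(mat), c(2L, 3L))
  expect_equal(colnames(mat), c("A", "B", "C"))
  expect_equal(unname(colSums(mat)), c(2, 1, 1))
  expect_equal(rownames(mat), c("R1", "R2"))
  expect_true(all(mat %in% 0:1))
  expect_true(all(rowSums(mat) >= 1) && all(colSums(mat) >= 1))

  disjoint <- build_profile_matrix(list(R1 = c("A", "B"), R2 = c("C")))
  expect_true(all(colSums(disjoint) == 1))
})

test_that("identical profiles merge first at height zero", {
  mat <- build_profile_matrix(list(R1 = c("A", "B"), R2 = c("A", "B"),
                                   R3 = c("C", "D", "E")))
  dend <- ward_cluster(mat)
  sibs <- sibling_pairs(dend)
  expect_true(any(sibs$receptor_a == "R1" & sibs$receptor_b == "R2"))
  expect_equal(min(dend$hclust$height), 0)
  expect_error(ward_cluster(mat[1, , drop = FALSE]),
               class = "silactp_usage_error")
})

test_that("planted 90% profile overlap is recovered as a sibling pair", {
  design <- tibble::tibble(receptor_a = "Trn-1", receptor_b = "Trn-2",
                           fraction = 0.9)
  sim <- generate_silac_data(simulation_config(
    n_proteins = 500,
    receptors = c("Trn-1", "Trn-2", "Imp-4", "Imp-5", "Imp-9"),
    sharing_design = design, seed = 41))
  sets <- split(sim$truth$cargo$accession, sim$truth$cargo$receptor)
  mat <- build_profile_matrix(sets)
  for (method in c("ward.D2", "ward.D")) {
    sibs <- sibling_pairs(ward_cluster(mat, method))
    expect_true(any(sibs$receptor_a == "Trn-1" & sibs$receptor_b == "Trn-2"),
                info = method)
  }
})

test_that("clustering distances match brute-force Euclidean computation", {
  set.seed(8)
  mat <- matrix(rbinom(7 * 30, 1, 0.3), nrow = 7,
                dimnames = list(paste0("R", 1:7), NULL))
  dend <- ward_cluster(mat)
  d <- as.matrix(dend$dist)
  for (i in 1:7) for (j in 1:7) {
    expect_equal(d[i, j], sqrt(sum((mat[i, ] - mat[j, ])^2)))
  }
  # merge heights are non-decreasing (ward.D2 on Euclidean distances)
  expect_true(all(diff(dend$hclust$height) >= -1e-12))
})

test_that("clustering is invariant to cargo-universe column order", {
  set.seed(12)
  mat <- matrix(rbinom(5 * 40, 1, 0.25), nrow = 5,
                dimnames = list(paste0("R", 1:5), paste0("C", 1:40)))
  d1 <- ward_cluster(mat)
  d2 <- ward_cluster(mat[, sample(ncol(mat))])
  expect_equal(d1$hclust$merge, d2$hclust$merge)
  expect_equal(d1$hclust$height, d2$hclust$height)
})

test_that("Newick export round-trips through a standard parser", {
  two <- ward_cluster(build_profile_matrix(list(A = c("X", "Y"),
                                                B = c("X", "Z"))))
  txt <- to_newick(two)
  expect_match(txt, "^\\(.*A.*B.*\\);$|^\\(.*B.*A.*\\);$")

  set.seed(3)
  mat <- matrix(rbinom(6 * 25, 1, 0.4), nrow = 6,
                dimnames = list(paste0("R", 1:6), NULL))
  dend <- ward_cluster(mat)
  path <- tempfile(fileext = ".nwk")
  to_newick(dend, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, paste0("R", 1:6))
  ref <- ape::as.phylo(dend$hclust)
  expect_true(ape::all.equal.phylo(phy, ref, use.edge.length = FALSE))

  # in a 3-leaf tree the sibling pair is the closest pair
  m3 <- mat[1:3, ]
  d3 <- ward_cluster(m3)
  sib <- sibling_pairs(d3)
  dm <- as.matrix(d3$dist)
  pairs <- utils::combn(rownames(m3), 2)
  dvals <- apply(pairs, 2, function(p) dm[p[1], p[2]])
  closest <- sort(pairs[, which.min(dvals)])
  expect_equal(c(sib$receptor_a, sib$receptor_b), closest)
})

test_that("dendrogram tidiers expose merges and summary", {
  mat <- build_profile_matrix(list(R1 = c("A", "B"), R2 = c("A", "B"),
                                   R3 = "C", R4 = "D"))
  dend <- ward_cluster(mat)
  td <- tidy(dend)
  expect_equal(nrow(td), 3L)
  expect_equal(td$n_members[3], 4L)
  gl <- glance(dend)
  expect_equal(gl$n_leaves, 4L)
  expect_equal(gl$method, "ward.D2")
})
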