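test_that("candidate selection follows the keyword/GO rules", {
  ann <- data.frame(
    locus_id = paste0("g", 1:6),
    defline = c("triacylglycerol lipase",
                "beta-galactosidase",
                "Beta-Hydrolase fold protein",
                "hypothetical protein",
                "hypothetical protein",
                "hypothetical protein"),
    go_ids = c(".", ".", ".",
               "GO:0016298",
               "GO:0016787",                 # hydrolase activity alone: no
               "GO:0016787;GO:0016042"),     # both terms: yes
    domain_id = ".", truncation = ".", has_start_codon = TRUE,
    localization = "O", stringsAsFactors = FALSE
  )
  expect_setequal(select_candidates(ann), c("g1", "g3", "g4", "g6"))
})

test_that("profile clustering joins identical profiles first", {
  profiles <- rbind(a = rep(0, 11), b = rep(0, 11), far = rep(10, 11))
  cl <- hcluster_profiles(profiles)
  expect_equal(cl$tree$height[1], 0)
  first <- rownames(profiles)[-cl$tree$merge[1, ]]
  expect_setequal(first, c("a", "b"))
})

test_that("complete linkage: cophenetic distances dominate pairwise distances", {
  set.seed(9)
  profiles <- matrix(rnorm(8 * 11), 8, 11,
                     dimnames = list(paste0("g", 1:8), NULL))
  cl <- hcluster_profiles(profiles)
  coph <- as.matrix(stats::cophenetic(cl$tree))
  d <- as.matrix(cl$distances)
  expect_true(all(coph >= d - 1e-12))
  # merge heights are monotone non-decreasing
  expect_true(all(diff(cl$tree$height) >= -1e-12))

  # row permutation: identical tree up to leaf relabelling
  perm <- sample(8)
  coph2 <- as.matrix(stats::cophenetic(hcluster_profiles(profiles[perm, ])$tree))
  expect_equal(coph2[rownames(coph), colnames(coph)], coph)

  # translating every profile by the same vector preserves the tree
  shift <- matrix(rnorm(11), 8, 11, byrow = TRUE)
  coph3 <- as.matrix(stats::cophenetic(hcluster_profiles(profiles + shift)$tree))
  expect_equal(coph3, coph)
})

test_that("NA cells are imputed as zero by default, pairwise on request", {
  profiles <- rbind(a = c(NA, rep(1, 10)), b = rep(1, 11), c = rep(-5, 11))
  cl <- hcluster_profiles(profiles, na_policy = "zero")
  d <- as.matrix(cl$distances)
  expect_equal(d["a", "b"], 1)  # the NA cell contributes |0 - 1|
  clp <- hcluster_profiles(profiles, na_policy = "pairwise")
  expect_equal(as.matrix(clp$distances)["a", "b"], 0)
})

test_that("average silhouette matches the brute-force oracle", {
  # two tight, well-separated duplicate-point clusters -> 1
  pts <- rbind(matrix(0, 3, 2), matrix(10, 3, 2))
  d <- dist(pts)
  expect_equal(average_silhouette(rep(1:2, each = 3), d), 1.0)

  # all points identical: 0 by the 0/0 -> 0 convention
  same <- matrix(1, 6, 2)
  expect_equal(average_silhouette(rep(1:2, each = 3), dist(same)), 0)

  # random 2-D points, k = 3: equals the O(n^2) oracle
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(30 * 2), 30, 2)
    d <- dist(x)
    assign3 <- cutree(hclust(d, "complete"), k = 3)
    expect_equal(average_silhouette(assign3, d), silhouette_oracle(assign3, d),
                 tolerance = 1e-12)
    # and against the reference implementation in the cluster package
    expect_equal(average_silhouette(assign3, d),
                 mean(cluster::silhouette(assign3, d)[, "sil_width"]),
                 tolerance = 1e-12)
    expect_gte(average_silhouette(assign3, d), -1)
    expect_lte(average_silhouette(assign3, d), 1)
  }

  expect_error(average_silhouette(rep(1, 6), dist(same)), "two clusters")
})

test_that("silhouette-guided cut recovers planted clusters", {
  ds <- generate_dataset(small_config(noise_sd = 0))
  fc <- fold_change(ds$matrix)
  res <- cluster_gene_family(fc, ds$annotations)
  expect_equal(res$chosen_k, 4)
  truth <- ds$truth$cluster_id[names(res$assignment)]
  expect_equal(adjusted_rand_index(res$assignment, truth), 1)

  # the paper-style explicit cut overrides selection but reports silhouettes
  res4 <- cluster_gene_family(fc, ds$annotations, k = 5)
  expect_equal(res4$chosen_k, 5)
  expect_equal(res4$silhouettes, res$silhouettes)

  # k_range collapsed to a single value
  res3 <- cluster_gene_family(fc, ds$annotations, k_range = 3)
  expect_equal(res3$chosen_k, 3)
})

test_that("adjusted Rand index agrees with the mclust reference", {
  set.seed(13)
  for (rep in 1:10) {
    a <- sample(1:4, 40, replace = TRUE)
    b <- sample(1:3, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})
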