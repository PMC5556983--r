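test_that("stage response computes A_stage, log2R and classes", {
  m <- mk_matrix(
    up_lN = c(1, 1, 1, 1, 4, 4, 4, 4, 1, 1, 1, 1),
    sub   = c(2, 1, 2, 4, 2, 2, 2, 2, 2, 2, 2, 2),
    lowref = c(0.5, rep(10, 11))
  )
  resp <- stage_response(m)
  expect_equal(resp["up_lN", "A_lN"], 4)
  expect_equal(resp["up_lN", "log2R_lN"], 2)
  expect_equal(resp["up_lN", "class_lN"], "up")
  expect_equal(resp["up_lN", "class_eN"], "none")

  # hand arithmetic: e-N FPKMs (1,2,4) vs N_0 = 2 -> A = 7/3, log2(7/6)
  expect_equal(resp["sub", "A_eN"], 7 / 3)
  expect_equal(resp["sub", "log2R_eN"], log2(7 / 6))
  expect_equal(resp["sub", "class_eN"], "none")

  # reference below the floor: NA class in every stage
  expect_true(all(is.na(resp["lowref", c("class_eN", "class_lN", "class_rN")])))

  # floor can be disabled
  resp2 <- stage_response(m, apply_floor = FALSE)
  expect_false(anyNA(resp2["lowref", c("class_eN", "class_lN", "class_rN")]))
})

test_that("stage gene sets split by direction and exclude NA loci", {
  m <- mk_matrix(
    up_eN = c(2, 8, 8, 8, 2, 2, 2, 2, 2, 2, 2, 2),
    down_rN = c(8, 8, 8, 8, 8, 8, 8, 8, 2, 2, 2, 2),
    lowref = c(0.5, rep(10, 11))
  )
  sets <- stage_gene_sets(stage_response(m))
  expect_equal(sets$up_eN, "up_eN")
  expect_equal(sets$down_rN, "down_rN")
  expect_equal(attr(sets, "na_loci"), "lowref")
  expect_false("lowref" %in% unlist(sets))
})

test_that("venn partition covers the seven regions disjointly", {
  v <- venn_partition(c("a", "b"), c("b", "c"), "c",
                      names = c("E", "L", "R"))
  expect_equal(v$E, "a")
  expect_equal(v[["E&L"]], "b")
  expect_equal(v[["L&R"]], "c")
  expect_equal(lengths(v)[c("L", "R", "E&R", "E&L&R")],
               c(L = 0L, R = 0L, `E&R` = 0L, `E&L&R` = 0L))

  # identical sets populate only the triple region
  v2 <- venn_partition(letters[1:3], letters[1:3], letters[1:3])
  expect_equal(sort(v2[[7]]), letters[1:3])
  expect_equal(sum(lengths(v2[1:6])), 0)
})

test_that("venn regions satisfy inclusion-exclusion on random systems", {
  set.seed(11)
  for (rep in 1:20) {
    pool <- paste0("g", 1:30)
    a <- sample(pool, sample(0:30, 1))
    b <- sample(pool, sample(0:30, 1))
    c <- sample(pool, sample(0:30, 1))
    v <- venn_partition(a, b, c)
    u <- union(union(a, b), c)
    # regions partition the union
    expect_equal(sort(unlist(v, use.names = FALSE)), sort(u))
    expect_equal(sum(lengths(v)), length(u))
    # brute-force membership for every element
    for (g in u) {
      region <- names(v)[vapply(v, function(r) g %in% r, logical(1))]
      expect_length(region, 1)
      want <- paste(c("e-N", "l-N", "r+N")[c(g %in% a, g %in% b, g %in% c)],
                    collapse = "&")
      expect_equal(region, want)
    }
  }
})

test_that("Jensen-Shannon distance is the base-2 JSD square root", {
  m <- mk_matrix(g1 = rep(1, 12), g2 = 1:12, g3 = c(6:1, 1:6))
  d <- js_sample_distance(m)
  expect_equal(unname(diag(d)), rep(0, 12))
  expect_equal(d, t(d))

  # identical columns -> 0
  m2 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(9, 0, 1))
  d2 <- js_sample_distance(m2)
  expect_equal(d2["a", "b"], 0)

  # disjoint support -> 1 (the base-2 maximum)
  m3 <- cbind(a = c(1, 0), b = c(0, 5))
  expect_equal(js_sample_distance(m3)["a", "b"], 1)

  expect_error(js_sample_distance(cbind(a = c(0, 0), b = c(1, 1))),
               "all-zero")
})

test_that("JS distance matches the direct oracle and is a metric", {
  set.seed(5)
  m <- matrix(rexp(20 * 4), 20, 4, dimnames = list(NULL, paste0("s", 1:4)))
  d <- js_sample_distance(m)
  p <- sweep(m, 2, colSums(m), "/")
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], jsd_oracle(p[, i], p[, j]), tolerance = 1e-12)
  # triangle inequality over all triples
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("sample clustering returns a complete-linkage dendrogram", {
  ds <- generate_dataset(small_config(noise_sd = 0.1))
  d <- js_sample_distance(ds$matrix)
  dend <- cluster_samples(d)
  expect_s3_class(dend, "hclust")
  expect_equal(dend$method, "complete")
  expect_setequal(dend$labels, time_points())
})

test_that("phenotype formulas: cell weight and relative productivity", {
  expect_equal(cell_weight(1.0, 1e7), 100)   # pg per cell
  expect_equal(cell_weight(0.5, 1e7), 50)
  expect_error(cell_weight(1, 0), "positive")

  expect_equal(relative_volumetric_productivity(c(50, 150, 250), c(0, 1, 2)),
               c(day1 = 1.0, day2 = 1.0))
  expect_equal(relative_volumetric_productivity(c(50, 150, 350), c(0, 1, 2)),
               c(day1 = 1.0, day2 = 1.5))
  expect_error(relative_volumetric_productivity(c(50, 50, 100), c(0, 1, 2)),
               "day 1 is zero")
  expect_error(relative_volumetric_productivity(c(50, 100), c(1, 2)),
               "day 0 and day 1")
})
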