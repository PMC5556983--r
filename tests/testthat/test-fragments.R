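test_that("profile correlation works on log2(FPKM + 1) profiles", {
  x <- c(1, 5, 20, 100, 400, 80, 10, 3, 2, 1, 6, 9)
  expect_equal(profile_correlation(x, x), 1.0)

  ramp <- 1:12
  expect_lt(profile_correlation(ramp, rev(ramp)), 0)

  # direct-summation covariance oracle on the transformed profiles
  y <- 2 * (1:12)
  lx <- log2(ramp + 1); ly <- log2(y + 1)
  n <- 12
  cov_xy <- sum((lx - mean(lx)) * (ly - mean(ly))) / (n - 1)
  r_oracle <- cov_xy / sqrt(sum((lx - mean(lx))^2) / (n - 1) *
                              sum((ly - mean(ly))^2) / (n - 1))
  expect_equal(profile_correlation(ramp, y), r_oracle, tolerance = 1e-12)

  expect_error(profile_correlation(rep(3, 12), ramp), "constant profile")
})

test_that("scaffold-margin rule is boundary-inclusive at 500 nt", {
  rec <- function(s, e, len) data.frame(start = s, end = e, scaffold_length = len)
  expect_true(is_margin_gene(rec(1, 300, 1e6)))          # distance 0
  expect_true(is_margin_gene(rec(9000, 1e6 - 500, 1e6))) # exactly 500
  expect_false(is_margin_gene(rec(502, 1e6 - 501, 1e6))) # 501 on both sides
  expect_true(is_margin_gene(rec(501, 2000, 1e6)))       # start - 1 = 500
})

test_that("domain compatibility requires a shared, complementarily truncated domain", {
  hit <- function(dom, tr) data.frame(domain_id = dom, truncation = tr,
                                      stringsAsFactors = FALSE)
  expect_true(domains_compatible(hit("D1", "C"), hit("D1", "N")))
  expect_true(domains_compatible(hit("D1", "N"), hit("D1", "C")))
  expect_false(domains_compatible(hit("D1", "C"), hit("D1", "C")))
  expect_false(domains_compatible(hit("D1", "C"), hit("D2", "N")))
  expect_false(domains_compatible(hit("D1", "none"), hit("D1", "N")))
  expect_false(domains_compatible(NULL, hit("D1", "N")))
})

test_that("fragment pairs below the correlation threshold are not paired", {
  # two margin loci with compatible domains but r ~ 0.85 on transformed scale
  set.seed(3)
  x <- 2^c(3, 3, 3, 3, 5, 5, 5, 5, 3, 3, 3, 3)
  y <- 2^(log2(x) * 0.4 + rnorm(12, 0, 0.8) + 3)
  r <- profile_correlation(x, y)
  expect_lt(r, 0.9)  # fixture sits below the pairing threshold
  m <- mk_matrix(gA = x, gB = y)
  models <- data.frame(locus_id = c("gA", "gB"), scaffold_id = c("s1", "s2"),
                       start = c(101, 999001), end = c(1000, 999900),
                       strand = "+", scaffold_length = 1e6)
  ann <- data.frame(locus_id = c("gA", "gB"), defline = "x", go_ids = ".",
                    domain_id = "D1", truncation = c("C", "N"),
                    has_start_codon = c(TRUE, FALSE), localization = "O",
                    stringsAsFactors = FALSE)
  mm <- detect_fragment_pairs(m, models, ann)
  expect_equal(nrow(mm), 0)

  # identical profiles (r = 1) are paired, retaining the start-codon member
  m2 <- mk_matrix(gA = x, gB = x)
  mm2 <- detect_fragment_pairs(m2, models, ann)
  expect_equal(nrow(mm2), 1)
  expect_equal(mm2$retained, "gA")
  expect_equal(mm2$dropped, "gB")
})

test_that("planted pairs are recovered exactly at zero noise", {
  ds <- generate_dataset(small_config(noise_sd = 0))
  mm <- detect_fragment_pairs(ds$matrix, ds$models, ds$annotations)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(mm$locus_a, mm$locus_b),
                  key(ds$truth$pairs$locus_a, ds$truth$pairs$locus_b))
  expect_setequal(mm$retained, ds$truth$pairs$retained)

  # greedy matching is injective: no locus in two pairs
  ids <- c(mm$locus_a, mm$locus_b)
  expect_equal(anyDuplicated(ids), 0)

  # detection is invariant to input row order
  perm <- sample(nrow(ds$matrix))
  mm_perm <- detect_fragment_pairs(ds$matrix[perm, ], ds$models, ds$annotations)
  expect_equal(as.data.frame(mm_perm), as.data.frame(mm))
})

test_that("collapse drops exactly the 3' members and keeps rows intact", {
  ds <- generate_dataset(small_config(noise_sd = 0))
  mm <- detect_fragment_pairs(ds$matrix, ds$models, ds$annotations)
  collapsed <- collapse_fragments(ds$matrix, mm)
  expect_equal(nrow(collapsed), nrow(ds$matrix) - nrow(mm))
  expect_false(any(mm$dropped %in% rownames(collapsed)))
  expect_identical(collapsed[mm$retained, ], ds$matrix[mm$retained, ])

  # empty map is the identity
  empty <- mm[0, ]
  expect_identical(collapse_fragments(ds$matrix, empty), ds$matrix)

  # map referencing absent loci is a consistency error
  bad <- mm
  bad$locus_a[1] <- "XLOC_MISSING"
  expect_error(collapse_fragments(ds$matrix, bad), "absent from the matrix")
})
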