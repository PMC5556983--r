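test_that("expression TSV round-trips and normalizes column order", {
  m <- mk_matrix(g1 = 1:12, g2 = seq(2, 24, by = 2), g3 = rep(5, 12))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(m, f)
  expect_identical(read_expression(f), m)

  # permute columns on disk: same matrix after canonical reordering
  df <- read.delim(f, check.names = FALSE)
  df2 <- df[, c(1, sample(2:13))]
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(read_expression(f2), m)
})

test_that("expression reader rejects malformed input, naming the offence", {
  m <- mk_matrix(g1 = 1:12, g2 = 13:24)
  f <- withr::local_tempfile(fileext = ".tsv")

  bad <- m; bad["g2", "N_4"] <- -1
  write.table(data.frame(locus_id = rownames(bad), bad, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f), "negative FPKM.*g2.*N_4")

  dup <- rbind(m, m[1, , drop = FALSE])
  write.table(data.frame(locus_id = rownames(dup), dup, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f), "unique locus ids")

  short <- m[, -3]
  write.table(data.frame(locus_id = rownames(short), short, check.names = FALSE),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(f), "lacks canonical time point.*N_4")
})

test_that("gene models round-trip through GFF3 with scaffold lengths", {
  models <- data.frame(
    locus_id = c("gA", "gB", "gC"),
    scaffold_id = c("s1", "s1", "s2"),
    start = c(1L, 9600L, 50000L),
    end = c(300L, 9900L, 50900L),
    strand = c("+", "-", "+"),
    scaffold_length = c(10000L, 10000L, 1000000L),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(models, f)
  back <- read_gene_models(f)
  back <- back[match(models$locus_id, back$locus_id), ]
  rownames(back) <- NULL
  expect_equal(back, models)

  # margin distances per the scaffold-margin rule
  expect_equal(pmin(back$start - 1, back$scaffold_length - back$end),
               c(0, 100, 49999))

  # coordinates beyond the declared scaffold bounds are rejected
  lines <- readLines(f)
  lines <- sub("\t9900\t", "\t10500\t", lines, fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_gene_models(f), "exceeds its scaffold bounds")
})

test_that("annotation TSV round-trips and rejects invalid categories", {
  ann <- data.frame(
    locus_id = c("gA", "gB"),
    defline = c("putative lipase", "hypothetical protein"),
    go_ids = c("GO:0000004;GO:0000005", "."),
    domain_id = c("DOM1", "."),
    truncation = c("C", "."),
    has_start_codon = c(TRUE, FALSE),
    localization = c("C", "NA"),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(ann, f)
  expect_equal(read_annotations(f), ann)

  bad <- ann; bad$truncation[1] <- "X"
  write_annotations(bad, f)
  expect_error(read_annotations(f), "invalid truncation 'X'")

  bad <- ann; bad$localization[2] <- "Z"
  write_annotations(bad, f)
  expect_error(read_annotations(f), "invalid localization 'Z'")
})

test_that("OBO reader builds the is_a DAG and rejects defects", {
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid", "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf", "namespace: biological_process",
    "is_a: GO:0000002"
  ), f)
  dag <- read_obo(f)
  expect_equal(nrow(dag$terms), 3)
  expect_equal(sum(lengths(dag$parents)), 2)
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")

  # round trip through the writer
  f2 <- withr::local_tempfile(fileext = ".obo")
  write_obo(dag, f2)
  dag2 <- read_obo(f2)
  expect_equal(dag2$terms, dag$terms)
  expect_equal(dag2$parents, dag$parents)

  # undefined parent
  writeLines(c("[Term]", "id: GO:0000001", "name: a",
               "is_a: GO:9999999"), f)
  expect_error(read_obo(f), "undefined term")

  # cycle
  writeLines(c("[Term]", "id: GO:0000001", "name: a", "is_a: GO:0000002", "",
               "[Term]", "id: GO:0000002", "name: b", "is_a: GO:0000001"), f)
  expect_error(read_obo(f), "cycle")
})

test_that("hit tables round-trip and rank best hits per query", {
  hits <- data.frame(
    qseqid = c("q1", "q1", "q2", "q1"),
    sseqid = c("s1", "s2", "s3", "s4"),
    evalue = c(1e-10, 1e-30, 1e-5, 1e-30),
    bitscore = c(50, 200, 40, 100),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hit_table(hits, f)
  back <- read_hit_table(f)
  # best hit for q1: lowest e-value, tie broken by bit score
  expect_equal(back$sseqid[back$qseqid == "q1" & back$rank == 1], "s2")
  expect_equal(back$sseqid[back$qseqid == "q2" & back$rank == 1], "s3")
  # round trip preserves the rows
  expect_equal(nrow(back), nrow(hits))
  expect_setequal(back$sseqid, hits$sseqid)

  hits$evalue[1] <- -1
  write_hit_table(hits, f)
  expect_error(read_hit_table(f), "negative e-value")
})
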