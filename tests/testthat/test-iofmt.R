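test_that("expression matrix TSV round-trips and validates", {
  x <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(x, path)
  gm <- setNames(as.character(group_labels(x)), sample_ids(x))
  y <- read_expression_matrix(path, gm)
  expect_identical(dim(y), c(4L, 5L))
  expect_identical(probe_ids(y), probe_ids(x))
  expect_identical(sample_ids(y), sample_ids(x))
  expect_equal(y$values, x$values)

  # duplicate probe row names the probe
  writeLines(c("probe\ts1\ts2\ts3\ts4", "p1\t1\t2\t3\t4", "p1\t1\t2\t3\t4"),
             path)
  expect_error(read_expression_matrix(path, gm[1:4]), "p1")

  # non-numeric and nonpositive intensities rejected
  writeLines(c("probe\ts1\ts2\ts3\ts4", "p1\t1\tx\t3\t4"), path)
  expect_error(read_expression_matrix(path, gm[1:4]), "non-numeric")
  writeLines(c("probe\ts1\ts2\ts3\ts4", "p1\t1\t-2\t3\t4"), path)
  expect_error(read_expression_matrix(path, gm[1:4]), "finite and > 0")

  # sample missing from the group map
  writeLines(c("probe\ts1\ts9\ts3\ts4", "p1\t1\t2\t3\t4"), path)
  expect_error(read_expression_matrix(path, gm), "s9")
})

test_that("ExpressionMatrix invariants are enforced", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(v, c(s1 = "case", s2 = "case")),
               "both groups")
  expect_error(expression_matrix(v, c(s1 = "case", s2 = "weird")),
               "case.*control|control")
  v2 <- v; v2[1, 1] <- 0
  expect_error(expression_matrix(v2, c(s1 = "case", s2 = "control")),
               "> 0")
})

test_that("GMT parsing, categories and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:X\tdesc\tA\tB", "GO:Y\tBP|cell thing\tC\tD\tE"), path)
  gs <- read_gmt(path)
  expect_equal(length(gs), 2L)
  expect_setequal(gs$sets[["GO:X"]], c("A", "B"))
  expect_identical(gs$info$category, c("pathway", "BP"))
  expect_identical(gs$info$description[2], "cell thing")

  writeLines(c("GO:X\tdesc\tA", "GO:Y\tdesc"), path)
  expect_error(read_gmt(path), "line 2")

  gs2 <- gene_set_collection(c("S1", "S2"), c("MF", "pathway"),
                             c("d1", "d2"), list("A", c("B", "C")))
  write_gmt(gs2, path)
  back <- read_gmt(path)
  expect_identical(back$info, gs2$info)
  expect_identical(back$sets, gs2$sets)

  expect_error(gene_set_collection("S", "BP", "d", list(character(0))),
               "empty member")
  expect_error(gene_set_collection(c("S", "S"), c("BP", "BP"), c("a", "b"),
                                   list("A", "B")), "duplicate")
})

test_that("BED12 loci validate, round-trip, and match rtracklayer", {
  gr <- loci(c("L1", "L2"), "chr1", c(100L, 500L), c(200L, 900L),
             c("+", "-"),
             block_starts = list(0L, c(0L, 300L)),
             block_sizes = list(100L, c(100L, 100L)))
  expect_equal(GenomicRanges::start(gr), c(101L, 501L))  # 1-based internal
  expect_equal(tss(gr), c(101L, 900L))

  path <- withr::local_tempfile(fileext = ".bed")
  write_loci(gr, path)
  back <- read_loci(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_identical(S4Vectors::mcols(back)$name, S4Vectors::mcols(gr)$name)
  expect_identical(lapply(S4Vectors::mcols(back)$blocks, IRanges::start),
                   lapply(S4Vectors::mcols(gr)$blocks, IRanges::start))
  expect_identical(lapply(S4Vectors::mcols(back)$blocks, IRanges::width),
                   lapply(S4Vectors::mcols(gr)$blocks, IRanges::width))

  # independent reader agrees on the coordinate conversion
  rt <- rtracklayer::import(path, format = "bed")
  expect_equal(GenomicRanges::start(rt), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(rt), GenomicRanges::end(gr))

  expect_error(loci("L", "chr1", 100L, 100L, "+"), "end <= start")
  expect_error(loci("L", "chr1", 100L, 300L, "+",
                    block_starts = list(c(0L, 50L)),
                    block_sizes = list(c(100L, 100L))), "overlapping blocks")
  expect_error(loci("L", "chr1", 100L, 150L, "+",
                    block_starts = list(0L), block_sizes = list(100L)),
               "outside span")
})

test_that("network tables export SIF and enforce referential integrity", {
  nodes <- data.frame(id = c("A", "B"), biotype = c("lncRNA", "mRNA"))
  edges <- data.frame(source = "A", target = "B", weight = 0.99,
                      sign = "positive")
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- write_network_tables(nodes, edges, prefix)
  expect_identical(readLines(paste0(prefix, ".sif")), "A pp B")
  expect_true(all(file.exists(paste0(prefix,
                                     c("_nodes.tsv", "_edges.tsv", ".sif")))))

  edges$sign <- "negative"
  write_network_tables(nodes, edges, prefix)
  expect_identical(readLines(paste0(prefix, ".sif")), "A nn B")

  bad <- data.frame(source = "A", target = "Z", weight = 1, sign = "positive")
  expect_error(write_network_tables(nodes, bad, prefix), "Z")

  write_network_tables(nodes, edges[0, ], prefix)
  expect_identical(readLines(paste0(prefix, ".sif")), character(0))
})

test_that("miRNA target tables validate and round-trip", {
  df <- data.frame(mirna_id = c("m1", "m2"), target_id = c("g1", "g1"),
                   mre_count = c(1L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mirna_targets(mirna_target_table(df), path)
  expect_identical(read_mirna_targets(path), df)
  expect_error(mirna_target_table(rbind(df, df[1, ])), "duplicate")
  df$mre_count[1] <- 0L
  expect_error(mirna_target_table(df), "positive integer")
})
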