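test_that("count tables parse, validate and round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tsA\tsB", "OTU1\t3\t0", "OTU2\t1\t4"), tsv)
  writeLines(c("sample_id\tstation\tlibrary", "sA\tA\tDNA", "sB\tB\tDNA"),
             meta)
  tab <- read_count_table(tsv, meta)
  expect_equal(unname(colSums(tab$counts)), c(4, 4))
  expect_equal(rownames(tab$counts), c("OTU1", "OTU2"))
  expect_equal(tab$sample_meta$station, c("A", "B"))

  out <- tempfile(fileext = ".tsv"); outm <- tempfile(fileext = ".tsv")
  write_count_table(tab, out, outm)
  back <- read_count_table(out, outm)
  expect_identical(back$counts, tab$counts)
  expect_identical(back$sample_meta, tab$sample_meta)
})

test_that("malformed count tables are rejected with located messages", {
  meta <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstation\tlibrary", "sA\tA\tDNA", "sB\tB\tDNA"),
             meta)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tsA\tsB", "OTU1\t3\t-1", "OTU2\t1\t4"), bad)
  expect_error(read_count_table(bad, meta), "OTU1.*sB")
  writeLines(c("otu_id\tsA\tsB", "OTU1\t3\t2.5", "OTU2\t1\t4"), bad)
  expect_error(read_count_table(bad, meta), "2\\.5")
  writeLines(c("otu_id\tsA\tsB", "OTU1\t3\t1", "OTU1\t1\t4"), bad)
  expect_error(read_count_table(bad, meta), "duplicate otu_id")
  writeLines(c("otu_id\tsA\tsC", "OTU1\t3\t1", "OTU2\t1\t4"), bad)
  expect_error(read_count_table(bad, meta), "missing from metadata.*sC")

  m <- matrix(c(1, 2, 3, 4), 2, dimnames = list(c("a", "b"), c("x", "x")))
  expect_error(count_table(m, data.frame(sample_id = "x", station = "A",
                                         library = "DNA")),
               "duplicate sample_id")
  expect_error(make_table(matrix(c(1, 0, 2, 0), 2), library = "XNA"),
               "library")
})

test_that("taxonomy maps are total with explicit 'other' fill", {
  tab <- make_table(matrix(c(3, 1, 0, 4), 2))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("otu_id\tgroup", "OTU1\tTrichodesmium"), f)
  expect_warning(tax <- read_taxonomy(f, tab), "1 OTU")
  expect_equal(unname(tax[c("OTU1", "OTU2")]),
               c("Trichodesmium", "other"))

  writeLines(c("otu_id\tgroup", "OTU1\tTrichodesmium", "OTU2\tcluster III"),
             f)
  expect_no_warning(tax <- read_taxonomy(f, tab))
  expect_equal(sum(tax == "other"), 0)

  writeLines(c("otu_id\tgroup", "OTU1\tTrichodesmium", "OTU1\tcluster III"),
             f)
  expect_error(read_taxonomy(f, tab), "conflicting")
  writeLines("otu_id\tgroup", f)
  expect_error(read_taxonomy(f, tab), "empty")
})

test_that("qPCR records keep raw replicates and defer pairing checks", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,station,template,ct1,ct2,ct3",
               "stA,A,DNA,21.1,21.3,21.2",
               "stA,A,cDNA,24.0,24.1,23.9",
               "stB,B,DNA,20.5,20.6,20.4"), f)
  q <- read_qpcr(f)
  expect_s3_class(q, "qpcr_table")
  expect_equal(q$ct[[1]], c(21.1, 21.3, 21.2))
  ## stB misses cDNA: accepted at read time, flagged when ratio requested
  expect_warning(r <- bulk_expression_ratio(q, efficiency = 2),
                 "stB.*missing template cDNA")
  expect_equal(r$sample_id, "stA")

  writeLines(c("sample_id,station,template,ct1",
               "stA,A,DNA,NaN"), f)
  expect_error(read_qpcr(f), "Ct replicates")
  writeLines(c("sample_id,station,template,ct1",
               "stA,A,RNA,21.0"), f)
  expect_error(read_qpcr(f), "template")
  qw <- tempfile(fileext = ".csv")
  q2 <- make_qpcr("A", 20, 22, reps = 3)
  write_qpcr(q2, qw)
  back <- read_qpcr(qw)
  expect_equal(back$ct, q2$ct)
})
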