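test_that("OTU ranking aggregates both libraries with deterministic ties", {
  dna <- make_table(matrix(c(60, 6, 1, 40, 4, 0), 3, 2,
                           dimnames = list(c("OTU_a", "OTU_b", "OTU_c"),
                                           c("d1", "d2"))),
                    stations = c("A", "B"))
  rna <- make_table(matrix(c(0, 0, 1), 3, 1,
                           dimnames = list(c("OTU_a", "OTU_b", "OTU_c"),
                                           "r1")),
                    stations = "A", library = "RNA")
  r <- rank_abundant_otus(dna, rna, n = 2)
  expect_equal(r$otu_id, c("OTU_a", "OTU_b"))
  expect_equal(r$aggregated_reads, c(100, 10))
  expect_equal(r$cumulative_fraction, c(100, 110) / 112)

  tied <- make_table(matrix(c(5, 5, 5), 3, 1,
                            dimnames = list(c("b", "c", "a"), "s1")))
  r2 <- rank_abundant_otus(tied, tied, n = 3)
  expect_equal(r2$otu_id, c("a", "b", "c"))
  expect_equal(r2$cumulative_fraction[3], 1)
  expect_warning(rank_abundant_otus(tied, tied, n = 5), "truncated")
})

test_that("group frequencies are proportions summing to one per sample", {
  tab <- make_table(matrix(c(98, 1, 1, 50, 25, 25), 3, 2),
                    stations = c("A", "B"))
  tax <- c(OTU1 = "Trichodesmium", OTU2 = "other", OTU3 = "other")
  gf <- group_frequencies(tab, tax)
  expect_equal(gf$per_sample["Trichodesmium", "s1"], 0.98)
  expect_equal(unname(colSums(gf$per_sample)), c(1, 1), tolerance = 1e-9)
  expect_equal(gf$average["Trichodesmium", "DNA"], mean(c(0.98, 0.5)))
  expect_error(group_frequencies(tab, tax[1:2]), "does not cover")
})

test_that("proportionality classes follow the fold-threshold contract", {
  expect_equal(classify_proportionality(0.5, 0.5), "proportional")
  ## cluster III-like: present in DNA, negligible in RNA
  expect_equal(classify_proportionality(0.011, 0), "DNA-enriched")
  ## unicellular-cyanobacteria-like: 0.01% DNA vs 0.5% RNA
  expect_equal(classify_proportionality(0.0001, 0.005), "RNA-enriched")
  expect_equal(classify_proportionality(0, 0), "undefined")
  expect_equal(classify_proportionality(0.1, 0.2), "proportional")
  expect_equal(classify_proportionality(0.1, 0.201), "RNA-enriched")
  expect_equal(classify_proportionality(c(0.2, 0.1), c(0.1, 0.9)),
               c("proportional", "RNA-enriched"))
  expect_error(classify_proportionality(0.1, 0.1, threshold = 1), "> 1")
  expect_error(classify_proportionality(1.2, 0.1), "\\[0, 1\\]")
})

test_that("amplification efficiency derives from the standard-curve slope", {
  expect_equal(efficiency_from_slope(-3.3219), 2, tolerance = 1e-4)
  expect_equal(efficiency_from_slope(-3.5), 1.9307, tolerance = 1e-4)
  expect_error(efficiency_from_slope(1), "negative")
})

test_that("bulk ratio exponentiates the replicate-averaged delta Ct", {
  q <- make_qpcr("A", ct_dna = 21, ct_cdna = 21, reps = 3)
  expect_equal(bulk_expression_ratio(q, 1.7)$r_bulk, 1)
  q2 <- make_qpcr("A", 20, 22, reps = 3)
  r2 <- bulk_expression_ratio(q2, 2)
  expect_equal(r2$delta_ct, -2)
  expect_equal(r2$r_bulk, 0.25)
  q3 <- make_qpcr("A", 21, 20, reps = 1)
  expect_equal(bulk_expression_ratio(q3, 1.9)$r_bulk, 1.9)
  ## replicates averaged on the Ct scale
  q4 <- qpcr_table(data.frame(sample_id = c("stA", "stA"),
                              station = c("A", "A"),
                              template = c("DNA", "cDNA")),
                   list(c(20, 22), c(21, 21)))
  expect_equal(bulk_expression_ratio(q4, 2)$r_bulk, 1)
  expect_error(bulk_expression_ratio(q2, 1), "> 1")
})

test_that("group ratio follows R_bulk * f_RNA / f_DNA with an undefined case", {
  ## printed worked example: bulk 0.17, frequencies 87% RNA / 98% DNA
  expect_equal(round(group_expression_ratio(0.17, 0.87, 0.98), 2), 0.15)
  expect_equal(group_expression_ratio(0.4, 0.3, 0.3), 0.4)
  expect_true(is.na(group_expression_ratio(0.4, 0.2, 0)))
  expect_error(group_expression_ratio(0.4, -0.1, 0.5), "non-negative")
  expect_error(group_expression_ratio(-1, 0.5, 0.5), "positive")
})

test_that("group ratios are abundance-consistent and monotone", {
  set.seed(71)
  for (i in 1:20) {
    f_dna <- rexp(6); f_dna <- f_dna / sum(f_dna)
    f_rna <- rexp(6); f_rna <- f_rna / sum(f_rna)
    r_bulk <- runif(1, 0.01, 5)
    rg <- group_expression_ratio(r_bulk, f_rna, f_dna)
    ## sum over groups of f_DNA * R_group returns R_bulk exactly
    expect_equal(sum(f_dna * rg), r_bulk)
    ## monotone in f_RNA, antitone in f_DNA
    expect_gt(group_expression_ratio(r_bulk, f_rna[1] * 1.1, f_dna[1]),
              rg[1])
    expect_lt(group_expression_ratio(r_bulk, f_rna[1], f_dna[1] * 1.1),
              rg[1])
  }
})

test_that("expression table matches stations and honours average mode", {
  spec <- community_spec(n_stations = 3, library_size = 2000)
  sim <- simulate_pads(spec, seed = 8)
  fd <- group_frequencies(sim$dna, default_tax(spec))
  fr <- group_frequencies(sim$rna, default_tax(spec))
  bulk <- bulk_expression_ratio(sim$qpcr, spec$efficiency)
  et <- expression_ratio_table(bulk, fd, fr)
  expect_equal(nrow(et), 3 * length(unique(et$group)))
  i <- which(et$station == "B" & et$group == "Trichodesmium")
  expect_equal(et$r_group[i],
               bulk$r_bulk[bulk$station == "B"] *
                 fr$per_sample["Trichodesmium", "stB_RNA"] /
                 fd$per_sample["Trichodesmium", "stB_DNA"])
  eta <- expression_ratio_table(bulk, fd, fr, average_frequencies = TRUE)
  ja <- which(eta$station == "B" & eta$group == "Trichodesmium")
  expect_equal(eta$r_group[ja],
               bulk$r_bulk[bulk$station == "B"] *
                 fr$average["Trichodesmium", 1] /
                 fd$average["Trichodesmium", 1])
})
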