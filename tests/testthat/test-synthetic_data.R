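test_that("community specs validate their ground truth", {
  expect_error(community_spec(taxa = data.frame(
    taxon_id = "a", group = "g", d = 0.5, r = 1)), "sum to 1")
  expect_error(community_spec(taxa = data.frame(
    taxon_id = c("a", "b"), group = "g", d = c(0.5, 0.5), r = c(0, 0))),
    "RNA library undefined")
  expect_error(community_spec(efficiency = 1), "> 1")
  spec <- community_spec()
  expect_equal(sum(spec$taxa$d), 1)
  expect_equal(spec$library_size, 4746)
  expect_equal(spec$n_stations, 9)
})

test_that("ground-truth ratios obey the group-ratio algebra exactly", {
  spec2 <- community_spec(taxa = data.frame(
    taxon_id = c("a", "b"), group = c("ga", "gb"),
    d = c(0.5, 0.5), r = c(1, 3)))
  gt <- ground_truth_ratios(spec2)
  expect_equal(gt$r_bulk_true, 2)
  expect_equal(gt$taxa$f_rna, c(0.25, 0.75))
  ## R_bulk * f_RNA / f_DNA = r for every taxon, exactly
  expect_equal(gt$r_bulk_true * gt$taxa$f_rna / gt$taxa$f_dna, gt$taxa$r)

  const <- community_spec(taxa = data.frame(
    taxon_id = letters[1:3], group = letters[1:3],
    d = c(0.2, 0.3, 0.5), r = 4))
  gtc <- ground_truth_ratios(const)
  expect_equal(gtc$r_bulk_true, 4)
  expect_equal(gtc$taxa$f_rna, gtc$taxa$f_dna)
})

test_that("paired libraries renormalize activity into RNA proportions", {
  spec2 <- community_spec(taxa = data.frame(
    taxon_id = c("a", "b"), group = c("ga", "gb"),
    d = c(0.5, 0.5), r = c(1, 3)), n_stations = 2)
  ex <- simulate_pads(spec2, seed = 3, exact = TRUE)
  expect_equal(unname(ex$rna$counts[, 1]), c(0.25, 0.75))
  expect_equal(unname(ex$dna$counts[, 1]), c(0.5, 0.5))

  ## all r equal: expected RNA composition equals DNA composition
  unif <- community_spec(taxa = data.frame(
    taxon_id = c("a", "b"), group = c("ga", "gb"),
    d = c(0.3, 0.7), r = 1), n_stations = 1, library_size = 4000,
    station_effect_sd = 0, rna_dispersion_sd = 0)
  sims <- vapply(1:300, function(i) {
    s <- simulate_pads(unif, seed = i)
    (s$rna$counts[1, 1] - s$dna$counts[1, 1]) / 4000
  }, numeric(1))
  se <- sqrt(2 * 0.3 * 0.7 / 4000 / 300)
  expect_lt(abs(mean(sims)), 3 * se)

  s1 <- simulate_pads(spec2, seed = 12)
  s2 <- simulate_pads(spec2, seed = 12)
  expect_identical(s1$dna$counts, s2$dna$counts)
  expect_identical(s1$qpcr$ct, s2$qpcr$ct)

  ## per-station truth satisfies the bulk identity
  for (st in names(s1$truth)) {
    tr <- s1$truth[[st]]
    expect_equal(tr$r_bulk_true, sum(tr$d * tr$r) / sum(tr$d))
  }
})

test_that("noiseless qPCR inverts to the true bulk ratio", {
  spec <- community_spec(n_stations = 4)
  ex <- simulate_pads(spec, seed = 5, exact = TRUE)
  bulk <- bulk_expression_ratio(ex$qpcr, spec$efficiency)
  truth <- vapply(ex$truth, `[[`, numeric(1), "r_bulk_true")
  expect_equal(bulk$r_bulk, unname(truth[bulk$station]), tolerance = 1e-12)

  ## r_bulk_true = 1 gives delta Ct = 0
  one <- community_spec(taxa = data.frame(
    taxon_id = c("a", "b"), group = c("ga", "gb"),
    d = c(0.4, 0.6), r = 1), n_stations = 1)
  exo <- simulate_pads(one, seed = 2, exact = TRUE)
  expect_equal(bulk_expression_ratio(exo$qpcr, 2)$delta_ct, 0)
})

test_that("noisy qPCR recovery is unbiased on the log scale", {
  spec <- community_spec(taxa = data.frame(
    taxon_id = c("a", "b"), group = c("ga", "gb"),
    d = c(0.5, 0.5), r = c(0.1, 0.4)),
    n_stations = 1000, station_effect_sd = 0, rna_dispersion_sd = 0,
    library_size = 100)
  sim <- simulate_pads(spec, seed = 77)
  bulk <- bulk_expression_ratio(sim$qpcr, spec$efficiency)
  truth <- vapply(sim$truth, `[[`, numeric(1), "r_bulk_true")
  log_err <- log(bulk$r_bulk / truth[bulk$station])
  expect_lt(abs(mean(log_err)), 0.01)
})

test_that("the default scenario reproduces the dominant-taxon frequencies", {
  spec <- community_spec()
  ## ground truth targets 98% DNA / 87% RNA for the dominant taxon
  gt <- ground_truth_ratios(spec)
  i <- which(gt$taxa$taxon_id == "OTU_tricho")
  expect_equal(gt$taxa$f_dna[i], 0.9789)
  expect_equal(gt$taxa$f_rna[i], 0.87, tolerance = 1e-4)

  ## simulated averages stay near the targets; the RNA-side log-normal
  ## jitter skews realised means a few points below the ground truth
  f_dna <- f_rna <- numeric(0)
  for (s in 1:20) {
    sim <- simulate_pads(spec, seed = 300 + s)
    pd <- proportions_of_tab(sim$dna)
    pr <- proportions_of_tab(sim$rna)
    f_dna <- c(f_dna, pd["OTU_tricho", ])
    f_rna <- c(f_rna, pr["OTU_tricho", ])
  }
  expect_lt(abs(mean(f_dna) - 0.98), 0.015)
  expect_lt(abs(mean(f_rna) - 0.87), 0.05)
})

test_that("datasets round-trip through the standard file layout", {
  spec <- community_spec(n_stations = 3, library_size = 500)
  sim <- simulate_pads(spec, seed = 21)
  dir <- tempfile()
  paths <- write_pads_sim(sim, dir)
  expect_true(all(file.exists(paths)))
  dna <- read_count_table(paths["dna"], paths["meta"])
  expect_equal(dna$counts[, colnames(sim$dna$counts)], sim$dna$counts)
  q <- read_qpcr(paths["qpcr"])
  expect_equal(q$ct, sim$qpcr$ct, tolerance = 1e-10)
})
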