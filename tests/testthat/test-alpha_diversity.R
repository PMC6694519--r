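test_that("alpha indices match closed forms and hand-computed values", {
  expect_equal(shannon(c(100)), 0)
  expect_equal(shannon(rep(25, 4)), log(4))
  ## -(0.1 ln 0.1 + 0.2 ln 0.2 + 0.3 ln 0.3 + 0.4 ln 0.4)
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(shannon(p), 1.2798543, tolerance = 1e-7)

  expect_equal(simpson(c(100)), 0)
  expect_equal(simpson(rep(1, 7)), 1 - 1 / 7)
  expect_equal(simpson(p), 0.70)

  expect_equal(pielou(rep(3, 5)), 1)
  expect_equal(pielou(p), 1.2798543 / log(4), tolerance = 1e-7)
  expect_warning(j <- pielou(c(10)), "single-OTU")
  expect_true(is.na(j))

  expect_error(shannon(c(0, 0)), "all-zero")
  expect_error(simpson(c(-1, 2)), "non-negative")
})

test_that("Chao1 follows the singleton/doubleton formula with F2 = 0 correction", {
  expect_equal(chao1(c(5, 3, 3, 7)), 4)               # no singletons
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(5, 4))), 14)
  expect_equal(chao1(c(1, 1, 3, 3, 3)), 6)            # bias-corrected branch
  expect_error(chao1(c(1.5, 2)), "integer")
  x <- c(rep(1, 3), rep(2, 2), 4, 9)
  expect_gte(chao1(x), sum(x > 0))
})

test_that("indices are scale-invariant and respect merging/zero-padding", {
  set.seed(41)
  for (i in 1:20) {
    x <- rpois(12, 20) + 1
    expect_equal(shannon(x), shannon(x / sum(x)))
    expect_equal(simpson(x), simpson(x / sum(x)))
    expect_equal(shannon(c(x, 0)), shannon(x))
    expect_equal(simpson(c(x, 0)), simpson(x))
    ## merging two taxa never increases H or D
    merged <- c(x[1] + x[2], x[-(1:2)])
    expect_lte(shannon(merged), shannon(x) + 1e-12)
    expect_lte(simpson(merged), simpson(x) + 1e-12)
  }
})

test_that("alpha_diversity builds per-sample records with metadata", {
  tab <- make_table(matrix(c(5, 5, 0, 8, 1, 1), 3, 2),
                    stations = c("A", "B"), library = "DNA")
  rec <- alpha_diversity(tab)
  expect_equal(rec$sample_id, c("s1", "s2"))
  expect_equal(rec$observed_richness, c(2, 3))
  expect_equal(rec$H[1], log(2))
  expect_equal(rec$chao1[2], chao1(c(8, 1, 1)))
  ## real-valued tables leave chao1 NA unless supplied
  tabr <- make_table(matrix(c(0.5, 0.5, 0.2, 0.8), 2), stations = c("A", "B"),
                     integer_counts = FALSE)
  expect_true(all(is.na(alpha_diversity(tabr)$chao1)))
  rec2 <- alpha_diversity(tabr, chao1_values = c(s1 = 3, s2 = 4))
  expect_equal(rec2$chao1, c(3, 4))
})

test_that("alpha indices agree with an established implementation", {
  set.seed(17)
  for (i in 1:10) {
    x <- rpois(30, 8)
    x[1] <- x[1] + 1
    expect_equal(shannon(x), vegan::diversity(x, "shannon"))
    expect_equal(simpson(x), vegan::diversity(x, "simpson"))
  }
})

test_that("total-vs-active contrast reports Welch t and the equivalent ANOVA", {
  d1 <- data.frame(H = c(1, 1, 2, 2))
  expect_equal(compare_alpha(d1, d1, "H")$statistic, 0)
  expect_equal(compare_alpha(d1, d1, "H")$p_value, 1)

  set.seed(23)
  dna <- data.frame(H = rnorm(9, 1, 0.1))
  rna <- data.frame(H = rnorm(9, 2, 0.1))
  ct <- compare_alpha(dna, rna, "H")
  expect_lt(ct$p_value, 0.001)
  expect_equal(ct$direction, "RNA")
  ## F = t^2 algebraic identity (pooled-variance t)
  tt <- t.test(rna$H, dna$H, var.equal = TRUE)
  expect_equal(ct$F, unname(tt$statistic)^2)
  expect_equal(ct$p_anova,
               anova(lm(v ~ g, data.frame(v = c(dna$H, rna$H),
                                          g = rep(c("d", "r"), each = 9))))$
                 `Pr(>F)`[1])
  expect_error(compare_alpha(data.frame(H = 1), rna, "H"), ">= 2 samples")
  expect_error(compare_alpha(dna, rna, "nope"), "unknown index")
})
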