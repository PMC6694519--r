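#' Shannon diversity index
#'
#' H = -sum p_i ln p_i over the positive relative abundances p_i of one
#' sample. Natural logarithms (nats) are used throughout the package, so the
#' same base cancels in the Pielou evenness ratio.
#'
#' @param counts non-negative abundance vector (counts or proportions; the
#'   index is scale-invariant).
#' @return H in nats, >= 0.
#' @export
shannon <- function(counts) {
  p <- check_abundances(counts)
  -sum(p * log(p))
}

#' Simpson diversity index (Gini-Simpson form)
#'
#' D = 1 - sum p_i^2, the probability that two reads drawn at random belong
#' to different OTUs. The Gini-Simpson form is used so that larger values
#' mean more diverse, consistent with the other indices.
#'
#' @inheritParams shannon
#' @return D in [0, 1).
#' @export
simpson <- function(counts) {
  p <- check_abundances(counts)
  1 - sum(p^2)
}

#' Pielou evenness
#'
#' J = H / ln(S_obs) with S_obs the observed richness. Undefined for a
#' single-OTU sample (returned as `NA` with a warning, not silently zero).
#'
#' @inheritParams shannon
#' @return J in [0, 1], or `NA` when S_obs < 2.
#' @export
pielou <- function(counts) {
  p <- check_abundances(counts)
  s <- length(p)
  if (s < 2) {
    warning("Pielou evenness undefined for a single-OTU sample",
            call. = FALSE)
    return(NA_real_)
  }
  -sum(p * log(p)) / log(s)
}

#' Chao1 richness estimator
#'
#' S_obs + F1^2 / (2 F2) from the singleton (F1) and doubleton (F2) counts;
#' when F2 = 0 the bias-corrected form S_obs + F1 (F1 - 1) / (2 (F2 + 1))
#' avoids division by zero. Requires integer counts — rarefaction means are
#' not admissible; see [chao1_rarefied()].
#'
#' @param counts non-negative integer abundance vector.
#' @return Estimated richness, always >= observed richness.
#' @export
chao1 <- function(counts) {
  if (!is_wholenumber(counts))
    stop_input("chao1 requires integer counts; use chao1_rarefied() on a rarefied table")
  check_abundances(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Chao1 under repeated rarefaction
#'
#' Chao1 needs integer singleton/doubleton counts, so it is computed on each
#' integer rarefaction draw and averaged across iterations — unlike the
#' other indices, which operate on proportions of the mean table.
#'
#' @inheritParams rarefy_repeated
#' @return Named numeric vector of mean Chao1 per sample.
#' @export
chao1_rarefied <- function(table, depth = "auto", iterations = 100,
                           seed = NULL) {
  stopifnot(inherits(table, "count_table"))
  depth <- resolve_depth(table, depth)
  acc <- numeric(ncol(table$counts))
  with_seed(seed, {
    for (i in seq_len(iterations)) {
      draw <- rarefy_once(table, depth, seed = NULL)
      acc <- acc + apply(draw$counts, 2, chao1)
    }
  })
  stats::setNames(acc / iterations, colnames(table$counts))
}

check_abundances <- function(counts) {
  if (!is.numeric(counts) || any(!is.finite(counts)) || any(counts < 0))
    stop_input("abundances must be finite and non-negative")
  total <- sum(counts)
  if (total <= 0) stop_input("all-zero abundance vector")
  p <- counts / total
  p[p > 0]
}

#' Per-sample alpha-diversity records
#'
#' Computes Shannon, Simpson, Pielou and observed richness for every sample
#' of a table (integer counts or rarefaction means), plus Chao1 when the
#' counts are integral. For a rarefied-mean table supply `chao1_values`
#' from [chao1_rarefied()].
#'
#' @param table a [count_table()].
#' @param chao1_values optional named per-sample Chao1 vector overriding the
#'   direct computation.
#' @return data.frame with one row per sample: `sample_id`, `station`,
#'   `library`, `H`, `D`, `J`, `chao1`, `observed_richness`.
#' @export
alpha_diversity <- function(table, chao1_values = NULL) {
  stopifnot(inherits(table, "count_table"))
  m <- table$counts
  rec <- data.frame(
    sample_id = colnames(m),
    station = table$sample_meta$station,
    library = table$sample_meta$library,
    H = apply(m, 2, shannon),
    D = apply(m, 2, simpson),
    J = suppressWarnings(apply(m, 2, pielou)),
    chao1 = NA_real_,
    observed_richness = apply(m, 2, function(x) sum(x > 0)),
    row.names = NULL
  )
  if (!is.null(chao1_values)) {
    rec$chao1 <- unname(chao1_values[rec$sample_id])
  } else if (table$integer_counts) {
    rec$chao1 <- apply(m, 2, chao1)
  }
  rec
}

#' Contrast an alpha-diversity index between total (DNA) and active (RNA)
#' communities
#'
#' Two-sided two-sample comparison of one index between the DNA-derived and
#' RNA-derived libraries. Both a Welch t-test (default robustness to unequal
#' variances) and the classical one-way ANOVA are reported; for two groups
#' the ANOVA F is exactly the square of the pooled-variance t statistic.
#'
#' @param dna_records,rna_records data.frames from [alpha_diversity()] (or
#'   any with the index column), >= 2 rows each.
#' @param index column name to contrast, e.g. `"H"`.
#' @return List with `statistic` (Welch t), `p_value` (Welch), `F`,
#'   `p_anova`, `direction` (`"RNA"`/`"DNA"`/`"none"`, the library with the
#'   larger mean) and the two group means.
#' @export
compare_alpha <- function(dna_records, rna_records, index = "H") {
  x <- dna_records[[index]]
  y <- rna_records[[index]]
  if (is.null(x) || is.null(y)) stop_input("unknown index '", index, "'")
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2)
    stop_input("each library needs >= 2 samples with a finite index value")
  if (stats::var(c(x, y)) == 0) {
    welch <- list(statistic = 0, p.value = 1)
    f <- 0; p_f <- 1
  } else {
    welch <- stats::t.test(y, x)
    pooled <- stats::t.test(y, x, var.equal = TRUE)
    f <- unname(pooled$statistic)^2
    p_f <- stats::pf(f, 1, length(x) + length(y) - 2, lower.tail = FALSE)
  }
  dm <- mean(y) - mean(x)
  list(index = index,
       statistic = unname(welch$statistic),
       p_value = welch$p.value,
       F = f,
       p_anova = p_f,
       direction = if (dm > 0) "RNA" else if (dm < 0) "DNA" else "none",
       mean_DNA = mean(x), mean_RNA = mean(y))
}
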