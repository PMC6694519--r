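#' Fit the total-versus-active community analysis to paired nifH libraries
#'
#' The package's central entry point. Runs, in order: repeated-rarefaction
#' normalization of the DNA and RNA libraries to a common depth;
#' alpha-diversity (Shannon, Simpson, Pielou, Chao1) per sample with
#' total-vs-active contrasts; Bray-Curtis dissimilarities on rarefied-mean
#' proportions with NMDS ordination and beta-dispersion permutation test;
#' OTU abundance ranking, group frequencies and DNA:RNA proportionality
#' classes; and, when qPCR records are supplied, bulk (R_bulk = E^dCt) and
#' group-level (R_group = R_bulk f_RNA / f_DNA) expression ratios. Without
#' qPCR the expression stage is skipped with a message and the rest of the
#' fit is returned.
#'
#' @param dna,rna [count_table()]s of the DNA- and RNA-derived libraries
#'   (one library per station in each).
#' @param taxonomy named character vector `otu_id -> group` covering both
#'   tables.
#' @param qpcr optional `qpcr_table` with DNA and cDNA Ct records per
#'   station.
#' @param depth rarefaction depth; `"auto"` (default) uses the smallest
#'   library in either table.
#' @param iterations rarefaction iterations (default 100).
#' @param efficiency qPCR amplification efficiency E (default 2); see
#'   [efficiency_from_slope()].
#' @param top_n OTUs to keep in the abundance ranking (default 20).
#' @param fold_threshold proportionality band for
#'   [classify_proportionality()] (default 2).
#' @param n_permutations permutations for the beta-dispersion test.
#' @param average_frequencies use library-averaged group frequencies in the
#'   group expression ratio instead of station-matched ones.
#' @param seed master seed; every stochastic stage draws a deterministic
#'   sub-seed from it, so refitting with the same seed is bit-identical.
#' @return An object of class `pads_activity`; see [summary.pads_activity()].
#' @export
pads_activity <- function(dna, rna, taxonomy, qpcr = NULL,
                          depth = "auto", iterations = 100,
                          efficiency = 2, top_n = 20, fold_threshold = 2,
                          n_permutations = 999,
                          average_frequencies = FALSE, seed = 1) {
  stopifnot(inherits(dna, "count_table"), inherits(rna, "count_table"))
  if (!all(dna$sample_meta$library == "DNA"))
    stop_input("'dna' must contain only DNA libraries")
  if (!all(rna$sample_meta$library == "RNA"))
    stop_input("'rna' must contain only RNA libraries")
  if (!setequal(dna$sample_meta$station, rna$sample_meta$station))
    stop_input("DNA and RNA tables must cover the same stations")
  seeds <- spawn_seeds(seed, 5)

  if (identical(depth, "auto"))
    depth <- min(colSums(dna$counts), colSums(rna$counts))
  integer_input <- dna$integer_counts && rna$integer_counts
  if (integer_input) {
    dna_n <- rarefy_repeated(dna, depth, iterations, seed = seeds[1])
    rna_n <- rarefy_repeated(rna, depth, iterations, seed = seeds[2])
    chao_dna <- chao1_rarefied(dna, depth, iterations, seed = seeds[1])
    chao_rna <- chao1_rarefied(rna, depth, iterations, seed = seeds[2])
    alpha_dna <- alpha_diversity(dna_n, chao1_values = chao_dna)
    alpha_rna <- alpha_diversity(rna_n, chao1_values = chao_rna)
  } else {
    ## already-normalized (e.g. exact-proportion) tables pass through
    dna_n <- dna; rna_n <- rna
    alpha_dna <- alpha_diversity(dna_n)
    alpha_rna <- alpha_diversity(rna_n)
  }
  alpha <- rbind(alpha_dna, alpha_rna)
  contrasts <- lapply(c(H = "H", D = "D", J = "J", chao1 = "chao1"),
                      function(ix)
    tryCatch(compare_alpha(alpha_dna, alpha_rna, ix),
             error = function(e) NULL))
  contrasts <- Filter(Negate(is.null), contrasts)

  ## beta diversity on proportions of the combined normalized tables
  combined <- combine_tables(dna_n, rna_n)
  prop <- proportions_of(combined)
  d <- bray_curtis(prop)
  ord <- nmds(d, k = 2, restarts = 20, seed = seeds[3])
  disp <- beta_dispersion(d, combined$sample_meta$library,
                          n_permutations = n_permutations,
                          seed = seeds[4])

  ranking <- rank_abundant_otus(dna_n, rna_n, n = top_n)
  freq_dna <- group_frequencies(dna_n, taxonomy)
  freq_rna <- group_frequencies(rna_n, taxonomy)

  ## OTU-level DNA:RNA proportionality from library-average frequencies
  otus <- union(rownames(dna_n$counts), rownames(rna_n$counts))
  pad_mean <- function(tab) {
    f <- stats::setNames(numeric(length(otus)), otus)
    m <- rowMeans(proportions_of(tab))
    f[names(m)] <- m
    f
  }
  f_dna_otu <- pad_mean(dna_n)
  f_rna_otu <- pad_mean(rna_n)
  proportionality <- data.frame(
    otu_id = otus,
    group = unname(taxonomy[otus]),
    f_dna = unname(f_dna_otu),
    f_rna = unname(f_rna_otu),
    log2_ratio = log2(unname(f_rna_otu) / unname(f_dna_otu)),
    class = classify_proportionality(f_dna_otu, f_rna_otu,
                                     threshold = fold_threshold),
    row.names = NULL)

  expression <- NULL
  bulk <- NULL
  if (is.null(qpcr)) {
    message("no qPCR records supplied; expression-ratio stage skipped")
  } else {
    bulk <- bulk_expression_ratio(qpcr, efficiency = efficiency)
    bulk <- bulk[bulk$station %in% dna$sample_meta$station, , drop = FALSE]
    expression <- expression_ratio_table(
      bulk, freq_dna, freq_rna, average_frequencies = average_frequencies)
  }

  structure(list(
    alpha = alpha, contrasts = contrasts,
    distances = d, nmds = ord, dispersion = disp,
    ranking = ranking, freq_dna = freq_dna, freq_rna = freq_rna,
    proportionality = proportionality,
    bulk = bulk, expression = expression,
    normalized = list(dna = dna_n, rna = rna_n),
    params = list(depth = depth, iterations = iterations,
                  efficiency = efficiency, top_n = top_n,
                  fold_threshold = fold_threshold,
                  n_permutations = n_permutations,
                  average_frequencies = average_frequencies, seed = seed)
  ), class = "pads_activity")
}

combine_tables <- function(a, b) {
  otus <- union(rownames(a$counts), rownames(b$counts))
  pad <- function(tab) {
    m <- matrix(0, length(otus), ncol(tab$counts),
                dimnames = list(otus, colnames(tab$counts)))
    m[rownames(tab$counts), ] <- tab$counts
    m
  }
  count_table(cbind(pad(a), pad(b)),
              rbind(a$sample_meta, b$sample_meta),
              integer_counts = FALSE)
}

#' @export
print.pads_activity <- function(x, ...) {
  cat("Paired nifH DNA/RNA community analysis\n")
  cat("  ", length(unique(x$alpha$station)), " stations, rarefied to ",
      x$params$depth, " reads (", x$params$iterations, " iterations)\n",
      sep = "")
  cat("  NMDS stress-1: ", signif(x$nmds$stress, 3),
      "; beta-dispersion permutation p = ", signif(x$dispersion$p_perm, 3),
      "\n", sep = "")
  if (!is.null(x$bulk))
    cat("  bulk RNA/DNA ratio: mean ", signif(mean(x$bulk$r_bulk), 3),
        " (range ", paste(signif(range(x$bulk$r_bulk), 3),
                          collapse = " - "), ")\n", sep = "")
  invisible(x)
}

#' Summarise a fitted paired-library analysis
#'
#' @param object a `pads_activity` fit.
#' @param ... unused.
#' @return List of class `summary.pads_activity`: alpha contrast table,
#'   dispersion summary, per-library average group frequencies, top-OTU
#'   ranking, proportionality class counts and per-group expression-ratio
#'   summaries (mean, range, number of undefined stations).
#' @export
summary.pads_activity <- function(object, ...) {
  contrast_tab <- do.call(rbind, lapply(object$contrasts, function(ct)
    data.frame(index = ct$index, t = ct$statistic, p_welch = ct$p_value,
               F = ct$F, p_anova = ct$p_anova, direction = ct$direction,
               mean_DNA = ct$mean_DNA, mean_RNA = ct$mean_RNA,
               row.names = NULL)))
  freq_tab <- merge(
    data.frame(group = rownames(object$freq_dna$average),
               f_DNA = object$freq_dna$average[, 1]),
    data.frame(group = rownames(object$freq_rna$average),
               f_RNA = object$freq_rna$average[, 1]),
    by = "group", all = TRUE)
  expr_tab <- NULL
  if (!is.null(object$expression)) {
    sp <- split(object$expression, object$expression$group)
    expr_tab <- do.call(rbind, lapply(sp, function(gd) data.frame(
      group = gd$group[1],
      mean_r_group = mean(gd$r_group, na.rm = TRUE),
      min_r_group = suppressWarnings(min(gd$r_group, na.rm = TRUE)),
      max_r_group = suppressWarnings(max(gd$r_group, na.rm = TRUE)),
      n_undefined = sum(is.na(gd$r_group)),
      row.names = NULL)))
    rownames(expr_tab) <- NULL
  }
  structure(list(
    contrasts = contrast_tab,
    dispersion = list(group_means = object$dispersion$group_means,
                      F = object$dispersion$F,
                      p_parametric = object$dispersion$p_parametric,
                      p_perm = object$dispersion$p_perm),
    stress = object$nmds$stress,
    group_frequencies = freq_tab,
    ranking = object$ranking,
    proportionality = table(object$proportionality$class),
    bulk = if (!is.null(object$bulk))
      list(mean = mean(object$bulk$r_bulk),
           range = range(object$bulk$r_bulk)),
    expression = expr_tab
  ), class = "summary.pads_activity")
}

#' @export
print.summary.pads_activity <- function(x, ...) {
  cat("Alpha-diversity contrasts (active RNA vs total DNA):\n")
  print(transform(x$contrasts,
                  t = signif(t, 4), p_welch = signif(p_welch, 3),
                  F = signif(F, 4), p_anova = signif(p_anova, 3),
                  mean_DNA = signif(mean_DNA, 4),
                  mean_RNA = signif(mean_RNA, 4)), row.names = FALSE)
  cat("\nBeta-dispersion: F = ", signif(x$dispersion$F, 4),
      ", parametric p = ", signif(x$dispersion$p_parametric, 3),
      ", permutation p = ", signif(x$dispersion$p_perm, 3),
      " | NMDS stress-1 = ", signif(x$stress, 3), "\n", sep = "")
  cat("\nAverage group frequencies:\n")
  print(transform(x$group_frequencies, f_DNA = signif(f_DNA, 4),
                  f_RNA = signif(f_RNA, 4)), row.names = FALSE)
  if (!is.null(x$bulk))
    cat("\nBulk RNA/DNA ratio: mean ", signif(x$bulk$mean, 3), ", range ",
        paste(signif(x$bulk$range, 3), collapse = " - "), "\n", sep = "")
  if (!is.null(x$expression)) {
    cat("\nGroup expression ratios:\n")
    print(transform(x$expression, mean_r_group = signif(mean_r_group, 3),
                    min_r_group = signif(min_r_group, 3),
                    max_r_group = signif(max_r_group, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Extract expression-ratio coefficients from a fit
#'
#' @param object a `pads_activity` fit with a qPCR stage.
#' @param ... unused.
#' @return Named numeric vector: `R_bulk` (mean across stations) followed
#'   by the per-group mean `R_group` values (`NA` for groups undefined at
#'   every station).
#' @export
coef.pads_activity <- function(object, ...) {
  if (is.null(object$expression))
    stop_input("fit has no expression stage (no qPCR records supplied)")
  sp <- split(object$expression$r_group, object$expression$group)
  gr <- vapply(sp, function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE), numeric(1))
  c(R_bulk = mean(object$bulk$r_bulk), gr)
}

#' Plot a fitted paired-library analysis
#'
#' Draws the NMDS ordination (total vs active samples), the
#' beta-dispersion centroid distances, and — when the expression stage ran
#' — per-station group expression ratios on a log scale.
#'
#' @param x a `pads_activity` fit.
#' @param which subset of `c("nmds", "dispersion", "expression")`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.pads_activity <- function(x,
                               which = c("nmds", "dispersion",
                                         "expression"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  lib <- factor(c(x$normalized$dna$sample_meta$library,
                  x$normalized$rna$sample_meta$library))
  if ("nmds" %in% which) {
    co <- x$nmds$coordinates
    graphics::plot(co, col = as.integer(lib) + 1, pch = 19,
                   main = sprintf("NMDS (stress-1 = %.3g)", x$nmds$stress),
                   ...)
    graphics::legend("topright", legend = levels(lib),
                     col = seq_along(levels(lib)) + 1, pch = 19)
  }
  if ("dispersion" %in% which) {
    graphics::boxplot(split(x$dispersion$distances, x$dispersion$groups),
                      ylab = "distance to group centroid",
                      main = sprintf("Beta-dispersion (perm. p = %.3g)",
                                     x$dispersion$p_perm), ...)
  }
  if ("expression" %in% which && !is.null(x$expression)) {
    e <- x$expression[is.finite(x$expression$r_group) &
                        x$expression$r_group > 0, ]
    g <- factor(e$group)
    graphics::plot(as.integer(g), e$r_group, log = "y", xaxt = "n",
                   xlab = "", ylab = "RNA/DNA expression ratio",
                   main = "Group nifH expression ratios", ...)
    graphics::axis(1, at = seq_along(levels(g)), labels = levels(g),
                   las = 2, cex.axis = 0.7)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}
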