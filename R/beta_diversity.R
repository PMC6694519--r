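#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i). Bray-Curtis on raw counts is
#' not invariant to library depth, so the pipeline always feeds per-sample
#' proportions (the rarefied-mean table normalised column-wise); the
#' function itself accepts any non-negative abundance matrix.
#'
#' @param x a [count_table()] or a numeric matrix with samples in columns.
#' @return A `dist` object labelled by sample id, entries in [0, 1].
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "count_table")) x$counts else as.matrix(x)
  if (any(!is.finite(m)) || any(m < 0))
    stop_input("abundances must be finite and non-negative")
  zero <- colSums(m) <= 0
  if (any(zero))
    stop_input("all-zero sample(s): ",
               paste(colnames(m)[zero], collapse = ", "))
  vegan::vegdist(t(m), method = "bray")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal stress-1 (monotone-regression form, primary
#' tie-breaking) by iterative descent, starting from the principal
#' coordinate (metric scaling) configuration and from `restarts` random
#' configurations; the lowest-stress solution is returned. Descent uses
#' \code{vegan::monoMDS} with tight convergence tolerances so exactly
#' embeddable configurations reach numerically zero stress.
#'
#' @param d a `dist` of dissimilarities, n >= k + 1 points.
#' @param k target dimension (default 2).
#' @param restarts number of random starts in addition to the metric start.
#' @param seed integer seed controlling the random starts.
#' @return List of class `pads_nmds`: `coordinates` (n x k matrix),
#'   `stress` (Kruskal stress-1), `n_restarts_used`, `converged`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1) stop_input("need at least k + 1 = ", k + 1, " samples")
  fit_one <- function(init) {
    vegan::monoMDS(d, y = init, k = k, model = "global",
                   maxit = 300, smin = 1e-9, sfgrmin = 1e-9,
                   sratmax = 1 - 1e-9)
  }
  ## metric-scaling start; add = TRUE guards against negative eigenvalues
  init0 <- suppressWarnings(stats::cmdscale(d, k = k, add = TRUE)$points)
  if (ncol(init0) < k)  # degenerate (e.g. all-equal) distances
    init0 <- cbind(init0, matrix(0, n, k - ncol(init0)))
  best <- fit_one(init0)
  seeds <- spawn_seeds(seed, max(restarts, 0))
  for (i in seq_len(max(restarts, 0))) {
    cand <- fit_one(with_seed(seeds[i], matrix(stats::rnorm(n * k), n, k)))
    if (cand$stress < best$stress) best <- cand
  }
  coords <- best$points
  rownames(coords) <- attr(d, "Labels")
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(coordinates = coords,
                 stress = best$stress,
                 n_restarts_used = max(restarts, 0) + 1L,
                 converged = best$icause != 1L || best$stress < 1e-6),
            class = "pads_nmds")
}

#' @export
print.pads_nmds <- function(x, ...) {
  cat("NMDS ordination: ", nrow(x$coordinates), " samples, k = ",
      ncol(x$coordinates), ", stress-1 = ", signif(x$stress, 4),
      " (best of ", x$n_restarts_used, " starts)\n", sep = "")
  invisible(x)
}

#' Multivariate beta-dispersion with permutation test
#'
#' Quantifies between-community variation as each sample's distance to its
#' group centroid in the principal-coordinate embedding of the
#' dissimilarity matrix, with squared contributions from negative-eigenvalue
#' axes subtracted (floored at zero before the square root) — the
#' multivariate homogeneity-of-dispersions construction. Group differences
#' are tested by one-way ANOVA on the centroid distances; because those
#' distances are not exactly normal, a permutation p-value (group labels
#' permuted) is reported alongside the parametric one.
#'
#' @param d a `dist` of dissimilarities.
#' @param groups vector of group labels, one per sample (>= 2 groups of
#'   >= 2 samples).
#' @param n_permutations permutations for the label-permutation test.
#' @param seed integer seed for the permutations.
#' @return List of class `pads_dispersion`: `distances` (per-sample distance
#'   to group centroid), `group_means`, `F`, `p_parametric`, `p_perm`,
#'   `n_permutations`.
#' @export
beta_dispersion <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop_input("one group label required per sample")
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2))
    stop_input("need >= 2 groups, each with >= 2 samples")
  ## negative squared centroid distances from non-Euclidean axes are
  ## floored at zero by construction; vegan's note about it is expected
  mod <- withCallingHandlers(
    vegan::betadisper(d, groups, type = "centroid"),
    warning = function(w) {
      if (grepl("squared distances are negative", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  an <- stats::anova(mod)
  perm <- with_seed(seed,
    vegan::permutest(mod, permutations = n_permutations))
  structure(list(
    distances = stats::setNames(mod$distances, attr(d, "Labels")),
    groups = groups,
    group_means = tapply(mod$distances, groups, mean),
    F = an$`F value`[1],
    p_parametric = an$`Pr(>F)`[1],
    p_perm = perm$tab$`Pr(>F)`[1],
    n_permutations = n_permutations
  ), class = "pads_dispersion")
}

#' @export
print.pads_dispersion <- function(x, ...) {
  cat("Beta-dispersion (distance to group centroid)\n")
  print(round(x$group_means, 4))
  cat("F = ", signif(x$F, 4), ", parametric p = ",
      signif(x$p_parametric, 3), ", permutation p = ",
      signif(x$p_perm, 3), " (", x$n_permutations, " permutations)\n",
      sep = "")
  invisible(x)
}
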