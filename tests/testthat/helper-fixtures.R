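# In-code fixtures shared across test files.

make_table <- function(counts, stations = NULL, library = "DNA",
                       integer_counts = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(stations)) stations <- colnames(counts)
  meta <- data.frame(sample_id = colnames(counts), station = stations,
                     library = rep_len(library, ncol(counts)))
  count_table(counts, meta, integer_counts = integer_counts)
}

make_qpcr <- function(stations, ct_dna, ct_cdna, reps = 1) {
  recs <- do.call(rbind, lapply(seq_along(stations), function(i)
    data.frame(sample_id = rep(paste0("st", stations[i]), 2),
               station = stations[i], template = c("DNA", "cDNA"))))
  ct <- unlist(lapply(seq_along(stations), function(i)
    list(rep(ct_dna[i], reps), rep(ct_cdna[i], reps))), recursive = FALSE)
  qpcr_table(recs, ct)
}

# Independent Kruskal stress-1 oracle: isotonic regression of the
# configuration distances on the rank order of the input dissimilarities.
stress1_oracle <- function(config, d) {
  dhat <- as.vector(stats::dist(config))
  dv <- as.vector(stats::as.dist(d))
  ord <- order(dv)
  fit <- stats::isoreg(dhat[ord])$yf
  sqrt(sum((dhat[ord] - fit)^2) / sum(dhat^2))
}

# Brute-force NMDS oracle: direct minimisation of stress1_oracle over the
# configuration from many random starts plus the metric-scaling start.
nmds_oracle <- function(d, k = 2, n_starts = 40, seed = 1) {
  n <- attr(stats::as.dist(d), "Size")
  obj <- function(par) stress1_oracle(matrix(par, n, k), d)
  set.seed(seed)
  starts <- c(list(as.vector(suppressWarnings(
    stats::cmdscale(d, k = k, add = TRUE)$points[, 1:k]))),
    replicate(n_starts, stats::rnorm(n * k), simplify = FALSE))
  best <- Inf
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (fit$value < best) best <- fit$value
  }
  best
}

proportions_of_tab <- function(tab) {
  sweep(tab$counts, 2, colSums(tab$counts), "/")
}

default_tax <- function(spec = community_spec()) {
  stats::setNames(spec$taxa$group, spec$taxa$taxon_id)
}
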