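#' Rarefy each sample once to a common depth
#'
#' Subsamples every library without replacement (multivariate hypergeometric
#' draw) to exactly `depth` reads, removing depth-driven bias before
#' diversity estimation. With-replacement multinomial subsampling is
#' available via `replace = TRUE` but is not the default: a sequencing
#' library is a finite pool of reads.
#'
#' @param table a [count_table()] with integer counts.
#' @param depth target reads per sample; `"auto"` uses the smallest column
#'   sum.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param replace logical, subsample with replacement (multinomial).
#' @return A [count_table()] whose columns each sum to exactly `depth`; no
#'   OTU exceeds its original count (without replacement) and zero counts
#'   stay zero.
#' @export
rarefy_once <- function(table, depth = "auto", seed = NULL, replace = FALSE) {
  stopifnot(inherits(table, "count_table"))
  if (!table$integer_counts)
    stop_input("rarefaction requires integer counts")
  depth <- resolve_depth(table, depth)
  counts <- with_seed(seed,
    vapply(seq_len(ncol(table$counts)), function(j)
      subsample_column(table$counts[, j], depth, replace),
      numeric(nrow(table$counts))))
  counts <- matrix(counts, nrow = nrow(table$counts),
                   dimnames = dimnames(table$counts))
  count_table(counts, table$sample_meta)
}

resolve_depth <- function(table, depth) {
  cs <- colSums(table$counts)
  if (identical(depth, "auto")) depth <- min(cs)
  if (!is_wholenumber(depth) || depth < 1)
    stop_input("'depth' must be a positive integer or \"auto\"")
  low <- cs < depth
  if (any(low))
    stop_input("sample(s) below depth ", depth, ": ",
               paste(colnames(table$counts)[low], collapse = ", "))
  as.integer(depth)
}

subsample_column <- function(x, depth, replace = FALSE) {
  n <- sum(x)
  if (!replace && n == depth) return(x)
  if (replace) {
    as.vector(stats::rmultinom(1, depth, x / n))
  } else {
    drawn <- sample.int(n, depth)
    ## reads 1..n laid out by OTU in order; count how many land in each bin
    bins <- findInterval(drawn, cumsum(x) - x + 1)
    tabulate(bins, nbins = length(x))
  }
}

#' Repeated rarefaction: entrywise mean over many draws
#'
#' Averages `iterations` independent [rarefy_once()] draws. Column sums of
#' the mean table equal `depth` exactly (means of constant-sum draws); the
#' real-valued means are carried downstream unrounded, since the diversity
#' and frequency computations operate on proportions. Chao1 alone needs
#' integer singleton/doubleton counts and is therefore computed
#' per-iteration by [chao1_rarefied()].
#'
#' @inheritParams rarefy_once
#' @param iterations number of independent draws to average (default 100).
#' @return A [count_table()] with real-valued entries
#'   (`integer_counts = FALSE`).
#' @export
rarefy_repeated <- function(table, depth = "auto", iterations = 100,
                            seed = NULL, replace = FALSE) {
  stopifnot(inherits(table, "count_table"))
  if (!is_wholenumber(iterations) || iterations < 1)
    stop_input("'iterations' must be a positive integer")
  depth <- resolve_depth(table, depth)
  acc <- matrix(0, nrow(table$counts), ncol(table$counts))
  with_seed(seed, {
    for (i in seq_len(iterations)) {
      acc <- acc + rarefy_once(table, depth, seed = NULL,
                               replace = replace)$counts
    }
  })
  acc <- acc / iterations
  dimnames(acc) <- dimnames(table$counts)
  count_table(acc, table$sample_meta, integer_counts = FALSE)
}
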