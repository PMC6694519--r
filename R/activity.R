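#' Rank OTUs by aggregated normalized reads
#'
#' Ranks OTUs by the sum of their (normalized) reads across all samples of
#' both the DNA and the RNA tables, the criterion used to pick the most
#' abundant OTUs for phylogenetic placement and frequency comparison. The
#' OTU universe is the union of the two tables (missing rows count as 0);
#' ties break lexicographically by OTU id for determinism.
#'
#' @param dna,rna [count_table()] objects (integer or rarefied-mean).
#' @param n number of top OTUs to keep (default 20); truncated with a
#'   warning if it exceeds the number of OTUs.
#' @return data.frame: `otu_id`, `aggregated_reads`, `rank`,
#'   `cumulative_fraction` (of all reads in both tables).
#' @export
rank_abundant_otus <- function(dna, rna, n = 20) {
  stopifnot(inherits(dna, "count_table"), inherits(rna, "count_table"))
  otus <- union(rownames(dna$counts), rownames(rna$counts))
  agg <- stats::setNames(numeric(length(otus)), otus)
  add <- function(tab) {
    s <- rowSums(tab$counts)
    agg[names(s)] <<- agg[names(s)] + s
  }
  add(dna); add(rna)
  if (n > length(otus)) {
    warning("n = ", n, " exceeds the ", length(otus),
            " available OTUs; truncated", call. = FALSE)
    n <- length(otus)
  }
  ord <- order(-agg, names(agg))
  total <- sum(agg)
  out <- data.frame(otu_id = names(agg)[ord],
                    aggregated_reads = unname(agg[ord]),
                    rank = seq_along(ord),
                    cumulative_fraction = cumsum(unname(agg[ord])) / total,
                    row.names = NULL)
  out[seq_len(n), , drop = FALSE]
}

#' Per-sample and per-library taxonomic group frequencies
#'
#' Sums per-sample relative abundances within taxonomic groups. Because the
#' taxonomy map is total (unassigned OTUs fall in the explicit `"other"`
#' group), the frequencies of each sample sum to 1. Also returns
#' across-sample averages per library type — the "whole" bars of a
#' composition plot and the f values entering the group expression ratio in
#' averaged-frequency mode.
#'
#' @param table a [count_table()].
#' @param tax named character vector `otu_id -> group` covering the table
#'   (from [read_taxonomy()] or built in code).
#' @return List of class `group_frequencies`: `per_sample` (group x sample
#'   matrix of proportions), `average` (group x library-type matrix),
#'   `sample_meta`.
#' @export
group_frequencies <- function(table, tax) {
  stopifnot(inherits(table, "count_table"))
  otus <- rownames(table$counts)
  missing <- setdiff(otus, names(tax))
  if (length(missing) > 0)
    stop_input("taxonomy map does not cover OTU(s): ",
               paste(utils::head(missing, 3), collapse = ", "))
  p <- proportions_of(table)
  g <- factor(tax[otus])
  per_sample <- rowsum(p, g)
  per_sample <- as.matrix(per_sample)
  libs <- unique(table$sample_meta$library)
  average <- vapply(libs, function(l)
    rowMeans(per_sample[, table$sample_meta$library == l, drop = FALSE]),
    numeric(nrow(per_sample)))
  structure(list(per_sample = per_sample,
                 average = average,
                 sample_meta = table$sample_meta),
            class = "group_frequencies")
}

#' Classify DNA:RNA frequency proportionality of an OTU or group
#'
#' Compares a taxon's relative abundance in the DNA library (presence) and
#' the RNA library (activity) against the 1:1 line. Within `threshold`-fold
#' of proportionality the taxon is `"proportional"`; beyond it the taxon is
#' `"RNA-enriched"` or `"DNA-enriched"`. A taxon present in only one
#' library is classified to its nonzero side; absent from both is
#' `"undefined"`. The 2-fold default threshold is a package choice — the
#' underlying comparison draws only the 1:1 line.
#'
#' @param f_dna,f_rna frequencies in [0, 1] (vectorised).
#' @param threshold fold-change defining the proportional band (> 1).
#' @return character vector over
#'   `{proportional, RNA-enriched, DNA-enriched, undefined}`.
#' @export
classify_proportionality <- function(f_dna, f_rna, threshold = 2) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 1)
    stop_input("'threshold' must be a single fold-change > 1")
  if (any(f_dna < 0 | f_dna > 1 | f_rna < 0 | f_rna > 1, na.rm = TRUE))
    stop_input("frequencies must lie in [0, 1]")
  out <- rep("undefined", max(length(f_dna), length(f_rna)))
  f_dna <- rep_len(f_dna, length(out))
  f_rna <- rep_len(f_rna, length(out))
  only_rna <- f_dna == 0 & f_rna > 0
  only_dna <- f_rna == 0 & f_dna > 0
  both <- f_dna > 0 & f_rna > 0
  lr <- log2(f_rna[both] / f_dna[both])
  cls <- ifelse(abs(lr) <= log2(threshold), "proportional",
                ifelse(lr > 0, "RNA-enriched", "DNA-enriched"))
  out[both] <- cls
  out[only_rna] <- "RNA-enriched"
  out[only_dna] <- "DNA-enriched"
  out
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' E = 10^(-1 / slope), with the slope in cycles per log10 template copies
#' from a dilution series; a slope of -3.3219 corresponds to perfect
#' doubling (E = 2).
#'
#' @param slope standard-curve slope (must be negative).
#' @return Amplification efficiency E (fold per cycle, 1 < E <= ~2).
#' @export
efficiency_from_slope <- function(slope) {
  if (!is.numeric(slope) || any(!is.finite(slope)) || any(slope >= 0))
    stop_input("standard-curve slope must be negative")
  10^(-1 / slope)
}

#' Bulk community RNA/DNA expression ratio from qPCR
#'
#' For each sample with both templates measured, technical replicates are
#' averaged on the Ct scale (standard qPCR practice), dCt = mean Ct(DNA) -
#' mean Ct(cDNA), and R_bulk = E^dCt. With this sign convention more
#' transcript means a lower cDNA Ct and hence R_bulk > 1. Samples missing a
#' template are excluded with a warning rather than an error, so a partial
#' qPCR plate still yields ratios for the complete samples.
#'
#' @param qpcr a `qpcr_table` (see [read_qpcr()]).
#' @param efficiency amplification efficiency E (default 2, perfect
#'   doubling), or use [efficiency_from_slope()].
#' @param samples optional character vector restricting the samples.
#' @return data.frame: `sample_id`, `station`, `efficiency`, `ct_dna`,
#'   `ct_cdna`, `delta_ct`, `r_bulk`.
#' @export
bulk_expression_ratio <- function(qpcr, efficiency = 2, samples = NULL) {
  stopifnot(inherits(qpcr, "qpcr_table"))
  if (!is.numeric(efficiency) || length(efficiency) != 1 ||
      !is.finite(efficiency) || efficiency <= 1)
    stop_input("'efficiency' must be a single value > 1")
  ids <- unique(qpcr$sample_id)
  if (!is.null(samples)) ids <- intersect(ids, samples)
  rows <- lapply(ids, function(id) {
    sub <- qpcr[qpcr$sample_id == id, , drop = FALSE]
    ct_d <- sub$ct[sub$template == "DNA"]
    ct_c <- sub$ct[sub$template == "cDNA"]
    if (length(ct_d) == 0 || length(ct_c) == 0) {
      warning("sample '", id, "' missing template ",
              if (length(ct_d) == 0) "DNA" else "cDNA",
              "; excluded from expression ratios", call. = FALSE)
      return(NULL)
    }
    m_d <- mean(unlist(ct_d))
    m_c <- mean(unlist(ct_c))
    data.frame(sample_id = id, station = sub$station[1],
               efficiency = efficiency, ct_dna = m_d, ct_cdna = m_c,
               delta_ct = m_d - m_c,
               r_bulk = efficiency^(m_d - m_c))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop_input("no sample has both DNA and cDNA templates")
  rownames(out) <- NULL
  out
}

#' Group-level RNA/DNA expression ratio
#'
#' Distributes the bulk community expression ratio over taxonomic groups by
#' their library frequencies: R_group = R_bulk * f_RNA / f_DNA. Undefined
#' (returned as `NA`) when f_DNA = 0 — the group was never observed in the
#' DNA library, so its per-gene-copy activity has no denominator.
#'
#' @param r_bulk bulk ratio(s), > 0.
#' @param f_rna,f_dna group frequencies in the RNA / DNA library of the same
#'   sample (or library-averaged frequencies), in [0, 1].
#' @return Numeric vector of R_group, `NA` where f_DNA = 0.
#' @export
group_expression_ratio <- function(r_bulk, f_rna, f_dna) {
  if (any(!is.finite(r_bulk)) || any(r_bulk <= 0))
    stop_input("'r_bulk' must be positive")
  if (any(f_rna < 0, na.rm = TRUE) || any(f_dna < 0, na.rm = TRUE))
    stop_input("frequencies must be non-negative")
  out <- r_bulk * f_rna / f_dna
  out[f_dna == 0] <- NA_real_
  out
}

#' Per-sample expression ratio table for all groups
#'
#' Combines the bulk qPCR ratios with the group frequencies of the matching
#' station's DNA and RNA libraries to produce the full group x sample
#' expression-ratio table. By default each station uses its own library
#' frequencies; `average_frequencies = TRUE` instead applies the
#' library-averaged frequencies of every group to every station's bulk
#' ratio.
#'
#' @param bulk data.frame from [bulk_expression_ratio()].
#' @param freq_dna,freq_rna `group_frequencies` of the DNA and RNA tables.
#' @param average_frequencies use across-station average frequencies in
#'   place of station-matched ones.
#' @return data.frame: `station`, `group`, `f_dna`, `f_rna`, `r_bulk`,
#'   `r_group` (`NA` where f_DNA = 0).
#' @export
expression_ratio_table <- function(bulk, freq_dna, freq_rna,
                                   average_frequencies = FALSE) {
  stopifnot(inherits(freq_dna, "group_frequencies"),
            inherits(freq_rna, "group_frequencies"))
  groups <- union(rownames(freq_dna$per_sample),
                  rownames(freq_rna$per_sample))
  get_f <- function(gf, station) {
    if (average_frequencies) {
      f <- gf$average[, 1]
    } else {
      j <- which(gf$sample_meta$station == station)
      if (length(j) != 1)
        stop_input("station '", station,
                   "' does not map to exactly one library in the table")
      f <- gf$per_sample[, j]
    }
    out <- stats::setNames(numeric(length(groups)), groups)
    out[names(f)] <- f
    out
  }
  rows <- lapply(seq_len(nrow(bulk)), function(i) {
    st <- bulk$station[i]
    fd <- get_f(freq_dna, st)
    fr <- get_f(freq_rna, st)
    data.frame(station = st, group = groups,
               f_dna = unname(fd), f_rna = unname(fr),
               r_bulk = bulk$r_bulk[i],
               r_group = group_expression_ratio(bulk$r_bulk[i], fr, fd),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
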