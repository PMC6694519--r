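#' Specify a synthetic paired DNA/RNA diazotroph community
#'
#' Defines the ground truth from which paired amplicon libraries and qPCR
#' records are simulated: per-taxon relative DNA abundance d_i (summing to
#' 1) and activity multiplier r_i >= 0 (per-gene-copy transcription level,
#' so the station's true bulk RNA/DNA ratio is sum d_i r_i). The default
#' community mimics an oligotrophic-ocean plankton-associated diazotroph
#' assemblage: one hyperdominant filamentous cyanobacterium (~98% of DNA
#' reads, moderately active), rare but highly active heterocystous and
#' unicellular cyanobacteria and proteobacteria, and present-but-silent
#' cluster III / Betaproteobacteria taxa.
#'
#' @param taxa data.frame with columns `taxon_id`, `group`, `d` (relative
#'   DNA abundance, sums to 1), `r` (activity multiplier >= 0).
#' @param n_stations number of stations, each yielding one DNA and one RNA
#'   library (default 9).
#' @param library_size reads per library (default 4746).
#' @param station_effect_sd sd of the log-normal station perturbation of d.
#' @param rna_dispersion_sd sd of the log-normal station jitter on r; this
#'   is the knob that makes active communities more variable (higher
#'   beta-dispersion) than total ones.
#' @param ct_noise_sd sd (cycles) of Gaussian technical noise on each Ct
#'   replicate (default 0.15).
#' @param efficiency qPCR amplification efficiency E (> 1, default 2).
#' @param ct_anchor baseline Ct at unit template signal (default 15
#'   cycles; arbitrary but fixed so simulated plates are stable).
#' @param n_replicates technical qPCR replicates per sample/template.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(taxa = default_taxa(),
                           n_stations = 9,
                           library_size = 4746,
                           station_effect_sd = 0.3,
                           rna_dispersion_sd = 0.5,
                           ct_noise_sd = 0.15,
                           efficiency = 2,
                           ct_anchor = 15,
                           n_replicates = 3) {
  need <- c("taxon_id", "group", "d", "r")
  if (!is.data.frame(taxa) || !all(need %in% names(taxa)))
    stop_input("taxa must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(taxa$taxon_id)) stop_input("duplicate taxon_id")
  if (any(taxa$d < 0) || abs(sum(taxa$d) - 1) > 1e-9)
    stop_input("'d' must be non-negative and sum to 1")
  if (any(taxa$r < 0)) stop_input("'r' must be >= 0")
  if (all(taxa$r * taxa$d == 0))
    stop_input("at least one taxon needs d * r > 0 (RNA library undefined)")
  if (!is_wholenumber(n_stations) || n_stations < 1)
    stop_input("'n_stations' must be a positive integer")
  if (!is_wholenumber(library_size) || library_size < 1)
    stop_input("'library_size' must be a positive integer")
  if (efficiency <= 1) stop_input("'efficiency' must be > 1")
  structure(list(taxa = taxa, n_stations = n_stations,
                 library_size = library_size,
                 station_effect_sd = station_effect_sd,
                 rna_dispersion_sd = rna_dispersion_sd,
                 ct_noise_sd = ct_noise_sd, efficiency = efficiency,
                 ct_anchor = ct_anchor, n_replicates = n_replicates),
            class = "community_spec")
}

#' Default synthetic community
#'
#' Eight taxa whose abundances and activity multipliers echo the printed
#' magnitudes of a field survey of plankton-associated diazotrophs: the
#' dominant taxon holds ~97.9% of DNA reads and exactly 87% of the
#' ground-truth RNA proportions (activity 0.1607), the heterocystous group
#' is rare (0.4%) but highly active (r = 3.51), unicellular cyanobacteria
#' are rarer still with the strongest enrichment (0.01% of DNA, ~0.5% of
#' RNA), and cluster III / Betaproteobacteria are present (1.11% / 0.33%)
#' but exactly silent (r = 0; their expression is undetectable, so a
#' nonzero token activity would be a different community). The implied
#' base bulk RNA/DNA ratio sum(d * r) is ~0.181.
#'
#' @return data.frame usable as the `taxa` argument of [community_spec()].
#' @export
default_taxa <- function() {
  data.frame(
    taxon_id = c("OTU_tricho", "OTU_het", "OTU_ucyn", "OTU_gamma",
                 "OTU_delta", "OTU_cl3", "OTU_beta", "OTU_other"),
    group = c("Trichodesmium", "heterocystous cyanobacteria",
              "unicellular cyanobacteria", "Gammaproteobacteria",
              "Deltaproteobacteria", "cluster III", "Betaproteobacteria",
              "other"),
    d = c(0.9789, 0.004, 0.0001, 0.001, 0.001, 0.0111, 0.0033, 0.0006),
    r = c(0.1606, 3.51, 8.5, 4, 4, 0, 0, 1)
  )
}

#' Ground-truth expression ratios implied by a community spec
#'
#' At the proportion level the group ratio identity is exact: with
#' f_DNA,i = d_i / sum d and f_RNA,i = d_i r_i / sum d_j r_j, one has
#' R_bulk * f_RNA,i / f_DNA,i = r_i for every taxon with d_i > 0.
#'
#' @param spec a [community_spec()].
#' @return List: `r_bulk_true` (= sum d_i r_i / sum d_i), `taxa`
#'   (data.frame with `taxon_id`, `group`, `d`, `r`, `f_dna`, `f_rna`).
#' @export
ground_truth_ratios <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  t <- spec$taxa
  r_bulk <- sum(t$d * t$r) / sum(t$d)
  f_dna <- t$d / sum(t$d)
  f_rna <- t$d * t$r / sum(t$d * t$r)
  list(r_bulk_true = r_bulk,
       taxa = data.frame(taxon_id = t$taxon_id, group = t$group,
                         d = t$d, r = t$r, f_dna = f_dna, f_rna = f_rna))
}

#' Simulate paired DNA/RNA amplicon count tables
#'
#' Per station, DNA proportions are the spec's d perturbed by a log-normal
#' station effect (renormalised), activity multipliers are r jittered
#' log-normally (the active community's extra dispersion), and RNA
#' proportions are proportional to d_i r_i. Reads are drawn multinomially
#' at `library_size` — modelling amplicon read sampling with replacement;
#' the pipeline's rarefaction then subsamples those reads without
#' replacement, a distinct role. `exact = TRUE` skips both noise and read
#' sampling and stores the exact proportions as real-valued tables (the
#' noiseless, infinite-depth limit used for algebraic-recovery checks).
#'
#' @param spec a [community_spec()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @param exact logical; emit exact proportions with no station effects.
#' @return List of class `pads_sim`: `dna`, `rna` ([count_table()]s),
#'   `qpcr` (`qpcr_table`), `truth` (per-station list with `d`, `r`,
#'   `r_bulk_true` and per-taxon frequencies), `spec`.
#' @export
simulate_pads <- function(spec, seed = NULL, exact = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(seed, {
    stations <- make_station_ids(spec$n_stations)
    nt <- nrow(spec$taxa)
    dna <- rna <- matrix(0, nt, spec$n_stations,
                         dimnames = list(spec$taxa$taxon_id,
                                         paste0(stations, "_x")))
    truth <- vector("list", spec$n_stations)
    names(truth) <- stations
    for (s in seq_len(spec$n_stations)) {
      if (exact) {
        d_s <- spec$taxa$d
        r_s <- spec$taxa$r
      } else {
        ## mean-one lognormal jitters keep E[d_s] and E[r_s] at the spec
        d_s <- spec$taxa$d *
          exp(stats::rnorm(nt, -spec$station_effect_sd^2 / 2,
                           spec$station_effect_sd))
        d_s <- d_s / sum(d_s)
        r_s <- spec$taxa$r *
          exp(stats::rnorm(nt, -spec$rna_dispersion_sd^2 / 2,
                           spec$rna_dispersion_sd))
      }
      p_rna <- d_s * r_s
      p_rna <- p_rna / sum(p_rna)
      if (exact) {
        dna[, s] <- d_s
        rna[, s] <- p_rna
      } else {
        dna[, s] <- stats::rmultinom(1, spec$library_size, d_s)
        rna[, s] <- stats::rmultinom(1, spec$library_size, p_rna)
      }
      truth[[s]] <- list(d = d_s, r = r_s,
                         f_dna = d_s / sum(d_s), f_rna = p_rna,
                         r_bulk_true = sum(d_s * r_s) / sum(d_s))
    }
    dna_tab <- make_library_table(dna, stations, "DNA")
    rna_tab <- make_library_table(rna, stations, "RNA")
    qpcr <- simulate_qpcr(spec, truth, seed = NULL, exact = exact)
    structure(list(dna = dna_tab, rna = rna_tab, qpcr = qpcr,
                   truth = truth, spec = spec),
              class = "pads_sim")
  })
}

make_station_ids <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)] else sprintf("S%02d", seq_len(n))
}

make_library_table <- function(m, stations, library) {
  colnames(m) <- paste0("st", stations, "_", library)
  meta <- data.frame(sample_id = colnames(m), station = stations,
                     library = library)
  count_table(m, meta, integer_counts = all(abs(m - round(m)) < 1e-12))
}

#' Simulate qPCR Ct records from ground truth
#'
#' Per station, the DNA template signal is taken as 1 (arbitrary units) and
#' the cDNA signal as R_bulk_true, so Ct(DNA) = ct_anchor and Ct(cDNA) =
#' ct_anchor - log_E(R_bulk_true); each template gets `n_replicates`
#' technical replicates with independent Gaussian noise of sd
#' `ct_noise_sd` (zero noise when `exact = TRUE`). Inverting the delta-Ct
#' formula on noiseless replicates recovers R_bulk_true exactly.
#'
#' @param spec a [community_spec()].
#' @param truth per-station truth list as built by [simulate_pads()].
#' @param seed integer seed.
#' @param exact logical; suppress Ct noise.
#' @return A `qpcr_table` with one DNA and one cDNA record per station.
#' @export
simulate_qpcr <- function(spec, truth, seed = NULL, exact = FALSE) {
  stopifnot(inherits(spec, "community_spec"))
  e <- spec$efficiency
  sd <- if (exact) 0 else spec$ct_noise_sd
  with_seed(seed, {
    recs <- list(); ct <- list(); k <- 0
    for (st in names(truth)) {
      r_true <- truth[[st]]$r_bulk_true
      ct_dna <- spec$ct_anchor
      ct_cdna <- spec$ct_anchor - log(r_true, base = e)
      for (tmpl in c("DNA", "cDNA")) {
        k <- k + 1
        base_ct <- if (tmpl == "DNA") ct_dna else ct_cdna
        recs[[k]] <- data.frame(sample_id = paste0("st", st),
                                station = st, template = tmpl)
        ct[[k]] <- base_ct + stats::rnorm(spec$n_replicates, 0, sd)
      }
    }
    qpcr_table(do.call(rbind, recs), ct)
  })
}

#' @export
print.pads_sim <- function(x, ...) {
  cat("Synthetic paired nifH dataset: ", x$spec$n_stations,
      " stations x {DNA, RNA}, ", nrow(x$spec$taxa), " taxa, ",
      x$spec$library_size, " reads/library\n", sep = "")
  cat("  true bulk RNA/DNA ratios: ",
      paste(signif(range(vapply(x$truth, `[[`, numeric(1), "r_bulk_true")),
                   3), collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset as the four standard input files plus truth
#'
#' Writes `dna_counts.tsv`, `rna_counts.tsv`, `sample_meta.tsv`,
#' `taxonomy.tsv`, `qpcr.csv` and `truth.tsv` into `dir`, the exact layout
#' [run_pipeline()] consumes.
#'
#' @param sim a `pads_sim` from [simulate_pads()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_pads_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "pads_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dna = file.path(dir, "dna_counts.tsv"),
             rna = file.path(dir, "rna_counts.tsv"),
             meta = file.path(dir, "sample_meta.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             qpcr = file.path(dir, "qpcr.csv"),
             truth = file.path(dir, "truth.tsv"))
  meta <- rbind(sim$dna$sample_meta, sim$rna$sample_meta)
  write_count_table(sim$dna, paths["dna"], paths["meta"])
  write_count_table(sim$rna, paths["rna"], paths["meta"])
  utils::write.table(meta, paths["meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_taxonomy(stats::setNames(sim$spec$taxa$group,
                                 sim$spec$taxa$taxon_id),
                 paths["taxonomy"])
  write_qpcr(sim$qpcr, paths["qpcr"])
  truth_df <- do.call(rbind, lapply(names(sim$truth), function(st) {
    tr <- sim$truth[[st]]
    data.frame(station = st, taxon_id = sim$spec$taxa$taxon_id,
               d = tr$d, r = tr$r, f_dna = tr$f_dna, f_rna = tr$f_rna,
               r_bulk_true = tr$r_bulk_true)
  }))
  utils::write.table(truth_df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
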