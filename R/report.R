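#' Run the full file-based analysis pipeline
#'
#' Orchestrates normalize -> alpha -> beta -> activity on declared input
#' files and writes every stage's outputs plus a run manifest. The
#' configuration is either a YAML file or an equivalent named list with
#' elements `dna_counts`, `rna_counts`, `sample_meta`, `taxonomy`
#' (paths; `qpcr` optional) and any of the parameters of
#' [pads_activity()] (`depth`, `iterations`, `efficiency`, `top_n`,
#' `fold_threshold`, `n_permutations`, `average_frequencies`, `seed`).
#' Sample-id consistency across inputs is checked before any computation;
#' a missing qPCR file downgrades gracefully — alpha and beta stages run,
#' the expression stage is skipped with a notice. Re-running with the same
#' config and seed reproduces every output byte for byte; no stage mutates
#' an input file.
#'
#' @param config path to a YAML config or a named list.
#' @param out_dir output directory (default `"pads_results"`), created if
#'   needed.
#' @return The fitted [pads_activity()] object, invisibly, with the output
#'   paths in `attr(, "paths")`.
#' @export
run_pipeline <- function(config, out_dir = "pads_results") {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_input("'config' must be a list or a YAML path")
  need <- c("dna_counts", "rna_counts", "sample_meta", "taxonomy")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0)
    stop_input("config missing: ", paste(miss, collapse = ", "))
  infiles <- unlist(config[c(need, if (!is.null(config$qpcr)) "qpcr")])
  unreadable <- infiles[!file.exists(infiles)]
  if (length(unreadable) > 0)
    stop_input("input file(s) not found: ",
               paste(unreadable, collapse = ", "))

  dna <- read_count_table(config$dna_counts, config$sample_meta)
  rna <- read_count_table(config$rna_counts, config$sample_meta)
  dna <- subset_library(dna, "DNA")
  rna <- subset_library(rna, "RNA")
  taxonomy <- read_taxonomy(config$taxonomy, combine_tables(
    count_table(dna$counts, dna$sample_meta, dna$integer_counts),
    count_table(rna$counts, rna$sample_meta, rna$integer_counts)))
  qpcr <- if (!is.null(config$qpcr)) read_qpcr(config$qpcr)
  if (is.null(qpcr))
    message("config has no qPCR file: expression ratios will be skipped")

  par_names <- c("depth", "iterations", "efficiency", "top_n",
                 "fold_threshold", "n_permutations", "average_frequencies",
                 "seed")
  args <- c(list(dna = dna, rna = rna, taxonomy = taxonomy, qpcr = qpcr),
            config[intersect(par_names, names(config))])
  fit <- do.call(pads_activity, args)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fit_outputs(fit, out_dir)
  manifest <- list(
    package = "nifhact",
    version = as.character(utils::packageVersion("nifhact")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = fit$params,
    inputs = as.list(tools::md5sum(infiles))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(fit, "paths") <- c(paths, manifest = manifest_path)
  invisible(fit)
}

subset_library <- function(tab, lib) {
  keep <- tab$sample_meta$library == lib
  if (!any(keep)) stop_input("no ", lib, " libraries in table")
  count_table(tab$counts[, keep, drop = FALSE],
              tab$sample_meta[keep, , drop = FALSE],
              integer_counts = tab$integer_counts)
}

write_fit_outputs <- function(fit, out_dir) {
  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stats::setNames(p(f), sub("\\.tsv$", "", f))
  }
  s <- summary(fit)
  paths <- c(
    wt(fit$alpha, "alpha_diversity.tsv"),
    wt(s$contrasts, "alpha_contrasts.tsv"),
    wt(as.data.frame(as.matrix(fit$distances)), "bray_curtis.tsv"),
    wt(data.frame(sample_id = rownames(fit$nmds$coordinates),
                  fit$nmds$coordinates,
                  stress = fit$nmds$stress), "nmds_coordinates.tsv"),
    wt(data.frame(sample_id = names(fit$dispersion$distances),
                  group = fit$dispersion$groups,
                  dist_to_centroid = unname(fit$dispersion$distances)),
       "beta_dispersion.tsv"),
    wt(fit$ranking, "otu_ranking.tsv"),
    wt(s$group_frequencies, "group_frequencies.tsv"),
    wt(fit$proportionality, "proportionality.tsv"))
  if (!is.null(fit$expression)) {
    paths <- c(paths,
               wt(fit$bulk, "bulk_expression.tsv"),
               wt(fit$expression, "group_expression.tsv"))
  }
  summary_path <- p("summary.json")
  jsonlite::write_json(list(
    dispersion = list(F = fit$dispersion$F,
                      p_parametric = fit$dispersion$p_parametric,
                      p_perm = fit$dispersion$p_perm),
    stress = fit$nmds$stress,
    bulk = s$bulk,
    expression = s$expression
  ), summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(paths, summary = summary_path)
}

#' Render a plain-text report of a fitted analysis
#'
#' One diff-friendly document mirroring the analysis figures as tables:
#' alpha contrasts, dispersion summary, average group frequencies, top-OTU
#' ranking with cumulative fraction, proportionality classes, bulk-ratio
#' summary and per-group expression ratios. Group ratios undefined because
#' the group was never observed in a station's DNA library are rendered as
#' `n.d.` with that reason; an empty `other` group is omitted.
#'
#' @param fit a `pads_activity` object.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return Character vector of report lines, invisibly when written.
#' @export
generate_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "pads_activity"))
  s <- summary(fit)
  fmt_tab <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, 4))
    utils::capture.output(print(df, row.names = FALSE))
  }
  lines <- c(
    "Paired nifH DNA/RNA community analysis report",
    strrep("=", 46), "",
    sprintf("Stations: %s | rarefaction depth %d (%d iterations) | seed %s",
            paste(sort(unique(fit$alpha$station)), collapse = ", "),
            fit$params$depth, fit$params$iterations, fit$params$seed), "",
    "Alpha-diversity contrasts (active RNA vs total DNA)",
    fmt_tab(s$contrasts), "",
    sprintf("Beta-dispersion: F = %.4g, parametric p = %.3g, permutation p = %.3g (%d permutations)",
            s$dispersion$F, s$dispersion$p_parametric, s$dispersion$p_perm,
            fit$params$n_permutations),
    sprintf("NMDS stress-1 = %.3g", s$stress), "",
    "Average group frequencies per library")
  freq <- s$group_frequencies
  empty_other <- freq$group == "other" &
    rowSums(freq[c("f_DNA", "f_RNA")], na.rm = TRUE) == 0
  lines <- c(lines, fmt_tab(freq[!empty_other, , drop = FALSE]), "",
             sprintf("Top %d OTUs by aggregated normalized reads (cumulative fraction %.3f)",
                     nrow(s$ranking),
                     s$ranking$cumulative_fraction[nrow(s$ranking)]),
             fmt_tab(s$ranking), "",
             "DNA:RNA proportionality classes",
             utils::capture.output(print(s$proportionality)), "")
  if (!is.null(s$bulk)) {
    expr <- s$expression
    expr$mean_r_group <- ifelse(is.nan(expr$mean_r_group), "n.d.",
                                signif(expr$mean_r_group, 3))
    lines <- c(lines,
      sprintf("Bulk RNA/DNA expression ratio: mean %.3g, range %.3g - %.3g",
              s$bulk$mean, s$bulk$range[1], s$bulk$range[2]), "",
      "Group expression ratios (n.d.: no sequence found in the DNA library)",
      fmt_tab(expr), "")
  } else {
    lines <- c(lines, "Expression stage skipped: no qPCR records supplied.",
               "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
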