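#' Construct an OTU count table
#'
#' The central container of the package: an OTU-by-sample matrix of read
#' counts together with per-sample metadata (station and library type).
#' Orientation is fixed as OTU rows x sample columns; files laid out with
#' samples as rows must be transposed explicitly by the caller — there is no
#' auto-detection, to avoid silent transposition.
#'
#' @param counts numeric matrix, OTUs in rows, samples in columns, with
#'   dimnames. Entries must be non-negative; integral unless
#'   `integer_counts = FALSE` (rarefaction means are real-valued).
#' @param sample_meta data.frame with columns `sample_id`, `station`,
#'   `library` (one of `"DNA"`, `"RNA"`), one row per column of `counts`.
#' @param integer_counts logical; enforce integral counts (default `TRUE`).
#' @return An object of class `count_table`: a list with elements `counts`
#'   (matrix), `sample_meta` (data.frame) and `integer_counts` (flag).
#' @export
count_table <- function(counts, sample_meta, integer_counts = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_input("'counts' must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_input("'counts' must carry OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop_input("duplicate otu_id: ",
               paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                     collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop_input("duplicate sample_id: ",
               paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                     collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("negative or non-finite count at OTU '",
               rownames(counts)[bad[1, 1]], "', sample '",
               colnames(counts)[bad[1, 2]], "'")
  if (integer_counts) {
    bad <- which(abs(counts - round(counts)) > 1e-9, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop_input("non-integer count at OTU '", rownames(counts)[bad[1, 1]],
                 "', sample '", colnames(counts)[bad[1, 2]], "'")
    storage.mode(counts) <- "double"
    counts <- round(counts)
  }
  cs <- colSums(counts)
  if (any(cs <= 0))
    stop_input("sample(s) with zero total reads: ",
               paste(colnames(counts)[cs <= 0], collapse = ", "))
  sample_meta <- validate_sample_meta(sample_meta, colnames(counts))
  structure(list(counts = counts, sample_meta = sample_meta,
                 integer_counts = integer_counts),
            class = "count_table")
}

validate_sample_meta <- function(sample_meta, sample_ids) {
  need <- c("sample_id", "station", "library")
  if (!is.data.frame(sample_meta) || !all(need %in% names(sample_meta)))
    stop_input("sample_meta must be a data.frame with columns ",
               paste(need, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta)[need]
  sample_meta[] <- lapply(sample_meta, as.character)
  if (anyDuplicated(sample_meta$sample_id))
    stop_input("duplicate sample_id in metadata")
  missing <- setdiff(sample_ids, sample_meta$sample_id)
  if (length(missing) > 0)
    stop_input("sample(s) in table missing from metadata: ",
               paste(missing, collapse = ", "))
  bad <- !sample_meta$library %in% c("DNA", "RNA")
  if (any(bad))
    stop_input("library must be 'DNA' or 'RNA' (sample ",
               sample_meta$sample_id[bad][1], ")")
  ## keep metadata in column order of the table
  rownames(sample_meta) <- NULL
  sample_meta[match(sample_ids, sample_meta$sample_id), , drop = FALSE]
}

#' @export
print.count_table <- function(x, ...) {
  cat("OTU count table: ", nrow(x$counts), " OTUs x ", ncol(x$counts),
      " samples (", sum(x$sample_meta$library == "DNA"), " DNA / ",
      sum(x$sample_meta$library == "RNA"), " RNA)\n", sep = "")
  cat("  column sums: ", paste(range(colSums(x$counts)), collapse = "-"),
      if (!x$integer_counts) "  [real-valued rarefaction means]", "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read an OTU count table and its sample metadata
#'
#' The table is tab-delimited, first column `otu_id`, remaining columns one
#' per sample with sample ids in the header. Metadata is tab-delimited with
#' columns `sample_id`, `station`, `library`. Malformed values are rejected
#' with a message naming the offending cell, never coerced.
#'
#' @param path path to the count TSV.
#' @param meta_path path to the metadata TSV.
#' @return A validated [count_table()]; row and column order are preserved
#'   from the file.
#' @export
read_count_table <- function(path, meta_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop_input("count table needs an otu_id column and at least one sample")
  otu_ids <- raw[[1]]
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = list(otu_ids, colnames(mat))))
  bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 1e-9,
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_input("invalid count '", mat[bad[1, 1], bad[1, 2]], "' at OTU '",
               otu_ids[bad[1, 1]], "', sample '", colnames(mat)[bad[1, 2]], "'")
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            check.names = FALSE, colClasses = "character")
  count_table(num, meta)
}

#' Write an OTU count table and its sample metadata
#'
#' Inverse of [read_count_table()]; the round trip is lossless for counts,
#' ids and metadata.
#'
#' @param x a [count_table()].
#' @param path,meta_path output TSV paths.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "count_table"))
  df <- data.frame(otu_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read an OTU-to-group taxonomy map
#'
#' Two-column tab-delimited file (`otu_id`, `group`). The returned map is
#' total over the table's OTUs: ids absent from the file are assigned the
#' explicit catch-all group `"other"` (with a warning stating how many), so
#' group frequencies always sum to 1.
#'
#' @param path path to the taxonomy TSV.
#' @param table the [count_table()] whose OTU universe the map must cover.
#' @return Named character vector `otu_id -> group`, one entry per OTU row
#'   of `table`, in table order.
#' @export
read_taxonomy <- function(path, table) {
  stopifnot(inherits(table, "count_table"))
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0) stop_input("taxonomy file is empty")
  if (ncol(raw) < 2) stop_input("taxonomy file needs columns otu_id, group")
  dup <- raw[[1]][duplicated(raw[[1]])]
  if (length(dup) > 0) {
    conflict <- vapply(unique(dup), function(id)
      length(unique(raw[[2]][raw[[1]] == id])) > 1, logical(1))
    if (any(conflict))
      stop_input("conflicting group assignments for otu_id: ",
                 paste(unique(dup)[conflict], collapse = ", "))
    raw <- raw[!duplicated(raw[[1]]), , drop = FALSE]
  }
  map <- stats::setNames(raw[[2]], raw[[1]])
  otus <- rownames(table$counts)
  out <- stats::setNames(rep("other", length(otus)), otus)
  known <- intersect(otus, names(map))
  out[known] <- map[known]
  n_other <- length(otus) - length(known)
  if (n_other > 0)
    warning(n_other, " OTU(s) absent from taxonomy file assigned to 'other'",
            call. = FALSE)
  out
}

#' Write a taxonomy map
#' @param tax named character vector `otu_id -> group`.
#' @param path output TSV path.
#' @return `tax`, invisibly.
#' @export
write_taxonomy <- function(tax, path) {
  utils::write.table(data.frame(otu_id = names(tax), group = unname(tax)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tax)
}

#' Read qPCR cycle-threshold records
#'
#' CSV with columns `sample_id`, `station`, `template` (`DNA` or `cDNA`) and
#' one or more replicate columns `ct1..ctk`. Technical replicates are
#' retained raw — averaging happens only when the expression ratio is
#' computed, so Ct provenance stays auditable. A station missing its cDNA
#' (or DNA) row is accepted at read time and flagged only when the ratio is
#' requested.
#'
#' @param path path to the CSV.
#' @return A data.frame of class `qpcr_table` with columns `sample_id`,
#'   `station`, `template` and a list-column `ct` of replicate vectors.
#' @export
read_qpcr <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "station", "template")
  if (!all(need %in% names(raw)))
    stop_input("qPCR file needs columns ", paste(need, collapse = ", "))
  ctcols <- setdiff(names(raw), need)
  if (length(ctcols) == 0) stop_input("qPCR file has no Ct columns")
  ct <- lapply(seq_len(nrow(raw)), function(i) {
    v <- suppressWarnings(as.numeric(raw[i, ctcols]))
    v <- v[!is.na(raw[i, ctcols]) & nzchar(trimws(unlist(raw[i, ctcols])))]
    v
  })
  qpcr_table(data.frame(sample_id = raw$sample_id, station = raw$station,
                        template = raw$template), ct)
}

#' Construct a qPCR table from records and replicate lists
#' @param records data.frame with `sample_id`, `station`, `template`.
#' @param ct list of numeric replicate vectors, one per row of `records`.
#' @return A `qpcr_table` data.frame.
#' @export
qpcr_table <- function(records, ct) {
  need <- c("sample_id", "station", "template")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop_input("records must have columns ", paste(need, collapse = ", "))
  if (length(ct) != nrow(records))
    stop_input("one Ct replicate vector required per record")
  bad <- !records$template %in% c("DNA", "cDNA")
  if (any(bad))
    stop_input("template must be 'DNA' or 'cDNA' (sample ",
               records$sample_id[bad][1], ")")
  for (i in seq_along(ct)) {
    v <- ct[[i]]
    if (length(v) < 1 || !is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop_input("Ct replicates for sample '", records$sample_id[i],
                 "' (", records$template[i],
                 ") must be >=1 finite positive values")
  }
  out <- data.frame(sample_id = as.character(records$sample_id),
                    station = as.character(records$station),
                    template = as.character(records$template))
  out$ct <- ct
  class(out) <- c("qpcr_table", "data.frame")
  out
}

#' Write qPCR records
#' @param qpcr a `qpcr_table`.
#' @param path output CSV path.
#' @return `qpcr`, invisibly.
#' @export
write_qpcr <- function(qpcr, path) {
  k <- max(lengths(qpcr$ct))
  reps <- t(vapply(qpcr$ct, function(v) c(v, rep(NA_real_, k - length(v))),
                   numeric(k)))
  colnames(reps) <- paste0("ct", seq_len(k))
  utils::write.table(
    cbind(qpcr[c("sample_id", "station", "template")], reps),
    path, sep = ",", quote = FALSE, row.names = FALSE, na = "")
  invisible(qpcr)
}

## per-sample relative abundances (columns sum to 1)
proportions_of <- function(table) {
  stopifnot(inherits(table, "count_table"))
  sweep(table$counts, 2, colSums(table$counts), "/")
}
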