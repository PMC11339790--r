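# Annotation tables and per-item good/poor summaries.

QUALITY_ITEMS <- c("ic", "blur", "lc", "overall")

#' Packaged annotation counts of the multi-source fundus database
#'
#' Per-dataset counts of poor (0) and good (1) labels for the four quality
#' items (uneven illumination/color, blur, low contrast, overall) across the
#' eight color-fundus sub-databases and the ultrawide-field set, as published
#' with the source database. Label 1 = good quality.
#'
#' @return data.frame with columns `dataset`, `modality`, `item`, `n0`, `n1`
#' @export
mshf_annotation_counts <- function() {
  path <- system.file("extdata", "mshf_annotation_counts.csv",
                      package = "fundusiqa", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summarize annotation counts
#'
#' Pools count rows over the selected datasets and reports, per quality
#' item, the poor/good counts and the good and poor fractions
#' (`frac_good = n1 / (n0 + n1)`).
#'
#' @param counts data.frame with columns `dataset`, `item`, `n0`, `n1`
#' @param datasets character vector of dataset names to pool (default: all)
#' @return data.frame with columns `item`, `n0`, `n1`, `frac_good`, `frac_poor`
#' @export
summarize_counts <- function(counts, datasets = NULL) {
  stopifnot(all(c("dataset", "item", "n0", "n1") %in% names(counts)))
  if (!is.null(datasets)) {
    if (length(datasets) == 0L) stop("empty dataset filter")
    unknown <- setdiff(datasets, unique(counts$dataset))
    if (length(unknown) > 0L) {
      stop("unknown dataset name(s): ", paste(unknown, collapse = ", "))
    }
    counts <- counts[counts$dataset %in% datasets, , drop = FALSE]
  }
  agg <- stats::aggregate(cbind(n0, n1) ~ item, data = counts, FUN = sum)
  agg <- agg[match(intersect(QUALITY_ITEMS, agg$item), agg$item), ]
  agg$frac_good <- agg$n1 / (agg$n0 + agg$n1)
  agg$frac_poor <- agg$n0 / (agg$n0 + agg$n1)
  rownames(agg) <- NULL
  agg
}

#' Summarize an image-level annotation table
#'
#' Counts good/poor labels per quality item for an annotation table (columns
#' `image_path`, `dataset`, `ic`, `blur`, `lc`, `overall`; 1 = good),
#' optionally restricted to a subset of dataset names, reported per dataset
#' and pooled.
#'
#' @param table annotation data.frame
#' @param datasets optional dataset-name filter
#' @return list with `per_dataset` (data.frame `dataset`, `item`, `n0`,
#'   `n1`, `frac_good`) and `pooled` (as [summarize_counts()])
#' @export
summarize_table <- function(table, datasets = NULL) {
  if (nrow(table) == 0L) stop("empty annotation table")
  stopifnot(all(c("dataset", QUALITY_ITEMS) %in% names(table)))
  for (it in QUALITY_ITEMS) {
    if (!all(table[[it]] %in% c(0, 1))) stop("labels must be binary 0/1")
  }
  if (!is.null(datasets)) {
    if (length(datasets) == 0L) stop("empty dataset filter")
    unknown <- setdiff(datasets, unique(table$dataset))
    if (length(unknown) > 0L) {
      stop("unknown dataset name(s): ", paste(unknown, collapse = ", "))
    }
    table <- table[table$dataset %in% datasets, , drop = FALSE]
  }
  counts <- do.call(rbind, lapply(split(table, table$dataset), function(tb) {
    do.call(rbind, lapply(QUALITY_ITEMS, function(it) {
      data.frame(dataset = tb$dataset[1], item = it,
                 n0 = sum(tb[[it]] == 0), n1 = sum(tb[[it]] == 1))
    }))
  }))
  rownames(counts) <- NULL
  counts$frac_good <- counts$n1 / (counts$n0 + counts$n1)
  list(per_dataset = counts, pooled = summarize_counts(counts))
}

#' Read / write an annotation table CSV
#'
#' Annotation tables are CSV files with columns `image_path`, `dataset`,
#' `ic`, `blur`, `lc`, `overall` (0/1, 1 = good).
#'
#' @param path CSV path
#' @param table annotation data.frame
#' @return the table (reader) or the path (writer)
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_path", "dataset", QUALITY_ITEMS)
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L) {
    stop("annotation table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_annotations
#' @export
write_annotations <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
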