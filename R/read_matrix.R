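#' OTU read matrix with replicate metadata
#'
#' The central container of the filtering stage: an OTU-by-replicate matrix
#' of non-negative integer read counts together with one metadata row per
#' column describing what that column is (which sample, which method, which
#' kind of replicate, whether it is a negative control).
#'
#' @param counts integer matrix, rows = OTUs (rownames are OTU ids),
#'   columns = replicates (colnames are replicate ids).
#' @param meta data.frame with one row per column of `counts`, columns
#'   `replicate_id`, `sample_id`, `method` (`"bulk"`, `"edna"` or
#'   `"morphological"`), `replicate_kind` (`"extraction"`, `"filtration"` or
#'   `"pcr"`), `replicate_index` (the PCR replicate this column belongs to;
#'   several pre-merge extraction/filtration columns may share one index) and
#'   `is_control` (logical). Control columns carry `NA` as `sample_id`.
#'
#' @details Counts must be whole and non-negative; every non-control column
#' must map to exactly one sample; control columns must not carry a sample
#' id. Rows and columns are stored in the order given; readers sort
#' lexicographically for reproducible output.
#'
#' @return an object of class `read_matrix`: a list with elements `counts`
#'   and `meta`.
#' @seealso [read_otu_table()], [filter_pipeline()]
#' @export
read_matrix <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have OTU ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have replicate ids as colnames")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("replicate_id", "sample_id", "method", "replicate_kind",
                "replicate_index", "is_control")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L) {
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  }
  meta$is_control <- as.logical(meta$is_control)
  meta$sample_id <- as.character(meta$sample_id)
  meta$sample_id[!is.na(meta$sample_id) & meta$sample_id == ""] <- NA_character_
  if (!identical(as.character(meta$replicate_id), colnames(counts))) {
    meta <- meta[match(colnames(counts), meta$replicate_id), , drop = FALSE]
    if (anyNA(meta$replicate_id)) {
      stop("metadata does not cover every column of the count matrix")
    }
  }
  rownames(meta) <- NULL
  obj <- structure(list(counts = counts, meta = meta), class = "read_matrix")
  validate_read_matrix(obj)
  obj
}

#' @export
print.read_matrix <- function(x, ...) {
  ns <- length(unique(stats::na.omit(x$meta$sample_id)))
  cat(sprintf(
    "read_matrix: %d OTUs x %d replicates (%d samples, %d controls)\n",
    nrow(x$counts), ncol(x$counts), ns, sum(x$meta$is_control)))
  invisible(x)
}

validate_read_matrix <- function(m) {
  cnt <- m$counts
  if (any(is.na(cnt))) stop("counts contain NA")
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (any(abs(cnt - round(cnt)) > 1e-8)) stop("counts must be integer read counts")
  meta <- m$meta
  if (nrow(meta) != ncol(cnt)) stop("one metadata row per count column required")
  bad <- !meta$is_control & (is.na(meta$sample_id))
  if (any(bad)) {
    stop("non-control replicate(s) without sample_id: ",
         paste(meta$replicate_id[bad], collapse = ", "))
  }
  bad <- meta$is_control & !is.na(meta$sample_id)
  if (any(bad)) {
    stop("control replicate(s) must not carry a sample_id: ",
         paste(meta$replicate_id[bad], collapse = ", "))
  }
  # one method per sample
  smp <- meta[!meta$is_control, , drop = FALSE]
  nm <- tapply(smp$method, smp$sample_id, function(z) length(unique(z)))
  if (any(nm > 1L)) {
    stop("mixed methods within sample(s): ",
         paste(names(nm)[nm > 1L], collapse = ", "))
  }
  invisible(m)
}

sample_columns <- function(m, sample) {
  which(!m$meta$is_control & m$meta$sample_id == sample)
}

control_columns <- function(m) which(m$meta$is_control)

sample_ids <- function(m) {
  sort(unique(m$meta$sample_id[!m$meta$is_control]))
}

#' Read an OTU count table from TSV
#'
#' Expects rows = OTUs with the OTU id in the first column, remaining
#' columns one per replicate. Values must be non-negative whole numbers.
#'
#' @param path path to a tab-separated file.
#' @return integer matrix with OTU rownames and replicate colnames.
#' @export
read_otu_table <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated otu_id in ", path)
  cnt <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(cnt) <- "double"
  rownames(cnt) <- ids
  cnt[order(rownames(cnt)), order(colnames(cnt)), drop = FALSE]
}

#' Read replicate metadata from TSV
#'
#' Columns: `replicate_id`, `sample_id`, `method`, `replicate_kind`,
#' `replicate_index`, `is_control`. An empty `sample_id` marks a control.
#'
#' @param path path to a tab-separated file.
#' @return data.frame of replicate metadata.
#' @export
read_replicate_metadata <- function(path) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  meta$is_control <- as.logical(meta$is_control)
  meta[order(meta$replicate_id), , drop = FALSE]
}

#' Read a ranked taxonomy table from TSV
#'
#' Columns: `otu_id` then `phylum`, `class`, `order`, `family`, `genus`,
#' `species`; an empty cell means unassigned at that rank. Lineages may stop
#' at any depth but must not have gaps (a named genus implies a named
#' family, and so on up).
#'
#' @param path path to a tab-separated file.
#' @return data.frame with one row per OTU.
#' @export
read_taxonomy <- function(path) {
  tax <- read.delim(path, stringsAsFactors = FALSE)
  validate_taxonomy(tax)
  tax[order(tax$otu_id), , drop = FALSE]
}

validate_taxonomy <- function(tax) {
  need <- c("otu_id", rev(RANKS))
  missing <- setdiff(need, names(tax))
  if (length(missing) > 0L) {
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tax$otu_id)) stop("duplicated otu_id in taxonomy")
  for (r in rev(RANKS)) {
    tax[[r]][is.na(tax[[r]])] <- ""
  }
  # no gaps: each named rank implies all coarser ranks named
  coarse_to_fine <- rev(RANKS)
  for (i in seq_along(coarse_to_fine)[-1L]) {
    fine <- coarse_to_fine[i]
    coarser <- coarse_to_fine[i - 1L]
    gap <- nzchar(tax[[fine]]) & !nzchar(tax[[coarser]])
    if (any(gap)) {
      stop("taxonomy has rank gaps (", fine, " named but ", coarser,
           " empty) for: ", paste(tax$otu_id[gap], collapse = ", "))
    }
  }
  invisible(tax)
}

#' Deepest assigned rank of each lineage
#'
#' @param tax taxonomy data.frame as returned by [read_taxonomy()].
#' @return character vector (one of `r toString(RANKS)`, or `NA` for a fully
#'   unassigned row), named by `otu_id`.
#' @export
best_rank <- function(tax) {
  out <- rep(NA_character_, nrow(tax))
  for (r in rev(RANKS)) {     # coarse to fine so the finest wins
    named <- !is.na(tax[[r]]) & nzchar(tax[[r]])
    out[named] <- r
  }
  names(out) <- tax$otu_id
  out
}

#' Write a read matrix back to TSV
#'
#' Writes the count table (`otu_table.tsv`) and replicate metadata
#' (`metadata.tsv`) with rows and columns in lexicographic order.
#'
#' @param m a [read_matrix()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_read_matrix <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ord_r <- order(rownames(m$counts))
  ord_c <- order(colnames(m$counts))
  cnt <- m$counts[ord_r, ord_c, drop = FALSE]
  tab <- data.frame(otu_id = rownames(cnt), cnt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  p1 <- file.path(dir, "otu_table.tsv")
  write.table(tab, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(dir, "metadata.tsv")
  meta <- m$meta[order(m$meta$replicate_id), , drop = FALSE]
  write.table(meta, p2, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(c(p1, p2))
}
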