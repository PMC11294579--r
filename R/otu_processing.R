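#' Replicate-consistency retention policy
#'
#' How many PCR replicates an OTU must appear in to be retained. The two
#' policies used in metabarcoding river surveys are shipped as presets:
#' bulk samples require presence in all three PCR replicates
#' (`consistency_policy("bulk")`), eDNA requires at least two of three
#' (`consistency_policy("edna")`).
#'
#' @param min_replicates_present integer, or `"bulk"` / `"edna"` to use a
#'   preset.
#' @param total_replicates integer number of PCR replicates every sample
#'   must have.
#' @return object of class `consistency_policy`.
#' @export
consistency_policy <- function(min_replicates_present, total_replicates = 3L) {
  if (is.character(min_replicates_present)) {
    preset <- match.arg(min_replicates_present, c("bulk", "edna"))
    min_replicates_present <- if (preset == "bulk") 3L else 2L
    total_replicates <- 3L
  }
  m <- as.integer(min_replicates_present)
  k <- as.integer(total_replicates)
  if (is.na(m) || is.na(k) || m < 1L || m > k) {
    stop("need 1 <= min_replicates_present <= total_replicates")
  }
  structure(list(min_replicates_present = m, total_replicates = k),
            class = "consistency_policy")
}

#' Merge extraction (or filtration) replicates into PCR replicates
#'
#' DNA extractions (bulk) or filter membranes (eDNA) are often replicated
#' before PCR; their reads belong to the same PCR-replicate context and are
#' summed per OTU. Columns sharing `(sample_id, replicate_index)` are
#' combined into a single column of kind `"pcr"`; a group of one passes
#' through unchanged, and read totals are conserved. Control columns are
#' not touched here (blanks are aggregated later, at subtraction).
#'
#' @param m a [read_matrix()].
#' @return a [read_matrix()] with one column per (sample, PCR replicate).
#' @export
merge_extraction_replicates <- function(m) {
  validate_read_matrix(m)
  meta <- m$meta
  smp <- which(!meta$is_control)
  key <- paste(meta$sample_id[smp], meta$replicate_index[smp], sep = "\r")
  groups <- split(smp, key)
  # keep the original order of each group's first member
  groups <- groups[order(vapply(groups, min, 1L))]

  new_counts <- vector("list", length(groups))
  new_meta <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    cols <- groups[[i]]
    if (length(cols) == 1L) {
      new_counts[[i]] <- m$counts[, cols, drop = TRUE]
      new_meta[[i]] <- meta[cols, , drop = FALSE]
    } else {
      new_counts[[i]] <- rowSums(m$counts[, cols, drop = FALSE])
      row <- meta[cols[1L], , drop = FALSE]
      row$replicate_id <- paste0(row$sample_id, ".pcr", row$replicate_index)
      row$replicate_kind <- "pcr"
      new_meta[[i]] <- row
    }
  }
  ctrl <- which(meta$is_control)
  counts <- do.call(cbind, c(new_counts,
                             if (length(ctrl)) list(m$counts[, ctrl, drop = FALSE])))
  meta_out <- do.call(rbind, c(new_meta,
                               if (length(ctrl)) list(meta[ctrl, , drop = FALSE])))
  colnames(counts) <- meta_out$replicate_id
  if (anyDuplicated(meta_out$replicate_id)) {
    stop("merging produced duplicated replicate ids; check replicate_index values")
  }
  read_matrix(counts, meta_out)
}

#' Retain OTUs consistent across PCR replicates
#'
#' Within each sample, an OTU is kept only if it is present (count at or
#' above `presence_threshold`) in at least `policy$min_replicates_present`
#' of the sample's PCR replicates; otherwise all of its counts in that
#' sample are zeroed. Decisions are per sample: an OTU can survive in one
#' sample and be removed from another. Control columns pass through
#' untouched.
#'
#' With `level = "taxon"`, presence is pooled over all OTUs sharing the same
#' best-rank taxon before the rule is applied, so read support split across
#' OTUs of one taxon still counts (`taxonomy` required). The default
#' `"otu"` applies the rule per OTU for both bulk and eDNA policies.
#'
#' @param m a [read_matrix()] whose sample columns are PCR replicates.
#' @param policy a [consistency_policy()].
#' @param level `"otu"` (default) or `"taxon"`.
#' @param taxonomy taxonomy data.frame, required for `level = "taxon"`.
#' @param presence_threshold minimum count that counts as "present"
#'   (default 1 read).
#' @return filtered [read_matrix()].
#' @export
filter_replicate_consistency <- function(m, policy,
                                         level = c("otu", "taxon"),
                                         taxonomy = NULL,
                                         presence_threshold = 1L) {
  validate_read_matrix(m)
  level <- match.arg(level)
  if (!inherits(policy, "consistency_policy")) {
    stop("policy must be a consistency_policy()")
  }
  if (level == "taxon") {
    if (is.null(taxonomy)) stop("taxonomy required for taxon-level filtering")
    label <- taxon_label(taxonomy)[rownames(m$counts)]
    if (anyNA(label)) stop("taxonomy missing for some OTUs")
  }
  counts <- m$counts
  for (s in sample_ids(m)) {
    cols <- sample_columns(m, s)
    if (length(cols) != policy$total_replicates) {
      stop(sprintf("sample '%s' has %d PCR replicates but policy expects %d",
                   s, length(cols), policy$total_replicates))
    }
    present <- counts[, cols, drop = FALSE] >= presence_threshold
    if (level == "otu") {
      keep <- rowSums(present) >= policy$min_replicates_present
    } else {
      # taxon present in a replicate if any member OTU is present
      tax_pres <- rowsum(present + 0, label) > 0
      tax_keep <- rowSums(tax_pres) >= policy$min_replicates_present
      keep <- tax_keep[label]
    }
    counts[!keep, cols] <- 0
  }
  read_matrix(counts, m$meta)
}

# label each OTU by its best-rank name and rank (e.g. "family:Baetidae")
taxon_label <- function(taxonomy) {
  br <- best_rank(taxonomy)
  nm <- vapply(seq_len(nrow(taxonomy)), function(i) {
    r <- br[i]
    if (is.na(r)) "unassigned:" else paste0(r, ":", taxonomy[[r]][i])
  }, character(1))
  names(nm) <- taxonomy$otu_id
  nm
}

#' Subtract negative-control reads from every sample
#'
#' Extraction, filtration and PCR blanks reveal reagent and cross-sample
#' contamination. For each OTU, the control columns are aggregated to a
#' single count (`"max"` across blanks by default — conservative — or
#' `"sum"`), which is subtracted from that OTU's count in every non-control
#' column, floored at zero. Control columns are dropped from the output.
#'
#' If the matrix contains no control columns the matrix is returned
#' unchanged with a warning.
#'
#' @param m a [read_matrix()].
#' @param control_aggregation `"max"` or `"sum"`.
#' @return a [read_matrix()] without control columns.
#' @export
subtract_negative_controls <- function(m, control_aggregation = c("max", "sum")) {
  validate_read_matrix(m)
  control_aggregation <- match.arg(control_aggregation)
  ctrl <- control_columns(m)
  if (length(ctrl) == 0L) {
    warning("no control columns present; returning matrix unchanged")
    return(m)
  }
  cc <- m$counts[, ctrl, drop = FALSE]
  agg <- if (control_aggregation == "max") {
    apply(cc, 1L, max)
  } else {
    rowSums(cc)
  }
  keep <- setdiff(seq_len(ncol(m$counts)), ctrl)
  counts <- pmax(m$counts[, keep, drop = FALSE] - agg, 0)
  read_matrix(counts, m$meta[keep, , drop = FALSE])
}

#' Condense a read matrix into per-sample presence/absence taxa lists
#'
#' An OTU counts as present in a sample if it has any reads left in any of
#' the sample's replicates. Present OTUs are named at their deepest assigned
#' rank; OTUs resolving to the same (name, rank) collapse into one entry
#' that retains all contributing OTU ids.
#'
#' @param m a [read_matrix()].
#' @param taxonomy taxonomy data.frame covering every OTU in `m`.
#' @return named list of `taxa_list` data.frames (one per sample, sorted by
#'   sample id), each with columns `taxon`, `rank`, `otu_ids`
#'   (comma-separated) and the sample id as attribute `sample_id`.
#' @export
to_presence_absence <- function(m, taxonomy) {
  validate_read_matrix(m)
  missing <- setdiff(rownames(m$counts), taxonomy$otu_id)
  if (length(missing) > 0L) {
    stop("OTU(s) without taxonomy record: ", paste(missing, collapse = ", "))
  }
  tax <- taxonomy[match(rownames(m$counts), taxonomy$otu_id), , drop = FALSE]
  br <- best_rank(tax)
  out <- list()
  for (s in sample_ids(m)) {
    cols <- sample_columns(m, s)
    present <- which(rowSums(m$counts[, cols, drop = FALSE]) > 0 & !is.na(br))
    if (length(present) == 0L) {
      out[[s]] <- taxa_list(s, character(0), character(0), list())
      next
    }
    name <- vapply(present, function(i) tax[[br[i]]][i], character(1))
    rank <- unname(br[present])
    key <- paste(rank, name, sep = "\r")
    ids <- split(tax$otu_id[present], key)
    first <- !duplicated(key)
    out[[s]] <- taxa_list(s, name[first], rank[first],
                          ids[key[first]])
  }
  out[order(names(out))]
}

#' Construct a per-sample taxa list
#'
#' @param sample_id sample identifier.
#' @param taxon character vector of taxon names.
#' @param rank character vector of ranks, same length.
#' @param otu_ids list of character vectors of contributing OTU ids (or a
#'   character vector, one id per entry).
#' @return a `taxa_list` data.frame sorted by rank depth then name.
#' @export
taxa_list <- function(sample_id, taxon, rank, otu_ids = as.list(taxon)) {
  stopifnot(length(taxon) == length(rank))
  bad <- !rank %in% RANKS
  if (any(bad)) stop("unknown rank(s): ", paste(unique(rank[bad]), collapse = ", "))
  if (is.character(otu_ids)) otu_ids <- as.list(otu_ids)
  ids <- vapply(otu_ids, function(z) paste(sort(unique(z)), collapse = ","),
                character(1))
  df <- data.frame(taxon = as.character(taxon), rank = as.character(rank),
                   otu_ids = ids, stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("taxon", "rank")])) {
    stop("duplicate (taxon, rank) entries in taxa list")
  }
  df <- df[order(match(df$rank, RANKS), df$taxon), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "sample_id") <- sample_id
  class(df) <- c("taxa_list", "data.frame")
  df
}

#' Run the full OTU filtering pipeline
#'
#' Applies, in order: extraction-replicate merging, PCR replicate-consistency
#' filtering, negative-control subtraction, and condensation to
#' presence/absence taxa lists. `subtract_first = TRUE` swaps the middle two
#' steps (subtraction before the consistency check).
#'
#' @param m a [read_matrix()] of raw per-column reads.
#' @param policy a [consistency_policy()] (or `"bulk"` / `"edna"`).
#' @param taxonomy taxonomy data.frame.
#' @param control_aggregation passed to [subtract_negative_controls()];
#'   subtraction is skipped when the matrix has no control columns.
#' @param subtract_first subtract blanks before the consistency filter?
#' @param level,presence_threshold passed to [filter_replicate_consistency()].
#' @return list with elements `read_matrix` (the filtered matrix) and
#'   `taxa_lists` (per-sample presence/absence lists).
#' @export
filter_pipeline <- function(m, policy, taxonomy,
                            control_aggregation = "max",
                            subtract_first = FALSE,
                            level = "otu",
                            presence_threshold = 1L) {
  if (is.character(policy)) policy <- consistency_policy(policy)
  m <- merge_extraction_replicates(m)
  has_controls <- length(control_columns(m)) > 0L
  steps <- if (subtract_first) c("subtract", "consistency") else c("consistency", "subtract")
  for (st in steps) {
    if (st == "subtract") {
      if (has_controls) m <- subtract_negative_controls(m, control_aggregation)
    } else {
      m <- filter_replicate_consistency(m, policy, level = level,
                                        taxonomy = taxonomy,
                                        presence_threshold = presence_threshold)
    }
  }
  list(read_matrix = m, taxa_lists = to_presence_absence(m, taxonomy))
}

#' Write per-sample presence/absence taxa lists to TSV
#'
#' One file per sample (`<sample>_taxa.tsv`) with columns `taxon`, `rank`,
#' `present` (always 1) and `otu_ids`.
#'
#' @param lists named list of `taxa_list` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_taxa_lists <- function(lists, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in names(lists)) {
    df <- as.data.frame(lists[[s]])
    df$present <- if (nrow(df)) 1L else integer(0)
    p <- file.path(dir, paste0(s, "_taxa.tsv"))
    write.table(df[, c("taxon", "rank", "present", "otu_ids")], p,
                sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
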