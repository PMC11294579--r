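#' Tally taxonomic resolution of OTUs behind taxa lists
#'
#' Reports how many OTUs were assigned at each rank (species, genus, family,
#' order, class, phylum). Counts are per OTU, not per collapsed taxon, and
#' each OTU is counted once even if it appears in many samples.
#'
#' @param lists a single `taxa_list` or a (named) list of them, as produced
#'   by [to_presence_absence()].
#' @return list with elements `counts` (named integer vector over ranks,
#'   finest first), `n_otus` (total), `below_species` (OTUs identified at a
#'   coarser rank than species) and `pct_species` (percentage identified to
#'   species level, two decimals).
#' @export
tally_resolution <- function(lists) {
  lists <- as_taxa_list_collection(lists)
  otus_by_rank <- lapply(setNames(RANKS, RANKS), function(r) character(0))
  for (tl in lists) {
    if (nrow(tl) == 0L) next
    for (i in seq_len(nrow(tl))) {
      r <- tl$rank[i]
      ids <- strsplit(tl$otu_ids[i], ",", fixed = TRUE)[[1L]]
      otus_by_rank[[r]] <- c(otus_by_rank[[r]], ids)
    }
  }
  otus_by_rank <- lapply(otus_by_rank, unique)
  # an OTU's rank is fixed by its taxonomy, so ranks cannot overlap; guard anyway
  all_ids <- unlist(otus_by_rank, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("the same OTU appears at two ranks; inconsistent taxa lists")
  }
  counts <- vapply(otus_by_rank, length, integer(1))
  n <- sum(counts)
  below <- n - counts[["species"]]
  list(counts = counts,
       n_otus = n,
       below_species = unname(below),
       pct_species = if (n > 0L) round(100 * counts[["species"]] / n, 2) else NA_real_)
}

as_taxa_list_collection <- function(lists) {
  if (inherits(lists, "taxa_list")) return(list(lists))
  if (!is.list(lists) || !all(vapply(lists, inherits, TRUE, "taxa_list"))) {
    stop("expected a taxa_list or a list of taxa_list objects")
  }
  lists
}

#' Keep only taxa belonging to a whitelisted group
#'
#' Restricts a taxa list to entries whose lineage matches a whitelist taxon
#' at any rank — a species retained because its family is whitelisted, for
#' example. Used twice in the monitoring workflow: first with a
#' macrozoobenthos whitelist, then with the set of IBMWP scoring taxa.
#'
#' @param lists a `taxa_list` or list of them.
#' @param whitelist data.frame with columns `taxon` and `rank`.
#' @param taxonomy taxonomy data.frame used to look up full lineages of the
#'   entries' OTUs.
#' @return object of the same shape as `lists`, entries filtered, order
#'   preserved.
#' @export
filter_to_group <- function(lists, whitelist, taxonomy) {
  if (is.null(whitelist) || nrow(whitelist) == 0L) {
    stop("whitelist must be non-empty")
  }
  single <- inherits(lists, "taxa_list")
  coll <- as_taxa_list_collection(lists)
  wl <- split(normalize_name(whitelist$taxon), whitelist$rank)
  out <- lapply(coll, function(tl) {
    if (nrow(tl) == 0L) return(tl)
    keep <- vapply(seq_len(nrow(tl)), function(i) {
      lineage <- entry_lineage(tl$otu_ids[i], tl$taxon[i], tl$rank[i], taxonomy)
      any(vapply(names(lineage), function(r) {
        nzchar(lineage[[r]]) && !is.null(wl[[r]]) &&
          normalize_name(lineage[[r]]) %in% wl[[r]]
      }, logical(1)))
    }, logical(1))
    sub_taxa_list(tl, keep)
  })
  if (single) out[[1L]] else out
}

# lineage of a taxa-list entry, from its first OTU id (all OTUs collapsed
# into one entry share the lineage at and above the entry's rank)
entry_lineage <- function(otu_ids, taxon, rank, taxonomy) {
  id <- strsplit(otu_ids, ",", fixed = TRUE)[[1L]][1L]
  row <- match(id, taxonomy$otu_id)
  if (is.na(row)) {
    # fall back to the entry itself when taxonomy lacks the OTU
    lin <- setNames(rep("", length(RANKS)), RANKS)
    lin[[rank]] <- taxon
    return(as.list(lin))
  }
  lin <- lapply(setNames(RANKS, RANKS), function(r) {
    v <- taxonomy[[r]][row]
    if (is.na(v)) "" else v
  })
  # blank out ranks finer than the entry's own (they are not part of what
  # was retained)
  finer <- seq_len(match(rank, RANKS) - 1L)
  for (j in finer) lin[[RANKS[j]]] <- ""
  lin
}

sub_taxa_list <- function(tl, keep) {
  out <- tl[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(tl, "sample_id")
  class(out) <- class(tl)
  out
}

#' Read a species checklist from TSV
#'
#' Columns: `species_name`, `category` (`NIS`, `invasive` or `protected`)
#' and optionally `source`. Names must be unique within a category.
#'
#' @param path path to a tab-separated file.
#' @return data.frame checklist.
#' @export
read_checklist <- function(path) {
  cl <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_name", "category") %in% names(cl))) {
    stop("checklist needs columns species_name and category")
  }
  if (any(!nzchar(trimws(cl$species_name)))) stop("empty species_name in checklist")
  if (anyDuplicated(cl[, c("species_name", "category")])) {
    stop("duplicated (species_name, category) in checklist")
  }
  cl
}

#' Read a group whitelist from TSV
#'
#' Columns: `taxon`, `rank`.
#'
#' @param path path to a tab-separated file.
#' @return data.frame whitelist.
#' @export
read_whitelist <- function(path) {
  wl <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "rank") %in% names(wl))) {
    stop("whitelist needs columns taxon and rank")
  }
  wl
}

#' Screen taxa lists against a species checklist
#'
#' Matches species-level entries against checklist binomials (exact match
#' after trimming, whitespace collapsing and case folding — no fuzzy
#' matching, to avoid false invasive-species alerts). Entries at coarser
#' ranks never match. For each checklist species and survey method, counts
#' the samples with at least one match; multiple OTUs of the same species
#' within a sample count once.
#'
#' @param lists named list of `taxa_list` objects (names = sample ids).
#' @param checklist data.frame as from [read_checklist()].
#' @param methods named character vector mapping sample id to method, or a
#'   data.frame with columns `sample_id` and `method`.
#' @return a `detection_report` data.frame: `species`, `category`, `method`,
#'   `n_detected`, `n_total`, `fraction`.
#' @export
screen_checklist <- function(lists, checklist, methods) {
  coll <- as_taxa_list_collection(lists)
  if (is.null(names(coll))) stop("lists must be named by sample id")
  if (is.data.frame(methods)) {
    methods <- setNames(as.character(methods$method), methods$sample_id)
  }
  missing <- setdiff(names(coll), names(methods))
  if (length(missing) > 0L) {
    stop("no method recorded for sample(s): ", paste(missing, collapse = ", "))
  }
  key <- normalize_name(checklist$species_name)
  # species detected per sample (deduplicated within sample)
  detected <- lapply(coll, function(tl) {
    sp <- tl$taxon[tl$rank == "species"]
    unique(normalize_name(sp))
  })
  method_of <- methods[names(coll)]
  out <- list()
  for (m in sort(unique(method_of))) {
    in_m <- names(coll)[method_of == m]
    n_total <- length(in_m)
    hits <- vapply(key, function(k) {
      sum(vapply(in_m, function(s) k %in% detected[[s]], logical(1)))
    }, integer(1))
    out[[m]] <- data.frame(species = checklist$species_name,
                           category = checklist$category,
                           method = m,
                           n_detected = unname(hits),
                           n_total = n_total,
                           fraction = unname(hits) / n_total,
                           stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("detection_report", "data.frame")
  rep
}

#' Detection fractions as percentages
#'
#' Converts detection counts to the percentage of samples in which each
#' species was found, reported to two decimals.
#'
#' @param report a `detection_report` from [screen_checklist()], or an
#'   integer vector of detection counts (then `n_total` is required).
#' @param n_total total samples per method; only used when `report` is a
#'   plain count vector.
#' @return if given a report, the report with a `percent` column appended;
#'   if given counts, a numeric vector of percentages.
#' @export
detection_fraction <- function(report, n_total = NULL) {
  if (is.data.frame(report)) {
    if (any(report$n_total <= 0L)) stop("n_total must be positive")
    report$percent <- round(100 * report$n_detected / report$n_total, 2)
    return(report)
  }
  if (is.null(n_total)) stop("n_total required for count input")
  if (any(n_total <= 0L)) stop("n_total must be positive")
  if (any(report < 0L) || any(report > n_total)) {
    stop("counts must lie in [0, n_total]")
  }
  round(100 * report / n_total, 2)
}
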