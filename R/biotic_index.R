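#' Read an IBMWP score table from TSV
#'
#' Columns: `taxon`, `rank`, `score`. Scores are the index's fixed
#' pollution-sensitivity values, integers from 1 (most tolerant) to 10
#' (most sensitive); most scoring taxa are families, a few are coarser
#' groups. An editable copy of the published table ships with the package
#' (`system.file("extdata", "ibmwp_scores.tsv", package = "rivermetrix")`).
#'
#' @param path path to a tab-separated file.
#' @return a `score_table` data.frame.
#' @export
read_score_table <- function(path) {
  st <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "rank", "score") %in% names(st))) {
    stop("score table needs columns taxon, rank, score")
  }
  score_table(st$taxon, st$rank, st$score)
}

#' Construct a biotic-index score table
#'
#' @param taxon character vector of scoring taxon names (unique).
#' @param rank rank of each scoring taxon.
#' @param score integer sensitivity scores in 1..10.
#' @return a `score_table` data.frame.
#' @export
score_table <- function(taxon, rank, score) {
  score <- as.integer(score)
  if (any(is.na(score)) || any(score < 1L) || any(score > 10L)) {
    stop("scores must be integers in [1, 10]")
  }
  if (anyDuplicated(normalize_name(taxon))) stop("duplicated scoring taxon")
  st <- data.frame(taxon = as.character(taxon), rank = as.character(rank),
                   score = score, stringsAsFactors = FALSE)
  class(st) <- c("score_table", "data.frame")
  st
}

#' Reference values and status-class boundaries
#'
#' The Ecological Quality Ratio compares an observed index value against the
#' value expected at a type-specific, minimally disturbed reference site;
#' EQR cut-points then define the five Water Framework Directive status
#' classes. Both are intercalibration products that depend on river type and
#' jurisdiction, so they are mandatory configuration here — the package
#' ships an example (`system.file("extdata", "reference_example.yaml",
#' package = "rivermetrix")`) for testing, not an official set.
#'
#' @param reference_ibmwp reference IBMWP value, > 0.
#' @param boundaries four strictly decreasing EQR cut-points
#'   (High/Good, Good/Moderate, Moderate/Poor, Poor/Bad).
#' @param river_type free-text label.
#' @return a `reference_config` list.
#' @export
reference_config <- function(reference_ibmwp, boundaries, river_type = "unspecified") {
  reference_ibmwp <- as.numeric(reference_ibmwp)
  boundaries <- as.numeric(boundaries)
  if (length(reference_ibmwp) != 1L || !is.finite(reference_ibmwp) ||
      reference_ibmwp <= 0) {
    stop("reference_ibmwp must be a single positive number")
  }
  if (length(boundaries) != 4L || any(!is.finite(boundaries)) ||
      any(diff(boundaries) >= 0) || any(boundaries <= 0)) {
    stop("boundaries must be 4 strictly decreasing positive EQR cut-points")
  }
  structure(list(river_type = as.character(river_type),
                 reference_ibmwp = reference_ibmwp,
                 boundaries = boundaries),
            class = "reference_config")
}

#' Read a reference configuration from YAML
#'
#' Expected fields: `river_type`, `reference_ibmwp`, `boundaries` (list of
#' four decreasing EQR cut-points).
#'
#' @param path path to a YAML file.
#' @return a [reference_config()].
#' @export
read_reference_config <- function(path) {
  y <- yaml::read_yaml(path)
  reference_config(y$reference_ibmwp, unlist(y$boundaries),
                   river_type = if (is.null(y$river_type)) "unspecified" else y$river_type)
}

#' Map a taxa list onto index scoring taxa
#'
#' Each entry is walked up its lineage (species, genus, family, order,
#' class, phylum) and attached to the first name found in the score table;
#' several species of one scored family yield that family once. Entries
#' whose whole lineage is absent from the table are dropped and returned in
#' the `dropped` attribute. Because mixed-rank morphological lists and
#' species-level molecular lists funnel through the same mapping, index
#' values from the two methods are comparable by construction.
#'
#' @param list a `taxa_list`.
#' @param table a [score_table()].
#' @param taxonomy taxonomy data.frame for lineage lookup.
#' @return sorted character vector of scoring taxa (canonical table
#'   spelling), with unmapped entries in attribute `dropped`.
#' @export
map_to_scoring_taxa <- function(list, table, taxonomy) {
  stopifnot(inherits(list, "taxa_list"))
  key <- normalize_name(table$taxon)
  hit <- character(0)
  dropped <- character(0)
  for (i in seq_len(nrow(list))) {
    lin <- entry_lineage(list$otu_ids[i], list$taxon[i], list$rank[i], taxonomy)
    found <- NA_character_
    for (r in RANKS) {        # finest first
      nm <- lin[[r]]
      if (nzchar(nm)) {
        j <- match(normalize_name(nm), key)
        if (!is.na(j)) { found <- table$taxon[j]; break }
      }
    }
    if (is.na(found)) dropped <- c(dropped, list$taxon[i]) else hit <- c(hit, found)
  }
  out <- sort(unique(hit))
  attr(out, "dropped") <- dropped
  out
}

#' IBMWP biotic index
#'
#' Sum of the sensitivity scores of the scoring taxa present. The empty set
#' scores 0.
#'
#' @param scoring_taxa character vector of scoring taxa (a set).
#' @param table a [score_table()].
#' @return integer index value.
#' @export
ibmwp <- function(scoring_taxa, table) {
  scoring_taxa <- unique(scoring_taxa)
  if (length(scoring_taxa) == 0L) return(0L)
  j <- match(normalize_name(scoring_taxa), normalize_name(table$taxon))
  if (anyNA(j)) {
    stop("taxa missing from score table: ",
         paste(scoring_taxa[is.na(j)], collapse = ", "))
  }
  sum(table$score[j])
}

#' IASPT: mean score per scoring taxon
#'
#' IBMWP divided by the number of scoring taxa. With no scoring taxa the
#' value is reported as 0 with a warning (an empty site has no meaningful
#' per-taxon mean).
#'
#' @param ibmwp_value IBMWP index value (non-negative).
#' @param n_taxa number of scoring taxa (non-negative).
#' @return numeric IASPT.
#' @export
iaspt <- function(ibmwp_value, n_taxa) {
  if (ibmwp_value < 0 || n_taxa < 0) stop("inputs must be non-negative")
  if (n_taxa == 0) {
    warning("no scoring taxa; IASPT undefined, reporting 0")
    return(0)
  }
  ibmwp_value / n_taxa
}

#' Ecological Quality Ratio
#'
#' Observed index value divided by the type-specific reference value. Not
#' capped at 1 by default (molecular inventories can exceed the
#' morphology-calibrated reference).
#'
#' @param observed observed index value(s).
#' @param reference reference value, > 0.
#' @param cap cap the ratio at 1?
#' @return numeric EQR, vectorized over `observed`.
#' @export
eqr <- function(observed, reference, cap = FALSE) {
  if (length(reference) != 1L || !is.finite(reference) || reference <= 0) {
    stop("reference must be a single positive number")
  }
  out <- observed / reference
  if (cap) out <- pmin(out, 1)
  out
}

#' Classify EQR into a WFD ecological status class
#'
#' Half-open intervals with the boundary value belonging to the better
#' class: EQR at or above the first cut-point is High, at or above the
#' second Good, and so on; below the fourth is Bad.
#'
#' @param eqr_value numeric EQR value(s), non-negative.
#' @param cfg a [reference_config()].
#' @return ordered factor with levels Bad < Poor < Moderate < Good < High.
#' @export
classify_status <- function(eqr_value, cfg) {
  stopifnot(inherits(cfg, "reference_config"))
  if (any(eqr_value < 0, na.rm = TRUE)) stop("EQR must be non-negative")
  b <- cfg$boundaries
  cls <- cut(eqr_value, breaks = c(-Inf, rev(b), Inf),
             labels = STATUS_LEVELS, right = FALSE)
  factor(as.character(cls), levels = STATUS_LEVELS, ordered = TRUE)
}

#' Compute IBMWP, IASPT, EQR and status for each sample
#'
#' @param lists named list of `taxa_list` objects.
#' @param table a [score_table()].
#' @param taxonomy taxonomy data.frame.
#' @param cfg a [reference_config()].
#' @return an `index_result` data.frame with columns `sample_id`, `ibmwp`,
#'   `n_taxa`, `iaspt`, `eqr`, `status`; the per-sample scoring-taxon sets
#'   are kept in attribute `scoring_taxa`.
#' @export
compute_index <- function(lists, table, taxonomy, cfg) {
  coll <- as_taxa_list_collection(lists)
  if (is.null(names(coll))) stop("lists must be named by sample id")
  sets <- lapply(coll, map_to_scoring_taxa, table = table, taxonomy = taxonomy)
  score <- vapply(sets, ibmwp, numeric(1), table = table)
  n_taxa <- vapply(sets, length, integer(1))
  iaspt_v <- ifelse(n_taxa > 0, score / n_taxa, 0)
  eqr_v <- eqr(score, cfg$reference_ibmwp)
  res <- data.frame(sample_id = names(coll),
                    ibmwp = as.integer(score),
                    n_taxa = n_taxa,
                    iaspt = iaspt_v,
                    eqr = eqr_v,
                    status = classify_status(eqr_v, cfg),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "scoring_taxa") <- sets
  class(res) <- c("index_result", "data.frame")
  res
}
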