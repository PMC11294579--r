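#' Run the full biomonitoring pipeline from a config
#'
#' Executes, in fixed order: read inputs, filter the OTU table
#' (merge / replicate consistency / blank subtraction / presence-absence),
#' screen against a species checklist (if one is configured), tally
#' taxonomic resolution, restrict to a whitelisted group (if configured)
#' and compute IBMWP / IASPT / EQR / status (if a score table and reference
#' config are given). Per-stage TSV outputs, a consolidated `summary.json`
#' (with the resolved configuration embedded) and a run log are written to
#' `out_dir`. Identical config and seed give identical outputs. A failure
#' in any stage aborts with the stage name.
#'
#' @param config path to a YAML file or an equivalent named list. Fields:
#'   `otu_table`, `metadata`, `taxonomy` (input TSV paths), `policy`
#'   (`"bulk"`, `"edna"`, or a list with `min_replicates_present` /
#'   `total_replicates`), `control_aggregation` (`"max"`/`"sum"`),
#'   `subtract_first` (logical), `presence_threshold`, optional `checklist`,
#'   `whitelist`, `scores` + `reference` (paths), `seed`, `out_dir`.
#' @return invisibly, a list with `taxa_lists`, `resolution`, and (when
#'   configured) `detection`, `index`, plus the resolved `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  defaults <- list(control_aggregation = "max", subtract_first = FALSE,
                   presence_threshold = 1L, seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("otu_table", "metadata", "taxonomy", "policy", "out_dir")) {
    if (is.null(cfg[[nm]])) stop("config is missing required field '", nm, "'")
  }
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("rivermetrix %s",
                         as.character(utils::packageVersion("rivermetrix"))),
                 sprintf("R %s", as.character(getRversion())),
                 sprintf("seed %d", as.integer(cfg$seed)))
  report <- list(config = cfg)

  inputs <- stage("read_inputs", {
    counts <- read_otu_table(cfg$otu_table)
    meta <- read_replicate_metadata(cfg$metadata)
    list(m = read_matrix(counts, meta), taxonomy = read_taxonomy(cfg$taxonomy))
  })
  policy <- stage("policy", {
    if (is.character(cfg$policy)) consistency_policy(cfg$policy)
    else consistency_policy(cfg$policy$min_replicates_present,
                            cfg$policy$total_replicates)
  })
  filt <- stage("filter", {
    filter_pipeline(inputs$m, policy, inputs$taxonomy,
                    control_aggregation = cfg$control_aggregation,
                    subtract_first = isTRUE(cfg$subtract_first),
                    presence_threshold = cfg$presence_threshold)
  })
  stage("write_filtered", {
    write_read_matrix(filt$read_matrix, file.path(out_dir, "filtered"))
    write_taxa_lists(filt$taxa_lists, file.path(out_dir, "taxa"))
  })
  report$taxa_lists <- filt$taxa_lists
  log_lines <- c(log_lines, sprintf("filter: %d samples, policy %d/%d",
                                    length(filt$taxa_lists),
                                    policy$min_replicates_present,
                                    policy$total_replicates))

  meth <- inputs$m$meta
  meth <- unique(meth[!meth$is_control, c("sample_id", "method")])
  if (!is.null(cfg$checklist)) {
    report$detection <- stage("screen", {
      cl <- read_checklist(cfg$checklist)
      detection_fraction(screen_checklist(filt$taxa_lists, cl, meth))
    })
    stage("write_screen", {
      write.table(report$detection, file.path(out_dir, "detection_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })
    log_lines <- c(log_lines, sprintf("screen: %d checklist species",
                                      length(unique(report$detection$species))))
  }

  report$resolution <- stage("resolution", tally_resolution(filt$taxa_lists))

  lists <- filt$taxa_lists
  if (!is.null(cfg$whitelist)) {
    lists <- stage("group_filter", {
      filter_to_group(lists, read_whitelist(cfg$whitelist), inputs$taxonomy)
    })
    report$taxa_lists_filtered <- lists
  }

  if (!is.null(cfg$scores)) {
    if (is.null(cfg$reference)) stop("config field 'reference' required with 'scores'")
    report$index <- stage("index", {
      compute_index(lists, read_score_table(cfg$scores), inputs$taxonomy,
                    read_reference_config(cfg$reference))
    })
    stage("write_index", {
      write.table(as.data.frame(report$index),
                  file.path(out_dir, "index_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })
    log_lines <- c(log_lines,
                   sprintf("index: mean IBMWP %.1f over %d samples",
                           mean(report$index$ibmwp), nrow(report$index)))
  }

  stage("write_summary", {
    summary <- list(
      config = cfg,
      n_samples = length(filt$taxa_lists),
      resolution = report$resolution,
      detection = if (!is.null(report$detection)) report$detection,
      index = if (!is.null(report$index)) {
        df <- as.data.frame(report$index)
        df$status <- as.character(df$status)
        df
      })
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  })
  invisible(report)
}

#' Presence/absence matrix from taxa lists
#'
#' Observations-by-taxa binary matrix over one or more collections of taxa
#' lists — the input shape of [jaccard_dist()] and [permanova()]. Row names
#' combine the collection label and sample id.
#'
#' @param ... named arguments, each a named list of `taxa_list` objects
#'   (e.g. `bulk = lists_bulk, edna = lists_edna`).
#' @return list with `pa` (binary matrix) and `meta` (data.frame with
#'   `method` and `site` factors per row).
#' @export
pa_matrix <- function(...) {
  colls <- list(...)
  if (is.null(names(colls)) || any(!nzchar(names(colls)))) {
    stop("collections must be named by method")
  }
  rows <- list()
  meta <- list()
  for (m in names(colls)) {
    for (s in names(colls[[m]])) {
      tl <- colls[[m]][[s]]
      rows[[paste(m, s, sep = ".")]] <- paste(tl$rank, tl$taxon, sep = ":")
      meta[[paste(m, s, sep = ".")]] <- data.frame(method = m, site = s,
                                                   stringsAsFactors = FALSE)
    }
  }
  taxa <- sort(unique(unlist(rows)))
  pa <- t(vapply(rows, function(z) as.integer(taxa %in% z),
                 integer(length(taxa))))
  colnames(pa) <- taxa
  meta <- do.call(rbind, meta)
  meta$method <- factor(meta$method)
  meta$site <- factor(meta$site)
  list(pa = pa, meta = meta)
}
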