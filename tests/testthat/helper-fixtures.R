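# Shared in-code fixtures for the test suite.

# A minimal read matrix: `reps` per-sample PCR-replicate counts are given as
# a list of per-OTU count rows; controls optional.
toy_matrix <- function(counts, sample_ids, n_pcr = 3L, method = "bulk",
                       control_counts = NULL) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(sample_ids) * n_pcr)
  meta <- data.frame(
    replicate_id = paste0(rep(sample_ids, each = n_pcr), ".pcr",
                          rep(seq_len(n_pcr), length(sample_ids))),
    sample_id = rep(sample_ids, each = n_pcr),
    method = method, replicate_kind = "pcr",
    replicate_index = rep(seq_len(n_pcr), length(sample_ids)),
    is_control = FALSE, stringsAsFactors = FALSE)
  if (!is.null(control_counts)) {
    control_counts <- as.matrix(control_counts)
    meta <- rbind(meta, data.frame(
      replicate_id = paste0("CTRL", seq_len(ncol(control_counts))),
      sample_id = NA_character_, method = method, replicate_kind = "pcr",
      replicate_index = seq_len(ncol(control_counts)), is_control = TRUE,
      stringsAsFactors = FALSE))
    counts <- cbind(counts, control_counts)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU%03d", seq_len(nrow(counts)))
  }
  colnames(counts) <- meta$replicate_id
  read_matrix(counts, meta)
}

# random integer read matrix for property-style tests
random_matrix <- function(n_otu = 20L, n_samples = 3L, n_pcr = 3L,
                          n_controls = 0L, max_reads = 50L) {
  counts <- matrix(rbinom(n_otu * n_samples * n_pcr, max_reads, 0.3) *
                     rbinom(n_otu * n_samples * n_pcr, 1, 0.6),
                   nrow = n_otu)
  ctrl <- if (n_controls > 0L) {
    matrix(rpois(n_otu * n_controls, 1), nrow = n_otu)
  }
  toy_matrix(counts, sprintf("S%02d", seq_len(n_samples)), n_pcr,
             control_counts = ctrl)
}

# a small taxonomy covering OTU001..OTUnnn with simple lineages; every OTU
# is species-level unless listed in `coarse` (rank to truncate to)
toy_taxonomy <- function(otu_ids, species = NULL, family = "Baetidae",
                         order = "Ephemeroptera", class = "Insecta",
                         phylum = "Arthropoda") {
  n <- length(otu_ids)
  if (is.null(species)) species <- paste("Baetella", letters[seq_len(n)])
  data.frame(otu_id = otu_ids, phylum = phylum, class = class, order = order,
             family = rep_len(family, n),
             genus = vapply(strsplit(species, " "), `[[`, "", 1L),
             species = species, stringsAsFactors = FALSE)
}

example_score_table <- function() {
  read_score_table(system.file("extdata", "ibmwp_scores.tsv",
                               package = "rivermetrix"))
}

example_reference <- function() {
  read_reference_config(system.file("extdata", "reference_example.yaml",
                                    package = "rivermetrix"))
}

# enumerate all permutations of 1..n (small n only)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}
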