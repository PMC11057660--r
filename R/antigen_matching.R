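#' Construct an antigen-associated clonotype panel
#'
#' A panel is a set of (V gene, J gene, CDR3 amino acid) triples, e.g.
#' public tumour-antigen-specific clonotypes collected from sorted
#' antigen-specific T cells, or a single trackable transgenic clone.
#' Entries must be unique under the V/J/CDR3 key and pass the standard
#' CDR3 length filter.
#'
#' @param entries data frame with columns `v_gene`, `j_gene`, `cdr3_aa`
#'   and optionally `source`.
#' @param panel_id short identifier.
#' @param provenance free-text provenance note.
#' @return object of class `clonotype_panel`.
#' @export
clonotype_panel <- function(entries, panel_id = "panel", provenance = "") {
  e <- as_tibble(entries)
  need <- c("v_gene", "j_gene", "cdr3_aa")
  if (!all(need %in% names(e))) {
    stop("panel entries need columns: ", paste(need, collapse = ", "))
  }
  if (!"source" %in% names(e)) e$source <- NA_character_
  len <- nchar(e$cdr3_aa)
  if (any(len < 8 | len > 20)) {
    stop("panel CDR3s must be 8-20 amino acids long")
  }
  key <- key_of(e$cdr3_aa, e$v_gene, e$j_gene, scheme = "vjcdr3aa")
  if (anyDuplicated(key)) stop("panel entries must be unique under V/J/CDR3")
  structure(list(panel_id = panel_id, entries = e, provenance = provenance),
            class = "clonotype_panel")
}

#' Read a clonotype panel from CSV
#'
#' @param path CSV with columns `v_gene`, `j_gene`, `cdr3_aa`, optionally
#'   `source`.
#' @param panel_id identifier (defaults to the file name).
#' @return a `clonotype_panel`.
#' @export
read_panel <- function(path, panel_id = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  clonotype_panel(df,
                  panel_id = panel_id %||% sub("\\.csv$", "", basename(path)),
                  provenance = path)
}

#' Match a clonotype panel against a repertoire
#'
#' Exact string-equality matching on the chosen identity key. In
#' `"vjcdr3aa"` mode a panel entry matches only clones with the same
#' normalized V gene, J gene and CDR3 amino-acid sequence; in `"cdr3aa"`
#' mode the CDR3 alone decides. Gene labels on both sides are normalized
#' (allele suffixes stripped, prefixes unified) before comparison.
#'
#' @param sample a filtered `repertoire_sample`.
#' @param panel a `clonotype_panel`.
#' @param mode matching key, `"vjcdr3aa"` (default) or `"cdr3aa"`.
#' @return list with `sample_id`, `n_matched_clones` (panel entries found),
#'   `matched_mass` (summed frequency of matched repertoire clones) and
#'   `per_entry` (tibble of panel entries with their repertoire
#'   frequency, 0 when absent).
#' @export
match_panel <- function(sample, panel, mode = c("vjcdr3aa", "cdr3aa")) {
  mode <- match.arg(mode)
  if (nrow(panel$entries) == 0) stop("empty panel")
  p <- clone_freqs(sample, scheme = mode)
  pk <- key_of(panel$entries$cdr3_aa, panel$entries$v_gene,
               panel$entries$j_gene, scheme = mode)
  freq <- unname(p[pk])
  freq[is.na(freq)] <- 0
  matched_keys <- unique(pk[freq > 0])
  list(sample_id = sample$meta$sample_id,
       n_matched_clones = sum(freq > 0),
       matched_mass = sum(p[matched_keys]),
       per_entry = panel$entries |>
         mutate(key = pk, frequency = freq) |>
         select("v_gene", "j_gene", "cdr3_aa", "key", "frequency"))
}

#' Panel trajectory across a study
#'
#' Per-sample panel hits joined with metadata, ready for group-by-time
#' summaries and statistics.
#'
#' @param samples list of `repertoire_sample` objects.
#' @param panel a `clonotype_panel`.
#' @param mode matching key.
#' @return tibble with `sample_id`, `subject_id`, `group`, `timepoint`,
#'   `compartment`, `flank`, `n_matched`, `matched_mass`.
#' @export
panel_trajectory <- function(samples, panel, mode = c("vjcdr3aa", "cdr3aa")) {
  mode <- match.arg(mode)
  rows <- lapply(samples, function(s) {
    hit <- match_panel(s, panel, mode)
    tibble(sample_id = s$meta$sample_id, subject_id = s$meta$subject_id,
           group = s$meta$group, timepoint = s$meta$timepoint,
           compartment = s$meta$compartment, flank = s$meta$flank,
           n_matched = hit$n_matched_clones, matched_mass = hit$matched_mass)
  })
  bind_rows(rows)
}

#' Panel-entry occupancy matrix
#'
#' Entry-by-sample matrix of repertoire frequencies, the input for
#' heatmaps of how individual public clonotypes distribute across
#' subjects.
#'
#' @inheritParams panel_trajectory
#' @return numeric matrix, rows = panel keys, columns = sample ids.
#' @export
panel_occupancy <- function(samples, panel, mode = c("vjcdr3aa", "cdr3aa")) {
  mode <- match.arg(mode)
  cols <- lapply(samples, function(s) match_panel(s, panel, mode)$per_entry$frequency)
  m <- do.call(cbind, cols)
  pk <- key_of(panel$entries$cdr3_aa, panel$entries$v_gene,
               panel$entries$j_gene, scheme = mode)
  rownames(m) <- pk
  colnames(m) <- vapply(samples, function(s) s$meta$sample_id, character(1))
  m
}
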