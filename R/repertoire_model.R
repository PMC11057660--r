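#' Strip allele suffixes and unify prefixes of TCR gene labels
#'
#' Public clonotype panels and different annotation pipelines write the same
#' gene segment in several ways (`"TRBV13-2*01"`, `"TCRBV13-2"`). Allele
#' suffixes (`"*01"`) are stripped and the `"TCRB"` prefix is rewritten as
#' `"TRB"` so that gene-level comparisons are exact.
#'
#' @param x character vector of gene-segment labels (NA allowed).
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_gene(c("TRBV13-2*01", "TCRBJ2-7*02"))
normalize_gene <- function(x) {
  x <- as.character(x)
  x <- sub("\\*.*$", "", x)
  sub("^TCRB", "TRB", x)
}

#' Clonotype identity key
#'
#' Two identity schemes are supported: `"cdr3aa"`, where clonal T cells are
#' defined by the distinct CDR3 amino-acid sequence alone (the default used
#' by all diversity and tracking statistics), and `"vjcdr3aa"`, which
#' additionally requires exact V- and J-gene agreement (used for matching
#' against public antigen-associated clonotype panels). Gene labels are
#' passed through [normalize_gene()] before being joined.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences.
#' @param v_gene,j_gene gene-segment labels; required for `"vjcdr3aa"`.
#' @param scheme identity scheme, `"cdr3aa"` or `"vjcdr3aa"`.
#' @return character vector of keys.
#' @export
#' @examples
#' key_of("CASSF", "TRBV13-2*01", "TRBJ2-7*01", scheme = "vjcdr3aa")
key_of <- function(cdr3_aa, v_gene = NULL, j_gene = NULL,
                   scheme = c("cdr3aa", "vjcdr3aa")) {
  scheme <- match.arg(scheme)
  cdr3_aa <- as.character(cdr3_aa)
  if (scheme == "cdr3aa") return(cdr3_aa)
  if (is.null(v_gene) || is.null(j_gene)) {
    stop("v_gene and j_gene are required for the 'vjcdr3aa' scheme")
  }
  v <- normalize_gene(v_gene)
  j <- normalize_gene(j_gene)
  v[is.na(v)] <- ""
  j[is.na(j)] <- ""
  paste(v, j, cdr3_aa, sep = "|")
}

#' Sample metadata record
#'
#' @param sample_id,subject_id character identifiers.
#' @param compartment `"blood"` or `"tumor"`.
#' @param flank `"left"`, `"right"` or `"none"` (blood).
#' @param timepoint integer days relative to the first treatment dose.
#' @param group `"responder"`, `"non_responder"` or `"control"`.
#' @param tumor_model free-text tumour model label (e.g. `"AB1"`).
#' @return a named list of class `sample_meta`.
#' @export
sample_meta <- function(sample_id = NA_character_, subject_id = NA_character_,
                        compartment = NA_character_, flank = "none",
                        timepoint = NA_integer_, group = NA_character_,
                        tumor_model = NA_character_) {
  if (!is.na(compartment) && !compartment %in% c("blood", "tumor")) {
    stop("compartment must be 'blood' or 'tumor'")
  }
  if (!is.na(flank) && !flank %in% c("left", "right", "none")) {
    stop("flank must be 'left', 'right' or 'none'")
  }
  structure(list(sample_id = as.character(sample_id),
                 subject_id = as.character(subject_id),
                 compartment = as.character(compartment),
                 flank = as.character(flank),
                 timepoint = as.integer(timepoint),
                 group = as.character(group),
                 tumor_model = as.character(tumor_model)),
            class = "sample_meta")
}

#' Construct a repertoire sample
#'
#' A repertoire sample is a clonotype table plus its metadata. Rows are
#' stored at the finest identity (CDR3 amino acid + V + J); duplicate rows
#' under that key are aggregated by summing counts. `richness` reports the
#' number of distinct CDR3 amino-acid sequences, the clonal definition used
#' throughout.
#'
#' @param clonotypes a data frame with at least `cdr3_aa` and `count`;
#'   optional columns `cdr3_nt`, `v_gene`, `d_gene`, `j_gene`.
#' @param meta a [sample_meta()] record.
#' @return an object of class `repertoire_sample` with elements
#'   `meta`, `clonotypes`, `total_count`, `richness`.
#' @export
repertoire_sample <- function(clonotypes, meta = sample_meta()) {
  cl <- as_tibble(clonotypes)
  if (!all(c("cdr3_aa", "count") %in% names(cl))) {
    stop("clonotypes must have columns 'cdr3_aa' and 'count'")
  }
  for (col in c("cdr3_nt", "v_gene", "d_gene", "j_gene")) {
    if (!col %in% names(cl)) cl[[col]] <- NA_character_
  }
  if (any(is.na(cl$count)) || any(cl$count < 0)) {
    stop("clonotype counts must be non-negative and non-missing")
  }
  cl$count <- as.numeric(cl$count)
  cl <- cl[cl$count > 0,
           c("cdr3_aa", "cdr3_nt", "v_gene", "d_gene", "j_gene", "count"),
           drop = FALSE]
  skey <- key_of(cl$cdr3_aa, cl$v_gene, cl$j_gene, scheme = "vjcdr3aa")
  if (anyDuplicated(skey)) {
    agg <- rowsum(cl$count, skey)
    first <- !duplicated(skey)
    cl <- cl[first, , drop = FALSE]
    skey <- skey[first]
    cl$count <- agg[match(skey, rownames(agg)), 1]
  }
  cl <- cl[order(-cl$count, skey), , drop = FALSE]
  structure(list(meta = meta,
                 clonotypes = cl,
                 total_count = sum(cl$count),
                 richness = length(unique(cl$cdr3_aa))),
            class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "<repertoire_sample> %s: %d distinct CDR3aa, %s transcripts (%s/%s, day %s)\n",
    x$meta$sample_id, x$richness, format(x$total_count, big.mark = ","),
    x$meta$compartment, x$meta$group, x$meta$timepoint))
  print(head(x$clonotypes, 5))
  if (nrow(x$clonotypes) > 5) cat("...\n")
  invisible(x)
}

#' Aggregated clone counts under an identity scheme
#'
#' Collapses the stored clonotype rows under the requested identity scheme
#' and returns a named count vector in deterministic order: descending
#' count, ties broken by lexicographic key.
#'
#' @param sample a `repertoire_sample`.
#' @param scheme identity scheme passed to [key_of()].
#' @return named numeric vector of counts.
#' @export
clone_counts <- function(sample, scheme = c("cdr3aa", "vjcdr3aa")) {
  scheme <- match.arg(scheme)
  cl <- sample$clonotypes
  keys <- key_of(cl$cdr3_aa, cl$v_gene, cl$j_gene, scheme = scheme)
  x <- rowsum(cl$count, keys)
  v <- setNames(as.numeric(x), rownames(x))
  v[order(-v, names(v), method = "radix")]
}

#' Clone frequencies under an identity scheme
#'
#' @inheritParams clone_counts
#' @return named numeric vector of frequencies summing to 1.
#' @export
clone_freqs <- function(sample, scheme = c("cdr3aa", "vjcdr3aa")) {
  x <- clone_counts(sample, scheme)
  x / sum(x)
}

#' Filter clonotypes on CDR3 length and alphabet
#'
#' CDR3 amino-acid sequences with fewer than `min_len` or more than
#' `max_len` residues are excluded. When `standard_aa_only = TRUE` (the
#' default) sequences containing characters outside the 20 standard
#' amino-acid letters — stop (`*`), frameshift (`_`) or ambiguity (`X`)
#' marks — are removed as well rather than raising an error, since the
#' CDR3-amino-acid clonal definition implies productive chains.
#'
#' @param sample a `repertoire_sample`.
#' @param min_len,max_len inclusive CDR3 amino-acid length bounds.
#' @param standard_aa_only drop sequences with non-standard residues.
#' @return a filtered `repertoire_sample` (possibly empty).
#' @export
filter_cdr3 <- function(sample, min_len = 8L, max_len = 20L,
                        standard_aa_only = TRUE) {
  stopifnot(min_len <= max_len)
  cl <- sample$clonotypes
  len <- nchar(cl$cdr3_aa)
  keep <- !is.na(cl$cdr3_aa) & len >= min_len & len <= max_len
  if (standard_aa_only) {
    keep <- keep & grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"),
                         cl$cdr3_aa)
  }
  repertoire_sample(cl[keep, , drop = FALSE], meta = sample$meta)
}

airr_required_cols <- c("junction_aa", "v_call", "j_call", "duplicate_count")
csv_required_cols <- c("cdr3_aa", "v_gene", "j_gene", "count")

#' Read a repertoire sample from disk
#'
#' Two dialects are supported: `"airr"`, the AIRR-C rearrangement TSV
#' (columns `junction_aa`, optional `junction`, `v_call`, optional
#' `d_call`, `j_call`, `duplicate_count`), and `"simple_csv"` (columns
#' `cdr3_aa`, `v_gene`, `j_gene`, `count`). Rows sharing a clonotype key
#' are aggregated by summing counts.
#'
#' @param path file path.
#' @param dialect `"airr"` or `"simple_csv"`.
#' @param meta a [sample_meta()] record to attach.
#' @return a `repertoire_sample`.
#' @export
read_repertoire <- function(path, dialect = c("airr", "simple_csv"),
                            meta = sample_meta()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "airr") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(airr_required_cols, names(df))
    if (length(missing)) {
      stop("AIRR file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
    cl <- tibble(
      cdr3_aa = as.character(df$junction_aa),
      cdr3_nt = if ("junction" %in% names(df)) as.character(df$junction) else NA_character_,
      v_gene = as.character(df$v_call),
      d_gene = if ("d_call" %in% names(df)) as.character(df$d_call) else NA_character_,
      j_gene = as.character(df$j_call),
      count = df$duplicate_count)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(csv_required_cols, names(df))
    if (length(missing)) {
      stop("CSV file ", path, " is missing required column(s): ",
           paste(missing, collapse = ", "))
    }
    cl <- tibble(
      cdr3_aa = as.character(df$cdr3_aa),
      cdr3_nt = if ("cdr3_nt" %in% names(df)) as.character(df$cdr3_nt) else NA_character_,
      v_gene = as.character(df$v_gene),
      d_gene = if ("d_gene" %in% names(df)) as.character(df$d_gene) else NA_character_,
      j_gene = as.character(df$j_gene),
      count = df$count)
  }
  if (nrow(cl) == 0) stop("empty repertoire in ", path)
  repertoire_sample(cl, meta = meta)
}

#' Write a repertoire sample to disk
#'
#' Inverse of [read_repertoire()]; rows are written in deterministic order
#' (descending count, then lexicographic clonotype key). An empty
#' repertoire produces a header-only file.
#'
#' @inheritParams read_repertoire
#' @param sample a `repertoire_sample`.
#' @return the path, invisibly.
#' @export
write_repertoire <- function(sample, path, dialect = c("airr", "simple_csv")) {
  dialect <- match.arg(dialect)
  cl <- sample$clonotypes
  if (dialect == "airr") {
    out <- tibble(junction_aa = cl$cdr3_aa, junction = cl$cdr3_nt,
                  v_call = cl$v_gene, d_call = cl$d_gene, j_call = cl$j_gene,
                  duplicate_count = cl$count)
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    out <- tibble(cdr3_aa = cl$cdr3_aa, cdr3_nt = cl$cdr3_nt,
                  v_gene = cl$v_gene, d_gene = cl$d_gene, j_gene = cl$j_gene,
                  count = cl$count)
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a study metadata sheet
#'
#' @param path CSV with columns `sample_id`, `subject_id`, `compartment`,
#'   `flank`, `timepoint`, `group`, `tumor_model` and optionally `path`
#'   (per-sample repertoire file, relative to the sheet's directory).
#' @return a tibble.
#' @export
read_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "subject_id", "compartment", "flank",
                "timepoint", "group")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  key <- paste(df$subject_id, df$compartment, df$flank, df$timepoint)
  if (anyDuplicated(key)) {
    stop("(subject_id, compartment, flank, timepoint) must be unique")
  }
  df
}

#' Read all samples of a study from a metadata sheet
#'
#' @param meta_path path to the metadata CSV (see [read_metadata()]); its
#'   `path` column locates each sample file relative to the sheet.
#' @param dialect repertoire file dialect.
#' @return named list of `repertoire_sample` objects.
#' @export
read_study_samples <- function(meta_path, dialect = c("airr", "simple_csv")) {
  dialect <- match.arg(dialect)
  meta <- read_metadata(meta_path)
  if (!"path" %in% names(meta)) stop("metadata sheet lacks a 'path' column")
  base <- dirname(meta_path)
  samples <- lapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    read_repertoire(file.path(base, m$path), dialect = dialect,
                    meta = sample_meta(m$sample_id, m$subject_id,
                                       m$compartment, m$flank, m$timepoint,
                                       m$group,
                                       if ("tumor_model" %in% names(meta))
                                         m$tumor_model else NA_character_))
  })
  names(samples) <- meta$sample_id
  samples
}

#' Collect sample metadata into a tibble
#'
#' @param samples list of `repertoire_sample` objects.
#' @return tibble with one row per sample, including `total_count` and
#'   `richness`.
#' @export
meta_table <- function(samples) {
  bind_rows(lapply(samples, function(s) {
    as_tibble(s$meta[c("sample_id", "subject_id", "compartment", "flank",
                       "timepoint", "group", "tumor_model")]) |>
      mutate(total_count = s$total_count, richness = s$richness)
  }))
}
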