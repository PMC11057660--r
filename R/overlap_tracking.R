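#' Morisita-Horn overlap between two repertoires
#'
#' `MH = 2 * sum(x_i * y_i) / ((sum(x_i^2)/X^2 + sum(y_i^2)/Y^2) * X * Y)`
#' summed over the union of clone keys, where `X` and `Y` are the total
#' counts. Equals 1 for identical repertoires and 0 when no clone is
#' shared; invariant to uniform scaling of either sample's counts.
#' Compare samples rarefied to a common depth.
#'
#' @param a,b non-empty `repertoire_sample` objects.
#' @param scheme clonotype identity scheme.
#' @return list with `mh` and `shared_clones` (number of common keys).
#' @export
morisita_horn <- function(a, b, scheme = "cdr3aa") {
  x <- clone_counts(a, scheme)
  y <- clone_counts(b, scheme)
  if (length(x) == 0 || length(y) == 0) stop("empty repertoire")
  keys <- union(names(x), names(y))
  xv <- unname(x[keys]); xv[is.na(xv)] <- 0
  yv <- unname(y[keys]); yv[is.na(yv)] <- 0
  X <- sum(xv); Y <- sum(yv)
  # algebraically (sum(x^2)/X^2 + sum(y^2)/Y^2) * X * Y, arranged so that
  # comparing a repertoire with itself yields exactly 1 in floating point
  mh <- 2 * sum(xv * yv) / (sum(xv^2) * (Y / X) + sum(yv^2) * (X / Y))
  list(mh = mh, shared_clones = sum(xv > 0 & yv > 0))
}

#' Pairwise overlap matrix with subject stratification
#'
#' Computes Morisita-Horn overlap for all unordered sample pairs and
#' labels each pair `within_subject` or `between_subject`, the design used
#' to compare bilateral tumours within animals against tumours from
#' different animals.
#'
#' @param samples list of `repertoire_sample` objects (rarefied).
#' @param scheme clonotype identity scheme.
#' @return tibble with columns `sample_a`, `sample_b`, `mh`,
#'   `shared_clones`, `stratum`.
#' @export
overlap_matrix <- function(samples, scheme = "cdr3aa") {
  n <- length(samples)
  if (n < 2) stop("need at least two samples")
  ids <- vapply(samples, function(s) s$meta$sample_id, character(1))
  subj <- vapply(samples, function(s) s$meta$subject_id, character(1))
  pairs <- utils::combn(n, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ov <- morisita_horn(samples[[i]], samples[[j]], scheme)
    tibble(sample_a = ids[i], sample_b = ids[j],
           mh = ov$mh, shared_clones = ov$shared_clones,
           stratum = if (!is.na(subj[i]) && !is.na(subj[j]) &&
                         subj[i] == subj[j]) "within_subject"
                     else "between_subject")
  })
  bind_rows(rows)
}

#' Mean and SD of overlap per stratum
#'
#' @param overlaps output of [overlap_matrix()].
#' @return tibble with `stratum`, `n`, `mean_mh`, `sd_mh`.
#' @export
overlap_summary <- function(overlaps) {
  overlaps |>
    group_by(.data$stratum) |>
    summarise(n = n(), mean_mh = mean(.data$mh), sd_mh = sd(.data$mh),
              .groups = "drop")
}

rank_table <- function(sample, top_n, scheme) {
  x <- clone_counts(sample, scheme)      # deterministic rank order
  cutoff <- x[min(top_n, length(x))]     # boundary ties are included
  tibble(clone_key = names(x),
         frequency = as.numeric(x) / sum(x),
         rank = seq_along(x),
         in_top = as.numeric(x) >= cutoff)
}

#' Track clone trajectories across a longitudinal series
#'
#' For one subject/compartment series ordered by timepoint, computes each
#' clone's frequency and abundance rank per timepoint and flags
#' "persistent and abundant" clones: those ranked in the top `top_n` at
#' two or more timepoints. Clones whose count ties the `top_n`-th count
#' are included in the top set, so the cutoff is deterministic. Clones
#' absent at a timepoint get frequency 0 and no rank.
#'
#' @param series list of `repertoire_sample` objects from a single subject
#'   and compartment, two or more distinct timepoints (rarefy to a common
#'   depth first).
#' @param top_n abundance-rank cutoff (default 100).
#' @param scheme clonotype identity scheme.
#' @return long tibble: `clone_key`, `timepoint`, `frequency`, `rank`
#'   (NA when absent), `in_top`, and the per-clone flag
#'   `persistent_abundant`.
#' @export
track_clones <- function(series, top_n = 100L, scheme = "cdr3aa") {
  if (length(series) < 2) stop("need at least two timepoints")
  tps <- vapply(series, function(s) as.numeric(s$meta$timepoint), numeric(1))
  if (anyNA(tps) || anyDuplicated(tps)) {
    stop("series must have distinct, non-missing timepoints")
  }
  subj <- unique(vapply(series, function(s) s$meta$subject_id, character(1)))
  comp <- unique(vapply(series, function(s) s$meta$compartment, character(1)))
  if (length(subj) > 1 || length(comp) > 1) {
    stop("series must come from a single subject and compartment")
  }
  series <- series[order(tps)]
  tps <- sort(tps)
  long <- bind_rows(lapply(seq_along(series), function(i) {
    rank_table(series[[i]], top_n, scheme) |> mutate(timepoint = tps[i])
  }))
  long <- tidyr::complete(long, clone_key, timepoint = tps,
                          fill = list(frequency = 0, rank = NA_integer_,
                                      in_top = FALSE))
  flags <- long |>
    group_by(.data$clone_key) |>
    summarise(persistent_abundant = sum(.data$in_top) >= 2, .groups = "drop")
  left_join(long, flags, by = "clone_key") |>
    arrange(.data$clone_key, .data$timepoint)
}

#' Number of persistent and abundant clones in a series
#'
#' @inheritParams track_clones
#' @return integer count of clones ranked in the top `top_n` at two or
#'   more timepoints.
#' @export
persistent_count <- function(series, top_n = 100L, scheme = "cdr3aa") {
  tr <- track_clones(series, top_n = top_n, scheme = scheme)
  tr |>
    distinct(.data$clone_key, .data$persistent_abundant) |>
    summarise(n = sum(.data$persistent_abundant)) |>
    pull(n)
}

#' Clone flow table between consecutive timepoints
#'
#' Long-format input for circos-style plots: for each consecutive
#' timepoint pair, every clone present at either end with its frequency
#' at both.
#'
#' @inheritParams track_clones
#' @return tibble `clone_key`, `timepoint_from`, `timepoint_to`,
#'   `freq_from`, `freq_to`.
#' @export
clone_flow <- function(series, scheme = "cdr3aa") {
  tps <- vapply(series, function(s) as.numeric(s$meta$timepoint), numeric(1))
  series <- series[order(tps)]
  tps <- sort(tps)
  bind_rows(lapply(seq_len(length(series) - 1), function(i) {
    f1 <- clone_freqs(series[[i]], scheme)
    f2 <- clone_freqs(series[[i + 1]], scheme)
    keys <- union(names(f1), names(f2))
    a <- unname(f1[keys]); a[is.na(a)] <- 0
    b <- unname(f2[keys]); b[is.na(b)] <- 0
    tibble(clone_key = keys, timepoint_from = tps[i], timepoint_to = tps[i + 1],
           freq_from = a, freq_to = b)
  }))
}
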