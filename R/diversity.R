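#' Rarefy a repertoire to a fixed depth
#'
#' Draws `depth` transcripts uniformly WITHOUT replacement from the
#' multiset of the sample's transcripts (a multivariate hypergeometric
#' draw), mirroring classical rarefaction. Clones drawn to zero are
#' dropped. Never upsamples.
#'
#' @param sample a `repertoire_sample`.
#' @param depth target total count, `1 <= depth <= total_count`.
#' @param seed optional integer; when given the draw is reproducible and
#'   the global RNG stream is left untouched.
#' @return a rarefied `repertoire_sample` with `total_count == depth`.
#' @export
rarefy <- function(sample, depth, seed = NULL) {
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  total <- sample$total_count
  if (depth > total) {
    stop("depth (", depth, ") exceeds total count (", total,
         "); rarefaction never upsamples")
  }
  if (depth == total) return(sample)
  k <- sample$clonotypes$count
  cum <- cumsum(k)
  counts <- with_opt_seed(seed, {
    idx <- sample.int(total, depth)
    tabulate(findInterval(idx - 1L, cum) + 1L, nbins = length(k))
  })
  cl <- sample$clonotypes
  cl$count <- counts
  repertoire_sample(cl[counts > 0, , drop = FALSE], meta = sample$meta)
}

#' Smallest total count across samples
#'
#' The depth all samples are rarefied to for comparability.
#'
#' @param samples non-empty list of `repertoire_sample` objects.
#' @return integer minimum total count.
#' @export
common_depth <- function(samples) {
  if (length(samples) == 0) stop("no samples supplied")
  min(vapply(samples, function(s) s$total_count, numeric(1)))
}

#' Rarefy a set of samples to their common depth
#'
#' @param samples list of `repertoire_sample` objects.
#' @param depth `"auto"` (the smallest sample) or an integer.
#' @param seed integer; per-sample seeds are derived as `seed + index` so
#'   the set is reproducible as a whole.
#' @return list of rarefied samples.
#' @export
rarefy_all <- function(samples, depth = "auto", seed = 1L) {
  d <- if (identical(depth, "auto")) common_depth(samples) else as.integer(depth)
  out <- lapply(seq_along(samples), function(i) {
    rarefy(samples[[i]], d, seed = as.integer(seed) + i)
  })
  names(out) <- names(samples)
  out
}

#' Shannon entropy and evenness of a repertoire
#'
#' `H = -sum(p_i log p_i)` in nats; the normalized value is Pielou-style
#' evenness `H / log(S)` (defined as 0 for a single-clone repertoire), so
#' 1 means a perfectly even repertoire and low values a clonally expanded
#' one.
#'
#' @param sample a `repertoire_sample`.
#' @param scheme clonotype identity scheme.
#' @return list with elements `H` (nats) and `norm` (in `[0, 1]`).
#' @export
shannon <- function(sample, scheme = "cdr3aa") {
  p <- clone_freqs(sample, scheme)
  if (length(p) == 0) stop("empty repertoire")
  H <- -sum(p * log(p))
  S <- length(p)
  list(H = H, norm = if (S == 1) 0 else H / log(S))
}

#' Renyi diversity profile
#'
#' `H_alpha = log(sum(p_i^alpha)) / (1 - alpha)` in nats, with the limits
#' `H_0 = log(S)` (richness), `H_1 = ` Shannon entropy and
#' `H_Inf = -log(max p_i)` (dominance). The profile is non-increasing in
#' `alpha`; plotted against `alpha` it characterizes the clone-size
#' distribution graphically.
#'
#' @param sample a `repertoire_sample`.
#' @param alphas ordered vector of Renyi orders; `Inf` allowed.
#' @param scheme clonotype identity scheme.
#' @return tibble with columns `alpha`, `H`.
#' @export
renyi_profile <- function(sample, alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf),
                          scheme = "cdr3aa") {
  p <- clone_freqs(sample, scheme)
  H <- vapply(alphas, function(a) {
    if (a == 0) log(length(p))
    else if (is.infinite(a)) -log(max(p))
    else if (a == 1) -sum(p * log(p))
    else log(sum(p^a)) / (1 - a)
  }, numeric(1))
  tibble(alpha = alphas, H = H)
}

#' Gini index of the clone-size distribution
#'
#' The standard inequality coefficient
#' `G = sum_i sum_j |x_i - x_j| / (2 S^2 xbar)`, computed via the sorted
#' form. Because orientation conventions differ between toolchains, both
#' the inequality coefficient (`gini`: 0 = perfectly even) and its
#' complement (`evenness_gini = 1 - G`: 1 = perfectly even/diverse) are
#' returned; reporting uses `evenness_gini` so that values near 1 mean a
#' diverse repertoire. A single-clone repertoire has no measurable
#' inequality and returns `G = 0` by convention, flagged `degenerate`.
#'
#' @param sample a `repertoire_sample`.
#' @param scheme clonotype identity scheme.
#' @return list with `gini`, `evenness_gini`, `degenerate`.
#' @export
gini <- function(sample, scheme = "cdr3aa") {
  x <- sort(as.numeric(clone_counts(sample, scheme)))
  S <- length(x)
  if (S == 0) stop("empty repertoire")
  if (S == 1) return(list(gini = 0, evenness_gini = 1, degenerate = TRUE))
  G <- 2 * sum(seq_len(S) * x) / (S * sum(x)) - (S + 1) / S
  list(gini = G, evenness_gini = 1 - G, degenerate = FALSE)
}

#' Rank-abundance band masses
#'
#' Clones are ranked by descending count (ties broken by lexicographic
#' key) and the summed frequency in each rank band is reported.
#'
#' @param sample a `repertoire_sample`.
#' @param band_breaks upper rank bound of each band; the last may be `Inf`.
#' @param scheme clonotype identity scheme.
#' @return tibble with columns `band`, `mass`; masses sum to 1.
#' @export
rank_abundance <- function(sample, band_breaks = c(10, 100, 1000, Inf),
                           scheme = "cdr3aa") {
  p <- clone_freqs(sample, scheme)  # already in deterministic rank order
  lo <- c(1, head(band_breaks, -1) + 1)
  labels <- ifelse(is.finite(band_breaks),
                   paste0(lo, "-", band_breaks),
                   paste0(">", lo - 1))
  rank <- seq_along(p)
  band_idx <- findInterval(rank - 1, c(0, band_breaks)) # 1-based band
  mass <- vapply(seq_along(band_breaks),
                 function(b) sum(p[band_idx == b]), numeric(1))
  tibble(band = labels, mass = mass)
}

#' Large clones of a repertoire
#'
#' Clones occupying strictly more than `threshold` of the repertoire
#' (default 0.5%). Evaluate on rarefied data when comparing samples.
#'
#' @param sample a `repertoire_sample`.
#' @param threshold strict frequency threshold.
#' @param scheme clonotype identity scheme.
#' @return list with `count` and `keys`.
#' @export
large_clones <- function(sample, threshold = 0.005, scheme = "cdr3aa") {
  p <- clone_freqs(sample, scheme)
  hit <- p > threshold
  list(count = sum(hit), keys = names(p)[hit])
}

#' Full diversity profile of one sample
#'
#' @param sample a `repertoire_sample` (rarefy first for comparability).
#' @param alphas Renyi orders.
#' @param band_breaks rank-abundance band bounds.
#' @param threshold large-clone frequency threshold.
#' @param scheme clonotype identity scheme.
#' @return list bundling depth, richness, Shannon, Gini, Renyi profile,
#'   rank-band masses and the large-clone count.
#' @export
diversity_profile <- function(sample, alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf),
                              band_breaks = c(10, 100, 1000, Inf),
                              threshold = 0.005, scheme = "cdr3aa") {
  sh <- shannon(sample, scheme)
  gi <- gini(sample, scheme)
  list(sample_id = sample$meta$sample_id,
       depth = sample$total_count,
       richness_S = length(clone_counts(sample, scheme)),
       shannon_H = sh$H,
       shannon_norm = sh$norm,
       gini = gi$gini,
       evenness_gini = gi$evenness_gini,
       renyi = renyi_profile(sample, alphas, scheme),
       top_k_mass = rank_abundance(sample, band_breaks, scheme),
       large_clone_count = large_clones(sample, threshold, scheme)$count)
}

#' Per-sample diversity table for a sample set
#'
#' Rarefies all samples to a common depth, then computes the diversity
#' statistic suite for each; one row per sample, wide columns for the
#' Renyi grid and rank bands so the table writes directly to CSV.
#'
#' @param samples list of `repertoire_sample` objects.
#' @param depth `"auto"` (smallest sample) or integer.
#' @param seed integer controlling the rarefaction draws.
#' @inheritParams diversity_profile
#' @return a tibble, one row per sample, joined with sample metadata.
#' @export
diversity_table <- function(samples, depth = "auto", seed = 1L,
                            alphas = c(0, 0.25, 0.5, 1, 2, 4, 8, Inf),
                            band_breaks = c(10, 100, 1000, Inf),
                            threshold = 0.005, scheme = "cdr3aa") {
  rs <- rarefy_all(samples, depth = depth, seed = seed)
  rows <- lapply(rs, function(s) {
    pr <- diversity_profile(s, alphas, band_breaks, threshold, scheme)
    ren <- setNames(pr$renyi$H, paste0("renyi_", pr$renyi$alpha))
    bands <- setNames(pr$top_k_mass$mass,
                      paste0("mass_", gsub("[>]", "gt", pr$top_k_mass$band)))
    as_tibble(c(pr[c("sample_id", "depth", "richness_S", "shannon_H",
                     "shannon_norm", "gini", "evenness_gini",
                     "large_clone_count")],
                as.list(ren), as.list(bands)))
  })
  out <- bind_rows(rows)
  mt <- meta_table(samples) |> select(-"total_count", -"richness")
  left_join(out, mt, by = "sample_id")
}
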