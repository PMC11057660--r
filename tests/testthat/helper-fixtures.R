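# Fixture builders shared across test files. All repertoires are built in
# code; nothing is read from disk except files the tests themselves write.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A repertoire from a bare count vector; keys default to AA-valid strings
# so the length filter does not interfere.
make_sample <- function(counts, keys = NULL, v_gene = NULL, j_gene = NULL,
                        sample_id = "s1", subject_id = "m1",
                        compartment = "tumor", flank = "left",
                        timepoint = 0L, group = "responder") {
  n <- length(counts)
  keys <- keys %||% sprintf("CASSAAGV%04dF", seq_len(n))
  repertoire_sample(
    tibble::tibble(cdr3_aa = keys,
                   v_gene = v_gene %||% rep("TRBV1", n),
                   j_gene = j_gene %||% rep("TRBJ1-1", n),
                   count = counts),
    meta = sample_meta(sample_id, subject_id, compartment, flank,
                       timepoint, group))
}

# Random repertoire with S clones and roughly `depth` transcripts.
random_sample <- function(seed, max_S = 50, max_depth = 500, ...) {
  withr::with_seed(seed, {
    S <- sample(2:max_S, 1)
    counts <- as.numeric(rmultinom(1, sample(S:max_depth, 1),
                                   rexp(S) + 0.05))
    make_sample(counts[counts > 0], ...)
  })
}

# Brute-force oracles, written straight from the defining sums and kept
# independent of the package implementations.
bf_shannon <- function(counts) {
  p <- counts / sum(counts)
  -sum(p * log(p))
}
bf_renyi <- function(counts, alpha) {
  p <- counts / sum(counts)
  if (alpha == 0) return(log(length(p)))
  if (is.infinite(alpha)) return(-log(max(p)))
  if (alpha == 1) return(bf_shannon(counts))
  log(sum(p^alpha)) / (1 - alpha)
}
bf_gini <- function(counts) {
  S <- length(counts)
  tot <- 0
  for (i in seq_len(S)) for (j in seq_len(S)) {
    tot <- tot + abs(counts[i] - counts[j])
  }
  tot / (2 * S^2 * mean(counts))
}
bf_morisita_horn <- function(x, y) {
  keys <- union(names(x), names(y))
  xv <- ifelse(keys %in% names(x), x[keys], 0)
  yv <- ifelse(keys %in% names(y), y[keys], 0)
  X <- sum(xv); Y <- sum(yv)
  num <- 0
  for (k in seq_along(keys)) num <- num + xv[k] * yv[k]
  2 * num / ((sum(xv^2) / X^2 + sum(yv^2) / Y^2) * X * Y)
}
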