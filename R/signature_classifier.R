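#' k-mers of a set of CDR3 sequences
#'
#' @param seqs character vector.
#' @param k k-mer length.
#' @return list of character vectors (position-free k-mer multisets).
#' @noRd
kmer_list <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (is.na(s) || n < k) character(0) else substring(s, 1:(n - k + 1), k:n)
  })
}

#' Featurize clonotypes for the signature classifier
#'
#' Each clone is represented by position-free CDR3 amino-acid k-mer counts
#' (default k = 3), one-hot V and J gene usage (allele-normalized) and the
#' CDR3 length — the sequence patterns a repertoire classifier learns
#' from. The vocabulary (sorted k-mers and genes observed in the training
#' data) is fixed at fit time; features unseen in training are dropped at
#' scoring time, never added.
#'
#' @param clonotypes tibble with `cdr3_aa`, `v_gene`, `j_gene`.
#' @param vocabulary optional vocabulary from a previous call; built from
#'   the data when `NULL`.
#' @param k k-mer length.
#' @return list with `features` (sparse dgCMatrix, one row per clone) and
#'   `vocabulary`.
#' @export
featurize <- function(clonotypes, vocabulary = NULL, k = 3L) {
  cl <- as_tibble(clonotypes)
  n <- nrow(cl)
  v <- normalize_gene(cl$v_gene); v[is.na(v)] <- ""
  j <- normalize_gene(cl$j_gene); j[is.na(j)] <- ""
  km <- kmer_list(cl$cdr3_aa, k)
  if (is.null(vocabulary)) {
    vocabulary <- list(kmers = sort(unique(unlist(km))),
                       v_genes = sort(unique(v[v != ""])),
                       j_genes = sort(unique(j[j != ""])),
                       k = as.integer(k))
  }
  nk <- length(vocabulary$kmers)
  nv <- length(vocabulary$v_genes)
  nj <- length(vocabulary$j_genes)
  D <- nk + nv + nj + 1L
  ri <- rep.int(seq_len(n), lengths(km))
  ci <- match(unlist(km), vocabulary$kmers)
  ok <- !is.na(ci)
  ri <- ri[ok]; ci <- ci[ok]; xs <- rep(1, length(ri))
  vi <- match(v, vocabulary$v_genes)
  vok <- !is.na(vi)
  ji <- match(j, vocabulary$j_genes)
  jok <- !is.na(ji)
  i_all <- c(ri, which(vok), which(jok), seq_len(n))
  j_all <- c(ci, nk + vi[vok], nk + nv + ji[jok], rep.int(D, n))
  x_all <- c(xs, rep(1, sum(vok)), rep(1, sum(jok)), nchar(cl$cdr3_aa))
  X <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all, dims = c(n, D),
                            dimnames = list(NULL,
                              c(paste0("kmer:", vocabulary$kmers),
                                paste0("v:", vocabulary$v_genes),
                                paste0("j:", vocabulary$j_genes),
                                "cdr3_length")))
  list(features = X, vocabulary = vocabulary)
}

# Clone-level design table for a sample set: one row per stored clonotype,
# carrying its sample id, label and within-sample frequency weight.
clone_design <- function(samples, label_col, weighting = "frequency") {
  bind_rows(lapply(samples, function(s) {
    cl <- s$clonotypes
    tibble(sample_id = s$meta$sample_id,
           label = as.character(s$meta[[label_col]]),
           cdr3_aa = cl$cdr3_aa, v_gene = cl$v_gene, j_gene = cl$j_gene,
           count = cl$count,
           weight = if (weighting == "frequency") cl$count / s$total_count
                    else cl$count)
  }))
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with mid-ranks for ties: the probability that
#' a random positive scores above a random negative.
#'
#' @param scores numeric scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute an AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @param scores numeric scores.
#' @param positive logical vector.
#' @return tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, positive) {
  positive <- as.logical(positive)
  o <- order(-scores)
  tp <- cumsum(positive[o]); fp <- cumsum(!positive[o])
  tibble(threshold = scores[o],
         fpr = fp / sum(!positive), tpr = tp / sum(positive)) |>
    (\(d) bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), d))()
}

# Ridge-penalized weighted logistic fit over a lambda grid; returns the
# glmnet object (deterministic for fixed inputs).
ridge_fit <- function(X, y, w, lambda_grid) {
  glmnet::glmnet(X, factor(y, levels = c(FALSE, TRUE)), family = "binomial",
                 alpha = 0, weights = w, lambda = lambda_grid,
                 standardize = TRUE)
}

default_lambda_grid <- function() 10^seq(1, -4, length.out = 8)

#' Fit a repertoire signature model
#'
#' A transparent multiple-instance protocol: every clonotype inherits its
#' sample's label and enters a ridge-penalized logistic regression with
#' loss weight equal to its within-sample frequency, so a sample
#' contributes total weight 1 regardless of depth. The penalty strength
#' is chosen by an inner cross-validation that splits at the *sample*
#' level (never the clone level), on the training samples only. Training
#' may be restricted to selected timepoints, the protocol used to ask
#' whether a signature learned before therapy predicts later samples.
#'
#' @param samples list of labeled `repertoire_sample` objects.
#' @param label metadata field carrying the label: `"group"` or
#'   `"tumor_model"`. Exactly two labels must be present.
#' @param train_timepoints optional integer vector; when given only
#'   samples at these timepoints are used for fitting.
#' @param k k-mer length for featurization.
#' @param lambda optional fixed ridge penalty; chosen by inner CV when
#'   `NULL`.
#' @param weighting `"frequency"` (default) or `"count"` per-clone loss
#'   weights.
#' @param n_inner_folds sample-level folds for the inner lambda search.
#' @param seed integer seed for the inner fold assignment.
#' @return object of class `signature_model`: labels (negative, positive),
#'   vocabulary, intercept and coefficient vector, training base rate,
#'   chosen lambda and the training subset descriptor.
#' @export
fit_signature <- function(samples, label = c("group", "tumor_model"),
                          train_timepoints = NULL, k = 3L, lambda = NULL,
                          weighting = c("frequency", "count"),
                          n_inner_folds = 3L, seed = 1L) {
  label <- match.arg(label)
  weighting <- match.arg(weighting)
  if (!is.null(train_timepoints)) {
    tp <- vapply(samples, function(s) as.numeric(s$meta$timepoint), numeric(1))
    samples <- samples[tp %in% train_timepoints]
  }
  if (length(samples) < 2) stop("need at least two training samples")
  des <- clone_design(samples, label, weighting)
  labs <- sort(unique(des$label))
  if (length(labs) != 2) {
    stop("training set must contain exactly two labels, got: ",
         paste(labs, collapse = ", "))
  }
  fz <- featurize(des, vocabulary = NULL, k = k)
  y <- des$label == labs[2]
  grid <- default_lambda_grid()
  if (is.null(lambda)) {
    lambda <- choose_lambda(fz$features, y, des, labs, grid, n_inner_folds, seed)
  }
  fit <- ridge_fit(fz$features, y, des$weight, sort(unique(c(grid, lambda)),
                                                    decreasing = TRUE))
  co <- glmnet::coef.glmnet(fit, s = lambda, exact = FALSE)
  structure(list(labels = labs, vocabulary = fz$vocabulary,
                 intercept = as.numeric(co[1]),
                 beta = setNames(as.numeric(co[-1]), rownames(co)[-1]),
                 base_rate = weighted.mean(y, des$weight),
                 lambda = lambda, k = as.integer(k), label_field = label,
                 weighting = weighting,
                 train_timepoints = train_timepoints,
                 train_samples = vapply(samples,
                                        function(s) s$meta$sample_id,
                                        character(1))),
            class = "signature_model")
}

# Inner sample-level CV over the lambda grid; maximizes mean held-out
# sample-score AUC, breaking ties towards the stronger penalty.
choose_lambda <- function(X, y, des, labs, grid, n_folds, seed) {
  sample_lab <- des |> distinct(.data$sample_id, .data$label)
  if (any(table(sample_lab$label) < 2) || nrow(sample_lab) < 2 * n_folds) {
    return(0.01)
  }
  folds <- with_opt_seed(seed, {
    f <- integer(nrow(sample_lab))
    for (lb in labs) {
      idx <- which(sample_lab$label == lb)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  aucs <- matrix(NA_real_, n_folds, length(grid))
  for (fd in seq_len(n_folds)) {
    test_ids <- sample_lab$sample_id[folds == fd]
    if (length(unique(sample_lab$label[folds != fd])) < 2) next
    tr <- !des$sample_id %in% test_ids
    fit <- ridge_fit(X[tr, , drop = FALSE], y[tr], des$weight[tr], grid)
    pr <- glmnet::predict.glmnet(fit, newx = X[!tr, , drop = FALSE]) # link
    pr <- 1 / (1 + exp(-pr))
    te <- des[!tr, ]
    for (g in seq_along(grid)) {
      sc <- tibble(sample_id = te$sample_id, label = te$label,
                   w = te$weight, p = pr[, min(g, ncol(pr))]) |>
        group_by(.data$sample_id, .data$label) |>
        summarise(score = sum(.data$w * .data$p) / sum(.data$w),
                  .groups = "drop")
      if (length(unique(sc$label)) == 2) {
        aucs[fd, g] <- rank_auc(sc$score, sc$label == labs[2])
      }
    }
  }
  mean_auc <- colMeans(aucs, na.rm = TRUE)
  if (all(is.nan(mean_auc))) return(0.01)
  grid[which.max(replace(mean_auc, is.nan(mean_auc), -Inf))]
}

#' Score every clonotype of a sample under a signature model
#'
#' Returns the per-clone probability of the model's positive label
#' (probabilities for the two labels sum to 1). Clones with no feature
#' overlap with the training vocabulary (no known k-mer, V or J) receive
#' the training-set base rate.
#'
#' @param model a `signature_model`.
#' @param sample a `repertoire_sample`.
#' @return tibble with clone identity columns, `frequency` and one
#'   probability column per label (`prob_<label>`).
#' @export
score_sequences <- function(model, sample) {
  cl <- sample$clonotypes
  fz <- featurize(cl, vocabulary = model$vocabulary, k = model$k)
  X <- fz$features
  eta <- model$intercept + as.numeric(X %*% model$beta)
  p_pos <- plogis(eta)
  informative <- Matrix::rowSums(X[, -ncol(X), drop = FALSE] != 0) > 0
  p_pos[!informative] <- model$base_rate
  out <- tibble(cdr3_aa = cl$cdr3_aa, v_gene = cl$v_gene, j_gene = cl$j_gene,
                count = cl$count, frequency = cl$count / sample$total_count)
  out[[paste0("prob_", model$labels[1])]] <- 1 - p_pos
  out[[paste0("prob_", model$labels[2])]] <- p_pos
  out
}

#' Aggregate clone scores to a sample-level signature score
#'
#' The weighted proportion of the signature in a sample: the
#' frequency-weighted mean of per-clone label probabilities,
#' `sum_i p_i * score_i`. The predicted label is the argmax (0.5
#' threshold in the two-label case).
#'
#' @param model a `signature_model`.
#' @param sample a `repertoire_sample`.
#' @return one-row tibble: `sample_id`, one `signature_<label>` column per
#'   label, `predicted`.
#' @export
score_sample <- function(model, sample) {
  sc <- score_sequences(model, sample)
  w <- sc$frequency
  s_pos <- sum(w * sc[[paste0("prob_", model$labels[2])]])
  out <- tibble(sample_id = sample$meta$sample_id)
  out[[paste0("signature_", model$labels[1])]] <- 1 - s_pos
  out[[paste0("signature_", model$labels[2])]] <- s_pos
  out$predicted <- if (s_pos > 0.5) model$labels[2] else model$labels[1]
  out
}

#' Signature scores across a study
#'
#' @param model a `signature_model`.
#' @param samples list of `repertoire_sample` objects.
#' @return tibble of per-sample signature scores joined with metadata.
#' @export
signature_timecourse <- function(model, samples) {
  scores <- bind_rows(lapply(samples, function(s) score_sample(model, s)))
  mt <- meta_table(samples) |> select(-"total_count", -"richness")
  left_join(scores, mt, by = "sample_id")
}

#' Per-timepoint AUC of a fitted signature
#'
#' Scores all samples and computes, per timepoint, the AUC of the
#' sample-level signature score against the true labels — the protocol of
#' training at one timepoint and testing on the rest.
#'
#' @param model a `signature_model`.
#' @param samples list of labeled samples to evaluate.
#' @return tibble with `timepoint`, `n`, `auc`.
#' @export
timepoint_auc <- function(model, samples) {
  tc <- signature_timecourse(model, samples)
  pos_col <- paste0("signature_", model$labels[2])
  truth_col <- model$label_field
  tc |>
    group_by(.data$timepoint) |>
    summarise(n = n(),
              auc = if (length(unique(.data[[truth_col]])) == 2)
                rank_auc(.data[[pos_col]], .data[[truth_col]] == model$labels[2])
              else NA_real_,
              .groups = "drop")
}

#' Cross-validate the repertoire classification protocol
#'
#' Monte-Carlo cross-validation with *sample-level* splitting (clones from
#' a held-out sample never influence the vocabulary or weights), plus a
#' label-permutation null: sample labels are shuffled across samples —
#' preserving the clonotypes within each sample — before refitting, and
#' the same protocol is rerun.
#'
#' @param samples list of labeled `repertoire_sample` objects.
#' @param label `"group"` or `"tumor_model"`.
#' @param n_splits number of Monte-Carlo train/test splits.
#' @param train_frac fraction of samples (per label) used for training.
#' @param n_permutations number of label permutations for the null.
#' @param k,weighting passed to [fit_signature()].
#' @param lambda ridge penalty; when `NULL` it is chosen by inner CV on
#'   the first split's training samples and reused thereafter.
#' @param seed integer seed controlling splits and permutations.
#' @return object of class `validation_record`: per-split AUCs, observed
#'   mean AUC, pooled ROC points, permutation AUCs and the permutation
#'   p-value `(1 + #{perm >= observed}) / (n_permutations + 1)`.
#' @export
crossvalidate <- function(samples, label = c("group", "tumor_model"),
                          n_splits = 10L, train_frac = 0.7,
                          n_permutations = 0L, k = 3L,
                          weighting = "frequency", lambda = NULL,
                          seed = 1L) {
  label <- match.arg(label)
  labs_all <- vapply(samples, function(s) as.character(s$meta[[label]]),
                     character(1))
  labs <- sort(unique(labs_all))
  if (length(labs) != 2) stop("need exactly two labels")
  if (any(table(labs_all) < 2)) stop("need at least two samples per label")

  one_split <- function(lab_vec, split_seed, lam) {
    tr_idx <- with_opt_seed(split_seed, {
      unlist(lapply(labs, function(lb) {
        idx <- which(lab_vec == lb)
        n_tr <- max(1, min(length(idx) - 1, round(train_frac * length(idx))))
        sample(idx, n_tr)
      }))
    })
    train <- samples[tr_idx]
    test <- samples[-tr_idx]
    for (i in seq_along(train)) train[[i]]$meta[[label]] <- lab_vec[tr_idx][i]
    mdl <- fit_signature(train, label = label, k = k, lambda = lam,
                         weighting = weighting, seed = split_seed)
    pos_col <- paste0("signature_", mdl$labels[2])
    sc <- bind_rows(lapply(test, function(s) score_sample(mdl, s)))
    sc$truth <- lab_vec[-tr_idx]
    list(auc = rank_auc(sc[[pos_col]], sc$truth == labs[2]),
         scores = sc |> select("sample_id", score = all_of(pos_col), "truth"),
         lambda = mdl$lambda)
  }

  base_seed <- as.integer(seed)
  first <- one_split(labs_all, base_seed + 1L, lambda)
  lambda <- lambda %||% first$lambda
  splits <- c(list(first),
              lapply(seq_len(n_splits - 1L), function(i) {
                one_split(labs_all, base_seed + 1L + i, lambda)
              }))
  aucs <- vapply(splits, function(s) s$auc, numeric(1))
  pooled <- bind_rows(lapply(splits, function(s) s$scores))
  perm_aucs <- if (n_permutations > 0) {
    vapply(seq_len(n_permutations), function(p) {
      perm <- with_opt_seed(base_seed + 1000L + p, sample(labs_all))
      one_split(perm, base_seed + 2000L + p, lambda)$auc
    }, numeric(1))
  } else numeric(0)
  structure(list(
    label = label, labels = labs, n_splits = n_splits,
    auc_per_split = aucs, observed_auc = mean(aucs),
    roc = roc_points(pooled$score, pooled$truth == labs[2]),
    pooled_scores = pooled,
    lambda = lambda,
    perm_aucs = perm_aucs,
    perm_mean = if (length(perm_aucs)) mean(perm_aucs) else NA_real_,
    p_value = if (length(perm_aucs))
      (1 + sum(perm_aucs >= mean(aucs))) / (length(perm_aucs) + 1)
    else NA_real_,
    seed = seed),
    class = "validation_record")
}

#' @export
print.validation_record <- function(x, ...) {
  cat(sprintf("<validation_record> %s (%s vs %s)\n", x$label,
              x$labels[1], x$labels[2]))
  cat(sprintf("  observed AUC %.3f over %d sample-level splits\n",
              x$observed_auc, x$n_splits))
  if (length(x$perm_aucs)) {
    cat(sprintf("  permutation null: mean AUC %.3f over %d label shuffles, p = %.4f\n",
                x$perm_mean, length(x$perm_aucs), x$p_value))
  }
  invisible(x)
}

#' Correlate per-clone scores of two signature models
#'
#' Scores the pooled clonotypes of a sample set under two fitted models
#' (e.g. a tumour-model signature and a response signature) and reports
#' the Spearman rank correlation of the per-clone positive-label
#' probabilities. A constant scorer has no defined rank correlation and
#' is reported as `NA` with a note.
#'
#' @param model_a,model_b fitted `signature_model` objects.
#' @param samples list of `repertoire_sample` objects.
#' @return list with `pairs` (tibble of per-clone score pairs) and
#'   `spearman` (rho, or NA), `note`.
#' @export
correlate_signatures <- function(model_a, model_b, samples) {
  pairs <- bind_rows(lapply(samples, function(s) {
    sa <- score_sequences(model_a, s)
    sb <- score_sequences(model_b, s)
    tibble(sample_id = s$meta$sample_id, cdr3_aa = sa$cdr3_aa,
           v_gene = sa$v_gene, j_gene = sa$j_gene,
           score_a = sa[[paste0("prob_", model_a$labels[2])]],
           score_b = sb[[paste0("prob_", model_b$labels[2])]])
  }))
  if (sd(pairs$score_a) == 0 || sd(pairs$score_b) == 0) {
    return(list(pairs = pairs, spearman = NA_real_,
                note = "constant scorer: rank correlation undefined"))
  }
  list(pairs = pairs,
       spearman = cor(pairs$score_a, pairs$score_b, method = "spearman"),
       note = "")
}
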