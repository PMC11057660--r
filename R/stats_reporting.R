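#' Group-comparison statistics for repertoire metrics
#'
#' Runs the design-specified nonparametric test for one metric, optionally
#' per stratum (typically per timepoint), and applies the requested
#' multiple-comparison adjustment family-wise across strata:
#' * `mann_whitney` — two-sided Wilcoxon rank-sum between two groups
#'   (exact for small samples without ties, normal approximation with tie
#'   correction otherwise);
#' * `kruskal_wallis` — one-way nonparametric ANOVA across >= 2 groups;
#' * `friedman` — within-subject comparison across repeated measures,
#'   requiring complete blocks (`block_col`).
#'
#' Degenerate strata (fewer than two observations in a group, or all
#' values tied) are flagged and get no p-value.
#'
#' @param data a data frame.
#' @param value_col name of the numeric metric column.
#' @param group_col name of the grouping column (for `friedman`, the
#'   within-subject factor, e.g. timepoint).
#' @param by_col optional stratification column (e.g. timepoint for
#'   between-group tests); adjustment is applied across its levels.
#' @param block_col subject column, required for `friedman`.
#' @param test test name.
#' @param adjust `"holm"` (Holm-Bonferroni), `"BH"`
#'   (Benjamini-Hochberg) or `"none"`.
#' @return tibble with `metric`, `by`, `test`, `n`, `statistic`, `p_raw`,
#'   `p_adjusted`, `adjustment`, `note`.
#' @export
compare_groups <- function(data, value_col, group_col, by_col = NULL,
                           block_col = NULL,
                           test = c("mann_whitney", "kruskal_wallis",
                                    "friedman"),
                           adjust = c("holm", "BH", "none")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (test == "friedman" && is.null(block_col)) {
    stop("friedman test requires block_col")
  }
  strata <- if (is.null(by_col)) list(`all` = data)
            else split(data, data[[by_col]])
  rows <- lapply(names(strata), function(lv) {
    d <- strata[[lv]]
    v <- d[[value_col]]
    g <- factor(d[[group_col]])
    note <- ""
    stat <- NA_real_; p <- NA_real_
    res <- tryCatch({
      if (test == "mann_whitney") {
        if (nlevels(g) != 2) stop("need exactly two groups")
        if (min(table(g)) < 2) stop("fewer than two observations in a group")
        if (length(unique(v)) == 1) stop("all values tied")
        ht <- suppressWarnings(wilcox.test(v ~ g))
        list(stat = unname(ht$statistic), p = ht$p.value)
      } else if (test == "kruskal_wallis") {
        if (nlevels(g) < 2) stop("need at least two groups")
        ht <- kruskal.test(v, g)
        list(stat = unname(ht$statistic), p = ht$p.value)
      } else {
        b <- factor(d[[block_col]])
        tab <- table(b, g)
        if (any(tab != 1)) stop("friedman requires complete blocks")
        ht <- friedman.test(v, g, b)
        list(stat = unname(ht$statistic), p = ht$p.value)
      }
    }, error = function(e) {
      note <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) { stat <- res$stat; p <- res$p }
    tibble(metric = value_col, by = lv, test = test, n = nrow(d),
           statistic = stat, p_raw = p, note = note)
  })
  out <- bind_rows(rows)
  out$p_adjusted <- if (adjust == "none") out$p_raw
                    else p.adjust(out$p_raw, method = adjust)
  out$adjustment <- adjust
  out |> select("metric", "by", "test", "n", "statistic", "p_raw",
                "p_adjusted", "adjustment", "note")
}

#' End-to-end analysis report for a repertoire study
#'
#' Joins all pipeline stages on one study: per-compartment rarefied
#' diversity tables with responder/non-responder tests per timepoint
#' (Mann-Whitney, Holm-adjusted across timepoints), within- vs
#' between-subject Morisita-Horn overlap of bilateral tumours, persistent
#' abundant clone counts from blood series, planted/selected panel
#' trajectories with tests, and (optionally) a response-signature
#' timecourse with permutation validation. Sections whose inputs are
#' absent from the study are marked absent rather than failing. Rerunning
#' with the same study and seed reproduces the bundle.
#'
#' @param study a `repertoire_study` (simulated or assembled from files:
#'   a list with `samples`, `meta`, optionally `panel`).
#' @param panel optional `clonotype_panel` (defaults to `study$panel`).
#' @param seed integer seed for rarefaction and classifier splits.
#' @param top_n persistent-clone rank cutoff.
#' @param run_classifier fit and validate the response signature
#'   classifier (the slowest stage).
#' @param out_dir optional directory for CSV/JSON output.
#' @return list of class `study_report`.
#' @export
build_report <- function(study, panel = NULL, seed = 1L, top_n = 100L,
                         run_classifier = TRUE, out_dir = NULL) {
  panel <- panel %||% study$panel
  meta <- study$meta
  samples <- study$samples
  report <- list(seed = seed)

  comp_samples <- function(comp) samples[meta$sample_id[meta$compartment == comp]]

  # --- diversity, per compartment, rarefied to the compartment's minimum
  report$diversity <- list()
  for (comp in intersect(c("tumor", "blood"), unique(meta$compartment))) {
    ss <- comp_samples(comp)
    div <- diversity_table(ss, depth = "auto", seed = seed)
    tests <- if (length(unique(div$group)) == 2) {
      bind_rows(lapply(c("shannon_norm", "evenness_gini",
                         "large_clone_count"), function(mc) {
        compare_groups(div, mc, "group", by_col = "timepoint",
                       test = "mann_whitney", adjust = "holm")
      }))
    } else NULL
    report$diversity[[comp]] <- list(table = div, tests = tests)
  }
  if (length(report$diversity) == 0) report$diversity <- "absent"

  # --- bilateral overlap (tumour pairs within each timepoint)
  tumor_meta <- meta[meta$compartment == "tumor", ]
  if (nrow(tumor_meta) >= 2) {
    ov <- bind_rows(lapply(split(tumor_meta, tumor_meta$timepoint),
                           function(tm) {
      if (nrow(tm) < 2) return(NULL)
      rs <- rarefy_all(samples[tm$sample_id], depth = "auto", seed = seed)
      overlap_matrix(rs) |> mutate(timepoint = tm$timepoint[1])
    }))
    report$overlap <- list(pairs = ov, summary = overlap_summary(ov))
  } else report$overlap <- "absent"

  # --- persistent abundant clones in blood series
  blood_meta <- meta[meta$compartment == "blood", ]
  if (nrow(blood_meta) >= 2 && length(unique(blood_meta$timepoint)) >= 2) {
    pc <- bind_rows(lapply(split(blood_meta, blood_meta$subject_id),
                           function(bm) {
      if (length(unique(bm$timepoint)) < 2) return(NULL)
      series <- rarefy_all(samples[bm$sample_id], depth = "auto", seed = seed)
      tibble(subject_id = bm$subject_id[1], group = bm$group[1],
             persistent = persistent_count(series, top_n = top_n))
    }))
    report$persistent_clones <- pc
  } else report$persistent_clones <- "absent"

  # --- panel trajectory
  if (!is.null(panel)) {
    tumor_samples <- comp_samples("tumor")
    traj <- panel_trajectory(if (length(tumor_samples)) tumor_samples
                             else samples, panel)
    traj_tests <- if (length(unique(traj$group)) == 2) {
      compare_groups(traj, "matched_mass", "group", by_col = "timepoint",
                     test = "mann_whitney", adjust = "BH")
    } else NULL
    report$panel <- list(trajectory = traj, tests = traj_tests)
  } else report$panel <- "absent"

  # --- response signature classifier
  if (run_classifier && length(unique(meta$group)) == 2 &&
      "tumor" %in% meta$compartment) {
    ss <- comp_samples("tumor")
    cv <- crossvalidate(ss, label = "group", n_splits = 5L,
                        n_permutations = 20L, seed = seed)
    mdl <- fit_signature(ss, label = "group", seed = seed)
    report$signature <- list(validation = cv,
                             timecourse = signature_timecourse(mdl, ss),
                             per_timepoint_auc = timepoint_auc(mdl, ss))
  } else report$signature <- "absent"

  report <- structure(report, class = "study_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a study report bundle to disk
#'
#' One JSON summary plus the figure-level tables as CSVs.
#'
#' @param report a `study_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (is.data.frame(df)) {
      readr::write_csv(df, file.path(out_dir, name), progress = FALSE)
    }
  }
  summary <- list(seed = report$seed)
  if (is.list(report$diversity)) {
    for (comp in names(report$diversity)) {
      wcsv(report$diversity[[comp]]$table, paste0("diversity_", comp, ".csv"))
      wcsv(report$diversity[[comp]]$tests,
           paste0("diversity_tests_", comp, ".csv"))
    }
  }
  if (is.list(report$overlap)) {
    wcsv(report$overlap$pairs, "overlap_pairs.csv")
    wcsv(report$overlap$summary, "overlap_summary.csv")
    summary$overlap <- report$overlap$summary
  }
  if (is.data.frame(report$persistent_clones)) {
    wcsv(report$persistent_clones, "persistent_clones.csv")
  }
  if (is.list(report$panel)) {
    wcsv(report$panel$trajectory, "panel_trajectory.csv")
    wcsv(report$panel$tests, "panel_tests.csv")
  }
  if (is.list(report$signature)) {
    wcsv(report$signature$timecourse, "signature_timecourse.csv")
    wcsv(report$signature$per_timepoint_auc, "signature_timepoint_auc.csv")
    v <- report$signature$validation
    summary$signature <- list(observed_auc = v$observed_auc,
                              perm_mean = v$perm_mean, p_value = v$p_value)
  }
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
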