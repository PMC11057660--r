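# Murine TRB gene-segment labels used by the simulator.
TRBV_GENES <- c("TRBV1", "TRBV2", "TRBV3", "TRBV4", "TRBV5", "TRBV12-1",
                "TRBV12-2", "TRBV13-1", "TRBV13-2", "TRBV13-3", "TRBV14",
                "TRBV15", "TRBV16", "TRBV17", "TRBV19", "TRBV20", "TRBV23",
                "TRBV26", "TRBV29", "TRBV31")
TRBJ_GENES <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-3", "TRBJ1-4", "TRBJ1-5",
                "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-4", "TRBJ2-5",
                "TRBJ2-7")

#' Random CDR3 amino-acid sequences
#'
#' Sequences start with C and end with F (the canonical junction anchors),
#' with lengths drawn from a discretized normal peaked at 13-15 residues
#' and truncated to `[8, 20]`. When `motif` is given it is inserted at a
#' random internal position of every sequence.
#'
#' @param n number of sequences.
#' @param motif optional amino-acid motif planted in each sequence.
#' @param length_mean,length_sd,length_range length distribution controls.
#' @return character vector of length `n`.
#' @export
random_cdr3 <- function(n, motif = NULL, length_mean = 14, length_sd = 2,
                        length_range = c(8L, 20L)) {
  if (n == 0) return(character(0))
  lens <- pmin(pmax(round(rnorm(n, length_mean, length_sd)),
                    length_range[1]), length_range[2])
  if (!is.null(motif)) lens <- pmax(lens, nchar(motif) + 4L)
  out <- character(n)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    mid <- matrix(sample(AA_ALPHABET, length(idx) * (L - 2), replace = TRUE),
                  nrow = length(idx))
    body <- do.call(paste0, as.data.frame(mid, stringsAsFactors = FALSE))
    out[idx] <- paste0("C", body, "F")
  }
  if (!is.null(motif)) {
    mlen <- nchar(motif)
    pos <- 2L + floor(runif(n) * (lens - mlen - 2L))  # keep anchors intact
    out <- paste0(substr(out, 1, pos), motif,
                  substr(out, pos + mlen + 1L, lens))
  }
  out
}

#' Simulation configuration for a synthetic longitudinal repertoire study
#'
#' Defaults emulate a bilateral-tumour serial-sampling design: 8 subjects
#' per response group, tumours sampled at days 0/2/4/6 on both flanks with
#' total counts log-uniform in `[1e3, 1e5]` and unique background clones
#' log-uniform in `[1e2, 1e4]`; near-uniform blood repertoires; a planted
#' tumour-antigen-specific clonotype panel carrying a CDR3 motif whose
#' frequencies grow geometrically per timepoint step (fold 2.0 in
#' responders vs 1.2 in non-responders); and bilateral flanks drawn
#' multinomially from one underlying subject distribution.
#'
#' @param n_subjects subjects per group.
#' @param groups response groups simulated.
#' @param timepoints days relative to first dose.
#' @param compartments subset of `c("tumor", "blood")`.
#' @param flanks tumour flanks sampled per subject/timepoint.
#' @param tumor_model tumour model label.
#' @param tumor_total_range log-uniform range of tumour sample depths.
#' @param tumor_richness_range log-uniform range of background clone counts.
#' @param blood_depth,blood_richness blood sampling depth and latent
#'   background richness.
#' @param blood_evenness_sigma lognormal jitter (sd on the log scale) of
#'   the near-uniform blood clone distribution; the default is calibrated
#'   so normalized blood Shannon sits near 0.97.
#' @param size_law background clone-size law, `"power_law"` or
#'   `"lognormal"`.
#' @param power_exponent Zipf exponent of the power-law background (the
#'   default reproduces a pre-treatment top-10 clone mass near 19%).
#' @param lognormal_sigma sd (log scale) of the lognormal alternative.
#' @param panel_size number of planted tumour-specific panel clones.
#' @param panel_motif CDR3 amino-acid motif carried by panel clones.
#' @param panel_mass total tumour panel frequency at day 0.
#' @param panel_exponent Zipf exponent of clone sizes *within* the panel;
#'   the default (1.2) makes the planted expansion oligoclonal, with a few
#'   dominant antigen-specific clones, so that post-expansion top-10 clone
#'   mass approaches half the repertoire.
#' @param blood_panel_mass total blood panel frequency at day 0 (panel is
#'   strongly down-weighted in blood).
#' @param fold_responder,fold_non_responder,fold_control per-step
#'   geometric fold applied to panel frequencies before renormalization.
#' @param public_fraction fraction of each subject's panel drawn from a
#'   study-wide shared (public) pool.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 8L,
                              groups = c("responder", "non_responder"),
                              timepoints = c(0L, 2L, 4L, 6L),
                              compartments = c("tumor", "blood"),
                              flanks = c("left", "right"),
                              tumor_model = "AB1",
                              tumor_total_range = c(1e3, 1e5),
                              tumor_richness_range = c(1e2, 1e4),
                              blood_depth = 1e4,
                              blood_richness = 5e3,
                              blood_evenness_sigma = 0.7,
                              size_law = c("power_law", "lognormal"),
                              power_exponent = 0.8,
                              lognormal_sigma = 1.5,
                              panel_size = 50L,
                              panel_motif = "WGQE",
                              panel_mass = 0.10,
                              panel_exponent = 1.2,
                              blood_panel_mass = 5e-4,
                              fold_responder = 2.0,
                              fold_non_responder = 1.2,
                              fold_control = 1.0,
                              public_fraction = 0.5) {
  size_law <- match.arg(size_law)
  chk <- function(ok, field, msg) if (!ok) stop("invalid '", field, "': ", msg)
  chk(n_subjects >= 1, "n_subjects", "must be >= 1")
  chk(length(groups) >= 1 &&
        all(groups %in% c("responder", "non_responder", "control")),
      "groups", "must be among responder/non_responder/control")
  chk(length(timepoints) >= 1 && !is.unsorted(timepoints), "timepoints",
      "must be non-decreasing")
  chk(all(compartments %in% c("tumor", "blood")) && length(compartments) >= 1,
      "compartments", "must be a subset of tumor/blood")
  chk(all(flanks %in% c("left", "right")) && length(flanks) >= 1,
      "flanks", "must be left/right")
  chk(length(tumor_total_range) == 2 && tumor_total_range[1] >= 1 &&
        diff(tumor_total_range) >= 0, "tumor_total_range", "bad range")
  chk(length(tumor_richness_range) == 2 && tumor_richness_range[1] >= 2 &&
        diff(tumor_richness_range) >= 0, "tumor_richness_range", "bad range")
  chk(blood_depth >= 1, "blood_depth", "must be >= 1")
  chk(blood_richness >= 2, "blood_richness", "must be >= 2")
  chk(blood_evenness_sigma >= 0, "blood_evenness_sigma", "must be >= 0")
  chk(power_exponent >= 0, "power_exponent", "must be >= 0")
  chk(lognormal_sigma > 0, "lognormal_sigma", "must be > 0")
  chk(panel_size >= 1, "panel_size", "must be >= 1")
  chk(grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]{3,}$"),
            panel_motif), "panel_motif",
      "must be >= 3 standard amino-acid letters")
  chk(panel_mass > 0 && panel_mass < 1, "panel_mass", "must be in (0, 1)")
  chk(panel_exponent >= 0, "panel_exponent", "must be >= 0")
  chk(blood_panel_mass >= 0 && blood_panel_mass < 1, "blood_panel_mass",
      "must be in [0, 1)")
  chk(fold_responder > 0 && fold_non_responder > 0 && fold_control > 0,
      "fold_responder/fold_non_responder/fold_control", "must be > 0")
  chk(public_fraction >= 0 && public_fraction <= 1, "public_fraction",
      "must be in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects), groups = groups,
                 timepoints = as.integer(timepoints),
                 compartments = compartments, flanks = flanks,
                 tumor_model = tumor_model,
                 tumor_total_range = tumor_total_range,
                 tumor_richness_range = tumor_richness_range,
                 blood_depth = as.integer(blood_depth),
                 blood_richness = as.integer(blood_richness),
                 blood_evenness_sigma = blood_evenness_sigma,
                 size_law = size_law, power_exponent = power_exponent,
                 lognormal_sigma = lognormal_sigma,
                 panel_size = as.integer(panel_size),
                 panel_motif = panel_motif, panel_mass = panel_mass,
                 panel_exponent = panel_exponent,
                 blood_panel_mass = blood_panel_mass,
                 folds = c(responder = fold_responder,
                           non_responder = fold_non_responder,
                           control = fold_control),
                 public_fraction = public_fraction),
            class = "simulation_config")
}

# Normalized within-panel clone-size weights (oligoclonal by default).
panel_weights <- function(config) {
  w <- (seq_len(config$panel_size))^(-config$panel_exponent)
  w / sum(w)
}

# Background clone-size weights under the configured law.
size_law_weights <- function(config, S) {
  if (config$size_law == "power_law") (1:S)^(-config$power_exponent)
  else exp(rnorm(S, 0, config$lognormal_sigma))
}

log_uniform <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

# Expected total panel mass after `step` geometric fold steps, starting
# from mass m0, with the background renormalized.
expected_panel_mass <- function(m0, fold, step) {
  w <- m0 * fold^step
  w / ((1 - m0) + w)
}

#' Simulate a longitudinal bilateral-tumour repertoire study
#'
#' For each subject a latent background clone distribution is drawn from
#' the configured size law and a tumour-antigen-specific panel (partly
#' shared across subjects, all entries carrying the planted CDR3 motif)
#' is added at the configured day-0 mass. At each timepoint the panel
#' frequencies are scaled by the group's geometric fold and renormalized;
#' each tumour flank and the blood compartment are then independent
#' multinomial draws from the subject's latent distribution at that
#' timepoint, so bilateral flanks share one underlying distribution while
#' subjects' backgrounds are disjoint by construction. Fully reproducible
#' given the seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @param out_dir optional directory; when given, AIRR TSVs, `meta.csv`,
#'   `panel.csv` and `truth.json` are written there.
#' @return list of class `repertoire_study` with elements `samples`
#'   (named list of `repertoire_sample`), `meta` (tibble), `truth`
#'   (latent ground truth), `panel` (the shared public pool as a
#'   [clonotype_panel()]), `config`, `seed`.
#' @export
simulate_study <- function(config = simulation_config(), seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  study <- withr::with_seed(as.integer(seed), simulate_study_impl(config))
  study$seed <- as.integer(seed)
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

simulate_study_impl <- function(config) {
  tps <- config$timepoints
  steps <- seq_along(tps) - 1L
  shared_pool <- tibble(
    cdr3_aa = random_cdr3(config$panel_size, motif = config$panel_motif),
    v_gene = sample(TRBV_GENES, config$panel_size, replace = TRUE),
    j_gene = sample(TRBJ_GENES, config$panel_size, replace = TRUE))
  n_pub <- round(config$public_fraction * config$panel_size)
  group_prefix <- c(responder = "R", non_responder = "N", control = "C")

  samples <- list()
  meta_rows <- list()
  subjects <- list()

  for (g in config$groups) {
    fold <- config$folds[[g]]
    for (si in seq_len(config$n_subjects)) {
      subject_id <- sprintf("%s%02d", group_prefix[[g]], si)
      pub_idx <- if (n_pub > 0) sample(config$panel_size, n_pub) else integer(0)
      panel <- bind_rows(
        shared_pool[pub_idx, ],
        tibble(cdr3_aa = random_cdr3(config$panel_size - length(pub_idx),
                                     motif = config$panel_motif),
               v_gene = sample(TRBV_GENES, config$panel_size - length(pub_idx),
                               replace = TRUE),
               j_gene = sample(TRBJ_GENES, config$panel_size - length(pub_idx),
                               replace = TRUE)))
      subj <- list(subject_id = subject_id, group = g, panel = panel)

      if ("tumor" %in% config$compartments) {
        S_bg <- max(50L, round(log_uniform(1, config$tumor_richness_range)) -
                      config$panel_size)
        bg <- tibble(cdr3_aa = random_cdr3(S_bg),
                     v_gene = sample(TRBV_GENES, S_bg, replace = TRUE),
                     j_gene = sample(TRBJ_GENES, S_bg, replace = TRUE))
        w_bg <- size_law_weights(config, S_bg)
        clones <- bind_rows(bg |> mutate(is_panel = FALSE),
                            panel |> mutate(is_panel = TRUE))
        w_panel <- panel_weights(config)
        base <- c(w_bg / sum(w_bg) * (1 - config$panel_mass),
                  w_panel * config$panel_mass)
        exp_freq <- vapply(steps, function(s) {
          w <- base * ifelse(clones$is_panel, fold^s, 1)
          w / sum(w)
        }, numeric(nrow(clones)))
        subj$tumor_clones <- clones
        subj$tumor_expected <- exp_freq
        for (ti in seq_along(tps)) {
          for (fl in config$flanks) {
            depth <- round(log_uniform(1, config$tumor_total_range))
            counts <- drop(rmultinom(1, depth, exp_freq[, ti]))
            sid <- sprintf("%s_tumor_%s_d%d", subject_id, fl, tps[ti])
            smp <- repertoire_sample(
              clones |> mutate(count = counts) |> filter(.data$count > 0),
              meta = sample_meta(sid, subject_id, "tumor", fl, tps[ti], g,
                                 config$tumor_model))
            samples[[sid]] <- smp
          }
        }
      }

      if ("blood" %in% config$compartments) {
        S_bl <- config$blood_richness
        bl_bg <- tibble(cdr3_aa = random_cdr3(S_bl),
                        v_gene = sample(TRBV_GENES, S_bl, replace = TRUE),
                        j_gene = sample(TRBJ_GENES, S_bl, replace = TRUE))
        w_bl <- exp(rnorm(S_bl, 0, config$blood_evenness_sigma))
        bl_clones <- bind_rows(bl_bg |> mutate(is_panel = FALSE),
                               panel |> mutate(is_panel = TRUE))
        base_bl <- c(w_bl / sum(w_bl) * (1 - config$blood_panel_mass),
                     panel_weights(config) * config$blood_panel_mass)
        exp_bl <- vapply(steps, function(s) {
          w <- base_bl * ifelse(bl_clones$is_panel, fold^s, 1)
          w / sum(w)
        }, numeric(nrow(bl_clones)))
        subj$blood_clones <- bl_clones
        subj$blood_expected <- exp_bl
        for (ti in seq_along(tps)) {
          counts <- drop(rmultinom(1, config$blood_depth, exp_bl[, ti]))
          sid <- sprintf("%s_blood_d%d", subject_id, tps[ti])
          samples[[sid]] <- repertoire_sample(
            bl_clones |> mutate(count = counts) |> filter(.data$count > 0),
            meta = sample_meta(sid, subject_id, "blood", "none", tps[ti], g,
                               config$tumor_model))
        }
      }
      subjects[[subject_id]] <- subj
    }
  }

  meta <- meta_table(samples)
  schedule <- bind_rows(lapply(config$groups, function(g) {
    tibble(group = g, timepoint = tps, step = steps,
           expected_tumor_panel_mass =
             expected_panel_mass(config$panel_mass, config$folds[[g]], steps),
           expected_blood_panel_mass =
             expected_panel_mass(config$blood_panel_mass, config$folds[[g]],
                                 steps))
  }))
  truth <- list(subjects = subjects, schedule = schedule)
  structure(list(samples = samples, meta = meta, truth = truth,
                 panel = clonotype_panel(shared_pool,
                                         panel_id = "planted_panel",
                                         provenance = "simulated shared pool"),
                 config = config),
            class = "repertoire_study")
}

#' Write a simulated study to disk
#'
#' AIRR rearrangement TSV per sample, a `meta.csv` sheet with a `path`
#' column, the shared panel as `panel.csv`, and a `truth.json` summary
#' (expansion schedule, per-subject panel keys, sample depths).
#'
#' @param study a `repertoire_study`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "samples"), showWarnings = FALSE)
  paths <- vapply(names(study$samples), function(sid) {
    p <- file.path("samples", paste0(sid, ".tsv"))
    write_repertoire(study$samples[[sid]], file.path(out_dir, p), "airr")
    p
  }, character(1))
  meta <- study$meta |> mutate(path = unname(paths[.data$sample_id]))
  readr::write_csv(meta, file.path(out_dir, "meta.csv"), progress = FALSE)
  readr::write_csv(study$panel$entries |> mutate(source = "simulated"),
                   file.path(out_dir, "panel.csv"), progress = FALSE)
  truth_summary <- list(
    seed = study$seed,
    schedule = study$truth$schedule,
    depths = study$meta |> select("sample_id", "total_count"),
    subject_panels = lapply(study$truth$subjects, function(s) {
      key_of(s$panel$cdr3_aa, s$panel$v_gene, s$panel$j_gene, "vjcdr3aa")
    }))
  jsonlite::write_json(truth_summary, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Check simulated samples against their generative ground truth
#'
#' Verifies, per sample, that (i) the empirical planted-panel mass matches
#' the group schedule within `sigma` multinomial standard errors, (ii) the
#' empirical frequency of the largest expected clone matches its latent
#' frequency within `sigma` standard errors, and (iii) tumour depths lie
#' inside the configured bounds.
#'
#' @param study a `repertoire_study` (as returned by [simulate_study()]).
#' @param sigma tolerance in multinomial standard errors.
#' @return tibble with columns `check`, `sample_id`, `observed`,
#'   `expected`, `tol`, `pass`.
#' @export
truth_check <- function(study, sigma = 3) {
  config <- study$config
  rows <- list()
  for (sid in names(study$samples)) {
    smp <- study$samples[[sid]]
    m <- smp$meta
    subj <- study$truth$subjects[[m$subject_id]]
    ti <- match(m$timepoint, config$timepoints)
    n <- smp$total_count
    if (m$compartment == "tumor") {
      clones <- subj$tumor_clones
      expf <- subj$tumor_expected[, ti]
    } else {
      clones <- subj$blood_clones
      expf <- subj$blood_expected[, ti]
    }
    keys <- key_of(clones$cdr3_aa, clones$v_gene, clones$j_gene, "vjcdr3aa")
    x <- clone_counts(smp, "vjcdr3aa")
    obs <- unname(x[keys]); obs[is.na(obs)] <- 0

    exp_mass <- sum(expf[clones$is_panel])
    obs_mass <- sum(obs[clones$is_panel]) / n
    tol <- sigma * sqrt(exp_mass * (1 - exp_mass) / n) + 2 / n
    rows[[length(rows) + 1]] <- tibble(
      check = "panel_mass", sample_id = sid, observed = obs_mass,
      expected = exp_mass, tol = tol, pass = abs(obs_mass - exp_mass) <= tol)

    top <- which.max(expf)
    tol2 <- sigma * sqrt(expf[top] * (1 - expf[top]) / n) + 2 / n
    rows[[length(rows) + 1]] <- tibble(
      check = "top_clone_freq", sample_id = sid, observed = obs[top] / n,
      expected = expf[top], tol = tol2,
      pass = abs(obs[top] / n - expf[top]) <= tol2)

    if (m$compartment == "tumor") {
      lo <- config$tumor_total_range[1]; hi <- config$tumor_total_range[2]
      rows[[length(rows) + 1]] <- tibble(
        check = "depth_bounds", sample_id = sid, observed = n,
        expected = NA_real_, tol = NA_real_, pass = n >= lo - 1 && n <= hi + 1)
    }
  }
  bind_rows(rows)
}
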