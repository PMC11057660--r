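small_cfg <- function(...) {
  simulation_config(n_subjects = 2, timepoints = c(0L, 2L),
                    tumor_total_range = c(500, 1500),
                    tumor_richness_range = c(80, 200),
                    blood_depth = 2000, blood_richness = 400, ...)
}

test_that("configuration validation names the offending field", {
  expect_error(simulation_config(n_subjects = 0), "n_subjects")
  expect_error(simulation_config(panel_mass = 1.2), "panel_mass")
  expect_error(simulation_config(panel_motif = "xy"), "panel_motif")
  expect_error(simulation_config(tumor_total_range = c(10, 1)),
               "tumor_total_range")
  expect_error(simulation_config(public_fraction = 2), "public_fraction")
  expect_error(simulation_config(groups = "maybe"), "groups")
})

test_that("identical config and seed give identical studies; seeds differ", {
  st1 <- simulate_study(small_cfg(), seed = 42)
  st2 <- simulate_study(small_cfg(), seed = 42)
  st3 <- simulate_study(small_cfg(), seed = 43)
  expect_identical(st1$meta, st2$meta)
  expect_identical(lapply(st1$samples, function(s) s$clonotypes),
                   lapply(st2$samples, function(s) s$clonotypes))
  expect_false(identical(lapply(st1$samples, function(s) s$clonotypes),
                         lapply(st3$samples, function(s) s$clonotypes)))
})

test_that("written studies round-trip byte-identically", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(small_cfg(), seed = 7, out_dir = d1)
  simulate_study(small_cfg(), seed = 7, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("meta.csv", "panel.csv", "truth.json") %in% f1))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("samples pass their generative truth checks at a fixed seed", {
  st <- simulate_study(small_cfg(), seed = 31)
  tc <- truth_check(st)
  expect_true(all(tc$pass))
  # corrupting one sample's counts fails a named check
  bad <- st
  subj_panel <- bad$truth$subjects[["R01"]]$panel
  panel_keys <- key_of(subj_panel$cdr3_aa, subj_panel$v_gene,
                       subj_panel$j_gene, "vjcdr3aa")
  sid <- "R01_tumor_left_d0"
  cl <- bad$samples[[sid]]$clonotypes
  skey <- key_of(cl$cdr3_aa, cl$v_gene, cl$j_gene, "vjcdr3aa")
  hit <- skey %in% panel_keys
  cl$count[hit] <- cl$count[hit] * 20 + 5
  bad$samples[[sid]] <- repertoire_sample(cl, meta = bad$samples[[sid]]$meta)
  tc_bad <- truth_check(bad)
  failed <- tc_bad[!tc_bad$pass, ]
  expect_gt(nrow(failed), 0)
  expect_true("panel_mass" %in% failed$check)
})

test_that("empirical frequencies converge to latent frequencies with depth", {
  cfg_lo <- small_cfg()
  st <- simulate_study(cfg_lo, seed = 3)
  subj <- st$truth$subjects[["R01"]]
  expf <- subj$tumor_expected[, 1]
  keys <- key_of(subj$tumor_clones$cdr3_aa, subj$tumor_clones$v_gene,
                 subj$tumor_clones$j_gene, "vjcdr3aa")
  err_at_depth <- function(depth, seed) {
    cnt <- withr::with_seed(seed, drop(rmultinom(1, depth, expf)))
    mean(abs(cnt / depth - expf))
  }
  expect_lt(err_at_depth(2e4, 5), err_at_depth(500, 5))
})

test_that("a null expansion schedule leaves groups indistinguishable", {
  cfg <- simulation_config(n_subjects = 5, timepoints = c(0L, 6L),
                           compartments = "tumor", flanks = "right",
                           tumor_total_range = c(2000, 3000),
                           tumor_richness_range = c(200, 400),
                           fold_responder = 1, fold_non_responder = 1)
  st <- simulate_study(cfg, seed = 17)
  div <- diversity_table(st$samples, seed = 1)
  d6 <- div[div$timepoint == 6, ]
  p <- wilcox.test(shannon_norm ~ group, data = d6)$p.value
  expect_gt(p, 0.05)
})

test_that("responder diversity falls by day 6 while non-responders stay flatter", {
  cfg <- simulation_config(n_subjects = 4, compartments = "tumor",
                           flanks = "right",
                           tumor_total_range = c(2000, 5000),
                           tumor_richness_range = c(200, 600))
  st <- simulate_study(cfg, seed = 23)
  div <- diversity_table(st$samples, seed = 2)
  agg <- div |>
    dplyr::group_by(group, timepoint) |>
    dplyr::summarise(sn = mean(shannon_norm), .groups = "drop")
  r0 <- agg$sn[agg$group == "responder" & agg$timepoint == 0]
  r6 <- agg$sn[agg$group == "responder" & agg$timepoint == 6]
  n0 <- agg$sn[agg$group == "non_responder" & agg$timepoint == 0]
  n6 <- agg$sn[agg$group == "non_responder" & agg$timepoint == 6]
  expect_lt(r6, r0)
  expect_lt(r6 - r0, n6 - n0)   # responders drop more
  # consistent with the planted expected frequencies, not just sampling noise
  sched <- st$truth$schedule
  expect_gt(sched$expected_tumor_panel_mass[sched$group == "responder" &
                                              sched$timepoint == 6],
            sched$expected_tumor_panel_mass[sched$group == "non_responder" &
                                              sched$timepoint == 6])
})

test_that("blood repertoires are near-uniform with evenness around 0.97", {
  cfg <- simulation_config(n_subjects = 3, timepoints = 0L,
                           compartments = "blood")
  st <- simulate_study(cfg, seed = 29)
  sn <- vapply(st$samples, function(s) shannon(s)$norm, numeric(1))
  expect_true(all(abs(sn - 0.97) < 0.1))
  expect_gt(mean(sn), 0.9)
})

test_that("planted panel clones all carry the configured motif", {
  st <- simulate_study(small_cfg(), seed = 12)
  expect_true(all(grepl("WGQE", st$panel$entries$cdr3_aa)))
  for (subj in st$truth$subjects) {
    expect_true(all(grepl("WGQE", subj$panel$cdr3_aa)))
    # public sharing: half of each subject's panel comes from the pool
    shared <- sum(subj$panel$cdr3_aa %in% st$panel$entries$cdr3_aa)
    expect_equal(shared, 25)
  }
})
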