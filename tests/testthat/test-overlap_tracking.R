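test_that("Morisita-Horn boundary identities hold exactly", {
  a <- make_sample(c(12, 7, 3, 1))
  expect_identical(morisita_horn(a, a)$mh, 1)
  b <- make_sample(c(5, 5), keys = c("CWWWAAGVWWWF", "CWWWCCGVWWWF"))
  expect_equal(morisita_horn(a, b)$mh, 0)
  expect_equal(morisita_horn(a, b)$shared_clones, 0)
})

test_that("Morisita-Horn matches hand computation, symmetry and scale invariance", {
  keys <- c("CASSXAGVAAAF", "CASSYAGVAAAF")
  a <- make_sample(c(30, 10), keys = keys)
  b <- make_sample(c(10, 30), keys = keys)
  expect_equal(morisita_horn(a, b)$mh, 0.6, tolerance = 1e-12)
  # permuted labels of an even pair are still identical repertoires
  u1 <- make_sample(c(10, 10), keys = keys)
  u2 <- make_sample(c(10, 10), keys = rev(keys))
  expect_equal(morisita_horn(u1, u2)$mh, 1, tolerance = 1e-12)
  for (seed in 1:15) {
    x <- random_sample(seed, sample_id = "x")
    y <- random_sample(seed + 100, sample_id = "y")
    # shared key space for about half the clones
    cl <- y$clonotypes
    n_shared <- min(nrow(cl), x$richness) %/% 2
    if (n_shared > 0) {
      cl$cdr3_aa[seq_len(n_shared)] <- x$clonotypes$cdr3_aa[seq_len(n_shared)]
    }
    y <- repertoire_sample(cl, meta = y$meta)
    expect_equal(morisita_horn(x, y)$mh, morisita_horn(y, x)$mh,
                 tolerance = 1e-14)
    y10 <- repertoire_sample(dplyr::mutate(y$clonotypes, count = count * 10),
                             meta = y$meta)
    expect_equal(morisita_horn(x, y10)$mh, morisita_horn(x, y)$mh,
                 tolerance = 1e-12)
  }
  expect_error(morisita_horn(a, filter_cdr3(make_sample(1, keys = "CF"))),
               "empty")
})

test_that("Morisita-Horn matches the brute-force double sum on random pairs", {
  for (seed in 1:100) {
    x <- random_sample(seed, max_S = 30, max_depth = 200)
    y <- random_sample(seed + 1000, max_S = 30, max_depth = 200)
    cl <- y$clonotypes
    k <- min(nrow(cl), x$richness)
    share <- withr::with_seed(seed, sample(k, sample.int(k, 1)))
    cl$cdr3_aa[share] <- x$clonotypes$cdr3_aa[share]
    y <- repertoire_sample(cl, meta = y$meta)
    expect_equal(morisita_horn(x, y)$mh,
                 unname(bf_morisita_horn(clone_counts(x), clone_counts(y))),
                 tolerance = 1e-12)
  }
})

test_that("overlap matrix enumerates strata like a bilateral design", {
  # 6 subjects x 2 flanks: 6 within-subject pairs, 60 between-subject pairs
  samples <- list()
  for (m in 1:6) for (fl in c("left", "right")) {
    samples[[paste0("m", m, fl)]] <-
      random_sample(m * 10 + nchar(fl), sample_id = paste0("m", m, "_", fl),
                    subject_id = paste0("m", m), flank = fl)
  }
  ov <- overlap_matrix(samples)
  expect_equal(nrow(ov), choose(12, 2))
  expect_equal(sum(ov$stratum == "within_subject"), 6)
  expect_equal(sum(ov$stratum == "between_subject"), 60)
  sm <- overlap_summary(ov)
  expect_setequal(sm$stratum, c("within_subject", "between_subject"))
  # duplicated sample set: within-subject overlap is exactly 1
  dup <- list(random_sample(5, sample_id = "a", subject_id = "m1"),
              random_sample(5, sample_id = "b", subject_id = "m1"))
  ovd <- overlap_matrix(dup)
  expect_equal(ovd$mh, 1)
  expect_error(overlap_matrix(dup[1]), "two samples")
})

test_that("clone trajectories flag persistence by the top-n rule", {
  mk <- function(tp, counts, keys) {
    make_sample(counts, keys = keys, sample_id = paste0("b", tp),
                compartment = "blood", flank = "none", timepoint = tp)
  }
  keys <- sprintf("CASSAAGQ%03dF", 1:5)
  series <- list(mk(0, c(50, 40, 30, 20, 10), keys),
                 mk(3, c(5, 45, 35, 25, 15), keys[c(1, 2, 3, 4, 5)]),
                 mk(6, c(60, 1, 2, 3, 4), keys))
  tr <- track_clones(series, top_n = 2)
  wide <- tr |> dplyr::distinct(clone_key, persistent_abundant)
  # clone 1 is top-2 at days 0 and 6; clone 2 at days 0 and 3
  expect_true(all(wide$persistent_abundant[wide$clone_key %in% keys[1:2]]))
  expect_false(any(wide$persistent_abundant[wide$clone_key %in% keys[4:5]]))
  expect_equal(persistent_count(series, top_n = 2), 2)
  # absent clones carry frequency zero and no rank
  series2 <- list(mk(0, c(10, 10), keys[1:2]), mk(3, c(10, 10), keys[3:4]))
  tr2 <- track_clones(series2, top_n = 100)
  absent <- tr2[tr2$clone_key == keys[1] & tr2$timepoint == 3, ]
  expect_equal(absent$frequency, 0)
  expect_true(is.na(absent$rank))
  expect_equal(persistent_count(series2), 0)
})

test_that("rank ties at the top-n boundary are all included", {
  keys <- sprintf("CASSTTGQ%03dF", 1:4)
  mk <- function(tp) make_sample(c(10, 5, 5, 1), keys = keys,
                                 sample_id = paste0("s", tp),
                                 compartment = "blood", timepoint = tp)
  tr <- track_clones(list(mk(0), mk(3)), top_n = 2)
  in_top0 <- tr$in_top[tr$timepoint == 0]
  # ranks 2 and 3 tie on count 5: both inside the top-2 boundary
  expect_equal(sum(in_top0), 3)
  expect_equal(persistent_count(list(mk(0), mk(3)), top_n = 2), 3)
})

test_that("trajectory preconditions are enforced", {
  s1 <- random_sample(1, subject_id = "m1", compartment = "blood", timepoint = 0)
  s2 <- random_sample(2, subject_id = "m2", compartment = "blood", timepoint = 3)
  expect_error(track_clones(list(s1)), "two timepoints")
  expect_error(track_clones(list(s1, s2)), "single subject")
})

test_that("clone flow reports paired frequencies for consecutive timepoints", {
  keys <- sprintf("CASSFFGQ%03dF", 1:3)
  s0 <- make_sample(c(8, 2, 0) + c(0, 0, 5), keys = keys, timepoint = 0,
                    compartment = "blood", sample_id = "f0")
  s3 <- make_sample(c(5, 5, 5), keys = keys, timepoint = 3,
                    compartment = "blood", sample_id = "f3")
  fl <- clone_flow(list(s0, s3))
  expect_equal(nrow(fl), 3)
  expect_equal(sum(fl$freq_from), 1, tolerance = 1e-12)
  expect_equal(sum(fl$freq_to), 1, tolerance = 1e-12)
})

test_that("simulated bilateral flanks overlap far more within than between subjects", {
  skip_if_not_installed("vegan")  # cross-check inside
  cfg <- simulation_config(n_subjects = 3, timepoints = 0L,
                           compartments = "tumor",
                           tumor_total_range = c(2000, 4000),
                           tumor_richness_range = c(150, 400))
  st <- simulate_study(cfg, seed = 21)
  rs <- rarefy_all(st$samples, seed = 2)
  ov <- overlap_matrix(rs)
  sm <- overlap_summary(ov)
  expect_gt(sm$mean_mh[sm$stratum == "within_subject"],
            sm$mean_mh[sm$stratum == "between_subject"] + 0.3)
  # vegan cross-check of one within-subject pair (MH = 1 - horn dissimilarity)
  pair <- st$samples[grep("R01_tumor", names(st$samples))]
  keys <- union(names(clone_counts(pair[[1]])), names(clone_counts(pair[[2]])))
  m <- rbind(a = clone_counts(pair[[1]])[keys], b = clone_counts(pair[[2]])[keys])
  m[is.na(m)] <- 0
  vh <- 1 - as.numeric(vegan::vegdist(m, method = "horn"))
  expect_equal(morisita_horn(pair[[1]], pair[[2]])$mh, vh, tolerance = 1e-10)
})
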