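# Small two-model study used across classifier tests: two tumour models,
# each with its own planted CDR3 motif carried by ~20% of repertoire mass.
two_model_study <- function(seed = 1, n_subjects = 4,
                            timepoints = c(0L, 2L)) {
  mk <- function(model, motif, sd) {
    simulate_study(simulation_config(
      n_subjects = n_subjects, timepoints = timepoints,
      compartments = "tumor", flanks = "right", tumor_model = model,
      tumor_total_range = c(1500, 3000),
      tumor_richness_range = c(150, 350),
      panel_motif = motif, panel_mass = 0.20,
      fold_responder = 1.5, fold_non_responder = 1.1), seed = sd)
  }
  a <- mk("AB1", "WGQE", seed)
  b <- mk("RENCA", "DNTY", seed + 500)
  # subject ids must differ between the two sub-studies
  bs <- lapply(b$samples, function(s) {
    s$meta$subject_id <- paste0("X", s$meta$subject_id)
    s$meta$sample_id <- paste0("X", s$meta$sample_id)
    s
  })
  names(bs) <- paste0("X", names(b$samples))
  c(a$samples, bs)
}

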