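test_that("simulation configs are validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_repeats = 0), "n_repeats")
  expect_error(simulation_config(inter_repeat_mutation_rate = 1.5), "\\[0,1\\]")
  expect_error(simulation_config(detection_probability = 0), "detection")
  expect_error(simulation_config(ambiguous_fraction = 1), "ambiguous")
  expect_error(simulation_config(noise_sigma = -1), "noise_sigma")
  expect_error(simulation_config(fixed_occupancy = c(1, 1, 0, 0)), "summing")
})

test_that("repeat-protein generation is deterministic and structured", {
  cfg <- simulation_config(n_repeats = 3, inter_repeat_mutation_rate = 0,
                           seed = 5)
  p1 <- generate_repeat_protein(cfg)
  p2 <- generate_repeat_protein(cfg)
  expect_equal(p1$sequence, p2$sequence)

  L <- attr(p1, "unit_length")
  starts <- attr(p1, "repeat_starts")
  expect_equal(nchar(p1$sequence),
               cfg$head_length + 3 * L + cfg$tail_length)
  units <- substring(p1$sequence, starts, starts + L - 1)
  expect_equal(units[1], units[2])
  expect_equal(units[1], units[3])
  expect_gte(count_lysines(protein_record("u", units[1])), 1)

  # single repeat, no mutation: head + unit + tail
  cfg1 <- simulation_config(n_repeats = 1, inter_repeat_mutation_rate = 0,
                            seed = 5)
  expect_equal(nchar(generate_repeat_protein(cfg1)$sequence),
               cfg1$head_length + L + cfg1$tail_length)

  # mutation diversifies copies but keeps the lysine register
  cfgm <- simulation_config(n_repeats = 3, inter_repeat_mutation_rate = 0.3,
                            seed = 5)
  pm <- generate_repeat_protein(cfgm)
  um <- substring(pm$sequence, attr(pm, "repeat_starts"),
                  attr(pm, "repeat_starts") + L - 1)
  expect_true(um[1] != um[2])
  kreg <- lapply(strsplit(um, ""), function(x) which(x == "K"))
  expect_equal(kreg[[1]], kreg[[2]])
  expect_equal(kreg[[1]], kreg[[3]])
})

test_that("ground-truth occupancy schemes behave as declared", {
  cfg <- simulation_config(seed = 9)
  p <- generate_repeat_protein(cfg)

  t_un <- assign_truth(p, simulation_config(
    seed = 9, occupancy_scheme = "all-unmethylated"))
  expect_true(all(t_un$occupancy[, "un"] == 1))

  t_fix <- assign_truth(p, simulation_config(seed = 9,
                                             occupancy_scheme = "fixed"))
  expect_true(all(apply(t_fix$occupancy, 1,
                        function(r) all(r == c(0.74, 0.26, 0, 0)))))

  t_dir1 <- assign_truth(p, cfg)
  t_dir2 <- assign_truth(p, cfg)
  expect_equal(t_dir1$occupancy, t_dir2$occupancy)
  expect_equal(unname(rowSums(t_dir1$occupancy)),
               rep(1, nrow(t_dir1$occupancy)), tolerance = 1e-12)
  expect_equal(rownames(t_dir1$occupancy),
               as.character(lysine_positions(p)))
  # mono-dominant defaults: unmethylated leads, trimethyl is trace
  expect_gt(mean(t_dir1$occupancy[, "un"]), mean(t_dir1$occupancy[, "mono"]))
  expect_lt(mean(t_dir1$occupancy[, "tri"]), 0.1)
})

test_that("an all-unmethylated noiseless simulation emits only unmodified species", {
  cfg <- simulation_config(n_repeats = 2, noise_sigma = 0,
                           detection_probability = 1, ambiguous_fraction = 0,
                           occupancy_scheme = "all-unmethylated", seed = 3)
  ds <- simulate_methylation_dataset(cfg)
  expect_gt(length(ds$psms$observations), 0)
  expect_true(all(vapply(ds$psms$observations,
                         function(o) nrow(o$modifications) == 0, TRUE)))
})

test_that("simulated tables are byte-identical under one seed and differ across seeds", {
  cfg <- simulation_config(n_repeats = 2, seed = 21, noise_sigma = 0.3,
                           detection_probability = 0.8,
                           ambiguous_fraction = 0.1)
  a <- simulate_methylation_dataset(cfg)
  b <- simulate_methylation_dataset(cfg)
  expect_identical(a$psms$table, b$psms$table)
  cfg2 <- simulation_config(n_repeats = 2, seed = 22, noise_sigma = 0.3,
                            detection_probability = 0.8,
                            ambiguous_fraction = 0.1)
  c <- simulate_methylation_dataset(cfg2)
  expect_false(identical(a$psms$table, c$psms$table))
})

test_that("a single-lysine protein recovers its planted occupancy in closed form", {
  p <- protein_record("single", "AAADDDKFFFGGG")
  truth <- manual_truth(p, stats::setNames(list(c(0.8, 0.2, 0, 0)), "7"))
  cfg <- simulation_config(noise_sigma = 0, detection_probability = 1,
                           ambiguous_fraction = 0, abundance_base = 1000,
                           seed = 1)
  psms <- simulate_psm_table(truth, cfg)

  tab <- psms$table
  full <- tab[tab$peptide == "AAADDDK", ]
  expect_equal(full$abundance[full$modifications == ""], 800)
  expect_equal(full$abundance[full$modifications == "K7(Monomethyl)"], 200)
  expect_false(any(grepl("Dimethyl|Trimethyl", tab$modifications)))

  st <- residue_stoichiometry(psms$observations, p)
  expect_equal(st$pct_un, 80, tolerance = 1e-12)
  expect_equal(st$pct_mono, 20, tolerance = 1e-12)
  rec <- evaluate_recovery(st, truth)
  expect_equal(rec$max_abs_error, 0, tolerance = 1e-9)
  expect_equal(rec$coverage, 1)
})

test_that("cleavage blocking at methylated lysines changes the peptide set deterministically", {
  p <- protein_record("single", "AAADDDKFFFGGGR")
  truth <- manual_truth(p, stats::setNames(list(c(0, 1, 0, 0)), "7"))
  cfg <- simulation_config(noise_sigma = 0, detection_probability = 1,
                           ambiguous_fraction = 0,
                           p_block_cleavage_if_methylated = 1, seed = 2)
  psms <- simulate_psm_table(truth, cfg)
  # fully methylated K with certain blocking: the K7 site never cleaves
  expect_false("AAADDDK" %in% psms$table$peptide)
  expect_true("AAADDDKFFFGGGR" %in% psms$table$peptide)
  psms2 <- simulate_psm_table(truth, cfg)
  expect_identical(psms$table, psms2$table)
})

test_that("recovery evaluation reports errors, coverage and mismatches", {
  p <- protein_record("toy", "MKAAAR")
  truth <- manual_truth(p, stats::setNames(list(c(0.8, 0.2, 0, 0)), "2"))
  st <- residue_stoichiometry(
    list(peptide_observation("MKAAAR", abundance = 75),
         peptide_observation("MKAAAR", "K2(Monomethyl)", abundance = 25)), p)
  rec <- evaluate_recovery(st, truth)
  expect_equal(rec$per_residue$err_un, 5)
  expect_equal(rec$per_residue$err_mono, 5)
  expect_equal(rec$max_abs_error, 5)

  # undetected residues drop out of the error but lower the coverage
  st0 <- residue_stoichiometry(list(), p)
  rec0 <- evaluate_recovery(st0, truth)
  expect_true(is.na(rec0$max_abs_error))
  expect_equal(rec0$coverage, 0)

  other <- protein_record("other", "MKAAAR")
  truth_other <- manual_truth(other, stats::setNames(list(c(1, 0, 0, 0)), "2"))
  expect_error(evaluate_recovery(st, truth_other), "different proteins")
})

test_that("truth and config serialize to JSON", {
  cfg <- simulation_config(n_repeats = 2, seed = 4)
  ds <- simulate_methylation_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(ds$truth, cfg, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$protein_id, ds$protein$id)
  expect_equal(length(back$occupancy), count_lysines(ds$protein))
  expect_equal(back$config$n_repeats, 2)
})
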