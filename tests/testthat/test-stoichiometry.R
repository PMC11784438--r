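test_that("state assignment at a position follows the offset arithmetic", {
  unmod <- peptide_observation("MKAAAR", abundance = 1)
  mono <- peptide_observation("MKAAAR", "K2(Monomethyl)", abundance = 1)

  expect_equal(assign_state_at_position(unmod, 1, 2), "un")
  expect_equal(assign_state_at_position(mono, 1, 2), "mono")
  expect_equal(assign_state_at_position(mono, 1, 10), NA_character_)
  # occurrence elsewhere shifts the offset
  expect_equal(assign_state_at_position(mono, 5, 6), "mono")
  # non-methyl modification at the offset counts as unmethylated
  ox <- peptide_observation("MKAAAR", "M1(Oxidation)", abundance = 1)
  expect_equal(assign_state_at_position(ox, 1, 1), "un")
})

test_that("abundance apportionment splits equally and conserves the total", {
  expect_equal(unname(apportion_abundance(100, c(1, 50))), c(50, 50))
  expect_equal(unname(apportion_abundance(30, c(1, 10, 19))), c(10, 10, 10))
  expect_equal(unname(apportion_abundance(7, 4)), 7)
  expect_error(apportion_abundance(7, integer(0)), "non-empty")
  set.seed(31)
  for (rep in 1:10) {
    ab <- runif(1, 0, 1e6)
    k <- sample(1:7, 1)
    expect_equal(sum(apportion_abundance(ab, seq_len(k))), ab)
  }
})

test_that("per-lysine stoichiometry reproduces hand-computed cases", {
  p <- protein_record("toy", "MKAAAR")
  obs <- list(
    peptide_observation("MKAAAR", abundance = 80),
    peptide_observation("MKAAAR", "K2(Monomethyl)", abundance = 20)
  )
  st <- residue_stoichiometry(obs, p)
  expect_equal(nrow(st), 1)
  expect_equal(st$position, 2L)
  expect_true(st$detected)
  expect_equal(st$pct_un, 80)
  expect_equal(st$pct_mono, 20)
  expect_equal(st$pct_di, 0)
  expect_equal(st$pct_tri, 0)

  # repeat apportionment: one peptide mapping to two unit copies
  p2 <- protein_record("rep2", "AKGGAKGG")
  st2 <- residue_stoichiometry(
    list(peptide_observation("AKGG", "K2(Monomethyl)", abundance = 60)), p2)
  expect_equal(st2$position, c(2L, 6L))
  expect_equal(st2$abundance_mono, c(30, 30))
  expect_equal(st2$pct_mono, c(100, 100))
  expect_equal(attr(st2, "diagnostics")$n_multimapped, 1)

  # no observations: nothing detected, percentages NA (never zero-filled)
  st3 <- residue_stoichiometry(list(), p)
  expect_false(any(st3$detected))
  expect_true(all(is.na(st3$pct_un)))
  expect_equal(st3$abundance_un, 0)
})

test_that("duplicate rows of one peptide species are summed before mapping", {
  p <- protein_record("toy", "MKAAAR")
  obs <- list(
    peptide_observation("MKAAAR", abundance = 30),
    peptide_observation("MKAAAR", abundance = 50),
    peptide_observation("MKAAAR", "K2(Monomethyl)", abundance = 20)
  )
  st <- residue_stoichiometry(obs, p)
  expect_equal(st$abundance_un, 80)
  expect_equal(st$pct_mono, 20)
  expect_equal(attr(st, "diagnostics")$n_species, 2)
})

test_that("ambiguous and unmapped peptides are excluded and logged", {
  p <- protein_record("toy", "MKAAAR")
  obs <- list(
    peptide_observation("MKAAAR", abundance = 50),
    peptide_observation("MKAAAR", "K2(Monomethyl)", abundance = 50,
                        localization_confident = FALSE),  # excluded
    peptide_observation("WWDDEE", abundance = 10)          # maps nowhere
  )
  st <- residue_stoichiometry(obs, p)
  expect_equal(st$pct_un, 100)  # ambiguous mono peptide did not count
  d <- attr(st, "diagnostics")
  expect_equal(d$n_ambiguous_excluded, 1)
  expect_equal(d$ambiguous_peptides, "MKAAAR")
  expect_equal(d$n_unmapped, 1)
  expect_equal(d$unmapped_peptides, "WWDDEE")
})

test_that("arginine methylation counts as unmethylated at covered lysines", {
  p <- protein_record("toy", "MKAAAR")
  obs <- list(
    peptide_observation("MKAAAR", "R6(Monomethyl)", abundance = 40),
    peptide_observation("MKAAAR", "K2(Monomethyl)", abundance = 60)
  )
  st <- residue_stoichiometry(obs, p)
  expect_equal(st$pct_un, 40)
  expect_equal(st$pct_mono, 60)
})

test_that("stoichiometry is invariant to observation order and abundance scale", {
  set.seed(77)
  p <- protein_record("rnd", random_sequence(50))
  digest <- tryptic_digest(p, max_missed = 2)
  obs <- lapply(seq_len(nrow(digest)), function(i) {
    pep <- digest$peptide[i]
    kin <- which(strsplit(pep, "")[[1]] == "K")
    ann <- if (length(kin) && runif(1) < 0.5)
      sprintf("K%d(Monomethyl)", kin[1]) else ""
    peptide_observation(pep, ann, abundance = runif(1, 1, 100))
  })
  base <- residue_stoichiometry(obs, p)

  perm <- residue_stoichiometry(sample(obs), p)
  for (col in c("position", "abundance_un", "abundance_mono", "abundance_di",
                "abundance_tri", "pct_un", "pct_mono", "pct_di", "pct_tri",
                "detected"))
    expect_equal(perm[[col]], base[[col]])

  scaled_obs <- lapply(obs, function(o) { o$abundance <- o$abundance * 17; o })
  scaled <- residue_stoichiometry(scaled_obs, p)
  expect_equal(scaled$pct_un, base$pct_un)
  expect_equal(scaled$pct_mono, base$pct_mono)
  expect_equal(methylation_summary(scaled)$mean_methylation_percent,
               methylation_summary(base)$mean_methylation_percent)
})

test_that("detected percentages normalise and abundance is conserved", {
  set.seed(123)
  for (rep in 1:8) {
    p <- protein_record("rnd", random_sequence(sample(30:60, 1),
                                               letters = c(AA, "K", "K")))
    digest <- tryptic_digest(p, max_missed = 2)
    take <- sample(nrow(digest), min(nrow(digest), 15))
    obs <- lapply(take, function(i) {
      pep <- digest$peptide[i]
      kin <- which(strsplit(pep, "")[[1]] == "K")
      ann <- if (length(kin) && runif(1) < 0.6)
        sprintf("K%d(%s)", kin[sample.int(length(kin), 1)],
                sample(c("Monomethyl", "Dimethyl", "Trimethyl"), 1)) else ""
      peptide_observation(pep, ann, abundance = runif(1, 0, 50),
                          localization_confident = runif(1) > 0.2)
    })
    st <- residue_stoichiometry(obs, p)
    det <- st[st$detected, ]
    if (nrow(det))
      expect_equal(det$pct_un + det$pct_mono + det$pct_di + det$pct_tri,
                   rep(100, nrow(det)), tolerance = 1e-9)
    assigned <- sum(st$abundance_un + st$abundance_mono +
                      st$abundance_di + st$abundance_tri)
    expect_equal(assigned, brute_total_assigned(obs, p$sequence),
                 tolerance = 1e-9)
  }
})

test_that("protein-level summary counts and mean follow their definitions", {
  tab <- data.frame(
    protein_id = "toy", position = c(1L, 4L, 9L), residue = "K",
    abundance_un = c(80, 50, 0), abundance_mono = c(20, 0, 0),
    abundance_di = c(0, 0, 0), abundance_tri = c(0, 0, 0),
    pct_un = c(80, 100, NA), pct_mono = c(20, 0, NA),
    pct_di = c(0, 0, NA), pct_tri = c(0, 0, NA),
    detected = c(TRUE, TRUE, FALSE))
  s <- methylation_summary(tab)
  expect_equal(s$n_lysines_total, 3)
  expect_equal(s$n_detected, 2)
  expect_equal(s$n_methylated, 1)
  expect_equal(s$n_monomethylated, 1)
  expect_equal(s$n_dimethylated, 0)
  expect_equal(s$mean_methylation_percent, 10)  # (20 + 0) / 2

  all_un <- tab[1:2, ]
  all_un$abundance_mono <- 0; all_un$pct_un <- 100; all_un$pct_mono <- 0
  s2 <- methylation_summary(all_un)
  expect_equal(s2$n_methylated, 0)
  expect_equal(s2$mean_methylation_percent, 0)

  none <- tab[3, ]
  s3 <- methylation_summary(none)
  expect_equal(s3$n_detected, 0)
  expect_true(is.na(s3$mean_methylation_percent))
})
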