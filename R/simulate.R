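# Synthetic repetitive-adhesin benchmark: a repeat protein with known
# per-lysine methylation occupancy, and a simulated label-free peptide
# table with the statistical structure the quantification assumes
# (species-level abundances, multiplicative noise, incomplete detection,
# ambiguous localization, shared peptides from repeats).

BG_LETTERS <- setdiff(AA20, c("K", "R"))  # non-cleavage background

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator in one validated list. The
#' defaults describe an adhesin-like repeat protein: a short unique head,
#' \code{n_repeats} copies of a 30-residue unit carrying two cleavage
#' lysines (one mid-unit, one at the unit boundary; a lysine fraction of
#' ~7\%, as in large repetitive adhesins), and a short unique tail. Unit
#' copies diverge by point mutations at \code{inter_repeat_mutation_rate}
#' per background position. The proteolytic skeleton is kept fixed across
#' copies: cleavage lysines are never mutated and the residue after a
#' cleavage site is never proline, so repeats stay aligned at fragment
#' resolution while their sequences diverge.
#'
#' @param n_repeats Number of repeat-unit copies.
#' @param repeat_unit_length Unit length in residues (>= 8).
#' @param inter_repeat_mutation_rate Per-position substitution probability
#'   applied independently to each copy's background positions, in [0,1].
#' @param head_length,tail_length Lengths of the unique flanking segments
#'   (lysine/arginine-free background sequence).
#' @param max_missed Maximum missed cleavages used when enumerating
#'   peptide species (default 2, the common search-engine setting).
#' @param p_block_cleavage_if_methylated Probability that a cleavage site
#'   at a lysine is suppressed, scaled by that lysine's methylated
#'   fraction (default 0: digestion is modification-blind, which makes
#'   noiseless recovery exact).
#' @param abundance_base Expected peak-area sum of a fully observed
#'   peptide species before occupancy weighting (arbitrary units).
#' @param noise_sigma Standard deviation of the multiplicative log-normal
#'   abundance noise, on the natural-log scale.
#' @param detection_probability Probability that a peptide species is
#'   observed at all, in (0,1].
#' @param ambiguous_fraction Fraction of modified species flagged as
#'   having ambiguous modification localization, in [0,1).
#' @param occupancy_scheme One of \code{"dirichlet"} (per-lysine vectors
#'   from a Dirichlet with mono-dominant defaults),
#'   \code{"fixed"} (every lysine gets \code{fixed_occupancy}) or
#'   \code{"all-unmethylated"}.
#' @param dirichlet_alpha Length-4 concentration for the
#'   (un, mono, di, tri) states; the default (8, 3, 0.3, 0.1) gives
#'   mono-dominant methylation with a mean methylated fraction near 30\%
#'   and only trace di/tri.
#' @param fixed_occupancy Length-4 occupancy vector for the fixed scheme;
#'   the default c(0.74, 0.26, 0, 0) plants 26\% methylation, the
#'   wild-type-like regime.
#' @param seed Integer master seed; every random draw in the generator
#'   derives from it.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_repeats = 5L,
                              repeat_unit_length = 30L,
                              inter_repeat_mutation_rate = 0.2,
                              head_length = 18L,
                              tail_length = 12L,
                              max_missed = 2L,
                              p_block_cleavage_if_methylated = 0,
                              abundance_base = 1e6,
                              noise_sigma = 0.2,
                              detection_probability = 1,
                              ambiguous_fraction = 0,
                              occupancy_scheme = c("dirichlet", "fixed",
                                                   "all-unmethylated"),
                              dirichlet_alpha = c(8, 3, 0.3, 0.1),
                              fixed_occupancy = c(0.74, 0.26, 0, 0),
                              seed = 1L) {
  occupancy_scheme <- match.arg(occupancy_scheme)
  chk <- function(ok, msg) if (!ok) stop_input("simulation_config: %s", msg)
  chk(n_repeats >= 1, "'n_repeats' must be >= 1")
  chk(repeat_unit_length >= 8, "'repeat_unit_length' must be >= 8")
  chk(inter_repeat_mutation_rate >= 0 && inter_repeat_mutation_rate <= 1,
      "'inter_repeat_mutation_rate' must be in [0,1]")
  chk(head_length >= 0 && tail_length >= 0, "flank lengths must be >= 0")
  chk(max_missed >= 0, "'max_missed' must be >= 0")
  chk(p_block_cleavage_if_methylated >= 0 &&
        p_block_cleavage_if_methylated <= 1, "'p_block...' must be in [0,1]")
  chk(abundance_base > 0, "'abundance_base' must be positive")
  chk(noise_sigma >= 0, "'noise_sigma' must be >= 0")
  chk(detection_probability > 0 && detection_probability <= 1,
      "'detection_probability' must be in (0,1]")
  chk(ambiguous_fraction >= 0 && ambiguous_fraction < 1,
      "'ambiguous_fraction' must be in [0,1)")
  chk(length(dirichlet_alpha) == 4L && all(dirichlet_alpha >= 0),
      "'dirichlet_alpha' must be 4 non-negative numbers")
  chk(length(fixed_occupancy) == 4L && all(fixed_occupancy >= 0) &&
        abs(sum(fixed_occupancy) - 1) < 1e-9,
      "'fixed_occupancy' must be 4 non-negative numbers summing to 1")
  structure(list(
    n_repeats = as.integer(n_repeats),
    repeat_unit_length = as.integer(repeat_unit_length),
    inter_repeat_mutation_rate = inter_repeat_mutation_rate,
    head_length = as.integer(head_length),
    tail_length = as.integer(tail_length),
    max_missed = as.integer(max_missed),
    p_block_cleavage_if_methylated = p_block_cleavage_if_methylated,
    abundance_base = abundance_base,
    noise_sigma = noise_sigma,
    detection_probability = detection_probability,
    ambiguous_fraction = ambiguous_fraction,
    occupancy_scheme = occupancy_scheme,
    dirichlet_alpha = dirichlet_alpha,
    fixed_occupancy = fixed_occupancy,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Sample one background letter (optionally excluding proline, for the
# position right after a cleavage site) different from `not`.
sample_bg <- function(n, no_proline = FALSE, not = NULL) {
  pool <- if (no_proline) setdiff(BG_LETTERS, "P") else BG_LETTERS
  if (!is.null(not)) pool <- setdiff(pool, not)
  sample(pool, n, replace = TRUE)
}

#' Generate a repetitive test protein
#'
#' Builds head + \code{n_repeats} unit copies + tail. The unit template
#' carries two lysines (mid-unit and unit-terminal); each copy is then
#' independently point-mutated at \code{inter_repeat_mutation_rate} on its
#' background positions. Deterministic given \code{config$seed}.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{protein_record}} with attributes
#'   \code{repeat_starts} (1-based start of each unit copy) and
#'   \code{unit_length}.
#' @export
generate_repeat_protein <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    L <- config$repeat_unit_length
    mid <- (L + 1L) %/% 2L
    k_offsets <- c(mid, L)                       # cleavage lysines
    no_p <- c(1L, mid + 1L)                      # follow a cleavage site
    template <- character(L)
    template[k_offsets] <- "K"
    bg_idx <- setdiff(seq_len(L), k_offsets)
    for (i in bg_idx) template[i] <- sample_bg(1L, no_proline = i %in% no_p)

    copies <- vapply(seq_len(config$n_repeats), function(j) {
      unit <- template
      mut <- bg_idx[stats::runif(length(bg_idx)) <
                      config$inter_repeat_mutation_rate]
      for (i in mut)
        unit[i] <- sample_bg(1L, no_proline = i %in% no_p, not = unit[i])
      paste(unit, collapse = "")
    }, "")

    head_seq <- if (config$head_length > 0)
      paste(sample_bg(config$head_length), collapse = "") else ""
    tail_seq <- if (config$tail_length > 0)
      paste(c(sample_bg(1L, no_proline = TRUE),
              if (config$tail_length > 1L) sample_bg(config$tail_length - 1L)),
            collapse = "") else ""

    p <- protein_record(
      sprintf("SYNREP_n%d_seed%d", config$n_repeats, config$seed),
      paste0(head_seq, paste(copies, collapse = ""), tail_seq),
      sprintf("synthetic repeat protein (%d x %d aa unit)",
              config$n_repeats, L))
    attr(p, "repeat_starts") <-
      config$head_length + (seq_len(config$n_repeats) - 1L) * L + 1L
    attr(p, "unit_length") <- L
    p
  })
}

#' Assign ground-truth occupancy vectors
#'
#' Draws, for every lysine of the protein, a ground-truth occupancy vector
#' over the four methylation states (unmethylated, mono, di, tri), under
#' the scheme selected in the config. Deterministic given
#' \code{config$seed} (an offset stream separate from sequence
#' generation).
#'
#' @param protein A \code{\link{protein_record}}.
#' @param config A \code{\link{simulation_config}}.
#' @return An object of class \code{synthetic_truth}: list with
#'   \code{protein} and \code{occupancy}, a (number of lysines) x 4 matrix
#'   with position rownames and state colnames, rows summing to 1.
#' @export
assign_truth <- function(protein, config) {
  stopifnot(inherits(config, "simulation_config"))
  protein <- as_protein_record(protein)
  k_pos <- lysine_positions(protein)
  if (length(k_pos) == 0L)
    stop_input("protein '%s' has no lysines to assign occupancy to",
               protein$id)
  occ <- with_seed(config$seed + 1L, {
    switch(config$occupancy_scheme,
      "all-unmethylated" = matrix(rep(c(1, 0, 0, 0), each = length(k_pos)),
                                  ncol = 4L),
      "fixed" = matrix(rep(config$fixed_occupancy, each = length(k_pos)),
                       ncol = 4L),
      "dirichlet" = {
        g <- matrix(stats::rgamma(length(k_pos) * 4L,
                                  shape = rep(config$dirichlet_alpha,
                                              each = length(k_pos))),
                    ncol = 4L)
        g / rowSums(g)
      })
  })
  dimnames(occ) <- list(as.character(k_pos), METHYL_STATES)
  stopifnot(all(abs(rowSums(occ) - 1) < 1e-12))
  structure(list(protein = protein, occupancy = occ),
            class = "synthetic_truth")
}

#' Simulate a label-free peptide observation table
#'
#' Enumerates the tryptic peptide species of the protein (up to
#' \code{max_missed} missed cleavages) and, for each peptide and each
#' combination of methylation states over its lysines, computes the
#' expected species abundance \code{abundance_base * prod(occupancy)}.
#' Species arising identically from several repeat occurrences are merged
#' by summing expected abundances (the table reports peptide species, not
#' positions — this is what makes repeat multi-mapping a real problem for
#' the downstream quantification). Each merged species then receives one
#' multiplicative log-normal noise draw, is emitted with
#' \code{detection_probability}, and modified species are flagged
#' ambiguous with \code{ambiguous_fraction}. With
#' \code{p_block_cleavage_if_methylated > 0}, cleavage sites at lysines
#' are suppressed with probability \code{p_block * methylated fraction}
#' before enumeration. Deterministic given \code{config$seed}.
#'
#' @param truth A \code{\link{assign_truth}} result.
#' @param config A \code{\link{simulation_config}}.
#' @return A list of class \code{synthetic_psm_set}: \code{observations}
#'   (list of \code{\link{peptide_observation}}), \code{table} (native
#'   dialect data.frame), and \code{provenance} (config plus species
#'   counts).
#' @export
simulate_psm_table <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(config, "simulation_config"))
  protein <- truth$protein
  occ <- truth$occupancy
  k_pos <- as.integer(rownames(occ))
  seqn <- protein$sequence

  with_seed(config$seed + 2L, {
    sites <- cleavage_sites(seqn)
    if (config$p_block_cleavage_if_methylated > 0) {
      chars <- strsplit(seqn, "", fixed = TRUE)[[1]]
      keep <- vapply(sites, function(s) {
        if (chars[s] != "K") return(TRUE)
        f_meth <- 1 - occ[as.character(s), "un"]
        stats::runif(1) >= config$p_block_cleavage_if_methylated * f_meth
      }, TRUE)
      sites <- sites[keep]
    }
    peptides <- digest_from_sites(seqn, sites, config$max_missed)

    expected <- new.env(parent = emptyenv())
    add_species <- function(key, value) {
      assign(key, (if (exists(key, envir = expected)) get(key, envir = expected)
                   else 0) + value, envir = expected)
    }
    state_names <- c(mono = "Monomethyl", di = "Dimethyl", tri = "Trimethyl")
    for (r in seq_len(nrow(peptides))) {
      pep <- peptides$peptide[r]
      kp <- k_pos[k_pos >= peptides$start[r] & k_pos <= peptides$end[r]]
      if (length(kp) == 0L) {
        add_species(paste0(pep, "\r"), config$abundance_base)
        next
      }
      offsets <- kp - peptides$start[r] + 1L
      combos <- expand.grid(rep(list(METHYL_STATES), length(kp)),
                            stringsAsFactors = FALSE)
      for (ci in seq_len(nrow(combos))) {
        states <- as.character(combos[ci, ])
        w <- prod(occ[cbind(as.character(kp), states)])
        if (w <= 0) next
        modded <- states != "un"
        ann <- if (any(modded))
          paste(sprintf("K%d(%s)", offsets[modded], state_names[states[modded]]),
                collapse = "; ") else ""
        add_species(paste0(pep, "\r", ann), config$abundance_base * w)
      }
    }

    keys <- sort(ls(expected), method = "radix")
    obs <- vector("list", length(keys))
    n_emitted <- 0L
    for (key in keys) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      pep <- parts[1L]
      ann <- if (length(parts) > 1L) parts[2L] else ""
      mu <- get(key, envir = expected)
      noise <- if (config$noise_sigma > 0)
        exp(stats::rnorm(1, 0, config$noise_sigma)) else 1
      detected <- stats::runif(1) < config$detection_probability
      confident <- !(nzchar(ann) &&
                       stats::runif(1) < config$ambiguous_fraction)
      if (!detected) next
      n_emitted <- n_emitted + 1L
      obs[[n_emitted]] <- peptide_observation(
        pep, ann, abundance = mu * noise,
        localization_confident = confident)
    }
    obs <- obs[seq_len(n_emitted)]

    structure(list(
      observations = obs,
      table = psm_table_frame(obs),
      provenance = list(config = unclass(config),
                        protein_id = protein$id,
                        n_species_possible = length(keys),
                        n_species_emitted = n_emitted)
    ), class = "synthetic_psm_set")
  })
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: generates the protein, assigns truth, and
#' simulates the observation table from a single config.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A list with \code{protein}, \code{truth} and \code{psms}.
#' @export
simulate_methylation_dataset <- function(config) {
  protein <- generate_repeat_protein(config)
  truth <- assign_truth(protein, config)
  psms <- simulate_psm_table(truth, config)
  list(protein = protein, truth = truth, psms = psms)
}

#' Compare estimated stoichiometry with planted truth
#'
#' Per-residue absolute errors (in percentage points) between estimated
#' state percentages and the planted occupancy, for detected residues;
#' undetected residues are excluded from the error and reported through
#' the coverage instead.
#'
#' @param stoich A \code{\link{residue_stoichiometry}} table.
#' @param truth A \code{\link{synthetic_truth}}.
#' @return A list of class \code{recovery_report}: \code{per_residue}
#'   (data.frame of absolute errors per state), \code{max_abs_error},
#'   \code{mean_abs_error} (both in percentage points, \code{NA} when
#'   nothing was detected), \code{coverage} (fraction of lysines
#'   detected), \code{n_detected}, \code{n_lysines}.
#' @export
evaluate_recovery <- function(stoich, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!all(stoich$protein_id == truth$protein$id))
    stop_input("stoichiometry table and truth describe different proteins (%s vs %s)",
               stoich$protein_id[1L], truth$protein$id)
  occ <- truth$occupancy
  if (!setequal(rownames(occ), as.character(stoich$position)))
    stop_input("lysine positions of estimate and truth disagree")
  det <- stoich[stoich$detected, , drop = FALSE]
  if (nrow(det)) {
    est <- as.matrix(det[, c("pct_un", "pct_mono", "pct_di", "pct_tri")])
    tru <- occ[as.character(det$position), , drop = FALSE] * 100
    err <- abs(est - tru)
    per_residue <- data.frame(position = det$position,
                              err_un = err[, 1L], err_mono = err[, 2L],
                              err_di = err[, 3L], err_tri = err[, 4L],
                              row.names = NULL)
    max_err <- max(err)
    mean_err <- mean(err)
  } else {
    per_residue <- data.frame(position = integer(0), err_un = numeric(0),
                              err_mono = numeric(0), err_di = numeric(0),
                              err_tri = numeric(0))
    max_err <- NA_real_
    mean_err <- NA_real_
  }
  structure(list(per_residue = per_residue,
                 max_abs_error = max_err,
                 mean_abs_error = mean_err,
                 coverage = nrow(det) / nrow(stoich),
                 n_detected = nrow(det),
                 n_lysines = nrow(stoich)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d/%d lysines detected (coverage %.1f%%)\n",
              x$n_detected, x$n_lysines, 100 * x$coverage))
  cat(sprintf("  absolute error (percentage points): max %.3g, mean %.3g\n",
              x$max_abs_error, x$mean_abs_error))
  invisible(x)
}

#' Write ground truth and config as JSON
#'
#' @param truth A \code{\link{synthetic_truth}}.
#' @param config The \code{\link{simulation_config}} used.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, config, path) {
  payload <- list(
    protein_id = truth$protein$id,
    sequence = truth$protein$sequence,
    occupancy = lapply(rownames(truth$occupancy), function(p)
      as.list(stats::setNames(truth$occupancy[p, ], METHYL_STATES))),
    positions = as.integer(rownames(truth$occupancy)),
    config = unclass(config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
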