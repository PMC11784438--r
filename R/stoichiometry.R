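#' Methylation state of one residue position under one peptide occurrence
#'
#' Given a peptide observation and one exact occurrence of its sequence in
#' the protein (by start position), returns the methylation state the
#' observation implies at a protein position: \code{"mono"}, \code{"di"} or
#' \code{"tri"} when a K/R methylation is annotated at the corresponding
#' within-peptide offset, \code{"un"} when the occurrence covers the
#' position but carries no methylation there (other modification kinds are
#' ignored), and \code{NA} when the occurrence does not cover the position.
#'
#' @param obs A \code{\link{peptide_observation}}.
#' @param occurrence_start 1-based start of the occurrence in the protein.
#' @param position 1-based protein position to interrogate.
#' @return \code{"un"}, \code{"mono"}, \code{"di"}, \code{"tri"} or
#'   \code{NA_character_} (not covered).
#' @export
assign_state_at_position <- function(obs, occurrence_start, position) {
  offset <- position - occurrence_start + 1L
  if (offset < 1L || offset > nchar(obs$peptide_seq)) return(NA_character_)
  mods <- obs$modifications
  if (nrow(mods)) {
    hit <- which(mods$position == offset &
                 mods$kind %in% c("monomethyl", "dimethyl", "trimethyl"))
    if (length(hit) == 1L)
      return(c(monomethyl = "mono", dimethyl = "di",
               trimethyl = "tri")[[mods$kind[hit]]])
  }
  "un"
}

#' Apportion a peptide's abundance across its repeat occurrences
#'
#' When a peptide sequence occurs at several positions of a repetitive
#' protein, label-free quantification cannot distinguish the copies; the
#' peptide's abundance is divided by the number of occurrences and assigned
#' equally to each. Shares always sum to the original abundance.
#'
#' @param abundance Non-negative numeric scalar (or a
#'   \code{\link{peptide_observation}}, whose abundance is used).
#' @param occurrences Non-empty vector of occurrence start positions.
#' @return Numeric vector of per-occurrence shares, named by start position.
#' @examples
#' apportion_abundance(100, c(1, 50))
#' @export
apportion_abundance <- function(abundance, occurrences) {
  if (inherits(abundance, "peptide_observation"))
    abundance <- abundance$abundance
  if (length(occurrences) == 0L)
    stop_input("'occurrences' must be non-empty; unmapped peptides are a diagnostic event, not an apportionment input")
  shares <- rep(abundance / length(occurrences), length(occurrences))
  names(shares) <- as.character(occurrences)
  shares
}

# Merge rows reporting the same peptide species (same sequence, same
# modification set, same confidence flag) by summing their abundances —
# label-free peptide abundance is the sum of the species' peak areas.
aggregate_observations <- function(observations) {
  if (!length(observations)) return(observations)
  keys <- vapply(observations, function(o) {
    paste(o$peptide_seq, format_modifications(o$modifications),
          o$localization_confident, sep = "\r")
  }, "")
  split_idx <- split(seq_along(observations), factor(keys, levels = unique(keys)))
  lapply(split_idx, function(idx) {
    o <- observations[[idx[1L]]]
    o$abundance <- sum(vapply(observations[idx], function(x) x$abundance, 0))
    o
  })
}

#' Per-lysine methylation stoichiometry
#'
#' The core computation: every peptide observation is mapped by exact
#' sequence onto the protein; peptides with ambiguously localized
#' modifications are excluded; the abundance of a peptide occurring at
#' several positions is divided equally among all occurrences; and for
#' every lysine of the protein the apportioned abundances of all covering
#' peptide occurrences are summed per methylation state (unmethylated,
#' mono-, di-, trimethylated, as implied by the modification at the
#' corresponding within-peptide offset). For detected residues (total
#' abundance above \code{min_abundance}) the state percentages are the
#' state abundances divided by the residue total times 100; for undetected
#' residues the percentages are \code{NA}, never silently zero.
#'
#' Rows reporting the same peptide species are first merged by summing
#' abundances. Peptides that map nowhere in the protein are excluded and
#' counted in the diagnostics (they may belong to other proteins).
#'
#' @param observations List of \code{\link{peptide_observation}}s.
#' @param protein A \code{\link{protein_record}}.
#' @param min_abundance Detection threshold on a residue's total abundance;
#'   the default 0 means any strictly positive abundance counts as
#'   detected.
#' @return A data.frame of class \code{residue_stoichiometry} with one row
#'   per lysine: \code{protein_id}, \code{position}, \code{residue},
#'   \code{abundance_un/mono/di/tri}, \code{pct_un/mono/di/tri},
#'   \code{detected}. Attribute \code{"diagnostics"} carries counts and
#'   identities of ambiguous-excluded, unmapped and multi-mapping peptides.
#' @export
residue_stoichiometry <- function(observations, protein, min_abundance = 0) {
  protein <- as_protein_record(protein)
  k_pos <- lysine_positions(protein)
  n_obs_in <- length(observations)
  observations <- aggregate_observations(observations)
  keep_flag <- vapply(observations, function(o) {
    nrow(o$modifications) == 0L || o$localization_confident
  }, TRUE)
  kept <- observations[keep_flag]
  n_ambiguous <- sum(!keep_flag)
  ambiguous_peptides <- vapply(observations[!keep_flag],
                               function(o) o$peptide_seq, "")

  ab <- matrix(0, nrow = length(k_pos), ncol = 4L,
               dimnames = list(as.character(k_pos), METHYL_STATES))
  unmapped <- character(0)
  multimapped <- character(0)
  for (o in kept) {
    occ <- map_peptide_occurrences(o$peptide_seq, protein)
    if (length(occ) == 0L) {
      unmapped <- c(unmapped, o$peptide_seq)
      next
    }
    if (length(occ) > 1L) multimapped <- c(multimapped, o$peptide_seq)
    shares <- apportion_abundance(o$abundance, occ)
    len <- nchar(o$peptide_seq)
    for (j in seq_along(occ)) {
      covered <- k_pos[k_pos >= occ[j] & k_pos <= occ[j] + len - 1L]
      for (p in covered) {
        st <- assign_state_at_position(o, occ[j], p)
        ab[as.character(p), st] <- ab[as.character(p), st] + shares[j]
      }
    }
  }

  total <- rowSums(ab)
  detected <- total > min_abundance
  pct <- ab / ifelse(total > 0, total, NA_real_) * 100
  pct[!detected, ] <- NA_real_

  out <- data.frame(
    protein_id = protein$id,
    position = k_pos,
    residue = "K",
    abundance_un = ab[, "un"], abundance_mono = ab[, "mono"],
    abundance_di = ab[, "di"], abundance_tri = ab[, "tri"],
    pct_un = pct[, "un"], pct_mono = pct[, "mono"],
    pct_di = pct[, "di"], pct_tri = pct[, "tri"],
    detected = detected,
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (length(k_pos) == 0L)
    warning(sprintf("protein '%s' contains no lysine residues", protein$id))
  attr(out, "diagnostics") <- list(
    n_observations_in = n_obs_in,
    n_species = length(observations),
    n_ambiguous_excluded = n_ambiguous,
    ambiguous_peptides = unique(ambiguous_peptides),
    n_unmapped = length(unmapped),
    unmapped_peptides = unique(unmapped),
    n_multimapped = length(unique(multimapped)),
    multimapped_peptides = unique(multimapped)
  )
  class(out) <- c("residue_stoichiometry", class(out))
  out
}

#' Protein-level methylation summary
#'
#' Counts of detected and methylated lysines, per-state site counts, and
#' the average percentage of lysine methylation: the unweighted mean over
#' detected residues of (100 − unmethylated percentage), i.e. every methyl
#' state counts as methylated.
#'
#' @param stoich A \code{\link{residue_stoichiometry}} table for one
#'   protein.
#' @return A list of class \code{methylation_summary}:
#'   \code{n_lysines_total}, \code{n_detected}, \code{n_methylated},
#'   \code{n_monomethylated}, \code{n_dimethylated},
#'   \code{n_trimethylated}, \code{mean_methylation_percent} (\code{NA}
#'   when no residue was detected).
#' @export
methylation_summary <- function(stoich) {
  if (length(unique(stoich$protein_id)) > 1L)
    stop_input("summary is defined per protein; got %d protein ids",
               length(unique(stoich$protein_id)))
  det <- stoich[stoich$detected, , drop = FALSE]
  methyl_ab <- det$abundance_mono + det$abundance_di + det$abundance_tri
  mean_pct <- if (nrow(det)) mean(100 - det$pct_un) else NA_real_
  structure(list(
    protein_id = if (nrow(stoich)) stoich$protein_id[1L] else NA_character_,
    n_lysines_total = nrow(stoich),
    n_detected = nrow(det),
    n_methylated = sum(methyl_ab > 0),
    n_monomethylated = sum(det$abundance_mono > 0),
    n_dimethylated = sum(det$abundance_di > 0),
    n_trimethylated = sum(det$abundance_tri > 0),
    mean_methylation_percent = mean_pct
  ), class = "methylation_summary")
}

#' @export
print.methylation_summary <- function(x, ...) {
  cat(sprintf("<methylation_summary> %s\n", x$protein_id))
  cat(sprintf("  lysines: %d total, %d detected, %d methylated\n",
              x$n_lysines_total, x$n_detected, x$n_methylated))
  cat(sprintf("  sites: %d mono, %d di, %d tri\n",
              x$n_monomethylated, x$n_dimethylated, x$n_trimethylated))
  cat(sprintf("  mean methylation of detected residues: %s\n",
              if (is.na(x$mean_methylation_percent)) "undefined (none detected)"
              else sprintf("%.1f%%", x$mean_methylation_percent)))
  invisible(x)
}

#' Write stoichiometry results
#'
#' \code{write_stoichiometry_tsv} writes the per-lysine table as
#' tab-separated text; \code{write_summary_json} writes a
#' \code{\link{methylation_summary}} as JSON.
#'
#' @param stoich A \code{residue_stoichiometry} table.
#' @param summary A \code{methylation_summary}.
#' @param path Output file path.
#' @export
write_stoichiometry_tsv <- function(stoich, path) {
  utils::write.table(as.data.frame(stoich), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stoichiometry_tsv
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
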