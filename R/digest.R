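#' In-silico tryptic digestion
#'
#' Enumerates the peptides produced by trypsin, which cleaves C-terminal to
#' lysine (K) or arginine (R) except when the next residue is proline (P),
#' allowing up to \code{max_missed} internal (missed) cleavage sites per
#' peptide. Digestion operates on the bare sequence; modifications are
#' never consulted here.
#'
#' @param protein A \code{\link{protein_record}} or a sequence string.
#' @param max_missed Maximum number of internal cleavage sites per peptide
#'   (non-negative integer; search engines commonly allow 2).
#' @param min_length,max_length Optional peptide-length filters; \code{NULL}
#'   (the default) disables them.
#' @return A data.frame with columns \code{peptide}, \code{start},
#'   \code{end} (1-based inclusive) and \code{missed_cleavages}, sorted by
#'   (start, end).
#' @examples
#' tryptic_digest("AKRPKA", max_missed = 0)
#' @export
tryptic_digest <- function(protein, max_missed = 2L,
                           min_length = NULL, max_length = NULL) {
  protein <- as_protein_record(protein)
  if (!is.numeric(max_missed) || length(max_missed) != 1L || max_missed < 0)
    stop_input("'max_missed' must be a single non-negative integer")
  sites <- cleavage_sites(protein$sequence)
  out <- digest_from_sites(protein$sequence, sites, as.integer(max_missed))
  if (!is.null(min_length)) out <- out[nchar(out$peptide) >= min_length, ]
  if (!is.null(max_length)) out <- out[nchar(out$peptide) <= max_length, ]
  rownames(out) <- NULL
  out
}

# Positions i such that the bond after residue i is cleaved by trypsin:
# residue i is K or R and residue i+1 exists and is not P.
cleavage_sites <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R"))
  idx[chars[idx + 1L] != "P"]
}

# Enumerate peptides given an explicit (possibly thinned) cleavage-site
# list; shared by tryptic_digest and the simulator's cleavage-blocking
# option.
digest_from_sites <- function(sequence, sites, max_missed) {
  n <- nchar(sequence)
  bounds <- c(0L, sites, n)           # fragment f spans bounds[f]+1..bounds[f+1]
  nfrag <- length(bounds) - 1L
  rows <- vector("list", 0L)
  k <- 0L
  for (f in seq_len(nfrag)) {
    last <- min(nfrag, f + max_missed)
    for (g in f:last) {
      k <- k + 1L
      rows[[k]] <- c(bounds[f] + 1L, bounds[g + 1L], g - f)
    }
  }
  m <- do.call(rbind, rows)
  ord <- order(m[, 1L], m[, 2L])
  m <- m[ord, , drop = FALSE]
  data.frame(
    peptide = substring(sequence, m[, 1L], m[, 2L]),
    start = m[, 1L],
    end = m[, 2L],
    missed_cleavages = m[, 3L],
    stringsAsFactors = FALSE
  )
}

#' Map a peptide to all its occurrences in a protein
#'
#' Exact-substring search returning every 1-based start position of
#' \code{peptide_seq} in the protein, in ascending order; overlapping
#' occurrences count. \code{X} residues (in either string) never match, so
#' peptides containing \code{X} map nowhere. Absence is a valid result
#' (empty integer vector), not an error.
#'
#' @param peptide_seq Non-empty amino-acid string.
#' @param protein A \code{\link{protein_record}} or a sequence string.
#' @return Integer vector of start positions (possibly empty).
#' @examples
#' map_peptide_occurrences("AA", "AAA")   # overlapping: 1, 2
#' @export
map_peptide_occurrences <- function(peptide_seq, protein) {
  if (!is.character(peptide_seq) || length(peptide_seq) != 1L ||
      !nzchar(peptide_seq))
    stop_input("'peptide_seq' must be a non-empty string")
  protein <- as_protein_record(protein)
  peptide_seq <- toupper(peptide_seq)
  if (grepl("X", peptide_seq, fixed = TRUE)) return(integer(0))
  if (nchar(peptide_seq) > nchar(protein$sequence)) return(integer(0))
  hits <- Biostrings::matchPattern(peptide_seq,
                                   Biostrings::AAString(protein$sequence))
  starts <- Biostrings::start(hits)
  if (length(starts) == 0L) return(integer(0))
  # X in the protein never matches anything, including X in the peptide
  matched <- substring(protein$sequence, starts,
                       starts + nchar(peptide_seq) - 1L)
  sort(starts[!grepl("X", matched, fixed = TRUE)])
}
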