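#' Extract flanking-sequence windows around residues
#'
#' For each given lysine position, returns the sequence window spanning
#' \code{flank} residues on either side (length \code{2*flank + 1});
#' positions outside the protein are padded with \code{"-"}. Aligning such
#' windows centered on methylated lysines is the standard way to look for
#' a linear consensus motif around a modification site.
#'
#' @param protein A \code{\link{protein_record}}.
#' @param positions 1-based positions; each must be a K within the
#'   protein.
#' @param flank Number of residues on each side (default 10).
#' @return Character vector of windows (one per position), with the
#'   positions as names.
#' @export
extract_windows <- function(protein, positions, flank = 10L) {
  protein <- as_protein_record(protein)
  if (flank < 0) stop_input("'flank' must be non-negative")
  n <- nchar(protein$sequence)
  if (length(positions) == 0L) return(character(0))
  if (any(positions < 1L | positions > n))
    stop_input("window center position out of sequence bounds (1..%d)", n)
  centers <- substring(protein$sequence, positions, positions)
  if (any(centers != "K"))
    stop_input("window centers must be lysine residues; offending position(s): %s",
               paste(positions[centers != "K"], collapse = ", "))
  windows <- vapply(positions, function(p) {
    lo <- p - flank
    hi <- p + flank
    core <- substring(protein$sequence, max(1L, lo), min(n, hi))
    paste0(strrep("-", max(0L, 1L - lo)), core, strrep("-", max(0L, hi - n)))
  }, "")
  names(windows) <- as.character(positions)
  windows
}

#' Select methylated lysines from a stoichiometry table
#'
#' A lysine counts as methylated when any methyl-state abundance is
#' strictly positive; optionally a minimum total methylation percentage
#' can be required instead.
#'
#' @param stoich A \code{\link{residue_stoichiometry}} table.
#' @param min_percent Minimum (100 − pct_un) to qualify; the default 0
#'   keeps every residue with any methylated abundance.
#' @return Integer vector of positions.
#' @export
methylated_positions <- function(stoich, min_percent = 0) {
  methyl_ab <- stoich$abundance_mono + stoich$abundance_di +
    stoich$abundance_tri
  sel <- stoich$detected & methyl_ab > 0
  if (min_percent > 0)
    sel <- sel & (100 - stoich$pct_un) >= min_percent
  stoich$position[sel]
}

#' Position frequency matrix with information content
#'
#' Builds per-column amino-acid counts from equal-length windows and
#' computes each column's information content, \code{log2(20)} minus the
#' Shannon entropy of the column's letter frequencies. Pad characters
#' (\code{"-"}) are excluded from the counts and from the frequency
#' denominators, so columns near the protein termini rest on fewer
#' observations.
#'
#' @param windows Character vector of equal-length windows (from
#'   \code{\link{extract_windows}}).
#' @return An object of class \code{position_frequency_matrix}: a list
#'   with \code{counts} (20 x width integer matrix), \code{n_windows},
#'   \code{n_letters} (per-column non-pad counts) and
#'   \code{information_content} (bits; \code{NA} for all-pad columns).
#' @export
build_pfm <- function(windows) {
  if (length(windows) == 0L) stop_input("no windows supplied")
  widths <- unique(nchar(windows))
  if (length(widths) != 1L)
    stop_input("windows must have uniform length; got lengths %s",
               paste(widths, collapse = ", "))
  w <- widths
  mat <- do.call(rbind, strsplit(windows, "", fixed = TRUE))
  counts <- matrix(0L, nrow = length(AA20), ncol = w,
                   dimnames = list(AA20, seq_len(w)))
  for (j in seq_len(w)) {
    tab <- table(factor(mat[, j], levels = AA20))
    counts[, j] <- as.integer(tab)
  }
  n_letters <- colSums(counts)
  ic <- vapply(seq_len(w), function(j) {
    nj <- n_letters[j]
    if (nj == 0L) return(NA_real_)
    f <- counts[, j] / nj
    f <- f[f > 0]
    log2(20) - (-sum(f * log2(f)))
  }, 0)
  structure(list(counts = counts, n_windows = length(windows),
                 n_letters = n_letters, information_content = ic),
            class = "position_frequency_matrix")
}

#' @export
print.position_frequency_matrix <- function(x, ...) {
  cat(sprintf("<position_frequency_matrix> %d windows, width %d\n",
              x$n_windows, ncol(x$counts)))
  cat("  information content (bits):\n  ")
  cat(sprintf("%.2f", x$information_content), sep = " ")
  cat("\n")
  invisible(x)
}

#' Consensus verdict from a position frequency matrix
#'
#' Flags columns whose information content reaches \code{ic_threshold}
#' and reports whether any flanking column (the center column, which is
#' lysine by construction and therefore uninformative, is excluded) shows
#' a consensus signal.
#'
#' @param pfm A \code{\link{build_pfm}} result.
#' @param ic_threshold Information-content threshold in bits (default 1).
#' @param center Column index of the window center; defaults to the middle
#'   column.
#' @return A list with \code{column_flags} (logical per column; the center
#'   is \code{NA}), \code{consensus} (single logical) and the threshold
#'   used.
#' @export
consensus_verdict <- function(pfm, ic_threshold = 1.0, center = NULL) {
  w <- ncol(pfm$counts)
  if (is.null(center)) center <- (w + 1L) %/% 2L
  flags <- pfm$information_content >= ic_threshold
  flags[center] <- NA
  list(column_flags = flags,
       consensus = isTRUE(any(flags[-center], na.rm = TRUE)),
       ic_threshold = ic_threshold,
       center = center)
}

#' Write motif outputs
#'
#' \code{write_windows_fasta} writes the aligned windows as FASTA-like
#' text (one record per center position); \code{write_pfm_tsv} writes the
#' count matrix with relative-offset column labels plus an information
#' content row.
#'
#' @param windows Named character vector from \code{\link{extract_windows}}.
#' @param pfm A \code{position_frequency_matrix}.
#' @param path Output path.
#' @param flank Flank size used (for offset labels).
#' @export
write_windows_fasta <- function(windows, path) {
  lines <- as.vector(rbind(paste0(">K", names(windows)), windows))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_windows_fasta
#' @export
write_pfm_tsv <- function(pfm, path, flank = (ncol(pfm$counts) - 1L) %/% 2L) {
  offs <- seq_len(ncol(pfm$counts)) - flank - 1L
  df <- as.data.frame(pfm$counts)
  colnames(df) <- sprintf("%+d", offs)
  colnames(df)[offs == 0L] <- "0"
  df <- cbind(letter = rownames(pfm$counts), df)
  ic <- c("IC_bits", sprintf("%.6g", pfm$information_content))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(ic, collapse = "\t"), con)
  invisible(path)
}
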