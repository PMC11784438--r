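# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: plain character loops, no Biostrings.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force trypsin digestion: enumerate every substring whose
# boundaries are termini or cleavage sites (after K/R not before P) and
# whose internal cleavage-site count is at most max_missed.
brute_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cut_after <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    if (chars[i] %in% c("K", "R") && chars[i + 1] != "P") cut_after[i] <- TRUE
  }
  rows <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      left_ok <- (i == 1) || cut_after[i - 1]
      right_ok <- (j == n) || cut_after[j]
      if (!left_ok || !right_ok) next
      internal <- if (j > i) sum(cut_after[i:(j - 1)]) else 0L
      if (internal > max_missed) next
      rows[[length(rows) + 1]] <- data.frame(
        peptide = paste(chars[i:j], collapse = ""),
        start = i, end = j, missed_cleavages = internal,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), ]
  rownames(out) <- NULL
  out
}

# Naive scan for exact occurrences (overlaps allowed; X never matches).
naive_occurrences <- function(s, protein_seq) {
  ls <- nchar(s)
  n <- nchar(protein_seq)
  if (grepl("X", s, fixed = TRUE) || ls > n) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - ls + 1)) {
    sub <- substr(protein_seq, i, i + ls - 1)
    if (sub == s && !grepl("X", sub, fixed = TRUE)) hits <- c(hits, i)
  }
  hits
}

random_sequence <- function(len, letters = AA) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Brute-force re-count of the total abundance a set of observations
# assigns across all lysines and states: for every mapped observation,
# each occurrence receives abundance/k and contributes one share per
# covered lysine.
brute_total_assigned <- function(observations, protein_seq) {
  kpos <- which(strsplit(protein_seq, "", fixed = TRUE)[[1]] == "K")
  total <- 0
  for (o in observations) {
    if (nrow(o$modifications) > 0 && !o$localization_confident) next
    occ <- naive_occurrences(o$peptide_seq, protein_seq)
    if (length(occ) == 0) next
    share <- o$abundance / length(occ)
    for (s in occ) {
      covered <- sum(kpos >= s & kpos <= s + nchar(o$peptide_seq) - 1)
      total <- total + share * covered
    }
  }
  total
}

# A minimal hand-rolled synthetic_truth for hand-crafted proteins.
manual_truth <- function(protein, occupancy_rows) {
  occ <- do.call(rbind, occupancy_rows)
  dimnames(occ) <- list(names(occupancy_rows),
                        c("un", "mono", "di", "tri"))
  structure(list(protein = protein, occupancy = occ),
            class = "synthetic_truth")
}
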