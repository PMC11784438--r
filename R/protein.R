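#' Protein record
#'
#' A minimal container for one protein: an identifier, an upper-case
#' amino-acid sequence over the 20 standard letters (plus \code{X} for
#' unknown residues), and an optional description. All residue positions
#' reported by this package are 1-based and refer to this sequence.
#'
#' @param id Character scalar identifier (e.g. a GenBank accession).
#' @param sequence Amino-acid sequence; coerced to upper case.
#' @param description Optional free-text description (FASTA header remainder).
#' @return An object of class \code{protein_record}.
#' @examples
#' protein_record("toy", "MKAAARKLP")
#' @export
protein_record <- function(id, sequence, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop_input("'id' must be a non-empty character scalar")
  if (!is.character(sequence) || length(sequence) != 1L)
    stop_input("'sequence' must be a character scalar")
  sequence <- toupper(gsub("[[:space:]]", "", sequence))
  if (!nzchar(sequence))
    stop_input("protein '%s': sequence is empty", id)
  bad <- setdiff(unique(strsplit(sequence, "", fixed = TRUE)[[1]]),
                 c(AA20, "X"))
  if (length(bad))
    stop_input("protein '%s': disallowed letters in sequence: %s",
               id, paste(bad, collapse = ", "))
  structure(
    list(id = id, sequence = sequence, description = description),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa, %d K)\n",
              x$id, nchar(x$sequence), count_lysines(x)))
  invisible(x)
}

as_protein_record <- function(x, id = "protein") {
  if (inherits(x, "protein_record")) return(x)
  if (is.character(x) && length(x) == 1L) return(protein_record(id, x))
  stop_input("expected a protein_record or a single sequence string")
}

#' Residue access helpers
#'
#' @param protein A \code{protein_record} (or a bare sequence string).
#' @return \code{lysine_positions()} returns the 1-based positions of all
#'   K residues; \code{count_lysines()} their number.
#' @examples
#' lysine_positions(protein_record("toy", "MKAAKR"))
#' @export
lysine_positions <- function(protein) {
  protein <- as_protein_record(protein)
  which(strsplit(protein$sequence, "", fixed = TRUE)[[1]] == "K")
}

#' @rdname lysine_positions
#' @export
count_lysines <- function(protein) length(lysine_positions(protein))

#' Read and write protein FASTA files
#'
#' Thin wrappers around \pkg{Biostrings} that convert between FASTA files
#' and lists of \code{\link{protein_record}} objects. The first whitespace
#' token of each header becomes the record id; the remainder is kept as the
#' description.
#'
#' @param path File path.
#' @param proteins For \code{write_fasta}, a \code{protein_record} or a list
#'   of them.
#' @return \code{read_fasta} returns a named list of \code{protein_record}s.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop_input("FASTA file contains no records: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  recs <- lapply(seq_along(set), function(i) {
    protein_record(ids[i], as.character(set[[i]]), desc[i])
  })
  names(recs) <- ids
  recs
}

#' @rdname read_fasta
#' @export
write_fasta <- function(proteins, path) {
  if (inherits(proteins, "protein_record")) proteins <- list(proteins)
  seqs <- Biostrings::AAStringSet(vapply(proteins, function(p) p$sequence, ""))
  names(seqs) <- vapply(proteins, function(p) {
    if (nzchar(p$description)) paste(p$id, p$description) else p$id
  }, "")
  Biostrings::writeXStringSet(seqs, filepath = path, width = 70L)
  invisible(path)
}
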