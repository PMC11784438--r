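#' Parse a modification annotation string
#'
#' Parses the compact annotation dialect used by search-engine peptide
#' exports: semicolon-separated tokens of the form \code{"X<pos>(<Name>)"}
#' where \code{X} is the residue letter and \code{<pos>} the 1-based
#' position within the peptide, e.g. \code{"K3(Monomethyl); K7(Dimethyl)"}.
#' \code{"N-Term(Acetyl)"} denotes N-terminal acetylation and maps to
#' position 0. Recognised names (case-insensitive): Monomethyl/Methyl,
#' Dimethyl, Trimethyl, Acetyl (N-terminal), Oxidation; anything else is
#' carried with kind \code{"other"}.
#'
#' @param text Annotation string; empty or \code{NA} yields zero rows.
#' @return A data.frame with columns \code{position} (integer, 0 = peptide
#'   N-terminus), \code{residue} (single letter, \code{"-"} for the
#'   N-terminus) and \code{kind} (one of \code{monomethyl}, \code{dimethyl},
#'   \code{trimethyl}, \code{acetyl-nterm}, \code{oxidation}, \code{other}).
#' @examples
#' parse_modification_string("K3(Monomethyl); K7(Dimethyl)")
#' @export
parse_modification_string <- function(text) {
  empty <- data.frame(position = integer(0), residue = character(0),
                      kind = character(0), stringsAsFactors = FALSE)
  if (is.null(text) || length(text) == 0L || is.na(text)) return(empty)
  text <- trimws(text)
  if (!nzchar(text)) return(empty)
  tokens <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(empty)
  rows <- lapply(tokens, function(tok) {
    if (grepl("^N-Term\\(([^)]+)\\)$", tok, ignore.case = TRUE)) {
      name <- sub("^N-Term\\(([^)]+)\\)$", "\\1", tok, ignore.case = TRUE)
      kind <- if (tolower(name) == "acetyl") "acetyl-nterm" else "other"
      return(data.frame(position = 0L, residue = "-", kind = kind,
                        stringsAsFactors = FALSE))
    }
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)\\(([^)]+)\\)$", tok))[[1]]
    if (length(m) != 4L)
      stop_input("unparseable modification token: '%s'", tok)
    kind <- switch(tolower(m[4]),
                   "monomethyl" = "monomethyl",
                   "methyl" = "monomethyl",
                   "dimethyl" = "dimethyl",
                   "trimethyl" = "trimethyl",
                   "oxidation" = "oxidation",
                   "other")
    data.frame(position = as.integer(m[3]), residue = toupper(m[2]),
               kind = kind, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Canonical annotation string for a modification table (inverse of the
# parser, up to token order: sorted by position).
format_modifications <- function(mods) {
  if (is.null(mods) || nrow(mods) == 0L) return("")
  mods <- mods[order(mods$position), , drop = FALSE]
  name_of <- c(monomethyl = "Monomethyl", dimethyl = "Dimethyl",
               trimethyl = "Trimethyl", oxidation = "Oxidation",
               `acetyl-nterm` = "Acetyl", other = "Other")
  toks <- ifelse(
    mods$position == 0L,
    sprintf("N-Term(%s)", name_of[mods$kind]),
    sprintf("%s%d(%s)", mods$residue, mods$position, name_of[mods$kind])
  )
  paste(toks, collapse = "; ")
}

#' Construct a peptide observation
#'
#' One identified, quantified peptide species: its sequence, attached
#' modifications, a label-free abundance (peak-area sum, arbitrary units)
#' and a localization-confidence flag. Modifications are validated against
#' the peptide: positions must lie within it (0 = N-terminus), at most one
#' modification per position, methyl kinds only on K or R.
#'
#' @param peptide_seq Amino-acid string.
#' @param modifications A data.frame as returned by
#'   \code{\link{parse_modification_string}}, or an annotation string.
#' @param abundance Non-negative numeric.
#' @param localization_confident Logical; \code{FALSE} marks a peptide
#'   whose modification site(s) could not be confidently localized.
#' @return An object of class \code{peptide_observation}.
#' @export
peptide_observation <- function(peptide_seq, modifications = NULL,
                                abundance = 0,
                                localization_confident = TRUE) {
  if (!is.character(peptide_seq) || length(peptide_seq) != 1L ||
      !nzchar(peptide_seq))
    stop_input("'peptide_seq' must be a non-empty string")
  peptide_seq <- toupper(peptide_seq)
  if (is.character(modifications))
    modifications <- parse_modification_string(modifications)
  if (is.null(modifications))
    modifications <- parse_modification_string("")
  if (!is.numeric(abundance) || length(abundance) != 1L ||
      is.na(abundance) || abundance < 0)
    stop_input("'abundance' must be a single non-negative number")
  if (!is.logical(localization_confident) ||
      length(localization_confident) != 1L || is.na(localization_confident))
    stop_input("'localization_confident' must be TRUE or FALSE")
  n <- nchar(peptide_seq)
  if (nrow(modifications)) {
    if (any(modifications$position > n))
      stop_input("modification position beyond peptide length (%d) in '%s'",
                 n, peptide_seq)
    if (anyDuplicated(modifications$position))
      stop_input("more than one modification at the same position in '%s'",
                 peptide_seq)
    internal <- modifications$position >= 1L
    if (any(internal)) {
      at <- substring(peptide_seq, modifications$position[internal],
                      modifications$position[internal])
      if (any(at != modifications$residue[internal]))
        stop_input("modification residue letter disagrees with peptide '%s'",
                   peptide_seq)
      methyl <- internal & modifications$kind %in%
        c("monomethyl", "dimethyl", "trimethyl")
      if (any(!modifications$residue[methyl] %in% c("K", "R")))
        stop_input("methylation annotated on a residue other than K/R in '%s'",
                   peptide_seq)
    }
  }
  modifications <- modifications[order(modifications$position), , drop = FALSE]
  rownames(modifications) <- NULL
  structure(
    list(peptide_seq = peptide_seq,
         modifications = modifications,
         abundance = as.numeric(abundance),
         localization_confident = localization_confident),
    class = "peptide_observation"
  )
}

#' @export
print.peptide_observation <- function(x, ...) {
  ann <- format_modifications(x$modifications)
  cat(sprintf("<peptide_observation> %s [%s] abundance=%g confident=%s\n",
              x$peptide_seq, if (nzchar(ann)) ann else "unmodified",
              x$abundance, x$localization_confident))
  invisible(x)
}

#' Column-mapping dialect for peptide tables
#'
#' Declarative description of a delimited peptide-table layout: which
#' column holds the peptide sequence, the modification annotation string,
#' the abundance, and the localization-confidence flag. The default is the
#' package's native tab-separated dialect; redefining the column names
#' adapts the reader to search-engine exports.
#'
#' @param peptide,modifications,abundance,confident Column names.
#' @param sep Field separator.
#' @return A list of class \code{psm_dialect}.
#' @export
psm_dialect <- function(peptide = "peptide",
                        modifications = "modifications",
                        abundance = "abundance",
                        confident = "localization_confident",
                        sep = "\t") {
  structure(list(peptide = peptide, modifications = modifications,
                 abundance = abundance, confident = confident, sep = sep),
            class = "psm_dialect")
}

#' Read a peptide identification/quantification table
#'
#' Reads a delimited text table (one row per peptide species) into a list
#' of \code{\link{peptide_observation}}s, using a \code{\link{psm_dialect}}
#' column mapping. Rows with zero abundance are retained. Malformed rows
#' (unparseable abundance, invalid modification annotations) are reported
#' together with their line numbers in a single error.
#'
#' @param path File path.
#' @param dialect A \code{\link{psm_dialect}}.
#' @return A list of \code{peptide_observation}s (empty for a header-only
#'   file).
#' @export
read_psm_table <- function(path, dialect = psm_dialect()) {
  if (!file.exists(path)) stop_input("peptide table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          quote = "", comment.char = "",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(dialect$peptide, dialect$modifications,
                dialect$abundance, dialect$confident)
  missing_cols <- setdiff(required, colnames(df))
  if (length(missing_cols))
    stop_input("peptide table %s: missing required column(s): %s",
               path, paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(list())
  errors <- character(0)
  obs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    ab <- suppressWarnings(as.numeric(df[[dialect$abundance]][i]))
    if (is.na(ab)) {
      errors <- c(errors, sprintf(
        "line %d: unparseable abundance '%s'", line, df[[dialect$abundance]][i]))
      next
    }
    conf_raw <- tolower(trimws(df[[dialect$confident]][i]))
    conf <- conf_raw %in% c("true", "t", "1", "yes", "high")
    res <- tryCatch(
      peptide_observation(df[[dialect$peptide]][i],
                          df[[dialect$modifications]][i],
                          abundance = ab,
                          localization_confident = conf),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors <- c(errors, sprintf("line %d: %s", line, res))
    } else {
      obs[[i]] <- res
    }
  }
  if (length(errors))
    stop_input("peptide table %s: %d malformed row(s):\n%s",
               path, length(errors), paste(errors, collapse = "\n"))
  obs[!vapply(obs, is.null, TRUE)]
}

#' @describeIn read_psm_table Write observations in the native tab-separated
#'   dialect (round-trips through \code{read_psm_table}).
#' @param observations List of \code{peptide_observation}s.
#' @export
write_psm_table <- function(observations, path, dialect = psm_dialect()) {
  df <- psm_table_frame(observations, dialect)
  utils::write.table(df, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

psm_table_frame <- function(observations, dialect = psm_dialect()) {
  df <- data.frame(
    peptide = vapply(observations, function(o) o$peptide_seq, ""),
    modifications = vapply(observations,
                           function(o) format_modifications(o$modifications), ""),
    abundance = vapply(observations, function(o) o$abundance, 0),
    localization_confident = vapply(observations,
                                    function(o) o$localization_confident, TRUE),
    stringsAsFactors = FALSE
  )
  colnames(df) <- c(dialect$peptide, dialect$modifications,
                    dialect$abundance, dialect$confident)
  df
}

#' Exclude peptides with ambiguously localized modifications
#'
#' Site-level quantification must not use peptides whose modification could
#' not be confidently placed on a specific residue: an observation carrying
#' one or more modifications with \code{localization_confident = FALSE} is
#' removed. Unmodified observations are always retained (there is nothing
#' to localize), and input order is preserved. Idempotent.
#'
#' @param observations List of \code{\link{peptide_observation}}s.
#' @return Filtered list.
#' @export
filter_ambiguous <- function(observations) {
  keep <- vapply(observations, function(o) {
    nrow(o$modifications) == 0L || o$localization_confident
  }, TRUE)
  observations[keep]
}
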