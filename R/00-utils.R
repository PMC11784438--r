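# Internal helpers shared across modules.

# Standard 20 amino-acid alphabet; 'X' is tolerated in sequences but is
# never matched when mapping peptides onto a protein.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

METHYL_STATES <- c("un", "mono", "di", "tri")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Evaluate `expr` under a fixed RNG state and restore the caller's state
# afterwards, so simulation determinism never leaks into user sessions.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
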