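# Shared alphabet tables and error helpers. Everything here is internal.

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

DNA_ALPHABET <- c(names(IUPAC_SETS), "-")

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-"
)

# Template character (row) vs primer base (column): TRUE when the primer base
# counts as a match. Ambiguity codes match iff their set contains the primer
# base; N and gaps match nothing (conservative).
MATCH_TBL <- local({
  m <- matrix(FALSE, nrow = length(DNA_ALPHABET), ncol = length(DNA_BASES),
              dimnames = list(DNA_ALPHABET, DNA_BASES))
  for (code in names(IUPAC_SETS)) {
    if (code == "N") next
    m[code, IUPAC_SETS[[code]]] <- TRUE
  }
  m
})

# classed condition so callers/tests can match on the error family
stop_aspcr <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "aspcr_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

# Uppercase, fold U->T (warn), and verify the IUPAC-DNA alphabet; returns the
# normalized string or raises a positioned alphabet error.
normalize_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop_aspcr("aspcr_alphabet_error", "%s must be a non-empty string", what)
  }
  s <- toupper(seq)
  if (grepl("U", s, fixed = TRUE)) {
    warning(sprintf("'U' converted to 'T' in %s", what), call. = FALSE)
    s <- gsub("U", "T", s, fixed = TRUE)
  }
  bad <- regexpr("[^ACGTRYSWKMBDHVN-]", s)
  if (bad != -1L) {
    stop_aspcr("aspcr_alphabet_error",
               "illegal character '%s' at position %d of %s",
               substr(s, bad, bad), as.integer(bad), what)
  }
  s
}
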