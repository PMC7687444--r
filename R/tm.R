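# Melting temperature and composition metrics.
#
# Nearest-neighbor parameters are the unified duplex set of SantaLucia (PNAS
# 1998): dH in kcal/mol, dS in cal/(mol K), one entry per propagation step
# read 5'->3' on the primer strand. The table is shipped in code (all 16
# dinucleotides, symmetric pairs duplicated) so the hand-summable oracle in
# the tests can read the same numbers.

NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)

NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

# duplex initiation per terminal base pair
NN_INIT_DH <- c(GC = 0.1, AT = 2.3)
NN_INIT_DS <- c(GC = -2.8, AT = 4.1)

GAS_CONSTANT <- 1.987 # cal/(mol K)

check_unambiguous <- function(seq, what = "sequence") {
  s <- normalize_dna(seq, what)
  bad <- regexpr("[^ACGT]", s)
  if (bad != -1L) {
    stop_aspcr("aspcr_alphabet_error",
               "%s contains non-A/C/G/T character '%s' at position %d",
               what, substr(s, bad, bad), as.integer(bad))
  }
  s
}

#' Wallace-rule melting temperature
#'
#' The classic 2+4 rule: `2*(A+T) + 4*(G+C)` degrees C. A crude estimate,
#' but closed-form and exact, which makes it the reference method in tests.
#'
#' @param seq unambiguous A/C/G/T string.
#' @return temperature in degrees Celsius.
#' @examples
#' tm_wallace("ATGC") # 12
#' @export
tm_wallace <- function(seq) {
  s <- check_unambiguous(seq)
  ch <- seq_chars(s)
  gc <- sum(ch %in% c("G", "C"))
  2 * (length(ch) - gc) + 4 * gc
}

#' Nearest-neighbor melting temperature
#'
#' Unified nearest-neighbor thermodynamics with monovalent-salt entropy
#' correction (`dS + 0.368 * (N-1) * ln[Na+]`) and the primer/template (non
#' self-complementary) formulation `Tm = 1000*dH / (dS + R*ln(Ct/4)) - 273.15`.
#'
#' @param seq unambiguous A/C/G/T string, at least 8 nt.
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @param primer_uM primer concentration in uM (default 0.5).
#' @return temperature in degrees Celsius.
#' @export
tm_nearest_neighbor <- function(seq, na_mM = 50, primer_uM = 0.5) {
  s <- check_unambiguous(seq, "primer")
  n <- nchar(s)
  if (n < 8L) {
    stop_aspcr("aspcr_config_error",
               "nearest-neighbor Tm needs at least 8 nt (got %d)", n)
  }
  steps <- substring(s, 1:(n - 1L), 2:n)
  dh <- sum(NN_DH[steps])
  ds <- sum(NN_DS[steps])
  ends <- ifelse(c(substr(s, 1, 1), substr(s, n, n)) %in% c("G", "C"),
                 "GC", "AT")
  dh <- dh + sum(NN_INIT_DH[ends])
  ds <- ds + sum(NN_INIT_DS[ends])
  ds <- ds + 0.368 * (n - 1L) * log(na_mM / 1000)
  ct <- primer_uM * 1e-6
  1000 * dh / (ds + GAS_CONSTANT * log(ct / 4)) - 273.15
}

#' GC fraction of a sequence
#'
#' Ambiguity codes and gaps are excluded from both numerator and denominator.
#'
#' @param seq DNA string.
#' @return fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  s <- normalize_dna(seq)
  ch <- seq_chars(s)
  ch <- ch[ch %in% DNA_BASES]
  if (length(ch) == 0L) {
    stop_aspcr("aspcr_alphabet_error", "no unambiguous bases in sequence")
  }
  sum(ch %in% c("G", "C")) / length(ch)
}

# Mismatch weakness ranking over primer-base . template-base facing pairs
# (lower rank = less stable duplex = preferred engineered mismatch).
# Pyrimidine.pyrimidine transversion-type mismatches destabilize extension
# most strongly, G.T wobble pairs least; the ordering reproduces G->T as the
# default edit against a template C.
MISMATCH_RANK <- c(
  TC = 1, CT = 1, CC = 2, AA = 3, TT = 4,
  AC = 5, CA = 5, AG = 6, GA = 6, GG = 7, GT = 8, TG = 8
)
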