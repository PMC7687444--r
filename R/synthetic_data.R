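# Seeded generator of species-structured alignments with planted diagnostic
# sites. The defaults emulate a small multi-species COI barcode study: 8
# species, 24 records (five species of 3, two of 2, one of 5), 574 bp,
# interspecific divergence ~8%/site, intraspecific noise 0.2%/site, and two
# diagnostic columns planted for the first species at positions 480 and 505
# (target C against background T). Planting happens AFTER noise, so the
# ground truth is exact by construction.

DEFAULT_SPECIES <- c("Cervus_nippon", "Cervus_elaphus", "Axis_porcinus",
                     "Dama_dama", "Elaphurus_davidianus",
                     "Elaphodus_cephalophus", "Rusa_unicolor",
                     "Rangifer_tarandus")

#' Specification of a synthetic species-labelled alignment
#'
#' The default values describe the package's reference world: a 24-record,
#' 574 bp, 8-species barcode-like alignment with two diagnostic columns
#' planted for the first species.
#'
#' @param n_species number of species.
#' @param seqs_per_species scalar or per-species record counts.
#' @param length alignment width in bp.
#' @param planted_sites data.frame with columns `position`,
#'   `target_species`, `target_base`, `background_base`.
#' @param interspecies_divergence per-site substitution rate from the root
#'   to each species consensus, in `[0, 0.75)`.
#' @param intraspecific_noise per-site substitution rate from consensus to
#'   each record, in `[0, 0.75)`.
#' @param seed integer RNG seed.
#' @param species_names optional species labels (default: eight cervid-style
#'   names).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species = 8L,
                           seqs_per_species = c(3L, 3L, 3L, 3L, 3L, 2L, 2L, 5L),
                           length = 574L,
                           planted_sites = data.frame(
                             position = c(480L, 505L),
                             target_species = "Cervus_nippon",
                             target_base = "C",
                             background_base = "T",
                             stringsAsFactors = FALSE),
                           interspecies_divergence = 0.08,
                           intraspecific_noise = 0.002,
                           seed = 1L,
                           species_names = NULL) {
  n_species <- as.integer(n_species)
  length <- as.integer(length)
  if (is.null(species_names)) {
    species_names <- if (n_species <= base::length(DEFAULT_SPECIES)) {
      DEFAULT_SPECIES[seq_len(n_species)]
    } else {
      c(DEFAULT_SPECIES, sprintf("Species_%02d", seq_len(n_species)))[seq_len(n_species)]
    }
  }
  if (base::length(species_names) != n_species) {
    stop_aspcr("aspcr_spec_error", "need %d species names, got %d",
               n_species, base::length(species_names))
  }
  if (base::length(seqs_per_species) == 1L) {
    seqs_per_species <- rep(as.integer(seqs_per_species), n_species)
  }
  seqs_per_species <- as.integer(seqs_per_species)
  if (base::length(seqs_per_species) != n_species || any(seqs_per_species < 1L)) {
    stop_aspcr("aspcr_spec_error",
               "seqs_per_species must give a positive count per species")
  }
  for (rate in c(interspecies_divergence, intraspecific_noise)) {
    if (!is.numeric(rate) || rate < 0 || rate >= 0.75) {
      stop_aspcr("aspcr_spec_error", "rates must lie in [0, 0.75)")
    }
  }
  ps <- planted_sites
  if (nrow(ps) > 0L) {
    if (anyDuplicated(ps$position) ||
        any(ps$position < 1L) || any(ps$position > length)) {
      stop_aspcr("aspcr_spec_error",
                 "planted positions must be unique and within [1, %d]", length)
    }
    if (any(ps$target_base == ps$background_base)) {
      stop_aspcr("aspcr_spec_error",
                 "planted target_base must differ from background_base")
    }
    if (!all(ps$target_species %in% species_names)) {
      stop_aspcr("aspcr_spec_error", "planted target_species not among species_names")
    }
  }
  structure(list(n_species = n_species, seqs_per_species = seqs_per_species,
                 length = length, planted_sites = ps,
                 interspecies_divergence = interspecies_divergence,
                 intraspecific_noise = intraspecific_noise,
                 seed = as.integer(seed), species_names = species_names),
            class = "synthetic_spec")
}

mutate_chars <- function(ch, rate, protected = integer(0)) {
  hit <- stats::runif(length(ch)) < rate
  if (length(protected) > 0L) hit[protected] <- FALSE
  idx <- which(hit)
  for (i in idx) {
    ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  }
  list(chars = ch, mutated = idx)
}

#' Randomly substitute bases in a sequence
#'
#' Each unprotected position is substituted independently with probability
#' `rate`; the new base is uniform over the other three.
#'
#' @param seq DNA string over A/C/G/T.
#' @param rate substitution probability per site, in `[0, 1]`.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @param protected integer positions never to touch.
#' @return the mutated string.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, protected = integer(0)) {
  s <- check_unambiguous(seq)
  if (!is.numeric(rate) || rate < 0 || rate > 1) {
    stop_aspcr("aspcr_spec_error", "rate must lie in [0, 1]")
  }
  run <- function() chars_seq(mutate_chars(seq_chars(s), rate, protected)$chars)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a synthetic species-labelled alignment with ground truth
#'
#' Draws a uniform random root sequence, evolves one consensus per species at
#' `interspecies_divergence`, copies each consensus into its records applying
#' `intraspecific_noise` everywhere except at planted positions, and finally
#' writes the planted alleles (target species get `target_base`, everyone
#' else `background_base`). Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec].
#' @return list with `alignment` (a [species_alignment]) and `truth` (list:
#'   `planted_sites`, `consensus` named character vector per species,
#'   `mutation_log` of noise positions per record).
#' @export
generate_alignment <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop_aspcr("aspcr_spec_error", "spec must be a synthetic_spec")
  }
  withr::with_seed(spec$seed, {
    root <- sample(DNA_BASES, spec$length, replace = TRUE)
    planted_pos <- spec$planted_sites$position
    consensus <- list()
    ids <- character(0); species <- character(0); seqs <- character(0)
    mutation_log <- list()
    for (si in seq_len(spec$n_species)) {
      sp <- spec$species_names[si]
      cons <- mutate_chars(root, spec$interspecies_divergence)$chars
      consensus[[sp]] <- chars_seq(cons)
      for (k in seq_len(spec$seqs_per_species[si])) {
        res <- mutate_chars(cons, spec$intraspecific_noise,
                            protected = planted_pos)
        rec <- res$chars
        if (length(planted_pos) > 0L) {
          is_target <- spec$planted_sites$target_species == sp
          rec[planted_pos] <- ifelse(is_target,
                                     spec$planted_sites$target_base,
                                     spec$planted_sites$background_base)
        }
        id <- sprintf("%s_%02d", sp, k)
        ids <- c(ids, id); species <- c(species, sp)
        seqs <- c(seqs, chars_seq(rec))
        mutation_log[[id]] <- res$mutated
      }
    }
    aln <- species_alignment(ids, species, seqs)
    # planting happens last, so realization is exact; assert anyway
    if (nrow(spec$planted_sites) > 0L) {
      m <- as.matrix(aln)
      for (r in seq_len(nrow(spec$planted_sites))) {
        ps <- spec$planted_sites[r, ]
        tgt <- aln$species == ps$target_species
        stopifnot(all(m[tgt, ps$position] == ps$target_base),
                  all(m[!tgt, ps$position] == ps$background_base))
      }
    }
    list(alignment = aln,
         truth = list(planted_sites = spec$planted_sites,
                      consensus = unlist(consensus),
                      mutation_log = mutation_log))
  })
}
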