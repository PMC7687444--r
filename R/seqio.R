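#' Construct a species-labelled alignment
#'
#' The central container of the package: an equal-length, gapped DNA alignment
#' in which every record carries a species label. All downstream stages
#' (diagnostic-site discovery, primer design, specificity screening, tree
#' building) consume this object.
#'
#' @param id character vector of unique record identifiers.
#' @param species character vector of species labels, same length as `id`.
#' @param seq character vector of aligned sequences over the IUPAC-DNA
#'   alphabet plus `-`; all must have equal length. Input is uppercased and
#'   `U` is folded to `T` with a warning.
#' @return An object of class `species_alignment`: a list with elements
#'   `id`, `species`, `seq` (parallel character vectors) and `length`
#'   (alignment width in bp).
#' @examples
#' aln <- species_alignment(c("a", "b"), c("SpA", "SpB"), c("ACGT", "ACGA"))
#' aln$length
#' @export
species_alignment <- function(id, species, seq) {
  if (length(id) == 0L) {
    stop_aspcr("aspcr_shape_error", "alignment must contain at least one record")
  }
  if (length(species) != length(id) || length(seq) != length(id)) {
    stop_aspcr("aspcr_shape_error", "id, species and seq must have equal length")
  }
  id <- as.character(id)
  species <- as.character(species)
  if (anyDuplicated(id)) {
    stop_aspcr("aspcr_label_error", "duplicate record id '%s'",
               id[duplicated(id)][1L])
  }
  if (any(is.na(species)) || any(!nzchar(species))) {
    stop_aspcr("aspcr_label_error", "missing species label for record '%s'",
               id[which(is.na(species) | !nzchar(species))[1L]])
  }
  seq <- vapply(seq_along(seq), function(i) {
    normalize_dna(seq[i], what = sprintf("record '%s'", id[i]))
  }, character(1))
  len <- nchar(seq)
  if (length(unique(len)) != 1L) {
    off <- which(len != len[1L])[1L]
    stop_aspcr("aspcr_shape_error",
               "record '%s' has length %d, expected %d (alignment not rectangular)",
               id[off], len[off], len[1L])
  }
  structure(list(id = id, species = species, seq = unname(seq),
                 length = unname(len[1L])),
            class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("species_alignment: %d records x %d bp, %d species\n",
              length(x$id), x$length, length(unique(x$species))))
  tab <- table(x$species)
  cat(paste(sprintf("  %s (%d)", names(tab), as.integer(tab)), collapse = "\n"),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.species_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$seq, "", fixed = TRUE))
  rownames(m) <- x$id
  m
}

#' Number of records in an alignment
#' @param aln a `species_alignment`.
#' @return integer count.
#' @export
n_records <- function(aln) length(aln$id)

#' Species labels present in an alignment
#' @param aln a `species_alignment`.
#' @return character vector of unique labels, in order of first appearance.
#' @export
species_labels <- function(aln) unique(aln$species)

#' Read a species-labelled alignment from FASTA
#'
#' Species labels are taken from a two-column TSV map (`id<TAB>species`, no
#' header) when one is supplied; otherwise the label is parsed from the FASTA
#' header as the field after the *last* `|` (GenBank-style headers contain
#' internal pipes, so only the final field is interpreted).
#'
#' @param path path to a multi-FASTA file of equal-length aligned sequences.
#' @param species_map optional path to the TSV id-to-species map.
#' @return a validated [species_alignment].
#' @export
read_alignment_fasta <- function(path, species_map = NULL) {
  if (!file.exists(path)) {
    stop_aspcr("aspcr_io_error", "FASTA file not found: %s", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop_aspcr("aspcr_io_error", "no FASTA records in %s", path)
  }
  headers <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  if (!is.null(species_map)) {
    if (!file.exists(species_map)) {
      stop_aspcr("aspcr_io_error", "species map not found: %s", species_map)
    }
    map <- utils::read.table(species_map, sep = "\t", header = FALSE,
                             quote = "", comment.char = "",
                             colClasses = "character")
    if (ncol(map) < 2L) {
      stop_aspcr("aspcr_io_error", "species map must have two tab-separated columns")
    }
    lookup <- stats::setNames(map[[2L]], map[[1L]])
    ids <- headers
    species <- unname(lookup[ids])
    # headers of the form id|species (our own writer) may carry a trailing
    # label the map does not include: fall back to the pre-pipe id
    strip <- sub("\\|[^|]*$", "", headers)
    retry <- is.na(species) & grepl("|", headers, fixed = TRUE) &
      !is.na(lookup[strip])
    ids[retry] <- strip[retry]
    species[retry] <- unname(lookup[strip[retry]])
    if (anyNA(species)) {
      stop_aspcr("aspcr_label_error", "no species map entry for record '%s'",
                 ids[which(is.na(species))[1L]])
    }
  } else {
    has_pipe <- grepl("|", headers, fixed = TRUE)
    if (!all(has_pipe)) {
      stop_aspcr("aspcr_label_error",
                 "record '%s' has no '|species' header field and no species map was given",
                 headers[which(!has_pipe)[1L]])
    }
    species <- sub(".*\\|", "", headers)
    ids <- sub("\\|[^|]*$", "", headers)
  }
  species_alignment(ids, species, seqs)
}

#' Write an alignment as wrapped multi-FASTA
#'
#' Headers are written as `>id|species` so that [read_alignment_fasta] without
#' a map reproduces the alignment exactly (round-trip identity).
#'
#' @param aln a `species_alignment`.
#' @param path output path.
#' @param width line-wrap width, default 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path, width = 60L) {
  if (!inherits(aln, "species_alignment")) {
    stop_aspcr("aspcr_shape_error", "aln must be a species_alignment")
  }
  wrap <- function(s) {
    starts <- seq(1L, nchar(s), by = width)
    substring(s, starts, pmin(starts + width - 1L, nchar(s)))
  }
  lines <- unlist(lapply(seq_along(aln$id), function(i) {
    c(sprintf(">%s|%s", aln$id[i], aln$species[i]), wrap(aln$seq[i]))
  }))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_aspcr("aspcr_io_error", "cannot write FASTA to %s", path)
  invisible(path)
}

#' Reverse complement of an IUPAC-DNA sequence
#'
#' Ambiguity codes map to their complements (R<->Y, K<->M, B<->V, D<->H,
#' S/W/N fixed); gaps are preserved in place.
#'
#' @param seq a single DNA string.
#' @return the reverse complement, 5' to 3'.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  s <- normalize_dna(seq)
  chars_seq(rev(unname(COMPLEMENT[seq_chars(s)])))
}

# strip gaps from one sequence (in silico PCR runs on ungapped templates)
ungap <- function(seq) gsub("-", "", seq, fixed = TRUE)
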