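#' Per-species base counts for one alignment column
#'
#' Gaps, `N` and all other ambiguity codes are tallied as missing — an assay
#' anchored on an uncertain base is unsafe, so only unambiguous A/C/G/T
#' observations count.
#'
#' @param aln a [species_alignment].
#' @param position 1-based column index.
#' @return An object of class `column_profile`: list with `position`,
#'   `counts_by_species` (named list of A/C/G/T count vectors) and
#'   `n_missing`.
#' @export
profile_column <- function(aln, position) {
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > aln$length) {
    stop_aspcr("aspcr_bounds_error",
               "position %s outside [1, %d]", as.character(position), aln$length)
  }
  col <- substr(aln$seq, position, position)
  unamb <- col %in% DNA_BASES
  counts <- lapply(split(col[unamb], aln$species[unamb]), function(x) {
    tab <- table(factor(x, levels = DNA_BASES))
    stats::setNames(as.integer(tab), DNA_BASES)
  })
  structure(list(position = position,
                 counts_by_species = counts,
                 n_missing = sum(!unamb)),
            class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat(sprintf("column %d (%d missing)\n", x$position, x$n_missing))
  for (sp in names(x$counts_by_species)) {
    ct <- x$counts_by_species[[sp]]
    ct <- ct[ct > 0]
    cat(sprintf("  %s: %s\n", sp,
                paste(sprintf("%s=%d", names(ct), ct), collapse = " ")))
  }
  invisible(x)
}

#' Find species-diagnostic alignment columns
#'
#' A column is diagnostic for the target species when (a) every non-missing
#' target record carries one and the same base, (b) that base occurs in zero
#' non-target records, and (c) the missing fraction (gaps, N, ambiguity
#' codes) does not exceed `max_missing_frac`. This is the strict
#' fixed-difference notion used in SNP-based species authentication:
#' fixed in the target AND absent in all others. Indel (gap) characters are
#' treated as missing, so gap columns are never diagnostic.
#'
#' @param aln a [species_alignment] with at least two species.
#' @param target_species species label to diagnose.
#' @param max_missing_frac maximum tolerated missing fraction per column,
#'   in `[0, 1)`; default 0.
#' @param require_strict if `TRUE` (default) any missing character in the
#'   column disqualifies it, regardless of `max_missing_frac`.
#' @return A `data.frame` of class `diagnostic_sites`, ordered by position,
#'   with columns `position`, `target_species`, `target_base`,
#'   `nontarget_bases` (comma-separated, sorted) and `strict` (no missing
#'   character anywhere in the column).
#' @export
find_diagnostic_sites <- function(aln, target_species, max_missing_frac = 0,
                                  require_strict = TRUE) {
  if (!target_species %in% aln$species) {
    stop_aspcr("aspcr_label_error", "species '%s' not present in alignment",
               target_species)
  }
  if (length(unique(aln$species)) < 2L) {
    stop_aspcr("aspcr_config_error",
               "diagnostic sites need at least two species in the alignment")
  }
  if (!is.numeric(max_missing_frac) || max_missing_frac < 0 ||
      max_missing_frac >= 1) {
    stop_aspcr("aspcr_config_error", "max_missing_frac must be in [0, 1)")
  }
  m <- as.matrix(aln)
  in_target <- aln$species == target_species
  n <- nrow(m)

  hits <- lapply(seq_len(aln$length), function(j) {
    col <- m[, j]
    missing <- !(col %in% DNA_BASES)
    if (require_strict && any(missing)) return(NULL)
    if (sum(missing) / n > max_missing_frac) return(NULL)
    tb <- unique(col[in_target & !missing])
    if (length(tb) != 1L) return(NULL)
    ob <- unique(col[!in_target & !missing])
    if (tb %in% ob) return(NULL)
    data.frame(position = j,
               target_species = target_species,
               target_base = tb,
               nontarget_bases = paste(sort(ob), collapse = ","),
               strict = !any(missing),
               stringsAsFactors = FALSE)
  })
  hits <- Filter(Negate(is.null), hits)
  out <- if (length(hits) > 0L) {
    do.call(rbind, c(hits, list(make.row.names = FALSE)))
  } else NULL
  if (is.null(out)) {
    out <- data.frame(position = integer(0), target_species = character(0),
                      target_base = character(0), nontarget_bases = character(0),
                      strict = logical(0), stringsAsFactors = FALSE)
  }
  class(out) <- c("diagnostic_sites", "data.frame")
  out
}

#' Write a diagnostic-site report as TSV
#'
#' Adds a `counts` column holding the JSON-encoded per-species base counts of
#' each reported column.
#'
#' @param sites result of [find_diagnostic_sites].
#' @param aln the alignment the sites came from.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, aln, path) {
  df <- as.data.frame(sites)
  df$counts <- vapply(df$position, function(p) {
    prof <- profile_column(aln, p)
    as.character(jsonlite::toJSON(lapply(prof$counts_by_species, as.list),
                                  auto_unbox = TRUE))
  }, character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
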