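# JSON / TSV serialization of designed assays, shared by the CLI and the
# screening stage.

primer_to_list <- function(p) {
  list(name = p$name, seq = p$seq, strand = p$strand,
       template_start = p$template_start, template_end = p$template_end,
       edits = p$edits, tm_c = p$tm_c, tm_wallace_c = p$tm_wallace_c,
       gc_frac = p$gc_frac)
}

primer_from_list <- function(x) {
  edits <- if (length(x$edits) == 0L || NROW(x$edits) == 0L) empty_edits()
           else as.data.frame(x$edits, stringsAsFactors = FALSE)
  new_primer(x$name, x$seq, x$strand, x$template_start, x$template_end, edits)
}

#' Write an assay design as JSON
#'
#' Primer sequences are written 5' to 3' with 1-based inclusive footprints;
#' both Tm estimates (nearest-neighbor and Wallace) are included.
#'
#' @param design an [assay_design].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(design, path) {
  jsonlite::write_json(list(
    target_species = design$target_species,
    anchor_site = as.list(design$anchor_site)[c("position", "target_base")],
    product_bp = design$product_bp,
    forward = primer_to_list(design$forward),
    reverse = primer_to_list(design$reverse)
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an assay design written by [write_design_json]
#' @param path JSON path.
#' @return an [assay_design].
#' @export
read_design_json <- function(path) {
  if (!file.exists(path)) {
    stop_aspcr("aspcr_io_error", "design file not found: %s", path)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  assay_design(primer_from_list(x$forward), primer_from_list(x$reverse),
               x$target_species,
               list(position = as.integer(x$anchor_site$position),
                    target_base = x$anchor_site$target_base))
}

#' Write an assay design as flat TSV (one row per primer)
#' @param design an [assay_design].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  row <- function(role, p) {
    data.frame(role = role, name = p$name, seq = p$seq, strand = p$strand,
               template_start = p$template_start,
               template_end = p$template_end,
               edits = if (nrow(p$edits)) {
                 paste(sprintf("%s>%s@%d", p$edits$original_base,
                               p$edits$replacement_base,
                               p$edits$offset_from_3prime), collapse = ";")
               } else "",
               tm_nn_c = round(p$tm_c, 2), tm_wallace_c = p$tm_wallace_c,
               gc_frac = round(p$gc_frac, 4),
               product_bp = design$product_bp, stringsAsFactors = FALSE)
  }
  utils::write.table(rbind(row("forward", design$forward),
                           row("reverse", design$reverse)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
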