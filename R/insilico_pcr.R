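# In silico PCR: the computational analogue of running the assay on a gel.
# Amplification is binary — a template yields a product iff both primers find
# an extendable binding site in a productive orientation within the allowed
# product size. "Extendable" encodes the allele-specific mechanism: a
# 3'-terminal mismatch blocks extension outright, and at most
# `max_mismatches_last5` mismatches are tolerated in the 3'-proximal 5 nt.
# The engineered offset-3 edit mismatches every template, so the default
# last-5 budget of 1 lets the target through while non-targets (edit + anchor
# mismatch = 2 in the last 5) fail.

#' Binding/extension model for in silico PCR
#'
#' @param max_total_mismatches sites with more total mismatches are not
#'   reported at all (default 3).
#' @param max_mismatches_last5 mismatch budget within 5 nt of the 3' end
#'   (default 1: exactly the engineered edit).
#' @param block_on_3prime_mismatch if `TRUE` (default) a mismatched
#'   3'-terminal base makes a site non-extendable regardless of budgets.
#' @param product_min_bp,product_max_bp admissible product sizes (default
#'   50-2000 bp).
#' @return a `binding_model` list.
#' @export
binding_model <- function(max_total_mismatches = 3L,
                          max_mismatches_last5 = 1L,
                          block_on_3prime_mismatch = TRUE,
                          product_min_bp = 50L, product_max_bp = 2000L) {
  if (max_mismatches_last5 > max_total_mismatches) {
    stop_aspcr("aspcr_config_error",
               "max_mismatches_last5 cannot exceed max_total_mismatches")
  }
  if (product_min_bp > product_max_bp) {
    stop_aspcr("aspcr_config_error", "product_min_bp exceeds product_max_bp")
  }
  structure(list(max_total_mismatches = as.integer(max_total_mismatches),
                 max_mismatches_last5 = as.integer(max_mismatches_last5),
                 block_on_3prime_mismatch = isTRUE(block_on_3prime_mismatch),
                 product_min_bp = as.integer(product_min_bp),
                 product_max_bp = as.integer(product_max_bp)),
            class = "binding_model")
}

# scan one oriented probe (character vector) along a template; returns for
# each admissible start the offsets-from-3' of mismatching positions.
# offset_fun maps window position 1..L to offset-from-3'.
scan_probe <- function(probe, tch, max_mm, offset_fun) {
  L <- length(probe)
  Tn <- length(tch)
  if (L > Tn) return(list(starts = integer(0), offsets = list()))
  starts <- seq_len(Tn - L + 1L)
  pos <- outer(seq_len(L) - 1L, starts, "+")   # L x S template positions
  ok <- MATCH_TBL[cbind(tch[pos], rep(probe, times = length(starts)))]
  dim(ok) <- c(L, length(starts))
  totals <- colSums(!ok)
  keep <- which(totals <= max_mm)
  offsets <- lapply(keep, function(k) offset_fun(which(!ok[, k]), L))
  list(starts = starts[keep], offsets = offsets)
}

#' Find primer binding sites on a template
#'
#' Exhaustive scan of both strands of the (gap-stripped) template. A site is
#' reported whenever its total mismatch count is within the model budget;
#' the `extendable` flag applies the 3'-end rules on top. Template ambiguity
#' codes match a primer base iff their set contains it; `N` matches nothing.
#'
#' @param primer a `primer` object (its `seq` is what is scanned).
#' @param template a list with `id` and `seq` (one alignment record), or a
#'   plain DNA string.
#' @param model a [binding_model].
#' @return data.frame of class `binding_sites`: `template_id`, `strand`,
#'   `start`, `end` (1-based on the ungapped template), `n_mismatch`,
#'   `mismatch_offsets` (list column of offsets-from-3'), `extendable`;
#'   ordered by position then strand.
#' @export
find_binding_sites <- function(primer, template, model = binding_model()) {
  if (is.character(template)) template <- list(id = "template", seq = template)
  tseq <- ungap(normalize_dna(template$seq, "template"))
  tch <- seq_chars(tseq)
  pch <- seq_chars(primer$seq)
  L <- length(pch)

  # plus strand: primer read 5'->3' along the template; window pos j has
  # offset L-j+1. minus strand: the reverse complement lies along the
  # template; window pos j has offset j.
  plus <- scan_probe(pch, tch, model$max_total_mismatches,
                     function(j, L) L - j + 1L)
  minus <- scan_probe(seq_chars(reverse_complement(primer$seq)), tch,
                      model$max_total_mismatches, function(j, L) j)

  build <- function(hits, strand) {
    if (length(hits$starts) == 0L) return(NULL)
    data.frame(template_id = template$id, strand = strand,
               start = hits$starts, end = hits$starts + L - 1L,
               n_mismatch = vapply(hits$offsets, length, integer(1)),
               mismatch_offsets = I(hits$offsets),
               stringsAsFactors = FALSE)
  }
  out <- rbind(build(plus, "plus"), build(minus, "minus"))
  if (is.null(out)) {
    out <- data.frame(template_id = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      n_mismatch = integer(0),
                      mismatch_offsets = I(list()), extendable = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("binding_sites", "data.frame")
    return(out)
  }
  out$extendable <- vapply(out$mismatch_offsets, function(off) {
    if (model$block_on_3prime_mismatch && 1L %in% off) return(FALSE)
    sum(off <= 5L) <= model$max_mismatches_last5
  }, logical(1))
  out <- out[order(out$start, match(out$strand, c("plus", "minus"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_sites", "data.frame")
  out
}

#' Predict PCR products on one template
#'
#' Pairs every extendable plus-strand site of one primer with every
#' extendable minus-strand site of the other (both assignments, so the
#' prediction is symmetric under reverse-complementing the template) and
#' reports each pairing whose product size falls inside the model's window.
#'
#' @param forward,reverse `primer` objects.
#' @param template one record (list with `id`, `seq`) or DNA string.
#' @param model a [binding_model].
#' @return data.frame with `template_id`, `start`, `end`, `product_bp`, one
#'   row per predicted product; zero rows when nothing amplifies.
#' @export
predict_amplicons <- function(forward, reverse, template,
                              model = binding_model()) {
  sf <- find_binding_sites(forward, template, model)
  sr <- find_binding_sites(reverse, template, model)
  pair_up <- function(plus_sites, minus_sites) {
    plus_sites <- plus_sites[plus_sites$strand == "plus" & plus_sites$extendable, ]
    minus_sites <- minus_sites[minus_sites$strand == "minus" & minus_sites$extendable, ]
    if (nrow(plus_sites) == 0L || nrow(minus_sites) == 0L) return(NULL)
    grid <- expand.grid(i = seq_len(nrow(plus_sites)),
                        j = seq_len(nrow(minus_sites)))
    ps <- plus_sites$start[grid$i]; pe <- plus_sites$end[grid$i]
    ms <- minus_sites$start[grid$j]; me <- minus_sites$end[grid$j]
    bp <- me - ps + 1L
    ok <- ps <= ms & pe <= me & bp >= model$product_min_bp &
      bp <= model$product_max_bp
    if (!any(ok)) return(NULL)
    data.frame(template_id = plus_sites$template_id[1L], start = ps[ok],
               end = me[ok], product_bp = bp[ok], stringsAsFactors = FALSE)
  }
  out <- rbind(pair_up(sf, sr), pair_up(sr, sf))
  if (is.null(out)) {
    out <- data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), product_bp = integer(0),
                      stringsAsFactors = FALSE)
  }
  out <- unique(out[order(out$start, out$end), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Screen an assay against every template of an alignment
#'
#' Runs [predict_amplicons] per gap-stripped record and summarizes the
#' result: the design is *specific* iff every target-species template
#' amplifies and no non-target template does — the in silico analogue of a
#' single-lane specificity gel.
#'
#' @param design an [assay_design].
#' @param templates a [species_alignment].
#' @param model a [binding_model].
#' @return data.frame of class `specificity_matrix` with `template_id`,
#'   `species`, `amplified`, `product_bp` (NA when not amplified),
#'   `n_products`; attributes `target_species` and `specific`.
#' @export
specificity_screen <- function(design, templates, model = binding_model()) {
  if (n_records(templates) == 0L) {
    stop_aspcr("aspcr_shape_error", "no templates to screen")
  }
  rows <- lapply(seq_along(templates$id), function(i) {
    preds <- predict_amplicons(design$forward, design$reverse,
                               list(id = templates$id[i], seq = templates$seq[i]),
                               model)
    data.frame(template_id = templates$id[i], species = templates$species[i],
               amplified = nrow(preds) > 0L,
               product_bp = if (nrow(preds) > 0L) preds$product_bp[1L] else NA_integer_,
               n_products = nrow(preds), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  is_target <- out$species == design$target_species
  attr(out, "target_species") <- design$target_species
  attr(out, "specific") <- all(out$amplified[is_target]) &&
    !any(out$amplified[!is_target])
  class(out) <- c("specificity_matrix", "data.frame")
  out
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat(sprintf("specificity screen vs %s: %s (%d/%d templates amplified)\n",
              attr(x, "target_species"),
              if (attr(x, "specific")) "SPECIFIC" else "NOT specific",
              sum(x$amplified), nrow(x)))
  print.data.frame(x)
  invisible(x)
}

#' Text rendering of the specificity screen as a virtual gel
#'
#' One lane per template; a `====` band is drawn at the predicted product
#' size on a log-ish ladder, mirroring an electrophoresis figure.
#'
#' @param mat a `specificity_matrix`.
#' @param width gel width in characters.
#' @return character vector of lines (also printable with `cat`).
#' @export
format_virtual_gel <- function(mat, width = 40L) {
  ladder <- c(2000L, 1000L, 750L, 500L, 250L, 100L)
  lane_for <- function(bp) {
    if (is.na(bp)) return(strrep(" ", width))
    frac <- 1 - (log10(bp) - 2) / (log10(2000) - 2)  # 100..2000 bp scale
    pos <- max(1L, min(width - 4L, round(frac * (width - 4L)) + 1L))
    paste0(strrep(" ", pos - 1L), "====",
           strrep(" ", width - pos - 3L))
  }
  idw <- max(nchar(mat$template_id), nchar("template"))
  spw <- max(nchar(mat$species), nchar("species"))
  hdr <- sprintf("%-*s  %-*s  |%s|  product", idw, "template", spw, "species",
                 strrep("-", width))
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    sprintf("%-*s  %-*s  |%s|  %s", idw, mat$template_id[i], spw,
            mat$species[i], lane_for(mat$product_bp[i]),
            if (is.na(mat$product_bp[i])) "-" else sprintf("%d bp", mat$product_bp[i]))
  }, character(1))
  scale <- sprintf("%-*s  %-*s  |%s|", idw, "", spw, "ladder(bp)",
                   {
                     ruler <- strrep(" ", width)
                     for (bp in ladder) {
                       frac <- 1 - (log10(bp) - 2) / (log10(2000) - 2)
                       pos <- max(1L, min(width, round(frac * (width - 4L)) + 1L))
                       lab <- as.character(bp)
                       substr(ruler, pos, min(width, pos + nchar(lab) - 1L)) <- lab
                     }
                     ruler
                   })
  c(hdr, lines, scale)
}

#' Write a specificity matrix as TSV
#' @param mat a `specificity_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specificity_tsv <- function(mat, path) {
  utils::write.table(as.data.frame(mat), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
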