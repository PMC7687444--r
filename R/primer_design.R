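# Allele-specific primer construction.
#
# The assay logic: put the diagnostic allele under the primer's 3'-terminal
# base (polymerases without 3'->5' proofreading extend poorly from a terminal
# mismatch, so non-target templates fail), then deliberately weaken the
# primer further with one engineered mismatch near the 3' end — by default at
# the antepenultimate position (offset 3) — so that near-match templates
# accumulate two 3'-proximal mismatches while the target keeps only the
# engineered one.

new_primer <- function(name, seq, strand, template_start, template_end,
                       edits = empty_edits()) {
  structure(list(
    name = name,
    seq = seq,
    strand = strand,
    template_start = as.integer(template_start),
    template_end = as.integer(template_end),
    edits = edits,
    tm_c = tm_nearest_neighbor(seq),
    tm_wallace_c = tm_wallace(seq),
    gc_frac = gc_content(seq)
  ), class = "primer")
}

empty_edits <- function() {
  data.frame(offset_from_3prime = integer(0), original_base = character(0),
             replacement_base = character(0), stringsAsFactors = FALSE)
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("primer %s (%s strand)\n  5'-%s-3'  %d nt\n", x$name, x$strand,
              x$seq, nchar(x$seq)))
  cat(sprintf("  footprint [%d, %d]  Tm %.1f C (Wallace %.0f)  GC %.2f\n",
              x$template_start, x$template_end, x$tm_c, x$tm_wallace_c,
              x$gc_frac))
  if (nrow(x$edits) > 0) {
    cat(sprintf("  engineered edit: %s->%s at offset %d from 3'\n",
                x$edits$original_base, x$edits$replacement_base,
                x$edits$offset_from_3prime))
  }
  invisible(x)
}

#' Perfect-match primer over a template footprint
#'
#' For `strand = "minus"` the primer is the reverse complement of
#' `template[anchor_pos .. anchor_pos + length - 1]`, so its 3'-terminal base
#' pairs with the template base at `anchor_pos` (the "downstream" primer of an
#' allele-specific assay sits with its 3' end directly on the SNP). For
#' `strand = "plus"` the footprint is `[anchor_pos - length + 1, anchor_pos]`
#' and the primer equals the template substring.
#'
#' @param template DNA string in alignment coordinates (may contain gaps
#'   outside the footprint, never inside it).
#' @param anchor_pos 1-based template position paired with the primer's
#'   3'-terminal base.
#' @param length primer length, minimum 15 nt.
#' @param strand `"plus"` or `"minus"`.
#' @param name primer name (default derived from coordinates).
#' @return a `primer` object with empty edit list and computed Tm/GC.
#' @export
perfect_match_primer <- function(template, anchor_pos, length,
                                 strand = c("minus", "plus"), name = NULL) {
  strand <- match.arg(strand)
  template <- normalize_dna(template, "template")
  length <- as.integer(length)
  if (is.na(length) || length < 15L) {
    stop_aspcr("aspcr_config_error", "primer length must be >= 15 nt")
  }
  anchor_pos <- as.integer(anchor_pos)
  if (strand == "minus") {
    start <- anchor_pos; end <- anchor_pos + length - 1L
  } else {
    start <- anchor_pos - length + 1L; end <- anchor_pos
  }
  if (is.na(anchor_pos) || start < 1L || end > nchar(template)) {
    stop_aspcr("aspcr_geometry_error",
               "primer footprint [%d, %d] outside template of %d bp",
               start, end, nchar(template))
  }
  fp <- substr(template, start, end)
  if (grepl("-", fp, fixed = TRUE)) {
    stop_aspcr("aspcr_gap_error",
               "template footprint [%d, %d] contains a gap", start, end)
  }
  if (grepl("[^ACGT]", fp)) {
    stop_aspcr("aspcr_alphabet_error",
               "template footprint [%d, %d] contains ambiguity codes", start, end)
  }
  seq <- if (strand == "minus") reverse_complement(fp) else fp
  if (is.null(name)) name <- sprintf("pm_%s_%d_%d", strand, start, end)
  new_primer(name, seq, strand, start, end)
}

# template base physically facing a primer position (hybridization partner);
# offset 1 = 3'-terminal primer base
facing_template_pos <- function(p, offset) {
  if (p$strand == "minus") p$template_start + offset - 1L
  else p$template_end - offset + 1L
}

#' Introduce a destabilizing mismatch near the primer 3' end
#'
#' Replaces the primer base at `offset_from_3prime` (1 = 3'-terminal) with a
#' deliberately non-complementary base. The 3'-terminal base itself is
#' protected — it carries the diagnostic allele and may never be edited.
#' When `replacement` is omitted, the base forming the weakest duplex
#' mismatch against the facing template base is chosen from a shipped
#' stability ranking (pyrimidine-pyrimidine transversions preferred; against
#' a template C with perfect-match base G this yields the classic G->T edit).
#'
#' @param p a `primer`.
#' @param template the template the primer was built on.
#' @param offset_from_3prime edit position counted from the 3' end; must be
#'   at least 2 and currently match the template.
#' @param replacement optional base to place; must differ from the current
#'   base.
#' @return a new `primer` with the edit applied and recorded, Tm/GC
#'   recomputed.
#' @export
introduce_destabilizing_mismatch <- function(p, template, offset_from_3prime,
                                             replacement = NULL) {
  template <- normalize_dna(template, "template")
  off <- as.integer(offset_from_3prime)
  L <- nchar(p$seq)
  if (is.na(off) || off < 1L || off > L) {
    stop_aspcr("aspcr_bounds_error", "offset %s outside primer of %d nt",
               as.character(offset_from_3prime), L)
  }
  if (off == 1L) {
    stop_aspcr("aspcr_config_error",
               "refusing to edit the 3'-terminal base: it is the diagnostic anchor")
  }
  i <- L - off + 1L
  orig <- substr(p$seq, i, i)
  tpos <- facing_template_pos(p, off)
  tbase <- substr(template, tpos, tpos)
  facing <- if (p$strand == "minus") tbase else unname(COMPLEMENT[tbase])
  if (!facing %in% DNA_BASES) {
    stop_aspcr("aspcr_alphabet_error",
               "template base at position %d is ambiguous", tpos)
  }
  if (orig != COMPLEMENT[facing]) {
    stop_aspcr("aspcr_config_error",
               "primer base %s at offset %d already mismatches the template", orig, off)
  }
  if (is.null(replacement)) {
    cand <- setdiff(DNA_BASES, orig)
    ranks <- MISMATCH_RANK[paste0(cand, facing)]
    replacement <- cand[which.min(ranks)]
  } else {
    replacement <- toupper(replacement)
    if (!replacement %in% DNA_BASES) {
      stop_aspcr("aspcr_alphabet_error", "replacement must be A, C, G or T")
    }
    if (replacement == orig) {
      stop_aspcr("aspcr_config_error",
                 "replacement equals the current base: edit would be a no-op")
    }
  }
  seq <- p$seq
  substr(seq, i, i) <- replacement
  edits <- rbind(p$edits, data.frame(
    offset_from_3prime = off, original_base = orig,
    replacement_base = replacement, stringsAsFactors = FALSE))
  new_primer(p$name, seq, p$strand, p$template_start, p$template_end, edits)
}

#' Design an allele-specific primer on a diagnostic site
#'
#' Builds the perfect-match primer anchored 3' on the diagnostic allele and
#' then destabilizes it at `mismatch_offset` (default 3, the antepenultimate
#' base; configurable 2-5). Deterministic given its inputs.
#'
#' @param template a target-species sequence in alignment coordinates; must
#'   carry `site$target_base` at `site$position`.
#' @param site one row of a [find_diagnostic_sites] result (or any list with
#'   `position` and `target_base`).
#' @param length primer length (default 26 nt).
#' @param strand `"minus"` (downstream primer, default) or `"plus"`.
#' @param mismatch_offset engineered-edit position from the 3' end, 2-5.
#' @param replacement optional explicit replacement base for the edit.
#' @param name primer name.
#' @return a `primer` carrying exactly one engineered edit.
#' @export
design_allele_specific_primer <- function(template, site, length = 26L,
                                          strand = c("minus", "plus"),
                                          mismatch_offset = 3L,
                                          replacement = NULL, name = "AS") {
  strand <- match.arg(strand)
  template <- normalize_dna(template, "template")
  pos <- as.integer(site$position)
  tb <- as.character(site$target_base)
  if (substr(template, pos, pos) != tb) {
    stop_aspcr("aspcr_config_error",
               "template carries '%s' at position %d, expected target allele '%s'",
               substr(template, pos, pos), pos, tb)
  }
  off <- as.integer(mismatch_offset)
  if (is.na(off) || off < 2L || off > 5L) {
    stop_aspcr("aspcr_config_error", "mismatch_offset must be between 2 and 5")
  }
  p <- perfect_match_primer(template, pos, length, strand, name = name)
  introduce_destabilizing_mismatch(p, template, off, replacement)
}

# reject candidates whose 3' 5-mer can seed a dimer on itself or the partner
passes_3prime_guard <- function(seq, partner_seq) {
  last5 <- substr(seq, nchar(seq) - 4L, nchar(seq))
  rc <- reverse_complement(last5)
  !grepl(rc, seq, fixed = TRUE) && !grepl(rc, partner_seq, fixed = TRUE)
}

#' Design conventional companion primers for an allele-specific primer
#'
#' Exhaustively scans every window on the opposite side of the assay that
#' satisfies the product-size, length, Tm-window and GC constraints and a
#' 3'-end self/cross-complementarity guard. Candidates are ranked by
#' `|Tm - Tm(as_primer)|` ascending, ties broken by position.
#'
#' @param template ungapped target-species sequence in alignment coordinates.
#' @param as_primer the allele-specific `primer` to pair with.
#' @param product_range `c(min, max)` product size in bp (default 100-1000).
#' @param length_range `c(min, max)` primer length (default 18-25).
#' @param tm_window `c(lo, hi)` Tm acceptance window in C (default 55-65).
#' @param gc_range `c(lo, hi)` GC fraction window (default 0.35-0.65).
#' @param tm_method `"nn"` (nearest-neighbor, default) or `"wallace"`.
#' @return list of `primer` objects, best first; empty list (with a message)
#'   when no window qualifies.
#' @export
design_companion_primer <- function(template, as_primer,
                                    product_range = c(100L, 1000L),
                                    length_range = c(18L, 25L),
                                    tm_window = c(55, 65),
                                    gc_range = c(0.35, 0.65),
                                    tm_method = c("nn", "wallace")) {
  tm_method <- match.arg(tm_method)
  template <- normalize_dna(template, "template")
  tm_of <- function(s) if (tm_method == "nn") tm_nearest_neighbor(s) else tm_wallace(s)
  ref_tm <- if (tm_method == "nn") as_primer$tm_c else as_primer$tm_wallace_c
  tlen <- nchar(template)
  cands <- list()
  for (len in seq(length_range[1L], length_range[2L])) {
    if (as_primer$strand == "minus") {
      # companion on plus strand, upstream: product = as_end - start + 1
      lo <- max(1L, as_primer$template_end - product_range[2L] + 1L)
      hi <- min(tlen - len + 1L, as_primer$template_end - product_range[1L] + 1L)
      starts <- if (hi >= lo) seq(lo, hi) else integer(0)
      starts <- starts[starts + len - 1L < as_primer$template_start]
      for (s in starts) {
        fp <- substr(template, s, s + len - 1L)
        if (grepl("[^ACGT]", fp)) next
        cands[[length(cands) + 1L]] <- list(seq = fp, start = s,
                                            end = s + len - 1L, strand = "plus")
      }
    } else {
      # companion on minus strand, downstream: product = end - as_start + 1
      lo <- max(len, as_primer$template_start + product_range[1L] - 1L)
      hi <- min(tlen, as_primer$template_start + product_range[2L] - 1L)
      ends <- if (hi >= lo) seq(lo, hi) else integer(0)
      ends <- ends[ends - len + 1L > as_primer$template_end]
      for (e in ends) {
        fp <- substr(template, e - len + 1L, e)
        if (grepl("[^ACGT]", fp)) next
        cands[[length(cands) + 1L]] <- list(seq = reverse_complement(fp),
                                            start = e - len + 1L, end = e,
                                            strand = "minus")
      }
    }
  }
  keep <- list()
  for (cd in cands) {
    gc <- gc_content(cd$seq)
    if (gc < gc_range[1L] || gc > gc_range[2L]) next
    tm <- tm_of(cd$seq)
    if (tm < tm_window[1L] || tm > tm_window[2L]) next
    if (!passes_3prime_guard(cd$seq, as_primer$seq)) next
    keep[[length(keep) + 1L]] <- c(cd, list(tm = tm))
  }
  if (length(keep) == 0L) {
    message("no companion primer window satisfies the constraints")
    return(list())
  }
  gap <- vapply(keep, function(k) abs(k$tm - ref_tm), numeric(1))
  pos <- vapply(keep, function(k) k$start, numeric(1))
  ord <- order(gap, pos)
  lapply(keep[ord], function(k) {
    new_primer(sprintf("companion_%s_%d_%d", k$strand, k$start, k$end),
               k$seq, k$strand, k$start, k$end)
  })
}

#' Expected amplicon size of a primer pair
#'
#' Geometry only: `reverse$template_end - forward$template_start + 1`, the
#' span from the forward primer's 5' end to the reverse primer's 5' end on
#' the template. Invariant to any sequence edits.
#'
#' @param forward plus-strand `primer`.
#' @param reverse minus-strand `primer`.
#' @return product size in bp.
#' @export
amplicon_size <- function(forward, reverse) {
  if (forward$strand != "plus" || reverse$strand != "minus") {
    stop_aspcr("aspcr_config_error",
               "amplicon_size expects a plus-strand forward and minus-strand reverse primer")
  }
  if (forward$template_start > reverse$template_end) {
    stop_aspcr("aspcr_geometry_error",
               "forward primer starts after the reverse primer ends")
  }
  reverse$template_end - forward$template_start + 1L
}

#' Assemble a designed assay
#'
#' @param forward plus-strand companion `primer`.
#' @param reverse minus-strand allele-specific `primer`.
#' @param target_species species the assay authenticates.
#' @param anchor_site the diagnostic site the reverse primer anchors on.
#' @return an `assay_design` with computed `product_bp`.
#' @export
assay_design <- function(forward, reverse, target_species, anchor_site) {
  if (forward$template_end >= reverse$template_start) {
    stop_aspcr("aspcr_geometry_error",
               "forward footprint must end before the reverse footprint starts")
  }
  structure(list(
    forward = forward,
    reverse = reverse,
    target_species = target_species,
    anchor_site = anchor_site,
    product_bp = amplicon_size(forward, reverse)
  ), class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat(sprintf("assay_design for %s (product %d bp, anchor at %d)\n",
              x$target_species, x$product_bp, x$anchor_site$position))
  print(x$forward); print(x$reverse)
  invisible(x)
}

#' Validate an assay design against its source alignment
#'
#' Re-derives every structural invariant: strand orientation, amplicon
#' geometry, the 3'-anchor rule (the reverse primer's terminal base must be
#' the Watson-Crick complement of the diagnostic allele and sit exactly on
#' the site), the single engineered edit (present in the sequence, never at
#' offset 1), and allele fixation in the target records.
#'
#' @param design an [assay_design].
#' @param aln the [species_alignment] the design was built from.
#' @return data.frame of class `design_validation` with columns `check`,
#'   `pass`, `detail`; attribute `overall` is `TRUE` iff all checks pass.
#' @export
validate_design <- function(design, aln) {
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  f <- design$forward; r <- design$reverse; site <- design$anchor_site

  add("strands", f$strand == "plus" && r$strand == "minus",
      sprintf("forward=%s reverse=%s", f$strand, r$strand))
  add("geometry",
      design$product_bp == r$template_end - f$template_start + 1L,
      sprintf("product_bp=%d footprint span=%d", design$product_bp,
              r$template_end - f$template_start + 1L))
  add("product_fits_primers",
      design$product_bp >= nchar(f$seq) + nchar(r$seq),
      sprintf("product %d vs primers %d+%d", design$product_bp,
              nchar(f$seq), nchar(r$seq)))
  anchor_base <- substr(r$seq, nchar(r$seq), nchar(r$seq))
  add("anchor",
      r$template_start == site$position &&
        anchor_base == unname(COMPLEMENT[site$target_base]),
      sprintf("3' base %s vs complement(%s), footprint start %d vs site %d",
              anchor_base, site$target_base, r$template_start, site$position))
  edit_ok <- nrow(r$edits) == 1L && all(r$edits$offset_from_3prime >= 2L)
  if (edit_ok) {
    tr <- which(aln$species == design$target_species)
    if (length(tr) > 0L) {
      tmpl <- aln$seq[tr[1L]]
      pm <- tryCatch(
        perfect_match_primer(tmpl, r$template_start, nchar(r$seq), "minus"),
        error = function(e) NULL)
      if (is.null(pm)) {
        edit_ok <- FALSE
      } else {
        diffs <- which(seq_chars(pm$seq) != seq_chars(r$seq))
        want <- nchar(r$seq) - r$edits$offset_from_3prime + 1L
        edit_ok <- identical(diffs, as.integer(want))
      }
    }
  }
  add("engineered_edit", edit_ok,
      sprintf("%d edit(s) recorded", nrow(r$edits)))
  tgt <- aln$seq[aln$species == design$target_species]
  fixed <- all(substr(tgt, site$position, site$position) == site$target_base)
  add("target_allele_fixed", fixed,
      sprintf("allele %s at %d in %d target record(s)", site$target_base,
              site$position, length(tgt)))

  out <- do.call(rbind, checks)
  attr(out, "overall") <- all(out$pass)
  class(out) <- c("design_validation", "data.frame")
  out
}

#' @export
print.design_validation <- function(x, ...) {
  cat(sprintf("design validation: %s\n",
              if (attr(x, "overall")) "PASS" else "FAIL"))
  print.data.frame(x)
  invisible(x)
}
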