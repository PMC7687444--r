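# Distance / neighbor-joining / bootstrap engine, implemented from scratch.
# Trees are emitted as ape-compatible "phylo" objects (edge matrix, tips
# numbered 1..n, root n+1) purely as a container convention; no tree
# inference is delegated.

pair_stats <- function(ca, cb, ids = c("a", "b")) {
  valid <- ca %in% DNA_BASES & cb %in% DNA_BASES   # pairwise deletion
  nv <- sum(valid)
  if (nv == 0L) {
    stop_aspcr("aspcr_saturation_error",
               "no comparable unambiguous sites between '%s' and '%s'",
               ids[1L], ids[2L])
  }
  a <- ca[valid]; b <- cb[valid]
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(a) == purine(b))  # transition: stays within purines/pyrimidines
  list(n = nv, p = mean(diff), P = mean(ts), Q = mean(diff & !ts))
}

#' Proportional (p) distance between two aligned sequences
#'
#' Differing sites divided by the number of sites where both sequences carry
#' an unambiguous base (pairwise deletion of gaps/ambiguity).
#'
#' @param a,b equal-length DNA strings.
#' @return fraction in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  a <- normalize_dna(a, "a"); b <- normalize_dna(b, "b")
  if (nchar(a) != nchar(b)) {
    stop_aspcr("aspcr_shape_error", "sequences have unequal lengths (%d vs %d)",
               nchar(a), nchar(b))
  }
  pair_stats(seq_chars(a), seq_chars(b))$p
}

k2p_from_PQ <- function(P, Q, ids = c("a", "b")) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop_aspcr("aspcr_saturation_error",
               "K2P distance saturated between '%s' and '%s' (P=%.3f, Q=%.3f)",
               ids[1L], ids[2L], P, Q)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

jc_from_p <- function(p, ids = c("a", "b")) {
  w <- 1 - 4 * p / 3
  if (w <= 0) {
    stop_aspcr("aspcr_saturation_error",
               "JC distance saturated between '%s' and '%s' (p=%.3f)",
               ids[1L], ids[2L], p)
  }
  -0.75 * log(w)
}

#' Kimura 2-parameter distance
#'
#' `-(1/2) ln(1-2P-Q) - (1/4) ln(1-2Q)` with `P` the transition and `Q` the
#' transversion fraction over pairwise-deleted sites. The standard corrected
#' distance for COI barcoding.
#'
#' @param a,b equal-length DNA strings.
#' @return distance in substitutions/site.
#' @export
k2p_distance <- function(a, b) {
  a <- normalize_dna(a, "a"); b <- normalize_dna(b, "b")
  if (nchar(a) != nchar(b)) {
    stop_aspcr("aspcr_shape_error", "sequences have unequal lengths (%d vs %d)",
               nchar(a), nchar(b))
  }
  st <- pair_stats(seq_chars(a), seq_chars(b))
  k2p_from_PQ(st$P, st$Q)
}

#' Jukes-Cantor distance
#' @param a,b equal-length DNA strings.
#' @return `-(3/4) ln(1 - 4p/3)` in substitutions/site.
#' @export
jc_distance <- function(a, b) jc_from_p(p_distance(a, b))

dist_from_chars <- function(M, model, ids) {
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      st <- pair_stats(M[i, ], M[j, ], ids = ids[c(i, j)])
      D[i, j] <- D[j, i] <- switch(model,
        p = st$p,
        jc = jc_from_p(st$p, ids[c(i, j)]),
        k2p = k2p_from_PQ(st$P, st$Q, ids[c(i, j)]))
    }
  }
  D
}

#' Pairwise distance matrix of an alignment
#'
#' @param aln a [species_alignment] with at least 3 records.
#' @param model `"k2p"` (default), `"jc"` or `"p"`.
#' @return object of class `distance_matrix`: list with `taxa`, symmetric
#'   matrix `d` and `model`.
#' @export
build_distance_matrix <- function(aln, model = c("k2p", "jc", "p")) {
  model <- match.arg(model)
  if (n_records(aln) < 3L) {
    stop_aspcr("aspcr_size_error", "need at least 3 records, got %d",
               n_records(aln))
  }
  D <- dist_from_chars(as.matrix(aln), model, aln$id)
  structure(list(taxa = aln$id, d = D, model = model),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("%s distance matrix over %d taxa\n", x$model, length(x$taxa)))
  print(round(x$d, 4))
  invisible(x)
}

#' Write a distance matrix as square TSV
#' @param dm a `distance_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(taxon = dm$taxa, dm$d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- NJ core -----------------------------------------------------------------

# recursive cluster -> ape-style phylo conversion
clusters_to_phylo <- function(root, taxa) {
  n <- length(taxa)
  env <- new.env()
  env$edge <- matrix(0L, nrow = 2L * n - 3L, ncol = 2L)
  env$len <- numeric(2L * n - 3L)
  env$nedge <- 0L
  env$next_internal <- n + 1L
  walk <- function(cl) {
    if (cl$kind == "tip") return(cl$index)
    me <- env$next_internal
    env$next_internal <- env$next_internal + 1L
    for (ch in cl$children) {
      child_id <- walk(ch$node)
      env$nedge <- env$nedge + 1L
      env$edge[env$nedge, ] <- c(me, child_id)
      env$len[env$nedge] <- ch$len
    }
    me
  }
  # assign ids in preorder: reserve root first, then children depth-first —
  # walk() as written assigns parent before descending, which is preorder
  walk(root)
  edge <- env$edge[seq_len(env$nedge), , drop = FALSE]
  raw <- env$len[seq_len(env$nedge)]
  clamped <- pmax(raw, 0)
  tree <- structure(list(edge = edge, edge.length = clamped,
                         tip.label = taxa, Nnode = n - 2L),
                    class = "phylo", order = "cladewise")
  if (any(raw < 0)) {
    attr(tree, "raw_edge.length") <- raw
    message(sprintf("%d negative NJ branch length(s) clamped to 0 (total deficit %.3g)",
                    sum(raw < 0), -sum(raw[raw < 0])))
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei/Studier-Keppler NJ: repeatedly join the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j`. Ties are broken by the
#' lexicographically smallest index pair in the current matrix, making the
#' result deterministic. Negative branch lengths are clamped to zero (raw
#' values kept in `attr(tree, "raw_edge.length")`).
#'
#' @param dm a `distance_matrix` (or a plain symmetric matrix with dimnames).
#' @return an unrooted tree of class `phylo` whose root trifurcation is the
#'   final NJ join.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "distance_matrix")) {
    D <- dm$d; taxa <- dm$taxa
  } else {
    D <- as.matrix(dm); taxa <- rownames(D)
    if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(D)))
  }
  n <- nrow(D)
  if (n < 3L) {
    stop_aspcr("aspcr_size_error", "neighbor joining needs at least 3 taxa")
  }
  active <- lapply(seq_len(n), function(i) list(kind = "tip", index = i))
  while (length(active) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    hits <- which(Q == min(Q), arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    i <- hits[1L, 1L]; j <- hits[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    joined <- list(kind = "node",
                   children = list(list(node = active[[i]], len = li),
                                   list(node = active[[j]], len = lj)))
    rest <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, rest] + D[j, rest] - D[i, j]) / 2
    D <- rbind(cbind(D[rest, rest, drop = FALSE], dnew),
               c(dnew, 0))
    active <- c(active[rest], list(joined))
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  root <- list(kind = "node", children = list(
    list(node = active[[1L]], len = (d12 + d13 - d23) / 2),
    list(node = active[[2L]], len = (d12 + d23 - d13) / 2),
    list(node = active[[3L]], len = (d13 + d23 - d12) / 2)))
  clusters_to_phylo(root, taxa)
}

# tips (as label character vectors) under each node, indexed by node id
tips_under <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  sets <- vector("list", nn)
  fill <- function(node) {
    if (node <= n) {
      sets[[node]] <<- tree$tip.label[node]
    } else {
      sets[[node]] <<- unlist(lapply(kids[[as.character(node)]], fill))
    }
    sets[[node]]
  }
  fill(n + 1L)
  sets
}

# canonical keys of the non-trivial bipartitions, named by child node id
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  sets <- tips_under(tree)
  internal_children <- tree$edge[tree$edge[, 2L] > n, 2L]
  keys <- vapply(internal_children, function(node) {
    side <- sets[[node]]
    if (tree$tip.label[1L] %in% side) side <- setdiff(tree$tip.label, side)
    paste(sort(side), collapse = "\x1f")
  }, character(1))
  stats::setNames(keys, internal_children)
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate and scores each internal edge of the full-data tree by the
#' fraction of replicates containing its bipartition. A replicate whose
#' distance matrix is uncomputable (saturation under resampling) contributes
#' no bipartitions but still counts in the denominator.
#'
#' @param aln a [species_alignment].
#' @param model distance model, as in [build_distance_matrix].
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed RNG seed (default 42); identical seeds give identical
#'   supports.
#' @return the full-data `phylo` tree with `$support` (fractions named by
#'   internal node id) and `$node.label` (integer percent, empty for the
#'   root and for unscored nodes).
#' @export
bootstrap_support <- function(aln, model = c("k2p", "jc", "p"),
                              replicates = 1000L, seed = 42L) {
  model <- match.arg(model)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop_aspcr("aspcr_config_error", "replicates must be >= 1")
  }
  M <- as.matrix(aln)
  tree <- neighbor_joining(build_distance_matrix(aln, model))
  keys <- bipartition_keys(tree)
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- aln$length
  withr::with_seed(seed, {
    for (rep in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      kb <- tryCatch(suppressMessages({
        Db <- dist_from_chars(M[, cols, drop = FALSE], model, aln$id)
        bipartition_keys(neighbor_joining(Db))
      }), aspcr_error = function(e) character(0))
      hit <- keys %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- counts / replicates
  n <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  labels[as.integer(names(keys)) - n] <-
    as.character(round(100 * support))
  tree$support <- stats::setNames(unname(support), names(keys))
  tree$node.label <- labels
  tree
}

#' Is a set of leaves monophyletic on an unrooted tree?
#'
#' `TRUE` iff some edge bipartitions exactly the given leaves from all
#' others. Singletons and the full leaf set are trivially monophyletic.
#'
#' @param tree a `phylo` tree.
#' @param taxa_subset character vector of leaf names.
#' @return logical.
#' @export
is_monophyletic <- function(tree, taxa_subset) {
  tips <- tree$tip.label
  taxa_subset <- unique(taxa_subset)
  if (length(taxa_subset) == 0L || !all(taxa_subset %in% tips)) {
    stop_aspcr("aspcr_label_error",
               "taxa_subset must be a non-empty subset of the leaf set")
  }
  k <- length(taxa_subset)
  if (k == 1L || k == length(tips)) return(TRUE)
  sets <- tips_under(tree)
  for (node in tree$edge[, 2L]) {
    side <- sets[[node]]
    if (setequal(side, taxa_subset) ||
        setequal(setdiff(tips, side), taxa_subset)) return(TRUE)
  }
  FALSE
}

#' Serialize a tree to Newick
#'
#' Branch lengths always written; internal node labels (bootstrap supports as
#' integer percent) written when present and non-empty. Output parses with
#' mainstream Newick readers.
#'
#' @param tree a `phylo` tree.
#' @param path optional output path; when `NULL` the string is returned only.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 6L) {
  n <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  fmt_len <- function(x) sprintf("%.*g", digits, x)
  node_label <- function(node) {
    if (is.null(tree$node.label)) return("")
    lb <- tree$node.label[node - n]
    if (is.na(lb)) "" else lb
  }
  render <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(render(tree$edge[e, 2L]), ":", fmt_len(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")", node_label(node))
  }
  nwk <- paste0(render(n + 1L), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
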