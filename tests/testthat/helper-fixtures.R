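# Shared fixtures and independent oracles. Everything here is deliberately
# naive / brute-force so the implementations under test are checked against
# code that shares none of their logic.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

toy_alignment <- function() {
  species_alignment(
    id = c("a1", "a2", "b1", "b2"),
    species = c("SpA", "SpA", "SpB", "SpB"),
    seq = c("ACGTACGT", "ACGTACGT", "ACGAACGT", "ACGAACGT"))
}

random_alignment <- function(n_records = 10L, len = 60L, n_species = 3L,
                             ambig_frac = 0, seed = 1L) {
  withr::with_seed(seed, {
    chars <- c("A", "C", "G", "T")
    pool <- c("N", "-", "R", "Y")
    seqs <- vapply(seq_len(n_records), function(i) {
      s <- sample(chars, len, replace = TRUE)
      if (ambig_frac > 0) {
        k <- rbinom(1, len, ambig_frac)
        if (k > 0) s[sample(len, k)] <- sample(pool, k, replace = TRUE)
      }
      paste(s, collapse = "")
    }, character(1))
    species_alignment(sprintf("r%02d", seq_len(n_records)),
                      sprintf("Sp%d", rep_len(seq_len(n_species), n_records)),
                      seqs)
  })
}

# mutually related sequences (shared root, moderate divergence) so corrected
# distances stay well below saturation
related_alignment <- function(n_records = 8L, len = 200L, mut = 0.1,
                              seed = 1L) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, len, replace = TRUE)
    seqs <- vapply(seq_len(n_records), function(i) {
      s <- root
      flip <- runif(len) < mut
      s[flip] <- vapply(s[flip], function(x)
        sample(setdiff(bases, x), 1L), character(1))
      paste(s, collapse = "")
    }, character(1))
    species_alignment(sprintf("r%02d", seq_len(n_records)),
                      sprintf("Sp%d", seq_len(n_records)), seqs)
  })
}

# naive double loop over columns x records, reimplementing the diagnostic
# definition from first principles
brute_force_sites <- function(aln, target, max_missing_frac = 0,
                              require_strict = TRUE) {
  m <- as.matrix(aln)
  bases <- c("A", "C", "G", "T")
  hits <- integer(0); tb_out <- character(0)
  for (j in seq_len(ncol(m))) {
    tgt <- character(0); oth <- character(0); miss <- 0L
    for (i in seq_len(nrow(m))) {
      ch <- m[i, j]
      if (!ch %in% bases) { miss <- miss + 1L; next }
      if (aln$species[i] == target) tgt <- c(tgt, ch) else oth <- c(oth, ch)
    }
    if (require_strict && miss > 0L) next
    if (miss / nrow(m) > max_missing_frac) next
    if (length(unique(tgt)) != 1L) next
    if (unique(tgt) %in% oth) next
    hits <- c(hits, j); tb_out <- c(tb_out, unique(tgt))
  }
  data.frame(position = hits, target_base = tb_out, stringsAsFactors = FALSE)
}

# random additive tree over n leaves: returns the leaf distance matrix, the
# set of non-trivial splits, and edge data for path-sum checks
random_additive_case <- function(n, seed) {
  withr::with_seed(seed, {
    leaves <- paste0("t", seq_len(n))
    comp <- lapply(leaves, function(l) list(node = l, leaves = l))
    edges <- list()
    next_id <- 0L
    splits <- list()
    while (length(comp) > 1L) {
      pick <- sample(length(comp), 2L)
      next_id <- next_id + 1L
      nid <- paste0("I", next_id)
      for (k in pick) {
        edges[[length(edges) + 1L]] <-
          list(a = nid, b = comp[[k]]$node, w = runif(1, 0.1, 1))
      }
      merged <- list(node = nid,
                     leaves = c(comp[[pick[1L]]]$leaves, comp[[pick[2L]]]$leaves))
      if (length(merged$leaves) >= 2L && length(merged$leaves) <= n - 2L) {
        splits[[length(splits) + 1L]] <- sort(merged$leaves)
      }
      comp <- c(comp[-pick], list(merged))
    }
    nodes <- unique(unlist(lapply(edges, function(e) c(e$a, e$b))))
    adj <- matrix(Inf, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    diag(adj) <- 0
    for (e in edges) adj[e$a, e$b] <- adj[e$b, e$a] <- e$w
    for (k in nodes) adj <- pmin(adj, outer(adj[, k], adj[k, ], "+"))
    D <- adj[leaves, leaves]
    list(D = D, splits = splits, leaves = leaves)
  })
}

# leaf-to-leaf path lengths on a phylo edge matrix, computed independently
tree_path_distances <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  adj <- matrix(Inf, nn, nn)
  diag(adj) <- 0
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    adj[a, b] <- adj[b, a] <- tree$edge.length[e]
  }
  for (k in seq_len(nn)) adj <- pmin(adj, outer(adj[, k], adj[k, ], "+"))
  D <- adj[seq_len(n), seq_len(n)]
  dimnames(D) <- list(tree$tip.label, tree$tip.label)
  D
}

# splits of a phylo tree as canonical sorted-leaf lists (independent of the
# package's internal bipartition code)
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  out <- list()
  for (child in tree$edge[, 2L]) {
    if (child <= n) next
    side <- sort(below(child))
    if (length(side) >= 2L && length(side) <= n - 2L) {
      if (tree$tip.label[1L] %in% side) {
        side <- sort(setdiff(tree$tip.label, side))
      }
      out[[length(out) + 1L]] <- side
    }
  }
  out
}

canon_splits <- function(splits, leaves) {
  unique(sort(vapply(splits, function(s) {
    if (leaves[1L] %in% s) s <- sort(setdiff(leaves, s))
    paste(s, collapse = "|")
  }, character(1))))
}

# noise-free two-clade alignment with `ndiff` fixed differences between the
# clades and a couple of private mutations per taxon
two_clade_alignment <- function(n_per_clade = 4L, len = 300L, ndiff = 15L,
                                seed = 99L) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, len, replace = TRUE)
    fixed <- sample(len, ndiff)
    other <- root
    for (j in fixed) other[j] <- sample(setdiff(bases, root[j]), 1L)
    mk <- function(template, label, k) {
      s <- template
      priv <- sample(setdiff(seq_len(len), fixed), 2L)
      for (j in priv) s[j] <- sample(setdiff(bases, s[j]), 1L)
      list(id = sprintf("%s%d", label, k), seq = paste(s, collapse = ""))
    }
    recs <- c(lapply(seq_len(n_per_clade), function(k) mk(root, "A", k)),
              lapply(seq_len(n_per_clade), function(k) mk(other, "B", k)))
    species_alignment(vapply(recs, `[[`, character(1), "id"),
                      rep(c("CladeA", "CladeB"), each = n_per_clade),
                      vapply(recs, `[[`, character(1), "seq"))
  })
}

# paper-shaped synthetic world used across acceptance tests
shaped_spec <- function(seed, noise = 0.002) {
  synthetic_spec(seed = seed, intraspecific_noise = noise)
}
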