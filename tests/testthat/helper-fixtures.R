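# Shared fixtures and independent oracles, built in code at test time.

# four-node toy phylogeny ((A1,A2)A,B)ROOT with one SNP per branch
toy_tree_files <- function(snp_rows = NULL) {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A1,A2)A,B)ROOT;", nwk)
  tsv <- tempfile(fileext = ".tsv")
  if (is.null(snp_rows)) {
    snp_rows <- data.frame(
      node = c("A", "A1", "A2", "B"),
      snp_id = c("sA", "sA1", "sA2", "sB"),
      ancestral = c("G", "C", "T", "A"),
      derived = c("A", "T", "C", "G"))
  }
  write.table(snp_rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(nwk = nwk, tsv = tsv)
}

toy_tree <- function() {
  f <- toy_tree_files()
  load_phylogeny(f$nwk, f$tsv)
}

# Build a GenotypePanel for a tree from per-individual lists of derived
# SNP ids (everything else ancestral unless listed in `missing`).
panel_from_states <- function(tree, derived = list(), missing = list()) {
  bs <- tree$branch_snps
  ids <- names(derived)
  calls <- matrix(rep(bs$ancestral, each = length(ids)),
                  nrow = length(ids),
                  dimnames = list(ids, bs$snp_id))
  for (i in ids) {
    calls[i, derived[[i]]] <- bs$derived[match(derived[[i]], bs$snp_id)]
    if (!is.null(missing[[i]])) calls[i, missing[[i]]] <- NA
  }
  genotype_panel(calls)
}

# Independent most-derived-haplogroup oracle: paths recomputed with ape,
# full enumeration of candidates, explicit tie rules.
oracle_assign <- function(nwk_text, branch_snps, calls_row) {
  tr <- ape::read.tree(text = nwk_text)
  labels <- c(tr$tip.label, tr$node.label)
  root <- labels[length(tr$tip.label) + 1L]
  path_of <- function(lab) {
    k <- match(lab, labels)
    idx <- ape::nodepath(tr, length(tr$tip.label) + 1L, k)
    setdiff(labels[idx], root)
  }
  derived <- names(calls_row)[!is.na(calls_row) &
    calls_row == branch_snps$derived[match(names(calls_row),
                                           branch_snps$snp_id)]]
  ancestral <- names(calls_row)[!is.na(calls_row) &
    calls_row == branch_snps$ancestral[match(names(calls_row),
                                             branch_snps$snp_id)]]
  observed <- names(calls_row)[!is.na(calls_row)]
  if (length(observed) == 0) return("unassigned")
  if (length(derived) == 0) return(root)
  snp_node <- setNames(branch_snps$node, branch_snps$snp_id)
  score <- sapply(labels, function(lab) {
    sum(snp_node[derived] %in% path_of(lab))
  })
  incons <- sapply(labels, function(lab) {
    sum(snp_node[ancestral] %in% path_of(lab))
  })
  missed <- names(calls_row)[is.na(calls_row)]
  miss <- sapply(labels, function(lab) {
    sum(snp_node[missed] %in% path_of(lab))
  })
  depth <- sapply(labels, function(lab) length(path_of(lab)))
  cand <- labels[score == max(score)]
  cand <- cand[incons[cand] == min(incons[cand])]
  cand <- cand[miss[cand] == min(miss[cand])]
  offpath <- length(derived) - score[cand]
  cand <- cand[offpath == min(offpath)]
  cand <- cand[depth[cand] == max(depth[cand])]
  sort(cand)[1]
}

# Independent iterate-to-convergence Tukey oracle
oracle_tukey <- function(x, k = 3) {
  keep <- !is.na(x)
  repeat {
    v <- x[which(keep)]
    q1 <- quantile(v, 0.25, names = FALSE)
    q3 <- quantile(v, 0.75, names = FALSE)
    iqr <- q3 - q1
    bad <- which(keep & (x < q1 - k * iqr | x > q3 + k * iqr))
    if (length(bad) == 0) break
    keep[bad] <- FALSE
  }
  keep[is.na(x)] <- NA
  keep
}
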