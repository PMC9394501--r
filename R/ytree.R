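## Y phylogeny representation, SNP panel QC, and haplogroup assignment.

#' Load a Y phylogeny and its branch-defining SNPs
#'
#' Reads a rooted Newick tree whose tip and internal node labels are
#' haplogroup names (ISOGG-style, e.g. `"J1a2b-L817"`) and a tab-separated
#' SNP map attaching branch-defining SNPs to each non-root node. Every
#' non-root node must carry at least one defining SNP: carrying the derived
#' allele at a node's SNPs is the evidence that a lineage passed through
#' that branch.
#'
#' @param tree_file path to a Newick file; all internal nodes must be
#'   labelled and labels must be unique.
#' @param snp_map path to a TSV with columns `node`, `snp_id`, `ancestral`,
#'   `derived`. Rows with missing alleles are reported and dropped.
#' @return An object of class `YPhylogeny`: a list with elements `nodes`,
#'   `root`, `parent` (named vector, child -> parent), `children`,
#'   `depth` (edges from root), `paths` (per node, the root-to-node node
#'   sequence excluding the root) and `branch_snps` (data frame).
#' @export
load_phylogeny <- function(tree_file, snp_map) {
  tr <- ape::read.tree(tree_file)
  ykc_assert(!is.null(tr), "could not parse Newick tree: ", tree_file)
  labels <- c(tr$tip.label, tr$node.label)
  ykc_assert(!anyNA(labels) && all(nzchar(labels)),
             "all tree nodes (including internal nodes) must be labelled")
  dup <- unique(labels[duplicated(labels)])
  if (length(dup)) ykc_stop("duplicate node labels in tree: ",
                            paste(dup, collapse = ", "))

  ntip <- length(tr$tip.label)
  root_idx <- ntip + 1L
  parent <- structure(labels[tr$edge[, 1]], names = labels[tr$edge[, 2]])

  snps <- utils::read.delim(snp_map, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("node", "snp_id", "ancestral", "derived")
  ykc_assert(all(need %in% names(snps)),
             "snp_map must have columns: ", paste(need, collapse = ", "))
  snps <- snps[, need]
  bad <- !nzchar(snps$ancestral) | !nzchar(snps$derived) |
    is.na(snps$ancestral) | is.na(snps$derived)
  if (any(bad)) {
    message("Dropping ", sum(bad), " SNP map row(s) with missing alleles: ",
            paste(utils::head(snps$snp_id[bad], 5), collapse = ", "))
    snps <- snps[!bad, , drop = FALSE]
  }
  unknown <- setdiff(unique(snps$node), labels)
  if (length(unknown)) {
    ykc_stop("snp_map references node(s) absent from the tree: ",
             paste(unknown, collapse = ", "))
  }

  root <- labels[root_idx]
  nonroot <- setdiff(labels, root)
  bare <- setdiff(nonroot, unique(snps$node))
  if (length(bare)) {
    ykc_stop("non-root node(s) without a defining SNP: ",
             paste(bare, collapse = ", "))
  }

  # root-to-node paths (excluding root, whose branch has no SNPs)
  paths <- lapply(labels, function(lab) {
    path <- character()
    while (lab != root) {
      path <- c(lab, path)
      lab <- parent[[lab]]
    }
    path
  })
  names(paths) <- labels

  children <- split(names(parent), factor(unname(parent), levels = labels))

  structure(list(
    nodes = labels,
    root = root,
    parent = parent,
    children = children,
    depth = vapply(paths, length, integer(1)),
    paths = paths,
    branch_snps = snps
  ), class = "YPhylogeny")
}

#' @export
print.YPhylogeny <- function(x, ...) {
  cat("YPhylogeny:", length(x$nodes), "nodes,",
      nrow(x$branch_snps), "branch-defining SNPs, root =", x$root, "\n")
  invisible(x)
}

#' All nodes in the subtree rooted at `node` (including `node` itself)
#' @param tree a `YPhylogeny`
#' @param node a node label
#' @return character vector of node labels
#' @export
subtree_nodes <- function(tree, node) {
  ykc_assert(node %in% tree$nodes, "unknown node: ", node)
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- unlist(tree$children[frontier], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

## ---- Genotype panel -------------------------------------------------------

#' Construct a haploid Y genotype panel
#'
#' @param calls character matrix of single-allele calls, individuals in rows
#'   (rownames = IDs), SNPs in columns (colnames = SNP IDs); `NA` = missing.
#' @return A `GenotypePanel`: list with `individuals`, `snps`, `calls` and
#'   per-SNP `call_rate`.
#' @export
genotype_panel <- function(calls) {
  ykc_assert(is.matrix(calls) && !is.null(rownames(calls)) &&
               !is.null(colnames(calls)),
             "calls must be a matrix with individual rownames and SNP colnames")
  storage.mode(calls) <- "character"
  calls[!is.na(calls) & calls %in% c("", ".", "-", "N")] <- NA_character_
  structure(list(
    individuals = rownames(calls),
    snps = colnames(calls),
    calls = calls,
    call_rate = colMeans(!is.na(calls))
  ), class = "GenotypePanel")
}

#' @export
print.GenotypePanel <- function(x, ...) {
  cat("GenotypePanel:", length(x$individuals), "individuals x",
      length(x$snps), "SNPs; median call rate",
      round(stats::median(x$call_rate), 3), "\n")
  invisible(x)
}

#' Read a haploid genotype table (long TSV: individual, snp_id, allele)
#' @param path TSV path with columns `individual`, `snp_id`, `allele`
#' @return a `GenotypePanel`
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("individual", "snp_id", "allele")
  ykc_assert(all(need %in% names(d)),
             "genotype TSV must have columns: ", paste(need, collapse = ", "))
  inds <- unique(d$individual)
  snps <- unique(d$snp_id)
  calls <- matrix(NA_character_, length(inds), length(snps),
                  dimnames = list(inds, snps))
  calls[cbind(match(d$individual, inds), match(d$snp_id, snps))] <- d$allele
  genotype_panel(calls)
}

#' Read haploid Y genotypes from a VCF
#'
#' Haploid GT fields (`0`, `1`) are mapped to REF/ALT alleles. Diploid
#' heterozygous GTs are treated as missing: the male Y is haploid, so a het
#' call is a genotyping artifact. Homozygous diploid GTs (`0/0`, `1/1`) are
#' accepted as their haploid equivalent.
#'
#' @param path VCF path (uncompressed or gzipped)
#' @return a `GenotypePanel` (individuals = VCF samples, SNPs = VCF IDs)
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    ykc_stop("reading VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ref <- vcfR::getREF(v)
  alt <- vcfR::getALT(v)
  ids <- vcfR::getID(v)
  ykc_assert(!anyNA(ids), "VCF records must carry SNP IDs")
  core <- gsub("\\|", "/", gt)
  allele_of <- function(g, i) {
    out <- rep(NA_character_, length(g))
    out[g %in% c("0", "0/0")] <- ref[i]
    out[g %in% c("1", "1/1")] <- alt[i]
    out  # "0/1", "1/0", "./." and friends stay missing
  }
  calls <- matrix(NA_character_, ncol(gt), nrow(gt),
                  dimnames = list(colnames(gt), ids))
  for (i in seq_len(nrow(gt))) calls[, i] <- allele_of(core[i, ], i)
  genotype_panel(calls)
}

#' Quality-control a SNP panel
#'
#' Removes SNPs with call rate below `min_call_rate`, then SNPs that are
#' monomorphic among the survivors' observed (non-missing) calls, in that
#' fixed order. Removal tallies are attached as the `"qc_log"` attribute and
#' reported via `message()`.
#'
#' @param panel a `GenotypePanel`
#' @param min_call_rate minimum fraction of non-missing calls (default 0.95)
#' @return the filtered `GenotypePanel`; errors if no SNP survives
#' @export
qc_snps <- function(panel, min_call_rate = 0.95) {
  ykc_assert(inherits(panel, "GenotypePanel"), "panel must be a GenotypePanel")
  ykc_assert(length(panel$snps) > 0, "panel has no SNPs")
  n_in <- length(panel$snps)

  keep_cr <- panel$call_rate >= min_call_rate
  n_low <- sum(!keep_cr)
  calls <- panel$calls[, keep_cr, drop = FALSE]

  n_obs_alleles <- apply(calls, 2, function(x) length(unique(x[!is.na(x)])))
  keep_poly <- n_obs_alleles >= 2L
  n_mono <- sum(!keep_poly)
  calls <- calls[, keep_poly, drop = FALSE]

  if (ncol(calls) == 0L) {
    ykc_stop("all SNPs removed by QC (", n_low, " low call rate, ",
             n_mono, " monomorphic)")
  }
  out <- genotype_panel(calls)
  log <- list(n_in = n_in, n_low_call_rate = n_low,
              n_monomorphic = n_mono, n_out = ncol(calls))
  attr(out, "qc_log") <- log
  message("qc_snps: ", n_in, " in, ", n_low, " removed (call rate < ",
          min_call_rate, "), ", n_mono, " removed (monomorphic), ",
          ncol(calls), " retained")
  out
}

## ---- Assignment -----------------------------------------------------------

# Map raw allele calls onto ancestral(0)/derived(1) indicators for the SNPs
# the tree knows about. Calls matching neither configured allele are treated
# as missing. Returns a numeric matrix individuals x tree SNPs.
derived_matrix <- function(tree, panel) {
  bs <- tree$branch_snps
  common <- intersect(bs$snp_id, panel$snps)
  ykc_assert(length(common) > 0,
             "no overlap between panel SNPs and tree branch SNPs")
  bs <- bs[match(common, bs$snp_id), , drop = FALSE]
  calls <- panel$calls[, common, drop = FALSE]
  D <- matrix(NA_real_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  anc <- matrix(bs$ancestral, nrow(calls), ncol(calls), byrow = TRUE)
  der <- matrix(bs$derived, nrow(calls), ncol(calls), byrow = TRUE)
  D[!is.na(calls) & calls == anc] <- 0
  D[!is.na(calls) & calls == der] <- 1
  n_bad <- sum(!is.na(calls) & calls != anc & calls != der)
  if (n_bad > 0) {
    warning(n_bad, " call(s) match neither configured allele; treated as missing",
            call. = FALSE)
  }
  attr(D, "snp_node") <- stats::setNames(bs$node, bs$snp_id)
  D
}

# snps x nodes indicator: is this SNP's branch on the root-to-node path?
path_membership <- function(tree, snp_node) {
  K <- length(tree$nodes)
  P <- matrix(0, length(snp_node), K,
              dimnames = list(names(snp_node), tree$nodes))
  for (k in seq_len(K)) {
    on_path <- snp_node %in% tree$paths[[tree$nodes[k]]]
    P[on_path, k] <- 1
  }
  P
}

#' Assign every individual its most-derived haplogroup
#'
#' For each individual, scores every node by the number of derived calls on
#' the root-to-node path and returns the best-supported node. Ties are
#' broken by parsimony: first fewer observed-*ancestral* calls on the
#' candidate path (a candidate contradicted by its own defining SNPs
#' loses), then fewer *missing* calls on the path (no descending into a
#' branch with no observed evidence), then fewer derived calls off the
#' path, then greater path depth, then lexicographic label order. The
#' consistency rules are what let a noise-free individual stopping at an
#' internal node be recovered exactly rather than pushed into a child
#' branch; among candidates tied on the derived-path score the off-path
#' count is constant, so depth and label settle the remaining genuine
#' conflicts (equal observed evidence on two branches). An individual with zero
#' derived calls is assigned the root; an individual with no observed calls
#' at all gets the sentinel `"unassigned"`.
#'
#' @param tree a `YPhylogeny`
#' @param panel a `GenotypePanel` whose SNPs overlap the tree's branch SNPs
#' @return named character vector of atomic haplogroup labels per individual
#' @export
assign_haplogroups <- function(tree, panel) {
  D <- derived_matrix(tree, panel)
  P <- path_membership(tree, attr(D, "snp_node"))
  D0 <- D
  D0[is.na(D0)] <- 0
  A0 <- !is.na(D) & D == 0                # observed ancestral
  M0 <- is.na(D)                          # missing
  score <- D0 %*% P                       # derived calls on path, per node
  incons <- A0 %*% P                      # ancestral calls on path, per node
  miss <- M0 %*% P                        # missing calls on path, per node
  total_derived <- rowSums(D0)
  # Hierarchical key: derived-path score desc, then observed-ancestral on
  # path asc, then missing on path asc, then depth desc. Off-path derived
  # (total - score) is constant among score-tied candidates so it needs no
  # term. m+1 bounds every minor term.
  m <- nrow(P)
  key <- ((score * (m + 1) - incons) * (m + 1) - miss) * (m + 1) +
    matrix(tree$depth[colnames(score)], nrow(score), ncol(score),
           byrow = TRUE)
  # columns in label order so ties.method = "first" is the label rule
  ord <- order(colnames(key))
  key_o <- key[, ord, drop = FALSE]
  best <- colnames(key_o)[max.col(key_o, ties.method = "first")]
  best[total_derived == 0] <- tree$root
  best[rowSums(!is.na(D)) == 0] <- "unassigned"
  stats::setNames(best, rownames(D))
}

#' Assign a single individual (see [assign_haplogroups()])
#' @param tree a `YPhylogeny`
#' @param panel a `GenotypePanel`
#' @param individual an individual ID present in the panel
#' @return atomic haplogroup label (or `"unassigned"`)
#' @export
assign_haplogroup <- function(tree, panel, individual) {
  if (!individual %in% panel$individuals) {
    ykc_stop("individual not in panel: ", individual)
  }
  sub <- genotype_panel(panel$calls[individual, , drop = FALSE])
  unname(assign_haplogroups(tree, sub)[individual])
}

## ---- Indicator matrix -----------------------------------------------------

#' Build the haplogroup indicator matrix
#'
#' Produces one binary column per atomic tree node (mutually exclusive),
#' plus composite columns (the union of their member atomic nodes) and
#' paragroup columns (carriers in an ancestor's subtree minus carriers in
#' the subtrees of enumerated excluded descendants; labels conventionally
#' end in `"*"`). `"unassigned"` individuals contribute 0 everywhere and so
#' fall into the non-carrier reference group of every model.
#'
#' @param assignments named character vector of atomic labels per individual
#'   (as from [assign_haplogroups()])
#' @param tree a `YPhylogeny`
#' @param composite_defs optional list of definitions; each element is a list
#'   with `label` and either `members` (character vector of atomic nodes) or
#'   `ancestor` + `exclude` for a paragroup. See [read_group_defs()].
#' @return a `HaplogroupMatrix`: list with `groups`, `indicators` (integer
#'   matrix individuals x groups), `definitions`, `counts`, `atomic`.
#' @export
build_indicator_matrix <- function(assignments, tree, composite_defs = NULL) {
  labs <- unique(assignments)
  bad <- setdiff(labs, c(tree$nodes, "unassigned"))
  if (length(bad)) {
    ykc_stop("assignment label(s) not in tree: ", paste(bad, collapse = ", "))
  }
  n <- length(assignments)
  atomic <- tree$nodes
  ind <- matrix(0L, n, length(atomic),
                dimnames = list(names(assignments), atomic))
  hit <- assignments != "unassigned"
  ind[cbind(which(hit), match(assignments[hit], atomic))] <- 1L

  defs <- list()
  extra <- NULL
  for (def in composite_defs) {
    ykc_assert(is.list(def) && !is.null(def$label),
               "each composite definition needs a label")
    if (!is.null(def$members)) {
      unknown <- setdiff(def$members, atomic)
      if (length(unknown)) {
        ykc_stop("composite '", def$label, "' references unknown node(s): ",
                 paste(unknown, collapse = ", "))
      }
      col <- as.integer(rowSums(ind[, def$members, drop = FALSE]) > 0)
      defs[[def$label]] <- list(type = "composite", members = def$members)
    } else if (!is.null(def$ancestor)) {
      unknown <- setdiff(c(def$ancestor, def$exclude), atomic)
      if (length(unknown)) {
        ykc_stop("paragroup '", def$label, "' references unknown node(s): ",
                 paste(unknown, collapse = ", "))
      }
      inc <- subtree_nodes(tree, def$ancestor)
      exc <- unique(unlist(lapply(def$exclude, subtree_nodes, tree = tree)))
      members <- setdiff(inc, exc)
      col <- as.integer(rowSums(ind[, members, drop = FALSE]) > 0)
      defs[[def$label]] <- list(type = "paragroup", ancestor = def$ancestor,
                                exclude = def$exclude, members = members)
    } else {
      ykc_stop("definition '", def$label,
               "' needs either 'members' or 'ancestor'")
    }
    extra <- cbind(extra, col)
    colnames(extra)[ncol(extra)] <- def$label
  }
  indicators <- if (is.null(extra)) ind else cbind(ind, extra)
  structure(list(
    groups = colnames(indicators),
    indicators = indicators,
    definitions = defs,
    counts = colSums(indicators),
    atomic = atomic
  ), class = "HaplogroupMatrix")
}

#' @export
print.HaplogroupMatrix <- function(x, ...) {
  cat("HaplogroupMatrix:", nrow(x$indicators), "individuals x",
      length(x$groups), "groups (", length(x$atomic), "atomic,",
      length(x$definitions), "derived )\n")
  invisible(x)
}

#' Read composite/paragroup definitions from YAML
#' @param path YAML file with a top-level `groups` list; each entry has
#'   `label` and either `members` or `ancestor` + `exclude`.
#' @return list of definitions suitable for [build_indicator_matrix()]
#' @export
read_group_defs <- function(path) {
  y <- yaml::read_yaml(path)
  ykc_assert(!is.null(y$groups), "group definition YAML needs a 'groups' key")
  y$groups
}

#' Filter haplogroups on carrier or carrier-case counts
#'
#' Continuous-trait mode (no `case_indicator`) keeps groups with at least
#' `min_carriers` carriers; binary-outcome mode keeps groups with at least
#' `min_cases` carriers who are cases.
#'
#' @param matrix a `HaplogroupMatrix`
#' @param min_carriers minimum carrier count (default 100)
#' @param case_indicator optional binary/logical vector aligned with
#'   individuals; switches to carrier-case counting
#' @param min_cases minimum carrier-case count (default 40)
#' @return the filtered `HaplogroupMatrix` (possibly with zero groups)
#' @export
filter_groups <- function(matrix, min_carriers = 100, case_indicator = NULL,
                          min_cases = 40) {
  ykc_assert(inherits(matrix, "HaplogroupMatrix"),
             "matrix must be a HaplogroupMatrix")
  if (is.null(case_indicator)) {
    keep <- matrix$counts >= min_carriers
  } else {
    ykc_assert(length(case_indicator) == nrow(matrix$indicators),
               "case_indicator must align with individuals")
    cc <- as.numeric(case_indicator)
    cc[is.na(cc)] <- 0
    keep <- colSums(matrix$indicators * cc) >= min_cases
  }
  message("filter_groups: retained ", sum(keep), " of ", length(keep),
          " groups")
  out <- matrix
  out$groups <- matrix$groups[keep]
  out$indicators <- matrix$indicators[, keep, drop = FALSE]
  out$counts <- matrix$counts[keep]
  out$definitions <- matrix$definitions[intersect(names(matrix$definitions),
                                                  out$groups)]
  out$atomic <- intersect(matrix$atomic, out$groups)
  out
}

#' Haplogroup prevalence by (hierarchical) area
#'
#' Counts each individual at the finest area level whose containing area
#' holds at least `min_area_n` individuals, then tabulates per-group
#' prevalence in each counted area. Individuals with no usable area at any
#' level are excluded and logged.
#'
#' @param matrix a `HaplogroupMatrix`
#' @param area_labels data frame of area codes per individual, one column per
#'   level ordered finest to coarsest; `NA` = unknown at that level
#' @param min_area_n minimum individuals per reported area (default 100)
#' @return data frame with columns `group`, `level`, `area`, `n`, `carriers`,
#'   `prevalence`; the number of excluded individuals is attached as
#'   attribute `"n_excluded"`.
#' @export
prevalence_by_area <- function(matrix, area_labels, min_area_n = 100) {
  ykc_assert(inherits(matrix, "HaplogroupMatrix"),
             "matrix must be a HaplogroupMatrix")
  area_labels <- as.data.frame(area_labels)
  n <- nrow(matrix$indicators)
  ykc_assert(nrow(area_labels) == n, "area_labels must align with individuals")

  chosen_level <- rep(NA_integer_, n)
  chosen_area <- rep(NA_character_, n)
  for (l in seq_along(area_labels)) {
    lab <- as.character(area_labels[[l]])
    sizes <- table(lab)
    ok <- is.na(chosen_level) & !is.na(lab) &
      sizes[lab] >= min_area_n & !is.na(sizes[lab])
    ok[is.na(ok)] <- FALSE
    chosen_level[ok] <- l
    chosen_area[ok] <- lab[ok]
  }
  excl <- is.na(chosen_level)
  if (any(excl)) {
    message("prevalence_by_area: excluded ", sum(excl),
            " individual(s) with no area reaching n >= ", min_area_n)
  }
  keep <- !excl
  key <- paste(chosen_level[keep], chosen_area[keep], sep = "\r")
  ind <- matrix$indicators[keep, , drop = FALSE]
  n_area <- as.vector(table(key)[unique(key)])
  ukey <- unique(key)
  rows <- lapply(seq_along(ukey), function(i) {
    sel <- key == ukey[i]
    parts <- strsplit(ukey[i], "\r", fixed = TRUE)[[1]]
    carriers <- colSums(ind[sel, , drop = FALSE])
    data.frame(group = matrix$groups,
               level = as.integer(parts[1]),
               area = parts[2],
               n = sum(sel),
               carriers = as.numeric(carriers),
               prevalence = as.numeric(carriers) / sum(sel),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- sum(excl)
  out
}
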