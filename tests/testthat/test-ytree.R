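test_that("toy phylogeny loads with one SNP per branch", {
  tree <- toy_tree()
  expect_s3_class(tree, "YPhylogeny")
  expect_equal(sort(tree$nodes), sort(c("ROOT", "A", "A1", "A2", "B")))
  expect_equal(tree$root, "ROOT")
  expect_length(tree$parent, 4)               # 4 edges
  expect_equal(as.vector(table(tree$branch_snps$node)[c("A", "A1", "A2", "B")]),
               rep(1L, 4))
  expect_equal(tree$paths[["A1"]], c("A", "A1"))
})

test_that("SNP map referencing an unknown node errors naming the node", {
  rows <- data.frame(node = c("A", "A1", "A2", "B", "C"),
                     snp_id = paste0("s", 1:5),
                     ancestral = "G", derived = "A")
  f <- toy_tree_files(rows)
  expect_error(load_phylogeny(f$nwk, f$tsv), "C")
})

test_that("duplicate node labels are a hard error", {
  nwk <- tempfile(fileext = ".nwk")
  writeLines("((A1,A2)A,(B1,B2)A)ROOT;", nwk)
  rows <- data.frame(node = c("A", "A1"), snp_id = c("s1", "s2"),
                     ancestral = "G", derived = "A")
  tsv <- tempfile(fileext = ".tsv")
  write.table(rows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_phylogeny(nwk, tsv), "duplicate")
})

test_that("several SNPs on one branch all attach to that edge", {
  rows <- data.frame(
    node = c("A", "A", "A", "A1", "A2", "B"),
    snp_id = c("sA_1", "sA_2", "sA_3", "sA1", "sA2", "sB"),
    ancestral = "G", derived = "A")
  f <- toy_tree_files(rows)
  tree <- load_phylogeny(f$nwk, f$tsv)
  expect_equal(sum(tree$branch_snps$node == "A"), 3)
})

test_that("qc_snps removes low-call-rate then monomorphic SNPs", {
  set.seed(1)
  n <- 40
  calls <- matrix("A", n, 10, dimnames = list(sprintf("i%02d", 1:n),
                                              paste0("s", 1:10)))
  for (j in 1:10) calls[sample(n, n / 2), j] <- "G"   # polymorphic
  calls[1:6, 1] <- NA                                  # 85% call rate
  calls[, 2] <- "A"                                    # monomorphic
  panel <- genotype_panel(calls)
  out <- suppressMessages(qc_snps(panel, min_call_rate = 0.95))
  expect_equal(length(out$snps), 8)
  expect_false(any(c("s1", "s2") %in% out$snps))
  log <- attr(out, "qc_log")
  expect_equal(log$n_low_call_rate, 1)
  expect_equal(log$n_monomorphic, 1)
})

test_that("a SNP monomorphic only through missingness is removed", {
  calls <- matrix("A", 20, 2, dimnames = list(sprintf("i%02d", 1:20),
                                              c("s1", "s2")))
  calls[1:10, 2] <- "G"
  calls[20, 1] <- NA       # the only variable call is missing
  panel <- genotype_panel(calls)
  out <- suppressMessages(qc_snps(panel, min_call_rate = 0.9))
  expect_equal(out$snps, "s2")
  expect_equal(attr(out, "qc_log")$n_monomorphic, 1)
})

test_that("panel with study-scale removal counts retains the expected SNPs", {
  # 232 SNPs in; 39 below the call-rate threshold; 27 monomorphic among the
  # survivors; 166 retained
  set.seed(42)
  n <- 200
  calls <- matrix(NA_character_, n, 232,
                  dimnames = list(sprintf("i%03d", 1:n), paste0("s", 1:232)))
  for (j in 1:232) {
    calls[, j] <- sample(c("A", "G"), n, TRUE)
    if (j <= 39) calls[sample(n, 0.1 * n), j] <- NA       # call rate 0.90
    else if (j <= 39 + 27) calls[, j] <- "A"              # monomorphic
  }
  out <- suppressMessages(qc_snps(genotype_panel(calls)))
  log <- attr(out, "qc_log")
  expect_equal(log$n_in, 232)
  expect_equal(log$n_low_call_rate, 39)
  expect_equal(log$n_monomorphic, 27)
  expect_equal(log$n_out, 166)
})

test_that("qc_snps is idempotent", {
  set.seed(2)
  calls <- matrix(sample(c("A", "G", NA), 600, TRUE, c(.48, .48, .04)),
                  30, 20, dimnames = list(sprintf("i%02d", 1:30),
                                          paste0("s", 1:20)))
  p1 <- suppressMessages(qc_snps(genotype_panel(calls), 0.9))
  p2 <- suppressMessages(qc_snps(p1, 0.9))
  expect_equal(p1$snps, p2$snps)
  expect_equal(p1$calls, p2$calls)
})

test_that("assignment handles the zero-derived and conflict cases", {
  tree <- toy_tree()
  panel <- panel_from_states(tree, derived = list(
    anc = character(),           # all ancestral
    a1 = c("sA", "sA1"),         # A then A1 derived
    conflict = c("sA1", "sB")))  # equal path scores at 1
  asn <- assign_haplogroups(tree, panel)
  expect_equal(unname(asn["anc"]), "ROOT")
  expect_equal(unname(asn["a1"]), "A1")
  # tie at score 1: A1's path carries an observed-ancestral call (sA) while
  # B's path is clean, so parsimony resolves to B (one error, not two)
  expect_equal(unname(asn["conflict"]), "B")
  expect_equal(unname(asn["conflict"]),
               oracle_assign("((A1,A2)A,B)ROOT;", tree$branch_snps,
                             panel$calls["conflict", ]))
  expect_equal(assign_haplogroup(tree, panel, "a1"), "A1")
  expect_error(assign_haplogroup(tree, panel, "nope"), "not in panel")
})

test_that("all-missing individuals get the unassigned sentinel", {
  tree <- toy_tree()
  panel <- panel_from_states(tree,
                             derived = list(x = character()),
                             missing = list(x = c("sA", "sA1", "sA2", "sB")))
  expect_equal(unname(assign_haplogroups(tree, panel)["x"]), "unassigned")
})

test_that("assignment agrees with a brute-force path-score oracle", {
  tree <- ykc_fixture_tree()
  bs <- tree$branch_snps
  nwk_text <- readLines(system.file("extdata", "fixture_tree.nwk",
                                    package = "ykincohort"))
  set.seed(11)
  for (rep in 1:40) {
    calls <- ifelse(runif(nrow(bs)) < 0.35, bs$derived, bs$ancestral)
    calls[runif(nrow(bs)) < 0.15] <- NA
    names(calls) <- bs$snp_id
    m <- matrix(calls, 1, dimnames = list("x", bs$snp_id))
    got <- unname(assign_haplogroups(tree, genotype_panel(m))["x"])
    expect_equal(got, oracle_assign(nwk_text, bs, calls))
  }
})

test_that("noise-free simulated genotypes are recovered exactly", {
  cfg <- sim_config(n_subjects = 300, snp_error_rate = 0,
                    snp_missing_rate = 0, emit_records = FALSE,
                    simulate_parents = FALSE, simulate_survival = FALSE,
                    seed = 5)
  sim <- simulate_cohort(cfg)
  asn <- assign_haplogroups(sim$tree, sim$panel)
  expect_equal(unname(asn), sim$cohort$haplogroup_true)
})

test_that("missingness restricted to off-path SNPs does not break recovery", {
  tree <- ykc_fixture_tree()
  bs <- tree$branch_snps
  set.seed(21)
  for (node in c("R1b-M343", "I1-M253", "F-M89", "Y")) {
    path <- tree$paths[[node]]
    onpath <- bs$snp_id[bs$node %in% path]
    offpath <- setdiff(bs$snp_id, onpath)
    drop <- sample(offpath, floor(length(offpath) / 2))
    panel <- panel_from_states(tree, derived = setNames(list(onpath), "x"),
                               missing = setNames(list(drop), "x"))
    expect_equal(unname(assign_haplogroups(tree, panel)["x"]), node)
  }
})

test_that("indicator matrix handles composites, paragroups, unassigned", {
  tree <- toy_tree()
  asn <- c(i1 = "A1", i2 = "A2", i3 = "B", i4 = "unassigned")
  defs <- list(list(label = "Acomp", members = c("A1", "A2")),
               list(label = "ALL",
                    members = c("ROOT", "A", "A1", "A2", "B")))
  m <- build_indicator_matrix(asn, tree, defs)
  expect_equal(unname(m$indicators[, "Acomp"]), c(1, 1, 0, 0))
  expect_equal(unname(m$indicators[, "ALL"]), c(1, 1, 1, 0))
  # atomic columns mutually exclusive; unassigned row all zero
  expect_true(all(rowSums(m$indicators[, m$atomic]) <= 1))
  expect_equal(sum(m$indicators["i4", ]), 0)
  expect_equal(m$counts, colSums(m$indicators))
  expect_error(build_indicator_matrix(asn, tree,
                                      list(list(label = "bad",
                                                members = "Zzz"))),
               "Zzz")
})

test_that("paragroup = ancestor subtree minus excluded descendant subtrees", {
  tree <- ykc_fixture_tree()
  asn <- c(a = "F-M89", b = "C-M130", c = "E1b-M215", d = "G-M201",
           e = "I1-M253", f = "R1b-M343", g = "Y")
  m <- build_indicator_matrix(asn, tree, ykc_fixture_groups())
  para <- m$indicators[, "F-M89*"]
  expect_equal(unname(para), c(1, 1, 1, 0, 0, 0, 0))
  # composite column equals the OR of its member atomic columns bit-exactly
  ij <- m$definitions[["IJ-M429"]]$members
  expect_identical(unname(m$indicators[, "IJ-M429"]),
                   as.integer(rowSums(m$indicators[, ij]) > 0))
})

test_that("indicator column sums are invariant to individual order", {
  tree <- ykc_fixture_tree()
  set.seed(3)
  asn <- setNames(sample(tree$nodes, 120, TRUE), sprintf("i%03d", 1:120))
  m1 <- build_indicator_matrix(asn, tree, ykc_fixture_groups())
  perm <- sample(length(asn))
  m2 <- build_indicator_matrix(asn[perm], tree, ykc_fixture_groups())
  expect_equal(m1$counts, m2$counts)
})

test_that("filter_groups applies closed thresholds in both modes", {
  tree <- toy_tree()
  asn <- setNames(rep(c("A1", "A2", "B"), c(99, 100, 150)),
                  sprintf("i%03d", 1:349))
  m <- build_indicator_matrix(asn, tree)
  kept <- suppressMessages(filter_groups(m, min_carriers = 100))
  expect_false("A1" %in% kept$groups)   # 99 carriers: dropped
  expect_true(all(c("A2", "B") %in% kept$groups))
  ident <- suppressMessages(filter_groups(m, min_carriers = 0))
  expect_equal(ident$groups, m$groups)

  cases <- as.numeric(seq_along(asn) <= 40)  # first 40 A1 carriers are cases
  kept2 <- suppressMessages(filter_groups(m, case_indicator = cases,
                                          min_cases = 40))
  expect_true("A1" %in% kept2$groups)   # exactly 40 carrier-cases: kept
  expect_false("B" %in% kept2$groups)
})

test_that("prevalence_by_area rolls up and conserves carriers", {
  tree <- toy_tree()
  n <- 150
  asn <- setNames(rep(c("A1", "B", "A2"), c(50, 60, 40)),
                  sprintf("i%03d", 1:n))
  m <- build_indicator_matrix(asn, tree)
  # fine area f1 has 50 people (below 100), f2 has 100; both share parent P
  areas <- data.frame(fine = rep(c("f1", "f2"), c(50, 100)),
                      coarse = "P")
  prev <- suppressMessages(prevalence_by_area(m, areas, min_area_n = 100))
  f2 <- prev[prev$area == "f2" & prev$group == "B", ]
  expect_equal(f2$level, 1)
  expect_equal(f2$prevalence, 60 / 100)   # 60 of f2's 100 carry B
  p <- prev[prev$area == "P", ]
  expect_true(all(p$n == 50))             # only the f1 people roll up
  # conservation: per group, sum over areas of carriers = total carriers
  for (g in m$groups) {
    expect_equal(sum(prev$carriers[prev$group == g]), unname(m$counts[g]))
  }
  expect_true(all(prev$prevalence >= 0 & prev$prevalence <= 1))
})

test_that("single-area prevalence is the direct ratio", {
  tree <- toy_tree()
  asn <- setNames(rep(c("A1", "B"), c(12, 88)), sprintf("i%03d", 1:100))
  m <- build_indicator_matrix(asn, tree)
  prev <- prevalence_by_area(m, data.frame(area = rep("only", 100)),
                             min_area_n = 100)
  expect_equal(prev$prevalence[prev$group == "A1"], 0.12)
})

test_that("VCF input maps haploid GTs and treats het calls as missing", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=Y>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tm1\tm2\tm3",
    "Y\t100\tsA\tG\tA\t.\tPASS\t.\tGT\t0\t1\t0/1",
    "Y\t200\tsB\tC\tT\t.\tPASS\t.\tGT\t1/1\t.\t0"
  ), vcf)
  panel <- read_genotypes_vcf(vcf)
  expect_equal(panel$calls["m1", "sA"], "G")
  expect_equal(panel$calls["m2", "sA"], "A")
  expect_true(is.na(panel$calls["m3", "sA"]))   # het on the Y -> missing
  expect_equal(panel$calls["m1", "sB"], "T")    # 1/1 accepted as haploid
  expect_true(is.na(panel$calls["m2", "sB"]))
  expect_equal(panel$calls["m3", "sB"], "C")
})
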