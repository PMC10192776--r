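test_that("p-distance uses pairwise deletion and never matches X", {
  aln <- aln_of(a = "AAAA", b = "AAAT", c = "A-CD")
  d <- p_distance(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "a"], 0)
  expect_equal(d, t(d))

  gap <- aln_of(a = "A-CD", b = "AKCD", c = "AAAA")
  expect_equal(p_distance(gap)["a", "b"], 0)  # gap column excluded: 0/3

  xx <- aln_of(a = "AX", b = "AX", c = "AA")
  expect_equal(p_distance(xx)["a", "b"], 0.5)  # X vs X is not a match

  disjoint <- aln_of(a = "AA--", b = "--AA", c = "AAAA")
  expect_error(p_distance(disjoint), "no comparable columns")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("NJ recovers additive matrices exactly and matches ape's NJ", {
  for (seed in 1:10) {
    gm <- generate_additive_matrix(n_taxa = 4 + (seed %% 7), seed = seed)
    tr <- suppressMessages(nj_tree(gm$d))
    co <- ape::cophenetic.phylo(tr)[rownames(gm$d), colnames(gm$d)]
    expect_lt(max(abs(co - gm$d)), 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(gm$tree), ape::unroot(tr)), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::dist.topo(ape::unroot(ape::nj(gm$d)), ape::unroot(tr)),
                 0, ignore_attr = TRUE)
  }
})

test_that("degenerate equidistant four taxa give a zero internal branch", {
  ids <- c("a", "b", "c", "d")
  d <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  tr <- suppressMessages(nj_tree(d))
  internal <- tr$edge[, 2] > ape::Ntip(tr)
  expect_equal(sum(tr$edge.length[internal]), 0)
  expect_equal(unname(ape::cophenetic.phylo(tr)["a", "b"]), 1)
})

test_that("non-symmetric or invalid distance matrices are rejected", {
  d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
               "at least 3|square", ignore.case = TRUE)
})

test_that("newick round trips preserve topology, lengths and supports", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2)90:1,C:3);", path)
  tr <- read_newick(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  ab_node <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(tr$node.label[ab_node - ape::Ntip(tr)], "90")

  out <- tempfile(fileext = ".nwk")
  write_newick(tr, out)
  tr2 <- read_newick(out)
  expect_equal(suppressWarnings(ape::dist.topo(tr, tr2)), 0,
               ignore_attr = TRUE)
  expect_equal(tr2$edge.length, tr$edge.length)
  expect_equal(tr2$node.label, tr$node.label)
  # canonical form: a second round trip is byte-identical
  out2 <- tempfile(fileext = ".nwk")
  write_newick(tr2, out2)
  expect_identical(readLines(out), readLines(out2))

  quoted <- tempfile(fileext = ".nwk")
  writeLines("(('taxon one':1,'taxon two':2):1,outgroup:3);", quoted)
  trq <- read_newick(quoted)
  expect_true("taxon one" %in% trq$tip.label)
  qout <- tempfile(fileext = ".nwk")
  write_newick(trq, qout)
  expect_setequal(read_newick(qout)$tip.label, trq$tip.label)

  badp <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2:1,C:3);", badp)
  expect_error(read_newick(badp))
})

test_that("bootstrap supports are deterministic and sane at n_reps = 1", {
  fam <- generate_family(family_config(
    n_groups = 2, records_per_group = 4, seq_length = 80,
    group_divergence = 0.4, within_noise = 0.05, seed = 21))
  b1 <- bootstrap_support(fam$aln, n_reps = 20, seed = 5)
  b2 <- bootstrap_support(fam$aln, n_reps = 20, seed = 5)
  expect_identical(b1$node.label, b2$node.label)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))

  one <- bootstrap_support(fam$aln, n_reps = 1, seed = 5)
  sup <- suppressWarnings(as.numeric(one$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0, 100)))
  expect_error(bootstrap_support(fam$aln, n_reps = 10), "seed")
})

test_that("supports do not depend on tip order", {
  fam <- generate_family(family_config(
    n_groups = 2, records_per_group = 4, seq_length = 80,
    group_divergence = 0.5, within_noise = 0.02, seed = 33))
  aln <- fam$aln
  ids <- rownames(aln$seq)
  perm <- subset_alignment(aln, rev(ids))
  b <- bootstrap_support(aln, n_reps = 50, seed = 2)
  bp <- bootstrap_support(perm, n_reps = 50, seed = 2)
  # compare support of the group-1 bipartition in both trees
  # support of the central bipartition: one of the two groups must form a
  # proper clade on each (arbitrarily rooted) unrooted tree
  sup_of <- function(tree, tips) {
    node <- ape::getMRCA(tree, tips)
    dt <- ape::extract.clade(tree, node)$tip.label
    if (!setequal(dt, tips)) return(NA_real_)
    as.numeric(tree$node.label[node - ape::Ntip(tree)])
  }
  central <- function(tree) {
    g1 <- ids[fam$truth$group == 1]; g2 <- ids[fam$truth$group == 2]
    s <- sup_of(tree, g1)
    if (is.na(s)) s <- sup_of(tree, g2)
    s
  }
  s1 <- central(b); s2 <- central(bp)
  expect_false(is.na(s1))
  expect_equal(s1, s2)
})

test_that("clade concordance reports purity and maximal pure clades", {
  # constructed tree: two perfectly label-partitioned supported clades
  path <- tempfile(fileext = ".nwk")
  writeLines("(((a1:1,a2:1)99:1,(a3:1,a4:1)99:1)99:1,((b1:1,b2:1)99:1,(b3:1,b4:1)99:1)99:1,c1:1);",
             path)
  tr <- read_newick(path)
  meta <- data.frame(id = c(paste0("a", 1:4), paste0("b", 1:4), "c1"),
                     env = c(rep("soil", 4), rep("marine", 4), "gut"))
  cc <- clade_concordance(tr, meta, "env", support_min = 50)
  expect_true(all(cc$clades$purity == 1))
  expect_equal(sort(cc$summary$label), c("marine", "soil"))
  expect_equal(cc$summary$largest_pure_clade, c(4, 4))
  expect_equal(cc$summary$n_pure_clades, c(1, 1))  # maximal ones only

  # all tips share one label -> every supported clade has purity 1
  # (the unsupported root is never evaluated, so the maximal pure clades
  # are the two supported 4-tip clades)
  meta1 <- data.frame(id = meta$id, env = "soil")
  cc1 <- clade_concordance(tr, meta1, "env")
  expect_true(all(cc1$clades$purity == 1))
  expect_equal(cc1$summary$largest_pure_clade, 4)
  expect_equal(cc1$summary$n_pure_clades, 2)

  # missing metadata becomes "unknown"; low support nodes are skipped
  meta2 <- meta; meta2$env[9] <- NA
  cc2 <- clade_concordance(tr, meta2, "env", support_min = 50)
  expect_false(any(cc2$clades$support < 50))
  expect_error(clade_concordance(tr, meta, "nope"), "not present")
})

test_that("random labels give purity near the label-frequency maximum in large clades", {
  set.seed(77)
  gm <- generate_additive_matrix(n_taxa = 40, seed = 15)
  tr <- suppressMessages(nj_tree(gm$d))
  tr$node.label <- rep("100", tr$Nnode)
  meta <- data.frame(id = tr$tip.label,
                     env = sample(c("x", "y"), 40, replace = TRUE))
  cc <- clade_concordance(tr, meta, "env")
  big <- cc$clades[cc$clades$size >= 15, ]
  expect_true(all(big$purity < 1))       # mixing is near-certain at this size
  expect_true(all(big$purity >= 0.5))    # majority fraction of two labels
})

test_that("iTOL export is deterministic and validates tip coverage", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)90:1,C:1);", path)
  tr <- read_newick(path)
  meta <- data.frame(id = c("A", "B", "C"), env = c("soil", "soil", "marine"))
  d1 <- file.path(tempdir(), "itol1"); d2 <- file.path(tempdir(), "itol2")
  p1 <- export_itol_annotations(tr, meta, "env", dir = d1)
  p2 <- export_itol_annotations(tr, meta, "env", dir = d2)
  l1 <- readLines(p1[["env"]])
  expect_identical(l1, readLines(p2[["env"]]))
  dat <- l1[(which(l1 == "DATA") + 1):length(l1)]
  expect_equal(length(dat), 3L)
  legend <- strsplit(l1[grepl("^LEGEND_LABELS", l1)], "\t")[[1]][-1]
  expect_equal(sort(legend), c("marine", "soil"))

  bad_meta <- meta[1:2, ]
  expect_error(export_itol_annotations(tr, bad_meta, "env", dir = d1),
               "missing from metadata")
})
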