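test_that("newick parsing yields unrooted binary trees with the right splits", {
  tr <- read_tree("((c,p),m,(k,b));")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 5L)
  bp <- tree_bipartitions(tr)
  expect_setequal(bp$bipartition, c("cp", "bk"))
  expect_error(read_tree("(a,b);"), "at least 4")
  expect_error(read_tree("((a,a),b,(c,d));"), "Duplicate")
  expect_error(read_tree("(a,b,c,d,e);"), "polytomies")
  expect_silent(read_tree("(a,b,c,d,e);", allow_polytomies = TRUE))
  # a rooted input is unrooted; bipartitions survive a write/parse cycle
  rooted <- read_tree("(((c,p),m),(k,b));")
  expect_setequal(tree_bipartitions(rooted)$bipartition, c("cp", "bk"))
  back <- read_tree(ape::write.tree(rooted))
  expect_setequal(tree_bipartitions(back)$bipartition, c("cp", "bk"))
})

test_that("tree bipartition counts follow the n - 3 rule", {
  expect_equal(nrow(tree_bipartitions(read_tree("((a,b),(c,d));"))), 1L)
  expect_equal(nrow(tree_bipartitions(read_tree("((c,p),m,(k,b));"))), 2L)
  tr7 <- read_tree("(((a,b),(c,d)),e,(f,g));")
  expect_equal(nrow(tree_bipartitions(tr7)), 4L)
})

test_that("informative sites map to their taxon bipartition", {
  expect_equal(site_bipartition(
    stats::setNames(c("N", "N", "N", "C", "C"), yeast_taxa)), "bk")
  # D in c,m,b vs H in p,k: named by the smaller {k,p} block
  expect_equal(site_bipartition(
    stats::setNames(c("D", "H", "D", "H", "D"), yeast_taxa)), "kp")
  expect_error(site_bipartition(
    stats::setNames(c("A", "A", "A", "A", "A"), yeast_taxa)), "exactly 2")
})

test_that("Fitch length matches anchors and is invariant to rooting", {
  tr <- yeast_tree()
  kb <- stats::setNames(c("N", "N", "N", "C", "C"), yeast_taxa)
  cb <- stats::setNames(c("N", "G", "G", "G", "N"), yeast_taxa)
  expect_equal(fitch_length(kb, tr), 1L)
  expect_equal(fitch_length(cb, tr), 2L)
  expect_equal(fitch_length(stats::setNames(rep("A", 5), yeast_taxa), tr), 0L)
  # invariance under re-rooting and taxon order
  for (tip in yeast_taxa) {
    rerooted <- ape::unroot(ape::root(tr, outgroup = tip))
    expect_equal(fitch_length(cb, rerooted), 2L)
    expect_equal(fitch_length(cb[sample(5)], rerooted), 2L)
  }
})

test_that("Fitch lengths agree with the phangorn implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  trees <- enumerate_unrooted_trees(letters[1:6])
  for (i in 1:40) {
    site <- random_site(letters[1:6], n_states = sample(2:4, 1))
    tr <- trees[[sample(length(trees), 1)]]
    pd <- phangorn::phyDat(as.matrix(site, ncol = 1), type = "AA")
    expect_equal(fitch_length(site, tr),
                 as.integer(phangorn::parsimony(tr, pd)),
                 info = paste(site, collapse = ""))
  }
})

test_that("missing residues act as parsimony wildcards", {
  tr <- yeast_tree()
  # with p and m unknown, a single change can explain the N/G contrast
  amb <- stats::setNames(c("N", "X", "-", "G", "N"), yeast_taxa)
  expect_equal(fitch_length(amb, tr), 1L)
  all_missing <- stats::setNames(rep("-", 5), yeast_taxa)
  expect_equal(fitch_length(all_missing, tr), 0L)
})

test_that("the minimum length over all trees is the state count minus one", {
  trees <- enumerate_unrooted_trees(yeast_taxa)
  set.seed(13)
  for (i in 1:20) {
    site <- random_site(yeast_taxa, n_states = sample(2:4, 1))
    best <- min(vapply(trees, function(tr) fitch_length(site, tr), 0L))
    expect_equal(min_length_any_tree(site), best,
                 info = paste(site, collapse = ""))
  }
  expect_equal(min_length_any_tree(c("A", "A", "C", "C")), 1L)
  expect_equal(min_length_any_tree(c("A", "G", "C", "C")), 2L)
  expect_equal(min_length_any_tree(rep("-", 4)), 0L)
})

test_that("homoplasy index takes the two-point form on five-taxon sites", {
  tr <- yeast_tree()
  kb <- stats::setNames(c("N", "N", "N", "C", "C"), yeast_taxa)
  cb <- stats::setNames(c("N", "G", "G", "G", "N"), yeast_taxa)
  expect_equal(homoplasy_index(kb, tr)$hi, 0)
  expect_equal(homoplasy_index(cb, tr)$hi, 0.5)
  expect_equal(homoplasy_index(stats::setNames(rep("A", 5), yeast_taxa), tr)$hi, 0)
})

test_that("topology enumeration is exhaustive and duplicate-free", {
  expect_equal(length(enumerate_unrooted_trees(letters[1:4])), 3L)
  expect_equal(length(enumerate_unrooted_trees(letters[1:5])), 15L)
  trees6 <- enumerate_unrooted_trees(letters[1:6])
  expect_equal(length(trees6), 105L)
  keys <- vapply(trees6, function(tr) {
    paste(sort(tree_bipartitions(tr)$bipartition), collapse = "|")
  }, "")
  expect_equal(anyDuplicated(keys), 0L)
  expect_error(enumerate_unrooted_trees(letters[1:3]), "4 to 8")
  expect_error(enumerate_unrooted_trees(letters[1:9]), "4 to 8")
})

test_that("exhaustive parsimony search recovers a planted topology", {
  plan <- tibble::tibble(bipartition = c("bk", "cp"),
                         class = "RGC_CAM", count = c(10, 10))
  sim <- generate_alignment(yeast_taxa, plan, n_constant = 5, seed = 21)
  res <- parsimony_search(sim$alignment)
  expect_equal(length(res$trees), 1L)
  expect_setequal(tree_bipartitions(res$trees[[1]])$bipartition, c("cp", "bk"))
  expect_equal(res$score, 20L)
  expect_equal(res$n_searched, 15L)
  # all topologies tie on constant data
  const <- generate_alignment(yeast_taxa, plan[0, ], n_constant = 6, seed = 3)
  res0 <- parsimony_search(const$alignment)
  expect_equal(length(res0$trees), 15L)
  expect_equal(res0$score, 0L)
})

test_that("tree length decomposes into consistent plus twice homoplastic sites", {
  plan <- tibble::tibble(bipartition = c("bk", "cp", "bc"),
                         class = "RGC_CAM", count = c(8, 7, 3))
  sim <- generate_alignment(yeast_taxa, plan, seed = 8)
  res <- parsimony_search(sim$alignment)
  n <- 18; m_h <- 3  # bc conflicts with the planted majority topology
  expect_equal(res$score, (n - m_h) + 2L * m_h)
})

test_that("bootstrap support is deterministic and saturates on clean signal", {
  plan <- tibble::tibble(bipartition = c("bk", "cp"),
                         class = "RGC_CAM", count = c(12, 12))
  sim <- generate_alignment(yeast_taxa, plan, seed = 31)
  bs1 <- bootstrap_support(sim$alignment, yeast_tree(), replicates = 60, seed = 5)
  bs2 <- bootstrap_support(sim$alignment, yeast_tree(), replicates = 60, seed = 5)
  expect_identical(bs1, bs2)
  expect_equal(unname(bs1$support), c(100, 100))
  # "any" semantics can only increase support relative to "strict"
  noisy <- generate_alignment(
    yeast_taxa,
    tibble::tibble(bipartition = c("bk", "cp", "bc"),
                   class = "RGC_CAM", count = c(4, 2, 3)),
    seed = 9)
  strict <- bootstrap_support(noisy$alignment, yeast_tree(), 40, seed = 2,
                              semantics = "strict")
  any_ <- bootstrap_support(noisy$alignment, yeast_tree(), 40, seed = 2,
                            semantics = "any")
  expect_true(all(any_$support >= strict$support))
})

test_that("support tables count sites per bipartition", {
  plan <- tibble::tibble(bipartition = c("bk", "bc"),
                         class = "RGC_CAM", count = c(3, 1))
  sim <- generate_alignment(yeast_taxa, plan, n_constant = 2, seed = 4)
  sites <- scan_alignment(sim$alignment, std_matrix())
  tab <- support_table(sites, "RGC_CAM", reference_tree = yeast_tree())
  expect_equal(attr(tab, "total"), 4L)
  expect_equal(tab$n[tab$bipartition == "bk"], 3L)
  expect_equal(tab$n[tab$bipartition == "bc"], 1L)
  expect_equal(sum(tab$n[tab$in_tree]) / attr(tab, "total"), 0.75)
  empty <- support_table(sites[0, ], "RGC_CAM")
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "total"), 0L)
})
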