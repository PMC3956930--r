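test_that("site classification applies the three criteria", {
  m <- std_matrix()
  expect_equal(classify_site(c("N", "N", "N", "C", "C"), m)$site_class, "RGC_CAM")
  expect_equal(classify_site(c("D", "D", "D", "H", "H"), m)$site_class, "RGC_non-CAM")
  expect_equal(classify_site(rep("A", 5), m)$site_class, "other")       # (a) fails
  expect_equal(classify_site(c("N", "N", "N", "N", "C"), m)$site_class, "other")  # (b): singleton
})

test_that("multi-residue sites require a uniform pair class", {
  m <- std_matrix()
  td <- tidy(m)
  multi <- td[td$pair_class == "multi-step", ]
  # find three mutually multi-step residues
  trip <- NULL
  for (i in seq_len(nrow(multi))) {
    a <- multi$aa1[i]; b <- multi$aa2[i]
    cands <- AA_LETTERS[m[a, ] >= 2 & m[b, ] >= 2]
    if (length(cands)) { trip <- c(a, b, cands[1]); break }
  }
  expect_false(is.null(trip))
  col <- rep(trip, each = 2)
  expect_equal(classify_site(col, m)$site_class, "RGC_CAM")
  # mix in a single-step relation: no longer all multi-step, not all single
  sing <- td[td$pair_class == "single-step", ][1, ]
  mixed <- c(rep(sing$aa1, 2), rep(sing$aa2, 2), rep(trip[1], 2))
  if (m[sing$aa1, trip[1]] >= 2 || m[sing$aa2, trip[1]] >= 2) {
    expect_equal(classify_site(mixed, m)$site_class, "other")
  }
})

test_that("missing data is ignored by default and disqualifying in strict mode", {
  m <- std_matrix()
  col <- c(a = "N", b = "N", c = "-", d = "C", e = "C", f = "X")
  expect_equal(classify_site(col, m)$site_class, "RGC_CAM")
  expect_equal(classify_site(col, m, strict = TRUE)$site_class, "other")
})

test_that("classification is invariant under taxon reordering and relabeling", {
  m <- std_matrix()
  set.seed(42)
  for (i in 1:25) {
    col <- random_site(letters[1:6], n_states = sample(2:3, 1))
    base <- classify_site(col, m)$site_class
    perm <- sample(length(col))
    expect_equal(classify_site(col[perm], m)$site_class, base)
    relabeled <- stats::setNames(unname(col), LETTERS[seq_along(col)])
    expect_equal(classify_site(relabeled, m)$site_class, base)
  }
})

test_that("scanning a toy alignment partitions its columns", {
  sites <- scan_alignment(toy_alignment(), std_matrix())
  counts <- attr(sites, "counts")
  expect_equal(unname(counts["RGC_CAM"]), 1L)
  expect_equal(unname(counts["RGC_non-CAM"]), 1L)
  expect_equal(unname(counts["other"]), 6L)
  expect_equal(sum(counts), toy_alignment()$n_sites)
  expect_equal(sites$site[sites$site_class == "RGC_CAM"], 3L)
  expect_equal(sites$site[sites$site_class == "RGC_non-CAM"], 7L)
  # both split c,p,m from k,b
  expect_equal(unique(stats::na.omit(sites$bipartition)), "bk")
})

test_that("an all-constant alignment has no informative sites", {
  aln <- aa_alignment(c(a = "GGG", b = "GGG", c = "GGG", d = "GGG"))
  counts <- attr(scan_alignment(aln, std_matrix()), "counts")
  expect_equal(unname(counts), c(0L, 0L, 3L))
})

test_that("extracted site classes round-trip through FASTA", {
  aln <- toy_alignment()
  sites <- scan_alignment(aln, std_matrix())
  cam <- extract_sites(aln, sites, "RGC_CAM")
  expect_equal(cam$n_sites, 1L)
  expect_equal(unname(cam$seqs), c("N", "N", "N", "C", "C"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_alignment(cam, f)
  back <- read_alignment(f)
  expect_equal(back$seqs, cam$seqs)
  expect_equal(back$taxa, cam$taxa)
  # empty selection
  none <- extract_sites(aln, sites[0, ], "RGC_CAM")
  expect_equal(none$n_sites, 0L)
  expect_equal(none$taxa, aln$taxa)
})

test_that("alignment reading rejects ragged, duplicated and empty input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">b", "MK"), f)
  expect_error(read_alignment(f), "equal length")
  writeLines(c(">a", "MKV", ">a", "MKV"), f)
  expect_error(read_alignment(f), "unique")
  writeLines(character(0), f)
  expect_error(read_alignment(f))
})

test_that("batch summaries aggregate per-alignment counts", {
  taxa <- yeast_taxa
  plan1 <- tibble::tibble(bipartition = "bk", class = "RGC_CAM", count = 1)
  plan2 <- tibble::tibble(bipartition = c("cp", "bk"),
                          class = c("RGC_CAM", "RGC_CAM"), count = c(1, 1))
  a1 <- generate_alignment(taxa, plan1, n_constant = 4, seed = 1)$alignment
  a2 <- generate_alignment(taxa, plan2, n_constant = 4, seed = 2)$alignment
  a3 <- generate_alignment(taxa, plan1[0, ], n_constant = 5, seed = 3)$alignment
  out <- batch_summary(list(one = a1, two = a2, zero = a3), std_matrix())
  expect_equal(out$per_alignment$n_cam, c(1L, 2L, 0L))
  expect_equal(out$histogram$n_alignments, c(1L, 1L, 1L))
  expect_equal(unname(out$totals["n_cam"]), 3L)
  expect_equal(unname(out$totals["n_sites"]),
               sum(out$per_alignment$n_sites))
  # inconsistent taxon sets are rejected
  alien <- aa_alignment(c(x = "AA", y = "AA", z = "AA", w = "AA"))
  expect_error(batch_summary(list(a1, alien)), "inconsistent")
})
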