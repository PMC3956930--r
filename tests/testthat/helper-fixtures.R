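# Shared fixtures and independent oracles, built in code.

.fixture_env <- new.env(parent = emptyenv())

# memoised standard-code distance matrix
std_matrix <- function() {
  if (is.null(.fixture_env$mat)) .fixture_env$mat <- cam_matrix()
  .fixture_env$mat
}

yeast_taxa <- c("c", "p", "m", "k", "b")

# Independent brute-force oracle for the minimum nucleotide distance
# between two amino acids: enumerates every codon pair directly from the
# Biostrings code table, bypassing the package's codon machinery.
oracle_min_dist <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  ca <- names(gc)[gc == a]
  cb <- names(gc)[gc == b]
  best <- 3L
  for (x in ca) {
    xs <- strsplit(x, "")[[1]]
    for (y in cb) {
      d <- sum(xs != strsplit(y, "")[[1]])
      if (d < best) best <- d
    }
  }
  best
}

# toy 5x8 alignment: col 3 is an N/C split (kb), col 7 a D/H split (kb),
# all other columns constant
toy_alignment <- function() {
  aa_alignment(c(
    c = "MANAAADG",
    p = "MANAAADG",
    m = "MANAAADG",
    k = "MACAAAHG",
    b = "MACAAAHG"
  ))
}

random_site <- function(taxa, n_states = 2) {
  states <- sample(AA_LETTERS, n_states)
  stats::setNames(sample(states, length(taxa), replace = TRUE), taxa)
}

# all set partitions of a small taxon set, as residue patterns with one
# distinct amino acid per block (covers every 5-taxon site shape up to
# state relabelling)
all_partition_patterns <- function(taxa) {
  n <- length(taxa)
  parts <- list(list(1L))
  for (i in seq_len(n - 1L) + 1L) {
    parts <- unlist(lapply(parts, function(p) {
      grown <- lapply(seq_along(p), function(j) {
        q <- p
        q[[j]] <- c(q[[j]], i)
        q
      })
      c(grown, list(c(p, list(i))))
    }), recursive = FALSE)
  }
  lapply(parts, function(p) {
    res <- character(n)
    for (j in seq_along(p)) res[p[[j]]] <- AA_LETTERS[j]
    stats::setNames(res, taxa)
  })
}
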