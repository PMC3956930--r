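#' Canonical bipartition name
#'
#' A split of the taxon set is named after its smaller block, taxa sorted;
#' when every label is a single character the labels are concatenated
#' (so the split separating k and b from c, p, m is `"bk"`), otherwise they
#' are joined with commas. For equal-sized blocks the lexicographically
#' smaller name is used.
#'
#' @param block Character vector: the taxa on one side of the split.
#' @param taxa The full taxon set.
#' @return A single string naming the split.
#' @export
bipartition_name <- function(block, taxa) {
  block <- sort(block)
  other <- sort(setdiff(taxa, block))
  if (!length(block) || !length(other)) abort("Both blocks must be non-empty.")
  sep <- if (all(nchar(taxa) == 1L)) "" else ","
  a <- paste(block, collapse = sep)
  b <- paste(other, collapse = sep)
  if (length(block) < length(other)) return(a)
  if (length(other) < length(block)) return(b)
  min(a, b)
}

#' Recover a bipartition block from its canonical name
#'
#' @param name A name produced by [bipartition_name()].
#' @param taxa The full taxon set.
#' @return Character vector of taxa in the named block.
#' @export
parse_bipartition_name <- function(name, taxa) {
  block <- if (all(nchar(taxa) == 1L)) strsplit(name, "")[[1L]]
           else strsplit(name, ",")[[1L]]
  if (!all(block %in% taxa)) {
    abort(paste0("Bipartition '", name, "' names taxa outside the taxon set."))
  }
  block
}

#' Read an unrooted binary tree from Newick
#'
#' @param x A Newick string or the path to a Newick file.
#' @param allow_polytomies Accept non-binary trees (bipartition extraction
#'   still works; parsimony operations require binary trees).
#' @return An unrooted `phylo` object (rooted inputs are unrooted by
#'   suppressing the root).
#' @examples
#' tr <- read_tree("((c,p),m,(k,b));")
#' @export
read_tree <- function(x, allow_polytomies = FALSE) {
  phy <- if (length(x) == 1L && !grepl("[(;]", x) && file.exists(x)) {
    ape::read.tree(x)
  } else {
    ape::read.tree(text = x)
  }
  if (is.null(phy)) abort("Could not parse Newick input.")
  if (anyDuplicated(phy$tip.label)) abort("Duplicate tip labels.")
  if (ape::Ntip(phy) < 4L) {
    abort("Need at least 4 taxa for a tree with internal structure.")
  }
  phy <- ape::unroot(phy)
  if (!allow_polytomies && !ape::is.binary(phy)) {
    abort("Tree contains polytomies (set allow_polytomies = TRUE).")
  }
  phy
}

#' Nontrivial bipartitions of a tree
#'
#' One split per internal edge; an unrooted binary tree over n taxa has
#' n - 3 of them.
#'
#' @param tree A `phylo` object.
#' @return A tibble with `bipartition` (canonical name) and `block`
#'   (list-column holding the smaller block).
#' @export
tree_bipartitions <- function(tree) {
  taxa <- tree$tip.label
  pp <- ape::prop.part(tree)
  blocks <- purrr::map(pp, function(idx) taxa[idx])
  # first entry of prop.part is the full tip set (the root); drop trivial
  blocks <- purrr::keep(blocks, function(b) {
    length(b) >= 2L && length(b) <= length(taxa) - 2L
  })
  names <- vapply(blocks, bipartition_name, "", taxa = taxa)
  keep <- !duplicated(names)
  tibble(bipartition = names[keep],
         block = purrr::map(blocks[keep], function(b) {
           canonical_block(b, taxa)
         }))
}

canonical_block <- function(block, taxa) {
  parse_bipartition_name(bipartition_name(block, taxa), taxa)
}

#' Bipartition induced by an informative site
#'
#' A site whose canonical residues form exactly two groups splits the taxa
#' into the two groups.
#'
#' @param residues Named character vector of residues (names = taxa).
#' @param taxa Full taxon set (defaults to `names(residues)`).
#' @return The canonical bipartition name.
#' @export
site_bipartition <- function(residues, taxa = names(residues)) {
  if (is.null(names(residues))) names(residues) <- taxa
  canonical <- residues[residues %in% AA_LETTERS]
  groups <- split(names(canonical), as.character(canonical))
  if (length(groups) != 2L) {
    abort(paste0("Site has ", length(groups),
                 " residue groups; a bipartition needs exactly 2."))
  }
  bipartition_name(groups[[1L]], taxa)
}

# --- Fitch parsimony -------------------------------------------------------

# Root an unrooted binary tree into a fully bifurcating rooted tree so the
# postorder pass visits exactly two children per internal node.
rooted_binary <- function(tree) {
  phy <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  stats::reorder(phy, "postorder")
}

# Leaf state bitmasks for a set of site patterns. m: residue matrix
# (taxa x sites). Missing (non-canonical) residues become wildcards over the
# states observed at that site; all-missing sites get a single dummy state.
leaf_masks <- function(m) {
  S <- ncol(m)
  masks <- matrix(0L, nrow(m), S, dimnames = list(rownames(m), NULL))
  for (j in seq_len(S)) {
    col <- m[, j]
    states <- unique(col[col %in% AA_LETTERS])
    if (!length(states)) {
      masks[, j] <- 1L
      next
    }
    full <- bitwShiftL(1L, length(states)) - 1L
    idx <- match(col, states)
    masks[, j] <- ifelse(is.na(idx), full, bitwShiftL(1L, idx - 1L))
  }
  masks
}

# Fitch change counts for all sites at once on one tree.
fitch_counts <- function(masks, tree) {
  phy <- rooted_binary(tree)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  S <- ncol(masks)
  M <- matrix(0L, ntip + nnode, S)
  M[seq_len(ntip), ] <- masks[phy$tip.label, , drop = FALSE]
  changes <- integer(S)
  seen <- logical(ntip + nnode)
  e <- phy$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1L]; ch <- e[k, 2L]
    cm <- M[ch, ]
    if (!seen[p]) {
      M[p, ] <- cm
      seen[p] <- TRUE
    } else {
      inter <- bitwAnd(M[p, ], cm)
      empty <- inter == 0L
      changes <- changes + empty
      M[p, ] <- ifelse(empty, bitwOr(M[p, ], cm), inter)
    }
  }
  changes
}

#' Fitch parsimony length of a site on a tree
#'
#' The minimum number of unordered state changes the site requires on the
#' given topology. Non-canonical residues are treated as missing data
#' (wildcards over the site's observed states).
#'
#' @param residues Named character vector of residues; names must cover the
#'   tree's tip labels.
#' @param tree An unrooted binary `phylo`.
#' @return Integer change count.
#' @examples
#' tr <- read_tree("((c,p),m,(k,b));")
#' fitch_length(c(c = "N", p = "N", m = "N", k = "C", b = "C"), tr)  # 1
#' @export
fitch_length <- function(residues, tree) {
  if (is.null(names(residues))) abort("`residues` must be named by taxon.")
  if (!all(tree$tip.label %in% names(residues))) {
    abort("Residues do not cover the tree's taxa.")
  }
  m <- matrix(residues[tree$tip.label], ncol = 1L,
              dimnames = list(tree$tip.label, NULL))
  fitch_counts(leaf_masks(m), tree)[1L]
}

#' Minimum length of a site over all topologies
#'
#' For unordered states this is the number of distinct canonical residues
#' minus one, independent of the tree.
#'
#' @param residues Character vector of residues.
#' @return Integer.
#' @export
min_length_any_tree <- function(residues) {
  max(0L, length(unique(residues[residues %in% AA_LETTERS])) - 1L)
}

#' Per-site homoplasy against a reference tree
#'
#' The homoplasy index of a site is 1 minus its consistency index, where
#' the consistency index is the minimum change count over all trees divided
#' by the change count on the reference tree. HI is 0 for sites fully
#' consistent with the tree; on a 5-taxon binary tree an informative
#' two-state site takes HI 0 (its split is in the tree) or 0.5 (it
#' conflicts). Constant sites are assigned HI 0.
#'
#' @param residues Named character vector of residues.
#' @param tree Reference unrooted binary `phylo`.
#' @return A list with `on_tree`, `min_any` and `hi`.
#' @export
homoplasy_index <- function(residues, tree) {
  on_tree <- fitch_length(residues, tree)
  min_any <- min_length_any_tree(residues)
  hi <- if (on_tree == 0L) 0 else 1 - min_any / on_tree
  list(on_tree = on_tree, min_any = min_any, hi = hi)
}

#' Homoplasy table for a whole alignment
#'
#' Vectorised [homoplasy_index()] over all columns.
#'
#' @param alignment An [aa_alignment()].
#' @param tree Reference tree covering the alignment's taxa.
#' @return Tibble: `site`, `on_tree`, `min_any`, `hi`.
#' @export
homoplasy_table <- function(alignment, tree) {
  stopifnot(inherits(alignment, "aa_alignment"))
  if (!all(tree$tip.label %in% alignment$taxa)) {
    abort("Tree taxa missing from the alignment.")
  }
  m <- as.matrix(alignment)[tree$tip.label, , drop = FALSE]
  patterns <- do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
  uniq <- unique(patterns)
  um <- do.call(cbind, lapply(uniq, function(p) strsplit(p, "")[[1L]]))
  rownames(um) <- tree$tip.label
  on_tree_u <- fitch_counts(leaf_masks(um), tree)
  min_any_u <- apply(um, 2L, min_length_any_tree)
  idx <- match(patterns, uniq)
  on_tree <- on_tree_u[idx]
  min_any <- min_any_u[idx]
  tibble(site = seq_along(patterns),
         on_tree = as.integer(on_tree),
         min_any = as.integer(min_any),
         hi = ifelse(on_tree == 0L, 0, 1 - min_any / on_tree))
}

# --- exhaustive topology enumeration and search ---------------------------

#' Enumerate all unrooted binary topologies
#'
#' Built by stepwise addition: each new taxon is attached to every edge of
#' every smaller tree, giving the full (2n-5)!! set without duplicates.
#' Guarded to 4..8 taxa.
#'
#' @param taxa Character vector of 4 to 8 unique labels.
#' @return A list of unrooted binary `phylo` objects.
#' @examples
#' length(enumerate_unrooted_trees(letters[1:5]))  # 15
#' @export
enumerate_unrooted_trees <- function(taxa) {
  n <- length(taxa)
  if (n < 4L || n > 8L) abort("Enumeration is supported for 4 to 8 taxa.")
  if (anyDuplicated(taxa)) abort("Taxon labels must be unique.")
  # internal representation: edge list over nodes; tips 1..k carry labels
  trees <- list(list(edges = rbind(c(4L, 1L), c(4L, 2L), c(4L, 3L)),
                     n_nodes = 4L))
  for (k in 4:n) {
    trees <- purrr::list_flatten(purrr::map(trees, function(tr) {
      purrr::map(seq_len(nrow(tr$edges)), function(e) {
        w <- tr$n_nodes + 1L   # new internal node
        z <- tr$n_nodes + 2L   # new tip (relabelled below)
        edges <- tr$edges
        u <- edges[e, 1L]; v <- edges[e, 2L]
        edges <- edges[-e, , drop = FALSE]
        edges <- rbind(edges, c(u, w), c(w, v), c(w, z))
        list(edges = edges, n_nodes = z, new_tip = z, tip_index = k)
      })
    }))
  }
  purrr::map(trees, function(tr) topo_to_phylo(tr, taxa, n))
}

# Convert the internal edge-list representation into a phylo via Newick.
# Tips, in order of addition, are nodes 1,2,3 then the even offsets added
# at each step; we re-derive tip nodes as those of degree 1.
topo_to_phylo <- function(tr, taxa, n) {
  edges <- tr$edges
  nodes <- sort(unique(as.vector(edges)))
  deg <- table(factor(as.vector(edges), levels = nodes))
  tip_nodes <- nodes[deg == 1L]
  # tips were created in order: 1, 2, 3, then one per addition step
  tip_order <- tip_nodes[order(tip_nodes)]
  labels <- stats::setNames(taxa[seq_along(tip_order)], tip_order)
  adj <- split(c(edges[, 2L], edges[, 1L]), c(edges[, 1L], edges[, 2L]))
  root <- nodes[deg > 1L][1L]
  nwk <- function(node, parent) {
    kids <- setdiff(adj[[as.character(node)]], parent)
    if (!length(kids)) return(labels[[as.character(node)]])
    paste0("(", paste(vapply(kids, nwk, "", parent = node), collapse = ","),
           ")")
  }
  ape::read.tree(text = paste0(nwk(root, NA), ";"))
}

# Unique site patterns and weights for an alignment (taxa in tree order).
site_patterns <- function(alignment, taxa) {
  m <- as.matrix(alignment)[taxa, , drop = FALSE]
  patterns <- if (ncol(m)) do.call(paste0,
                                   lapply(seq_len(nrow(m)), function(i) m[i, ]))
              else character(0)
  uniq <- unique(patterns)
  um <- if (length(uniq)) {
    mm <- do.call(cbind, lapply(uniq, function(p) strsplit(p, "")[[1L]]))
    rownames(mm) <- taxa
    mm
  } else matrix(character(0), length(taxa), 0L, dimnames = list(taxa, NULL))
  list(masks = leaf_masks(um),
       weights = as.integer(table(factor(patterns, levels = uniq))),
       index = match(patterns, uniq))
}

#' Exhaustive parsimony tree search
#'
#' Scores every unrooted binary topology over the alignment's taxa by total
#' Fitch length and returns all co-optimal trees. Limited to at most 8 taxa.
#'
#' @param alignment An [aa_alignment()].
#' @return A list with `trees` (all minimum-length topologies), `score`
#'   (total tree length), `n_searched`.
#' @export
parsimony_search <- function(alignment) {
  stopifnot(inherits(alignment, "aa_alignment"))
  taxa <- alignment$taxa
  trees <- enumerate_unrooted_trees(taxa)
  sp <- site_patterns(alignment, taxa)
  scores <- vapply(trees, function(tr) {
    sum(fitch_counts(sp$masks, tr) * sp$weights)
  }, 0)
  best <- which(scores == min(scores))
  list(trees = trees[best], score = as.integer(min(scores)),
       n_searched = length(trees))
}

#' Bootstrap support for a reference tree's bipartitions
#'
#' Resamples alignment columns with replacement, reruns the exhaustive
#' parsimony search on each replicate, and reports for each nontrivial
#' bipartition of the reference tree the percentage of replicates that
#' recover it. With `semantics = "strict"` a replicate counts only if the
#' split is present in every co-optimal tree; `"any"` credits presence in
#' at least one.
#'
#' @param alignment An [aa_alignment()].
#' @param reference_tree Unrooted binary `phylo` over the same taxa.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed; identical seeds give identical support.
#' @param semantics `"strict"` or `"any"`.
#' @return Tibble: `bipartition`, `support` (percentage).
#' @export
bootstrap_support <- function(alignment, reference_tree, replicates = 100,
                              seed = 1L, semantics = c("strict", "any")) {
  semantics <- match.arg(semantics)
  stopifnot(replicates >= 1)
  taxa <- alignment$taxa
  if (!setequal(taxa, reference_tree$tip.label)) {
    abort("Reference tree and alignment taxa differ.")
  }
  trees <- enumerate_unrooted_trees(taxa)
  sp <- site_patterns(alignment, taxa)
  # per-tree, per-pattern Fitch lengths computed once
  L <- do.call(rbind, purrr::map(trees, function(tr) fitch_counts(sp$masks, tr)))
  splits_per_tree <- purrr::map(trees, function(tr) tree_bipartitions(tr)$bipartition)
  ref_splits <- tree_bipartitions(reference_tree)$bipartition
  n_sites <- alignment$n_sites
  hits <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      draw <- sample.int(n_sites, n_sites, replace = TRUE)
      w <- tabulate(sp$index[draw], nbins = length(sp$weights))
      scores <- as.vector(L %*% w)
      best <- which(scores == min(scores))
      present <- if (semantics == "strict") {
        Reduce(intersect, splits_per_tree[best])
      } else {
        unique(unlist(splits_per_tree[best]))
      }
      hits[ref_splits %in% present] <- hits[ref_splits %in% present] + 1
    }
  })
  tibble(bipartition = ref_splits, support = 100 * hits / replicates)
}

#' Bipartition support table for a site class
#'
#' Counts, for every bipartition observed among the classified sites of one
#' class, how many sites support it — the machine form of a per-class
#' support table. With a reference tree, each bipartition is flagged as
#' present in (`TRUE`) or conflicting with (`FALSE`) the tree.
#'
#' @param sites An `rgc_scan` tibble from [scan_alignment()] (or any tibble
#'   with `site_class` and `bipartition` columns).
#' @param site_class Which class to tabulate.
#' @param reference_tree Optional `phylo` used to flag tree support.
#' @param taxa Taxon set; defaults to the scan's `taxa` attribute.
#' @return A tibble of class `support_table`: `bipartition`, `n`, `pct`
#'   (of the class total), and `in_tree` when a reference tree is given;
#'   sorted by decreasing count. The class total is attached as attribute
#'   `total`.
#' @export
support_table <- function(sites, site_class = "RGC_CAM",
                          reference_tree = NULL, taxa = NULL) {
  if (is.null(taxa)) taxa <- attr(sites, "taxa")
  rows <- sites[sites$site_class == site_class & !is.na(sites$bipartition), ]
  tab <- dplyr::count(rows, .data$bipartition, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$bipartition)
  total <- sum(tab$n)
  tab$pct <- if (total) 100 * tab$n / total else numeric(nrow(tab))
  if (!is.null(reference_tree)) {
    ref <- tree_bipartitions(reference_tree)$bipartition
    tab$in_tree <- tab$bipartition %in% ref
  }
  attr(tab, "total") <- total
  attr(tab, "taxa") <- taxa
  class(tab) <- c("support_table", class(tab))
  tab
}
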