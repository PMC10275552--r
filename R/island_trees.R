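# Newick-facing utilities: extracting island clades (stem/crown ages) from a
# dated tree, attaching missing species, and building a synthetic tree from a
# dataset (used for round-trip testing and for exporting fixtures).

node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

check_ultrametric <- function(tree, tol = 1e-6) {
  ages <- node_ages(tree)
  height <- max(ages)
  tip_ages <- ages[seq_len(ape::Ntip(tree))]
  if (any(abs(tip_ages) > tol * height)) {
    stop("tree is not ultrametric within tolerance (relative ", tol, ")")
  }
  invisible(ages)
}

#' Extract island clades from a dated phylogeny
#'
#' Partitions the island-endemic tips of an ultrametric tree into maximal
#' monophyletic island clades and reads off, for each, the colonization age
#' (stem age: the age of the node where the island lineage diverges from its
#' non-island sister) and the branching ages (ages of the internal nodes
#' within the clade, descending).
#'
#' @param tree An `ape::phylo` object or a Newick string.
#' @param island_tips Character vector of tip labels occurring on the island.
#' @param island_age Island age for the returned dataset; defaults to the
#'   root age of the tree.
#' @param M Mainland pool size recorded in the returned dataset.
#' @param singleton_status Status assigned to single-tip island clades (tree
#'   topology cannot distinguish non-endemic from anagenetic singletons).
#' @param tol Relative ultrametricity tolerance; tip ages below `tol` times
#'   the tree height are snapped to zero.
#' @return An [island_dataset()]; clades are named after their first tip and
#'   given mainland identifiers in colonization-age order.
#' @examples
#' ds <- extract_island_clades("((A:1,B:1):1,C:2);", c("A", "B"))
#' ds$clades[[1]]$colonization_age # 2: the stem age of (A,B)
#' @export
extract_island_clades <- function(tree, island_tips, island_age = NULL,
                                  M = 1000L,
                                  singleton_status = "non_endemic_singleton",
                                  tol = 1e-6) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  ages <- check_ultrametric(tree, tol)
  ntip <- ape::Ntip(tree)
  labels <- tree$tip.label
  miss <- setdiff(island_tips, labels)
  if (length(miss)) stop("island tips not in tree: ", paste(miss, collapse = ", "))
  if (all(labels %in% island_tips)) {
    stop("all tips are island tips: no non-island sister to anchor a stem age")
  }
  is_island_tip <- labels %in% island_tips

  # tips under each node
  nnode <- ntip + tree$Nnode
  tipsets <- vector("list", nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  for (ei in ape::postorder(tree)) { # children are visited before parents
    par <- tree$edge[ei, 1L]; chi <- tree$edge[ei, 2L]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[chi]])
  }
  all_island <- vapply(tipsets, function(ts) all(is_island_tip[ts]), logical(1))
  parent_of <- integer(nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  root <- ntip + 1L

  maximal <- integer(0)
  for (nd in which(all_island)) {
    par <- parent_of[nd]
    if (nd != root && par > 0L && !all_island[par]) maximal <- c(maximal, nd)
  }
  covered <- sort(unique(unlist(tipsets[maximal])))
  if (!setequal(covered, which(is_island_tip))) {
    stop("island tips could not be separated into monophyletic clades with ",
         "non-island sisters")
  }

  recs <- list()
  for (nd in maximal) {
    tips <- tipsets[[nd]]
    stem_age <- ages[parent_of[nd]]
    if (nd > ntip) {
      desc_nodes <- descendant_internal_nodes(tree, nd, ntip)
      branch <- sort(ages[desc_nodes], decreasing = TRUE)
      status <- "endemic_clade"
    } else {
      branch <- numeric(0)
      status <- singleton_status
    }
    recs[[length(recs) + 1L]] <- clade_record(
      name = labels[tips[1L]], mainland_species_id = 1L, status = status,
      colonization_age = stem_age, branching_ages = branch)
  }
  ord <- order(-vapply(recs, `[[`, numeric(1), "colonization_age"))
  recs <- recs[ord]
  for (i in seq_along(recs)) recs[[i]]$mainland_species_id <- i
  if (is.null(island_age)) island_age <- max(ages) * (1 + 1e-8)
  island_dataset(island_age, M, recs, validate = FALSE)
}

descendant_internal_nodes <- function(tree, node, ntip) {
  out <- node
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  for (k in kids) {
    if (k > ntip) out <- c(out, descendant_internal_nodes(tree, k, ntip))
  }
  out
}

#' Insert missing species into an ultrametric tree
#'
#' Grafts one extant (age-zero) tip per assignment onto the tree, repeated
#' `n_replicates` times with independent random placements. Two insertion
#' modes mirror the two kinds of taxonomic evidence for a missing species:
#' `"tip_branch"` attaches the new tip at a uniformly drawn height along the
#' anchor tip's terminal branch (for species formerly treated as a
#' subspecies of the anchor); `"within_clade"` attaches it at a point drawn
#' uniformly over the summed branch length of the anchor clade's crown
#' subtree (for species assigned to a clade on morphology). The attachment
#' height is the age of the chosen point, so the output stays ultrametric.
#'
#' @param tree An `ape::phylo` object or Newick string (ultrametric).
#' @param assignments A list; each element is a list with `species` (new tip
#'   label), `mode` (`"tip_branch"` or `"within_clade"`) and `anchor`
#'   (a single tip label, or a character vector of tips whose MRCA defines
#'   the clade).
#' @param n_replicates Number of independently randomized output trees.
#' @param seed Optional seed.
#' @return A list of `n_replicates` `phylo` objects, each with
#'   `length(assignments)` more tips than the input.
#' @export
insert_missing_species <- function(tree, assignments, n_replicates = 1L,
                                   seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"))
  check_ultrametric(tree)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_replicates), function(r) {
    tr <- tree
    for (a in assignments) {
      tr <- insert_one_species(tr, a)
    }
    tr
  })
}

insert_one_species <- function(tree, a) {
  mode <- match.arg(a$mode, c("tip_branch", "within_clade"))
  miss <- setdiff(a$anchor, tree$tip.label)
  if (length(miss)) stop("anchor tip(s) not found: ", paste(miss, collapse = ", "))
  ages <- node_ages(tree)
  if (mode == "tip_branch") {
    if (length(a$anchor) != 1L) stop("tip_branch mode needs a single anchor tip")
    tip <- match(a$anchor, tree$tip.label)
    parent <- tree$edge[tree$edge[, 2L] == tip, 1L]
    h <- stats::runif(1L, 0, ages[parent])
    attach_at(tree, node = tip, height = h, label = a$species, ages = ages)
  } else {
    tips <- match(a$anchor, tree$tip.label)
    mrca <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    sub_nodes <- subtree_nodes(tree, mrca)
    edges <- which(tree$edge[, 1L] %in% sub_nodes | tree$edge[, 2L] %in% sub_nodes)
    edges <- edges[tree$edge[edges, 1L] %in% sub_nodes] # crown subtree only
    if (!length(edges)) stop("empty subtree for anchor clade")
    len <- tree$edge.length[edges]
    e <- edges[sample.int(length(edges), 1L, prob = len)]
    pos <- stats::runif(1L, 0, tree$edge.length[e])
    child <- tree$edge[e, 2L]
    h <- ages[child] + pos # age of the chosen point along the edge
    attach_at(tree, node = child, height = h, label = a$species, ages = ages)
  }
}

subtree_nodes <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  out <- node
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  for (k in kids) out <- c(out, subtree_nodes(tree, k))
  out
}

# Attach a new extant tip to the edge above `node`, at the given age.
attach_at <- function(tree, node, height, label, ages) {
  position <- height - ages[node] # distance above the child end of the edge
  phytools::bind.tip(tree, label, edge.length = height, where = node,
                     position = position)
}

#' Build a synthetic tree from an island dataset
#'
#' Constructs an ultrametric Newick tree whose island clades reproduce the
#' dataset's colonization (stem) and branching ages exactly: each clade is
#' rendered as a caterpillar subtree of tips `"<clade>_s<i>"`, attached at
#' its stem age to a mainland sister tip `"mainland_<clade>"`, and the
#' clade-mainland pairs are chained on a backbone above the oldest
#' colonization. The within-clade topology is arbitrary (the data do not
#' record it); only the ages matter. An outgroup tip `"outgroup"` roots the
#' tree.
#'
#' @param ds A valid [island_dataset()].
#' @return An `ape::phylo` object; the island tips are
#'   `unlist(lapply(ds$clades, ...))` labelled by clade.
#' @seealso [extract_island_clades()] -- the inverse operation on the island
#'   part.
#' @export
dataset_to_tree <- function(ds) {
  stop_if_invalid(ds)
  if (!length(ds$clades)) stop("dataset has no clades; nothing to build")
  pair_newick <- function(cl) {
    m <- clade_size(cl)
    tips <- sprintf("%s_s%d", cl$name, seq_len(m))
    if (m == 1L) {
      sub <- tips[1L]
      sub_age <- 0
    } else {
      b <- cl$branching_ages
      sub <- tips[m]
      sub_age <- 0
      for (i in rev(seq_len(m - 1L))) {
        sub <- sprintf("(%s:%.12g,%s:%.12g)", tips[i], b[i], sub, b[i] - sub_age)
        sub_age <- b[i]
      }
    }
    a <- cl$colonization_age
    list(str = sprintf("(%s:%.12g,mainland_%s:%.12g)", sub, a - sub_age,
                       cl$name, a),
         age = a)
  }
  pairs <- lapply(ds$clades, pair_newick)
  ord <- order(vapply(pairs, `[[`, numeric(1), "age"))
  pairs <- pairs[ord]
  cur <- pairs[[1L]]
  step <- (ds$island_age - max(vapply(pairs, `[[`, numeric(1), "age"))) /
    (length(pairs) + 1L)
  for (i in seq_along(pairs)[-1L]) {
    new_age <- max(cur$age, pairs[[i]]$age) + step
    cur <- list(str = sprintf("(%s:%.12g,%s:%.12g)", cur$str, new_age - cur$age,
                              pairs[[i]]$str, new_age - pairs[[i]]$age),
                age = new_age)
  }
  root_age <- ds$island_age
  nwk <- sprintf("(%s:%.12g,outgroup:%.12g);", cur$str, root_age - cur$age,
                 root_age)
  ape::read.tree(text = nwk)
}

#' Island tip labels of a synthetic dataset tree
#'
#' @param ds The dataset a tree was built from with [dataset_to_tree()].
#' @return Character vector of the island tip labels.
#' @export
island_tip_labels <- function(ds) {
  unlist(lapply(ds$clades, function(cl)
    sprintf("%s_s%d", cl$name, seq_len(clade_size(cl)))))
}
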