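# Tree-side bookkeeping for externally inferred trees: rooting on the edge
# separating two named leaf sets, subtree-vs-cluster concordance, and iTOL
# annotation export.

#' Root a tree on the edge separating two leaf sets
#'
#' The two sets must be disjoint, jointly cover all leaves, and be
#' separated by a single edge of the unrooted topology. The root is placed
#' on that edge, at its midpoint when branch lengths are present.
#'
#' @param tree an `ape::phylo` tree (rooted or unrooted).
#' @param cladeA,cladeB character vectors of leaf names.
#' @return rooted `phylo` whose two root children have exactly the leaf
#'   sets `cladeA` and `cladeB`.
#' @export
root_between <- function(tree, cladeA, cladeB) {
  tips <- tree$tip.label
  if (length(intersect(cladeA, cladeB)) > 0L)
    stop_input("cladeA and cladeB overlap: ",
               paste(intersect(cladeA, cladeB), collapse = ", "))
  if (!setequal(union(cladeA, cladeB), tips)) {
    orphan <- setdiff(tips, union(cladeA, cladeB))
    stop_input("leaf sets must cover all leaves; uncovered: ",
               paste(orphan, collapse = ", "))
  }
  if (length(cladeA) == 0L || length(cladeB) == 0L)
    stop_input("both leaf sets must be non-empty")
  # anchor the root inside cladeA, then cladeB must appear as one clade
  anchor <- cladeA[1]
  t2 <- ape::root(ape::unroot(tree), outgroup = anchor, resolve.root = TRUE)
  node_b <- if (length(cladeB) == 1L) {
    match(cladeB, t2$tip.label)
  } else {
    ape::getMRCA(t2, cladeB)
  }
  desc <- tips_under(t2, node_b)
  if (!setequal(desc, cladeB)) {
    stop_input("no single edge separates the two sets; offending leaves: ",
               paste(setdiff(desc, cladeB), collapse = ", "))
  }
  has_bl <- !is.null(t2$edge.length)
  if (has_bl) {
    eidx <- which(t2$edge[, 2] == node_b)
    out <- phytools::reroot(t2, node_b,
                            position = t2$edge.length[eidx] / 2)
  } else {
    out <- ape::root(t2, node = node_b, resolve.root = TRUE)
    if (length(cladeB) == 1L)
      out <- ape::root(ape::unroot(tree), outgroup = cladeB,
                       resolve.root = TRUE)
  }
  out
}

# tip labels under a node of a rooted phylo (the node itself if a tip)
tips_under <- function(phy, node) {
  n_tip <- length(phy$tip.label)
  if (node <= n_tip) return(phy$tip.label[node])
  sets <- clade_tip_sets(phy)
  phy$tip.label[sets[[node]]]
}

# list: for every node (tips + internals), the tip indices below it
clade_tip_sets <- function(phy) {
  n_tip <- length(phy$tip.label)
  sets <- vector("list", n_tip + phy$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; ch <- po$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

#' Concordance between tree subtrees and class labels
#'
#' For each class, tests monophyly against the rooted topology and computes
#' the minimal number of leaves whose removal makes the class monophyletic
#' (exact: the minimum over all clades v of the intruders inside v plus
#' the class members outside v). The overall concordant-leaf fraction is
#' 1 - (sum of removal counts) / (number of leaves).
#'
#' @param tree rooted `ape::phylo`.
#' @param labels named character vector mapping every leaf to a class.
#' @return object of class `concordance_report`: list with `per_class`
#'   data.frame (`class`, `n_leaves`, `is_monophyletic`, `n_removals`) and
#'   `fraction_concordant`.
#' @export
class_concordance <- function(tree, labels) {
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    miss <- setdiff(tips, names(labels))
    stop_input("unlabeled leaves: ", paste(miss, collapse = ", "))
  }
  lab <- labels[tips]
  sets <- clade_tip_sets(tree)
  n_tip <- length(tips)
  classes <- sort(unique(unname(lab)))
  rows <- lapply(classes, function(cl) {
    members <- which(lab == cl)
    best <- length(members)  # worst case: shrink the class to nothing
    for (s in sets) {
      cost <- length(setdiff(s, members)) + length(setdiff(members, s))
      if (cost < best) best <- cost
    }
    data.frame(class = cl, n_leaves = length(members),
               is_monophyletic = best == 0L, n_removals = best,
               stringsAsFactors = FALSE)
  })
  per_class <- do.call(rbind, rows)
  structure(list(per_class = per_class,
                 fraction_concordant = 1 - sum(per_class$n_removals) / n_tip),
            class = "concordance_report")
}

#' @method print concordance_report
#' @export
print.concordance_report <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("fraction of concordant leaves: %.3f\n",
              x$fraction_concordant))
  invisible(x)
}

ITOL_PALETTE <- c("#1f78b4", "#33a02c", "#e31a1c", "#ff7f00", "#6a3d9a",
                  "#b15928", "#a6cee3", "#b2df8a", "#fb9a99", "#fdbf6f",
                  "#cab2d6", "#999999")

#' Export iTOL color-strip and domain annotations for a labeled tree
#'
#' Writes a color-strip dataset per label map (e.g. one ring for taxa, one
#' for cluster classes) and, when architecture calls are supplied, a
#' DATASET_DOMAINS file sketching each protein's domain string. Colors are
#' assigned to labels alphabetically from a fixed palette.
#'
#' @param labels named character vector (leaf id -> class label).
#' @param path output file.
#' @param dataset_label name shown in iTOL.
#' @param tree_ids optional leaf ids to check against; ids in `labels`
#'   missing from `tree_ids` trigger a warning listing the orphans.
#' @return the path, invisibly.
#' @export
export_itol_colorstrip <- function(labels, path,
                                   dataset_label = "classes",
                                   tree_ids = NULL) {
  if (!is.null(tree_ids)) {
    orphans <- setdiff(names(labels), tree_ids)
    if (length(orphans) > 0L)
      warning("labels not on the tree: ", paste(orphans, collapse = ", "))
  }
  lv <- sort(unique(unname(labels)))
  cols <- setNames(rep(ITOL_PALETTE, length.out = length(lv)), lv)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DATASET_COLORSTRIP", "SEPARATOR TAB",
               paste0("DATASET_LABEL\t", dataset_label),
               "COLOR\t#000000",
               paste0("LEGEND_TITLE\t", dataset_label),
               paste0("LEGEND_LABELS\t", paste(lv, collapse = "\t")),
               paste0("LEGEND_COLORS\t", paste(cols, collapse = "\t")),
               "DATA"), con)
  ids <- sort(names(labels))
  writeLines(paste(ids, cols[labels[ids]], labels[ids], sep = "\t"), con)
  invisible(path)
}

#' Read back the label map from an iTOL color-strip file
#' @param path file written by [export_itol_colorstrip()].
#' @return named character vector (leaf id -> label).
#' @export
read_itol_colorstrip <- function(path) {
  lines <- readLines(path)
  start <- match("DATA", lines)
  if (is.na(start) || start >= length(lines))
    return(setNames(character(0), character(0)))
  body <- lines[seq.int(start + 1L, length(lines))]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    return(setNames(character(0), character(0)))
  parts <- strsplit(body, "\t", fixed = TRUE)
  setNames(vapply(parts, `[`, character(1), 3L),
           vapply(parts, `[`, character(1), 1L))
}
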