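#' Agglomerative clustering of a distance matrix into a rooted tree
#'
#' Estimates a rooted ultrametric tree of historical relations from a
#' distance matrix by iteratively merging the pair of clusters with the
#' smallest average inter-cluster distance (UPGMA; single and complete
#' linkage are available behind the `linkage` flag). The merge height of
#' each internal node is half the inter-cluster distance at which it was
#' formed, so leaf-to-leaf path distances in the tree equal the cluster
#' distances. Heights are non-decreasing toward the root.
#'
#' Ties on the minimal distance are broken deterministically: among tied
#' cluster pairs, the pair whose (sorted) smallest member labels are
#' lexicographically least is merged first.
#'
#' @param d distance matrix (see [validate_dist_matrix]), n >= 2 labels.
#' @param linkage `"average"` (UPGMA, default), `"single"` or
#'   `"complete"`.
#' @return an object of class `cluster_tree`: a rooted binary tree stored
#'   as an hclust-style merge matrix with per-merge heights and the leaf
#'   labels.
#' @examples
#' d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
#'             dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
#' t <- upgma(d)
#' to_newick(t)
#' @export
upgma <- function(d, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  d <- validate_dist_matrix(d)
  n <- nrow(d)
  stopifnot(n >= 2L)
  labels <- rownames(d)
  # active clusters: node id (<0 leaf, >0 merge), size, smallest label
  id <- -seq_len(n)
  size <- rep(1L, n)
  key <- labels
  cur <- unname(d)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    m <- length(id)
    best <- NULL
    bestd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      dij <- cur[i, j]
      if (dij < bestd - 1e-15) {
        bestd <- dij; best <- c(i, j)
      } else if (abs(dij - bestd) <= 1e-15) {
        # tie: lexicographically smallest (sorted) label pair wins
        kn <- sort(c(key[i], key[j])); kb <- sort(key[best])
        if (kn[1] < kb[1] || (kn[1] == kb[1] && kn[2] < kb[2])) {
          bestd <- dij; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- bestd / 2
    others <- setdiff(seq_len(m), c(i, j))
    newd <- switch(linkage,
      average  = (size[i] * cur[i, others] + size[j] * cur[j, others]) /
                 (size[i] + size[j]),
      single   = pmin(cur[i, others], cur[j, others]),
      complete = pmax(cur[i, others], cur[j, others]))
    cur <- rbind(cbind(cur[others, others, drop = FALSE], newd),
                 c(newd, 0))
    id <- c(id[others], s)
    size <- c(size[others], size[i] + size[j])
    key <- c(key[others], min(key[i], key[j]))
  }
  structure(list(merge = merge, height = height, labels = labels,
                 linkage = linkage),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("<cluster_tree>", length(x$labels), "leaves,", x$linkage,
      "linkage, root height", format(max(x$height)), "\n")
  invisible(x)
}

# leaf index sets of each merge node, in merge order
merge_members <- function(t) {
  members <- vector("list", nrow(t$merge))
  for (s in seq_len(nrow(t$merge))) {
    members[[s]] <- unlist(lapply(t$merge[s, ], function(ch)
      if (ch < 0) -ch else members[[ch]]))
  }
  members
}

#' Cut a cluster tree into its top branches
#'
#' Removes the k-1 highest merges — cutting the tree just below the root
#' and its k-2 next-highest nodes — and returns the k resulting leaf sets,
#' the "top k branches" of the tree. Because merge heights are
#' non-decreasing, this equals undoing the last k-1 merges.
#'
#' @param t a `cluster_tree`.
#' @param k number of branches, between 1 and the number of leaves.
#' @return named list of k character vectors (leaf labels per branch),
#'   ordered by first leaf appearance in the label order.
#' @export
top_branches <- function(t, k) {
  stopifnot(inherits(t, "cluster_tree"))
  n <- length(t$labels)
  if (!(k >= 1 && k <= n)) stop("k must be in 1..", n, " (got ", k, ")")
  cl <- -seq_len(n)  # cluster id per leaf; apply first n-k merges
  nm <- nrow(t$merge)
  for (s in seq_len(nm - (k - 1L))) {
    for (ch in t$merge[s, ]) cl[cl == ch] <- s
  }
  parts <- unname(split(t$labels, factor(cl, unique(cl))))
  names(parts) <- paste0("branch", seq_along(parts))
  parts
}

#' Write branch (cluster) assignments as a two-column TSV
#' @param parts list of leaf sets, as returned by [top_branches].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_branches <- function(parts, path) {
  df <- data.frame(leaf = unlist(parts, use.names = FALSE),
                   branch = rep(names(parts), lengths(parts)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

newick_quote <- function(x) {
  needs <- grepl("[][(){},;:'\" \t]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a cluster tree to Newick
#'
#' Branch lengths, when requested, are parent height minus child height
#' (leaves sit at height 0), so the serialized tree is ultrametric and
#' parsing it back reconstructs topology and merge heights. Labels
#' containing Newick metacharacters are single-quoted per the standard.
#'
#' @param t a `cluster_tree`.
#' @param with_lengths include branch lengths (default `TRUE`).
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `;`.
#' @export
to_newick <- function(t, with_lengths = TRUE, digits = 10) {
  stopifnot(inherits(t, "cluster_tree"))
  node_str <- function(ch, parent_h) {
    if (ch < 0) {
      lab <- newick_quote(t$labels[-ch])
      h <- 0
    } else {
      lab <- paste0("(", node_str(t$merge[ch, 1], t$height[ch]), ",",
                    node_str(t$merge[ch, 2], t$height[ch]), ")")
      h <- t$height[ch]
    }
    if (with_lengths && !is.na(parent_h))
      paste0(lab, ":", format(parent_h - h, digits = digits,
                              scientific = FALSE, trim = TRUE))
    else lab
  }
  root <- nrow(t$merge)
  if (root == 0L) stop("tree has no merges")  # unreachable for n >= 2
  paste0("(", node_str(t$merge[root, 1], if (with_lengths) t$height[root]
                       else NA),
         ",", node_str(t$merge[root, 2], if (with_lengths) t$height[root]
                       else NA), ");")
}

#' Convert a cluster tree to an ape "phylo" object
#'
#' Convenience bridge to the wider phylogenetics ecosystem (plotting,
#' Robinson–Foulds comparison, ...). The conversion goes through Newick.
#'
#' @param t a `cluster_tree`.
#' @return an [ape::read.tree] phylo object.
#' @export
as_phylo <- function(t) {
  ape::read.tree(text = to_newick(t, with_lengths = TRUE, digits = 15))
}

#' Leaf-to-leaf path distances implied by a cluster tree
#'
#' For an ultrametric tree the path distance between two leaves is twice
#' the height of their lowest common ancestor; for ultrametric input
#' matrices UPGMA reproduces the input exactly.
#'
#' @param t a `cluster_tree`.
#' @return labeled symmetric matrix of cophenetic distances.
#' @export
tree_distances <- function(t) {
  stopifnot(inherits(t, "cluster_tree"))
  n <- length(t$labels)
  m <- matrix(0, n, n, dimnames = list(t$labels, t$labels))
  members <- merge_members(t)
  # at each merge, pairs straddling the two children meet their LCA
  for (s in seq_len(nrow(t$merge))) {
    side <- lapply(t$merge[s, ], function(ch)
      if (ch < 0) -ch else members[[ch]])
    for (i in side[[1]]) for (j in side[[2]]) {
      m[i, j] <- m[j, i] <- 2 * t$height[s]
    }
  }
  m
}
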