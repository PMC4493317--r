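#' Aggregate a variety-level distance matrix to group (province) level
#'
#' The distance between two groups is the arithmetic mean of the
#' variety-level distances over all cross-group pairs (one variety from
#' each group); within-group pairs never enter a between-group average.
#' Groups are ordered by first appearance among the matrix labels. Entries
#' of the group map that name varieties absent from the matrix are ignored;
#' a matrix variety missing from the map is an error.
#'
#' @param d variety-level distance matrix (see [validate_dist_matrix]).
#' @param group_map named character vector, variety id -> group id.
#' @return group-level distance matrix with zero diagonal.
#' @export
group_distance_matrix <- function(d, group_map) {
  d <- validate_dist_matrix(d, "variety distance matrix")
  v <- rownames(d)
  unmapped <- setdiff(v, names(group_map))
  if (length(unmapped))
    stop("variety(ies) missing from the group map: ",
         paste(unmapped, collapse = ", "))
  g <- unname(group_map[v])
  dropped <- setdiff(unique(unname(group_map)), g)
  if (length(dropped))
    warning("group(s) with no varieties in the matrix dropped: ",
            paste(dropped, collapse = ", "))
  groups <- unique(g)
  if (length(groups) < 2L)
    stop("need at least 2 groups after mapping; got ", length(groups))
  k <- length(groups)
  out <- matrix(0, k, k, dimnames = list(groups, groups))
  idx <- split(seq_along(v), factor(g, groups))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    out[i, j] <- out[j, i] <- mean(d[idx[[i]], idx[[j]]])
  }
  out
}

#' Trait-difference matrix between groups
#'
#' Entry (P, Q) is the absolute difference `|t_P - t_Q|` of the trait
#' values — e.g. how much two provinces differ in their proportion of rice
#' growing. Since traits lie in \[0, 1\], so do the entries.
#'
#' @param traits named numeric vector in \[0, 1\] (group -> trait value).
#' @param groups character vector of group ids to include, in order;
#'   defaults to all groups of `traits`.
#' @return symmetric matrix with zero diagonal, labeled by group.
#' @export
trait_difference_matrix <- function(traits, groups = names(traits)) {
  traits <- validate_trait_table(traits)
  miss <- setdiff(groups, names(traits))
  if (length(miss))
    stop("no trait value for group(s): ", paste(miss, collapse = ", "))
  x <- traits[groups]
  m <- abs(outer(unname(x), unname(x), "-"))
  dimnames(m) <- list(groups, groups)
  m
}

#' Restrict two distance matrices to their shared labels
#'
#' Both matrices are reduced to the intersection of their label sets, in
#' the order the labels appear in the first matrix — complete-case
#' analysis, mirroring an analysis restricted to provinces with both
#' lexical and trait data. Dropped labels are reported via `message()`.
#'
#' @param a,b labeled distance matrices.
#' @return list with elements `a` and `b`, both over the shared labels, and
#'   `dropped`, the labels removed from either input.
#' @export
align_matrices <- function(a, b) {
  a <- validate_dist_matrix(a, "matrix 'a'")
  b <- validate_dist_matrix(b, "matrix 'b'")
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3L)
    stop("matrices share only ", length(shared),
         " label(s); at least 3 are needed for a Mantel test")
  dropped <- setdiff(union(rownames(a), rownames(b)), shared)
  if (length(dropped))
    message("align_matrices: dropped label(s) without complete data: ",
            paste(dropped, collapse = ", "))
  list(a = a[shared, shared, drop = FALSE],
       b = b[shared, shared, drop = FALSE],
       dropped = dropped)
}
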