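#' Correlation between two distance matrices
#'
#' Pearson (default) or Spearman correlation over the n(n-1)/2
#' strictly-upper-triangle entries of two identically labeled matrices.
#' This is the observed statistic of the Mantel test.
#'
#' @param a,b distance matrices with identical labels in identical order.
#' @param method `"pearson"` or `"spearman"`.
#' @return a single correlation in \[-1, 1\].
#' @export
matrix_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_mantel_inputs(a, b)
  ut <- upper.tri(a)
  av <- a[ut]; bv <- b[ut]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("matrix correlation undefined: constant off-diagonal entries")
  cor(av, bv, method = method)
}

check_mantel_inputs <- function(a, b) {
  a <- validate_dist_matrix(a, "matrix 'a'")
  b <- validate_dist_matrix(b, "matrix 'b'")
  if (!identical(rownames(a), rownames(b)))
    stop("matrices must carry identical labels in identical order; ",
         "see align_matrices()")
  if (nrow(a) < 3L)
    stop("Mantel statistics need at least 3 labels")
  invisible(NULL)
}

new_mantel_result <- function(r_obs, n_perm, tail, p_value, seed, n,
                              method, exact = FALSE) {
  structure(list(r_obs = r_obs, n_perm = n_perm, tail = tail,
                 p_value = p_value, seed = seed, n = n, method = method,
                 exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf(
    "Mantel test (%s, tail = %s): r = %.4f, p = %.4g (%s, n = %d labels)\n",
    x$method, x$tail, x$r_obs, x$p_value,
    if (x$exact) sprintf("exact, %d relabelings", x$n_perm)
    else sprintf("%d permutations", x$n_perm), x$n))
  invisible(x)
}

#' Permutation Mantel test
#'
#' Tests the association between two distance matrices against the null
#' distribution obtained by jointly permuting the rows and columns of the
#' second matrix. Permutations are drawn uniformly (with replacement over
#' the permutation group) and the p-value uses the add-one correction
#' `p = (1 + #extreme) / (1 + n_perm)`, which counts the identity
#' relabeling and guarantees p > 0.
#'
#' The default tail is `"greater"`: the usual hypothesis is a positive
#' association (groups closer in history are also closer in the trait).
#'
#' @inheritParams matrix_correlation
#' @param n_perm number of permutations (default 10000).
#' @param tail `"greater"`, `"less"` or `"two_sided"`.
#' @param seed integer seed making the permutation draw reproducible;
#'   `NULL` uses the current RNG state.
#' @return a `mantel_result` with fields `r_obs`, `n_perm`, `tail`,
#'   `p_value`, `seed`, `n` and `method`.
#' @examples
#' set.seed(7)
#' x <- random_distance_matrix(6); y <- random_distance_matrix(6)
#' mantel_test(x, y, n_perm = 999, seed = 1)
#' @export
mantel_test <- function(a, b, n_perm = 10000,
                        tail = c("greater", "less", "two_sided"),
                        seed = NULL, method = c("pearson", "spearman")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  stopifnot(n_perm >= 1)
  r_obs <- matrix_correlation(a, b, method)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  ut <- upper.tri(a)
  av <- a[ut]
  r_perm <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(av, b[p, p][ut], method = method)
  }, numeric(1))
  p <- (1 + count_extreme(r_perm, r_obs, tail)) / (1 + n_perm)
  new_mantel_result(r_obs, n_perm, tail, p, seed, n, method)
}

count_extreme <- function(r_perm, r_obs, tail) {
  eps <- 1e-12  # treat floating-point ties as ties
  switch(tail,
         greater   = sum(r_perm >= r_obs - eps),
         less      = sum(r_perm <= r_obs + eps),
         two_sided = sum(abs(r_perm) >= abs(r_obs) - eps))
}

#' Exact Mantel test by full enumeration
#'
#' Enumerates all n! joint row/column relabelings of the second matrix and
#' reports the exact permutation p-value, the fraction of relabelings at
#' least as extreme as the observed correlation. The identity permutation
#' is part of the enumeration, so no add-one correction is applied and
#' p >= 1/n!. Limited to n <= 8 labels (8! = 40320).
#'
#' @inheritParams mantel_test
#' @return a `mantel_result` with `n_perm = n!` and `exact = TRUE`.
#' @export
mantel_exact <- function(a, b, tail = c("greater", "less", "two_sided"),
                         method = c("pearson", "spearman")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  r_obs <- matrix_correlation(a, b, method)
  n <- nrow(a)
  if (n > 8L)
    stop("mantel_exact enumerates n! relabelings and refuses n > 8 ",
         "(got n = ", n, "); use mantel_test()")
  perms <- all_permutations(n)
  ut <- upper.tri(a)
  av <- a[ut]
  r_perm <- vapply(seq_len(nrow(perms)), function(i) {
    p <- perms[i, ]
    cor(av, b[p, p][ut], method = method)
  }, numeric(1))
  p <- count_extreme(r_perm, r_obs, tail) / nrow(perms)
  new_mantel_result(r_obs, nrow(perms), tail, p, seed = NULL, n, method,
                    exact = TRUE)
}

# All permutations of 1..n as rows of an n! x n matrix (recursive).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L), deparse.level = 0)
  }))
}

#' Random symmetric distance matrix (for null simulations)
#'
#' Off-diagonal entries are i.i.d. uniform(0, 1), symmetrized by copying
#' the upper triangle; diagonal zero. Used to study the Mantel test's
#' behavior under independence.
#'
#' @param n number of labels.
#' @param labels optional label vector (default `L1..Ln`).
#' @return an n x n distance matrix.
#' @export
random_distance_matrix <- function(n, labels = paste0("L", seq_len(n))) {
  stopifnot(n >= 2L, length(labels) == n)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
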