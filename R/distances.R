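#' Levenshtein edit distance between words
#'
#' Minimal number of single-symbol insertions, deletions and substitutions
#' transforming one word into the other. Words are compared at the level of
#' Unicode code points after NFC normalization; there is no segmentation
#' into multi-character sound symbols.
#'
#' @param a,b character vectors, recycled to a common length; the distance
#'   is computed elementwise.
#' @return non-negative integer vector of edit distances.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' levenshtein("", "abc")            # 3
#' @export
levenshtein <- function(a, b) {
  a <- stringi::stri_trans_nfc(as.character(a))
  b <- stringi::stri_trans_nfc(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n),
         function(i) as.integer(adist(a[i], b[i], useBytes = FALSE)),
         integer(1))
}

# Cross matrix of edit distances (rows = a, cols = b), NFC applied.
lev_matrix <- function(a, b) {
  adist(stringi::stri_trans_nfc(a), stringi::stri_trans_nfc(b),
        useBytes = FALSE)
}

# Cross matrix of LDN values.
ldn_matrix <- function(a, b) {
  a <- stringi::stri_trans_nfc(a); b <- stringi::stri_trans_nfc(b)
  if (any(!nzchar(a)) && any(!nzchar(b)))
    stop("LDN is undefined when both words are empty")
  adist(a, b, useBytes = FALSE) /
    outer(nchar(a, type = "chars"), nchar(b, type = "chars"), pmax)
}

#' Normalized Levenshtein distance (LDN)
#'
#' Edit distance divided by the length of the longer word — the maximum
#' number of edits that could be needed — so the result lies in \[0, 1\]
#' and similar words have a lower distance.
#'
#' @inheritParams levenshtein
#' @return numeric vector in \[0, 1\]. Undefined (error) when both words of
#'   a pair are empty.
#' @examples
#' ldn("kat", "hat")  # 1/3
#' ldn("ab", "cd")    # 1
#' @export
ldn <- function(a, b) {
  a <- stringi::stri_trans_nfc(as.character(a))
  b <- stringi::stri_trans_nfc(as.character(b))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(!nzchar(a) & !nzchar(b)))
    stop("LDN is undefined when both words are empty")
  levenshtein(a, b) /
    pmax(nchar(a, type = "chars"), nchar(b, type = "chars"))
}

# Shared concepts of two wordlists, erroring when there are none.
shared_concepts <- function(w1, w2) {
  shared <- intersect(concepts(w1), concepts(w2))
  if (length(shared) == 0L)
    stop("no shared concepts between varieties '", w1$variety_id,
         "' and '", w2$variety_id, "'")
  shared
}

# LDN values between all forms of the shared concepts of two wordlists,
# plus the concept index of each row/column. One adist call per pair.
pair_ldn_tables <- function(w1, w2) {
  shared <- shared_concepts(w1, w2)
  f1 <- w1$forms[shared]; f2 <- w2$forms[shared]
  c1 <- rep(seq_along(shared), lengths(f1))
  c2 <- rep(seq_along(shared), lengths(f2))
  list(ldn = ldn_matrix(unlist(f1, use.names = FALSE),
                        unlist(f2, use.names = FALSE)),
       c1 = c1, c2 = c2, shared = shared)
}

#' Average lexical distance between two varieties (LDN)
#'
#' Mean over the concepts shared by both wordlists of the per-concept LDN.
#' When a concept has synonyms, the per-concept value is the minimum LDN
#' over all cross-variety form pairs for that concept, so synonyms never
#' inflate the distance.
#'
#' @param w1,w2 [wordlist] objects with at least one shared concept.
#' @return a single number in \[0, 1\].
#' @export
variety_ldn <- function(w1, w2) {
  mean(per_concept_ldn(pair_ldn_tables(w1, w2)))
}

# per-concept minimum LDN; rows/cols of tb$ldn are grouped by concept
per_concept_ldn <- function(tb) {
  if (length(tb$c1) == length(tb$shared) &&
      length(tb$c2) == length(tb$shared))
    return(diag(tb$ldn))  # single form per concept
  vapply(seq_along(tb$shared), function(k)
    min(tb$ldn[tb$c1 == k, tb$c2 == k, drop = FALSE]), numeric(1))
}

#' Doubly normalized lexical distance between two varieties (LDND)
#'
#' [variety_ldn] divided by the mean LDN over all cross-meaning form pairs
#' (every form of one variety for concept i against every form of the other
#' for concept j, i != j, both concepts shared). The cross-meaning mean
#' estimates how similar two unrelated words from these two sound
#' inventories look by chance, so the ratio corrects for accidental
#' similarity; it is computed per variety pair. Values can exceed 1.
#'
#' @inheritParams variety_ldn
#' @return a single non-negative number.
#' @export
ldnd <- function(w1, w2) {
  tb <- pair_ldn_tables(w1, w2)
  if (length(tb$shared) < 2L)
    stop("LDND needs at least 2 shared concepts (cross-meaning ",
         "normalizer) between '", w1$variety_id, "' and '",
         w2$variety_id, "'")
  # cross-meaning mean = (grand total - same-meaning total) / #cross pairs
  nsame <- sum(tabulate(tb$c1, length(tb$shared)) *
                 tabulate(tb$c2, length(tb$shared)))
  same_sum <- if (nsame == length(tb$shared)) sum(diag(tb$ldn))
  else sum(vapply(seq_along(tb$shared), function(k)
    sum(tb$ldn[tb$c1 == k, tb$c2 == k, drop = FALSE]), numeric(1)))
  denom <- (sum(tb$ldn) - same_sum) /
    (length(tb$c1) * length(tb$c2) - nsame)
  if (denom == 0)
    stop("degenerate LDND normalizer: all cross-meaning word pairs are ",
         "identical between '", w1$variety_id, "' and '",
         w2$variety_id, "'")
  mean(per_concept_ldn(tb)) / denom
}

#' Shared-cognate distance between two varieties
#'
#' Cognates are words related by descent, encoded as shared cognate-class
#' identifiers. Over the concepts shared by both wordlists, a concept
#' counts as shared-cognate when the two varieties' cognate-class sets for
#' it intersect (synonyms may carry several classes). The distance is one
#' minus the proportion of shared-cognate concepts: 0 = fully cognate,
#' 1 = no shared cognates.
#'
#' @inheritParams variety_ldn
#' @return a single number in \[0, 1\].
#' @export
cognate_distance <- function(w1, w2) {
  if (!has_cognates(w1) || !has_cognates(w2))
    stop("cognate distance needs cognate coding on both varieties ('",
         w1$variety_id, "', '", w2$variety_id, "')")
  shared <- shared_concepts(w1, w2)
  k1 <- w1$cognates[shared]; k2 <- w2$cognates[shared]
  hit <- if (all(lengths(k1) == 1L) && all(lengths(k2) == 1L))
    unlist(k1, use.names = FALSE) == unlist(k2, use.names = FALSE)
  else mapply(function(a, b) length(intersect(a, b)) > 0L, k1, k2)
  1 - sum(hit) / length(shared)
}

#' Pairwise variety distance matrix
#'
#' Applies one of the variety-level measures to every pair of wordlists.
#' Labels follow the input order, and permuting the input permutes rows and
#' columns identically. If any pair fails the measure's preconditions (no
#' shared concepts, missing cognate coding, degenerate LDND normalizer) all
#' failing pairs are reported in one aggregate error.
#'
#' @param wordlists list of two or more [wordlist] objects.
#' @param measure `"ldn"` ([variety_ldn]), `"ldnd"` ([ldnd]) or
#'   `"cognate"` ([cognate_distance]).
#' @return symmetric numeric matrix with zero diagonal, labeled by variety
#'   id.
#' @export
pairwise_matrix <- function(wordlists, measure = c("ldn", "ldnd", "cognate")) {
  measure <- match.arg(measure)
  stopifnot(length(wordlists) >= 2L)
  fun <- switch(measure, ldn = variety_ldn, ldnd = ldnd,
                cognate = cognate_distance)
  labels <- unname(vapply(wordlists, function(w) w$variety_id,
                          character(1)))
  if (anyDuplicated(labels))
    stop("duplicate variety ids: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  n <- length(wordlists)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  failures <- character(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- tryCatch(fun(wordlists[[i]], wordlists[[j]]), error = identity)
    if (inherits(d, "error")) {
      failures <- c(failures, sprintf("(%s, %s): %s", labels[i], labels[j],
                                      conditionMessage(d)))
    } else {
      m[i, j] <- m[j, i] <- d
    }
  }
  if (length(failures))
    stop("measure '", measure, "' failed for ", length(failures),
         " pair(s):\n  ", paste(failures, collapse = "\n  "))
  m
}
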