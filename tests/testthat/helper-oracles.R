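# Independent oracles and small fixture builders used across the suite.

# Brute-force Levenshtein oracle: memoized recursion straight from the
# mathematical definition (cost of best edit script on prefixes), written
# independently of the package's implementation.
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- matrix(NA_real_, length(ca) + 1L, length(cb) + 1L)
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    if (!is.na(memo[i + 1L, j + 1L])) return(memo[i + 1L, j + 1L])
    val <- min(rec(i - 1L, j) + 1,
               rec(i, j - 1L) + 1,
               rec(i - 1L, j - 1L) + (ca[i] != cb[j]))
    memo[i + 1L, j + 1L] <<- val
    val
  }
  as.numeric(rec(length(ca), length(cb)))
}

# Flat-vector Pearson correlation oracle for matrix_correlation: collect
# the strictly-upper-triangle entries by explicit double loop.
flat_cor_oracle <- function(a, b) {
  va <- vb <- numeric(0)
  n <- nrow(a)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    va <- c(va, a[i, j]); vb <- c(vb, b[i, j])
  }
  cor(va, vb)
}

# All strings of length 0..maxlen over the given alphabet.
all_strings <- function(alphabet, maxlen) {
  out <- ""
  layer <- ""
  for (l in seq_len(maxlen)) {
    layer <- as.vector(outer(layer, alphabet, paste0))
    out <- c(out, layer)
  }
  out
}

# Random ultrametric distance matrix built from a simulated tree's path
# distances (tree height 1).
ultrametric_matrix <- function(n, seed) {
  tree <- simulate_tree(n, seed = seed)
  m <- ape::cophenetic.phylo(tree)
  m <- m[sort(rownames(m)), sort(rownames(m))]
  (m + t(m)) / 2
}

toy_wordlists <- function() {
  list(
    A = wordlist("A", list(c1 = "aa", c2 = "bb"),
                 cognates = list(c1 = "k1", c2 = "k2")),
    B = wordlist("B", list(c1 = "aa", c2 = "bc"),
                 cognates = list(c1 = "k1", c2 = "k3")))
}
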