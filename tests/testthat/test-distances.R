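test_that("levenshtein matches hand-checked cases and axioms", {
  expect_identical(levenshtein("", "abc"), 3L)
  expect_identical(levenshtein("kitten", "sitting"), 3L)
  for (x in c("", "a", "xyz", "šui")) {
    expect_identical(levenshtein(x, x), 0L)
  }
  # symmetry and triangle inequality on random short strings
  set.seed(11)
  words <- replicate(30, paste(sample(letters[1:4], sample(0:5, 1),
                                      replace = TRUE), collapse = ""))
  for (i in 1:20) {
    abc <- sample(words, 3)
    expect_identical(levenshtein(abc[1], abc[2]),
                     levenshtein(abc[2], abc[1]))
    expect_lte(levenshtein(abc[1], abc[3]),
               levenshtein(abc[1], abc[2]) + levenshtein(abc[2], abc[3]))
  }
  # NFC normalization: precomposed vs combining-accent spellings coincide
  expect_identical(levenshtein("café", "café"), 0L)
})

test_that("ldn divides by the longer word and stays in [0,1]", {
  expect_equal(ldn("kat", "kat"), 0)
  expect_equal(ldn("ab", "cd"), 1)
  expect_equal(ldn("kat", "hat"), 1 / 3)
  expect_equal(ldn("", "abc"), 1)
  expect_error(ldn("", ""), "undefined")
  set.seed(2)
  a <- replicate(50, paste(sample(letters[1:5], sample(1:6, 1), TRUE),
                           collapse = ""))
  b <- replicate(50, paste(sample(letters[1:5], sample(1:6, 1), TRUE),
                           collapse = ""))
  v <- ldn(a, b)
  expect_true(all(v >= 0 & v <= 1))
  expect_equal(v, ldn(b, a))
})

test_that("variety-level LDN averages per-concept minima over shared concepts", {
  wl <- toy_wordlists()
  expect_equal(variety_ldn(wl$A, wl$B), 0.25)
  expect_equal(variety_ldn(wl$A, wl$A), 0)
  # synonyms: per-concept value is the min over cross-variety form pairs
  ws <- wordlist("C", list(c1 = c("aa", "zz"), c2 = "bb"))
  expect_equal(variety_ldn(ws, wl$B), (0 + 0.5) / 2)
  # only shared concepts enter
  wd <- wordlist("D", list(c1 = "aa", c9 = "qq"))
  expect_equal(variety_ldn(wd, wl$A), 0)
  # disjoint concept sets name both varieties in the error
  we <- wordlist("E", list(zz = "aa"))
  expect_error(variety_ldn(we, wl$A), "no shared concepts.*E.*A")
})

test_that("ldnd normalizes by the cross-meaning mean, per variety pair", {
  wl <- toy_wordlists()
  # numerator 0.25; cross pairs ("aa","bc") and ("bb","aa") both LDN 1
  expect_equal(ldnd(wl$A, wl$B), 0.25)
  expect_equal(ldnd(wl$A, wl$A), 0)
  w_same <- wordlist("S", list(c1 = "aa", c2 = "aa"))
  expect_error(ldnd(w_same, w_same), "degenerate")
  # agrees with a direct all-pairs recomputation on a synonym-rich pair
  w1 <- wordlist("X", list(c1 = c("abc", "abd"), c2 = "xy", c3 = "pq"))
  w2 <- wordlist("Y", list(c1 = "abe", c2 = c("xz", "yy"), c3 = "pr"))
  num <- mean(c(min(ldn("abc", "abe"), ldn("abd", "abe")),
                min(ldn("xy", "xz"), ldn("xy", "yy")),
                ldn("pq", "pr")))
  f1 <- list(c1 = c("abc", "abd"), c2 = "xy", c3 = "pq")
  f2 <- list(c1 = "abe", c2 = c("xz", "yy"), c3 = "pr")
  cross <- c()
  for (ci in names(f1)) for (cj in names(f2)) {
    if (ci == cj) next
    for (x in f1[[ci]]) for (y in f2[[cj]]) cross <- c(cross, ldn(x, y))
  }
  expect_equal(ldnd(w1, w2), num / mean(cross))
})

test_that("cognate distance counts concepts whose class sets intersect", {
  w1 <- wordlist("A", list(c1 = "a", c2 = "b", c3 = "c"),
                 cognates = list(c1 = "k1", c2 = "k2", c3 = "k3"))
  w2 <- wordlist("B", list(c1 = "a", c2 = "b", c3 = "d"),
                 cognates = list(c1 = "k1", c2 = "k2", c3 = "k9"))
  expect_equal(cognate_distance(w1, w2), 1 / 3)
  expect_equal(cognate_distance(w1, w1), 0)
  w3 <- wordlist("C", list(c1 = "x", c2 = "y", c3 = "z"),
                 cognates = list(c1 = "q1", c2 = "q2", c3 = "q3"))
  expect_equal(cognate_distance(w1, w3), 1)
  # multi-class synonyms: intersection logic
  w4 <- wordlist("D", list(c1 = c("a", "e"), c2 = "b", c3 = "c"),
                 cognates = list(c1 = c("k7", "k1"), c2 = "k5", c3 = "k3"))
  expect_equal(cognate_distance(w1, w4), 1 / 3)
  wu <- wordlist("U", list(c1 = "a"))
  expect_error(cognate_distance(w1, wu), "cognate coding")
})

test_that("pairwise_matrix is symmetric, order-covariant and aggregates failures", {
  set.seed(31)
  ds <- make_dataset(simulation_config(n_varieties = 6, groups = 3,
                                       n_concepts = 15, seed = 31))
  for (measure in c("ldn", "ldnd", "cognate")) {
    m <- pairwise_matrix(ds$wordlists, measure)
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    if (measure != "ldnd") expect_true(all(m <= 1))
    expect_true(all(m >= 0))
    # per-pair calls agree with the assembled matrix
    fun <- switch(measure, ldn = variety_ldn, ldnd = ldnd,
                  cognate = cognate_distance)
    expect_equal(m["v002", "v005"],
                 fun(ds$wordlists$v002, ds$wordlists$v005))
    # permuting the input permutes rows/columns identically
    perm <- c(4, 1, 6, 3, 2, 5)
    m2 <- pairwise_matrix(ds$wordlists[perm], measure)
    expect_equal(m2, m[perm, perm])
  }
  # uncoded wordlists cannot enter the cognate measure; all pairs reported
  plain <- lapply(ds$wordlists[1:3], function(w)
    wordlist(w$variety_id, w$forms))
  expect_error(pairwise_matrix(plain, "cognate"), "3 pair")
})
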