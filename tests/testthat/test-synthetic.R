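test_that("simulated trees are ultrametric with height 1 and deterministic", {
  for (n in c(2, 5, 23, 50)) {
    tree <- simulate_tree(n, seed = n)
    expect_equal(length(tree$tip.label), n)
    depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
    expect_equal(depths, rep(1, n), tolerance = 1e-9)
  }
  expect_identical(ape::write.tree(simulate_tree(12, seed = 99)),
                   ape::write.tree(simulate_tree(12, seed = 99)))
})

test_that("frozen evolution yields identical leaves; full replacement erases cognacy", {
  tree <- simulate_tree(6, seed = 4)
  frozen <- simulation_config(n_varieties = 6, groups = 3, n_concepts = 20,
                              mutation_rate = 0, replacement_rate = 0)
  wl <- evolve_lexicon(tree, frozen, seed = 1)
  m <- pairwise_matrix(wl, "ldn")
  expect_equal(unname(m), matrix(0, 6, 6))
  expect_equal(unname(pairwise_matrix(wl, "cognate")),
               matrix(0, 6, 6))

  # replacement oracle: two leaves share a concept's cognate class iff no
  # replacement event hit any branch on the path between them, so the
  # expected cognate distance is 1 - prod(1 - min(1, rate * len)) over the
  # path; at rate = 1 it approaches 1 for distant leaves
  hot <- simulation_config(n_varieties = 6, groups = 3, n_concepts = 20,
                           replacement_rate = 1)
  set.seed(10)
  n <- 6
  exp_cd <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    np <- ape::nodepath(tree, i, j)
    lens <- vapply(seq_len(length(np) - 1), function(k) {
      e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                 (tree$edge[, 1] == np[k + 1] & tree$edge[, 2] == np[k]))
      tree$edge.length[e]
    }, numeric(1))
    exp_cd[i, j] <- 1 - prod(1 - pmin(1, 1 * lens))
  }
  cd <- replicate(50, {
    w <- evolve_lexicon(tree, hot)
    mean(pairwise_matrix(w, "cognate")[upper.tri(diag(6))])
  })
  expect_equal(mean(cd), mean(exp_cd[upper.tri(exp_cd)]), tolerance = 0.05)
})

test_that("sister leaves are lexically closer than distant leaves on average", {
  cfg <- simulation_config(n_varieties = 8, groups = 4, n_concepts = 40)
  set.seed(77)
  tree <- simulate_tree(8, seed = 77)
  pd <- ape::cophenetic.phylo(tree)
  close_pair <- which(pd == min(pd[pd > 0]), arr.ind = TRUE)[1, ]
  far_pair <- which(pd == max(pd), arr.ind = TRUE)[1, ]
  diffs <- replicate(50, {
    wl <- evolve_lexicon(tree, cfg)
    m <- pairwise_matrix(wl, "ldn")
    m[far_pair[1], far_pair[2]] - m[close_pair[1], close_pair[2]]
  })
  expect_gt(mean(diffs), 0)
})

test_that("raising the replacement rate raises expected cognate distance", {
  tree <- simulate_tree(6, seed = 15)
  mean_cd <- function(rate) {
    cfg <- simulation_config(n_varieties = 6, groups = 3, n_concepts = 30,
                             replacement_rate = rate)
    mean(replicate(50, {
      wl <- evolve_lexicon(tree, cfg)
      mean(pairwise_matrix(wl, "cognate")[upper.tri(diag(6))])
    }))
  }
  set.seed(123)
  low <- mean_cd(0.1); high <- mean_cd(0.6)
  expect_gt(high, low)
})

test_that("borrowing is off at rate 0, converges at rate 1 for two varieties", {
  cfg0 <- simulation_config(n_varieties = 4, groups = 2, n_concepts = 10,
                            borrowing_rate = 0)
  tree <- simulate_tree(4, seed = 2)
  wl <- evolve_lexicon(tree, cfg0, seed = 3)
  out0 <- apply_borrowing(wl, config = cfg0, seed = 4)
  expect_identical(out0$wordlists, wl)
  expect_equal(nrow(out0$events), 0L)

  cfg1 <- simulation_config(n_varieties = 2, groups = 1, n_concepts = 10,
                            borrowing_rate = 1)
  tree2 <- simulate_tree(2, seed = 5)
  wl2 <- evolve_lexicon(tree2, cfg1, seed = 6)
  out1 <- apply_borrowing(wl2, config = cfg1, seed = 7)
  a <- out1$wordlists[[1]]; b <- out1$wordlists[[2]]
  expect_identical(a$forms, b$forms)
  expect_identical(a$cognates, b$cognates)
  # replaying the event log over the pre-borrowing state reproduces the
  # post-borrowing wordlists
  replay <- wl2
  for (r in seq_len(nrow(out1$events))) {
    ev <- out1$events[r, ]
    replay[[ev$receiver]]$forms[[ev$concept]] <-
      replay[[ev$donor]]$forms[[ev$concept]]
    replay[[ev$receiver]]$cognates[[ev$concept]] <-
      replay[[ev$donor]]$cognates[[ev$concept]]
  }
  expect_identical(replay, out1$wordlists)
})

test_that("borrowing pulls ring neighbors lexically closer", {
  mean_neighbor_ldn <- function(rate, seed) {
    cfg <- simulation_config(n_varieties = 10, groups = 5, n_concepts = 30,
                             borrowing_rate = rate, seed = seed)
    ds <- make_dataset(cfg)
    m <- pairwise_matrix(ds$wordlists, "ldn")
    geo <- names(ds$group_map)  # ring order used by make_dataset
    mean(vapply(seq_along(geo), function(i)
      m[geo[i], geo[1 + i %% length(geo)]], numeric(1)))
  }
  vals0 <- vapply(1:15, function(s) mean_neighbor_ldn(0, 3000 + s),
                  numeric(1))
  vals9 <- vapply(1:15, function(s) mean_neighbor_ldn(0.9, 3000 + s),
                  numeric(1))
  expect_gt(mean(vals0), mean(vals9))
})

test_that("trait evolution is seeded, bounded and collapses to 0.5 at zero variance", {
  tree <- simulate_tree(10, seed = 30)
  cfg <- simulation_config(n_varieties = 10, groups = 5)
  t1 <- evolve_trait(tree, cfg, seed = 8)
  t2 <- evolve_trait(tree, cfg, seed = 8)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 1))
  cfg0 <- simulation_config(n_varieties = 10, groups = 5,
                            trait_variance = 0)
  expect_equal(unname(evolve_trait(tree, cfg0, seed = 9)), rep(0.5, 10))
})

test_that("trait variance between deep clades exceeds variance within", {
  set.seed(55)
  ratios <- replicate(30, {
    tree <- simulate_tree(12)
    cfg <- simulation_config(n_varieties = 12, groups = 2)
    tr <- evolve_trait(tree, cfg)
    t2 <- upgma(ape::cophenetic.phylo(tree))
    sides <- top_branches(t2, 2)
    x <- tr[sides[[1]]]; y <- tr[sides[[2]]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    (mean(x) - mean(y))^2 / (var(x) + var(y) + 1e-12)
  })
  # clade means separate relative to within-clade spread in most runs
  expect_gt(median(ratios, na.rm = TRUE), 0.5)
})

test_that("make_dataset is deterministic and writes a parseable dataset", {
  cfg <- simulation_config(n_varieties = 12, groups = 4, n_concepts = 25,
                           borrowing_rate = 0.1, seed = 61)
  d1 <- make_dataset(cfg)
  d2 <- make_dataset(cfg)
  expect_identical(d1$wordlists, d2$wordlists)
  expect_identical(d1$trait_table, d2$trait_table)
  expect_equal(length(d1$wordlists), 12)
  expect_equal(length(unique(d1$group_map)), 4)
  expect_true(all(d1$trait_table >= 0 & d1$trait_table <= 1))
  # cognate classes are globally consistent identifiers
  expect_true(all(grepl("^k\\d+$",
                        unlist(lapply(d1$wordlists, `[[`, "cognates")))))

  dir <- withr::local_tempdir()
  write_dataset(d1, dir)
  wl <- read_wordlists(file.path(dir, "wordlists.tsv"))
  gm <- read_group_map(file.path(dir, "groups.tsv"))
  tt <- read_trait_table(file.path(dir, "traits.csv"))
  expect_setequal(names(wl), names(d1$wordlists))
  expect_equal(sort(names(gm)), sort(names(d1$group_map)))
  expect_equal(tt[names(d1$trait_table)], d1$trait_table,
               tolerance = 1e-12)
  tr <- ape::read.tree(file.path(dir, "true_tree.nwk"))
  expect_setequal(tr$tip.label, names(d1$wordlists))
  # round-tripped wordlists give identical distance matrices
  m0 <- pairwise_matrix(d1$wordlists, "cognate")
  m1 <- pairwise_matrix(wl[names(d1$wordlists)], "cognate")
  expect_equal(m1, m0)
})

test_that("tree path distance and cognate distance correlate without borrowing", {
  set.seed(91)
  rs <- replicate(15, {
    cfg <- simulation_config(n_varieties = 12, groups = 4, n_concepts = 40,
                             seed = sample.int(1e6, 1))
    ds <- make_dataset(cfg)
    pd <- ape::cophenetic.phylo(ds$tree)
    cd <- pairwise_matrix(ds$wordlists, "cognate")
    matrix_correlation(pd[rownames(cd), rownames(cd)], cd)
  })
  expect_gt(median(rs), 0)
})
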