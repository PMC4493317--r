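#' Configuration for the coupled lexicon + trait simulator
#'
#' The simulator emulates the statistical structure the analysis assumes:
#' language varieties related by a tree of descent, word forms diverging by
#' symbol edits and cognate replacement along its branches, optional
#' horizontal borrowing between geographic neighbors, and a bounded
#' continuous trait evolving on the same tree. All rates are per unit of
#' branch length; trees are scaled to total height 1, so a rate is also
#' (approximately) the expected number of events on a root-to-leaf path.
#'
#' @param n_varieties number of leaf varieties (>= 2).
#' @param n_concepts number of concepts in the vocabulary (>= 1).
#' @param alphabet_size number of distinct symbols words are built from
#'   (max 26, rendered as lowercase letters).
#' @param mutation_rate per-symbol, per-branch-unit probability of
#'   substitution by a different random symbol, in \[0, 1\].
#' @param replacement_rate per-concept, per-branch-unit probability that
#'   the word is replaced by an unrelated new word, founding a new cognate
#'   class, in \[0, 1\].
#' @param borrowing_rate per-concept probability that a variety copies its
#'   word (and cognate class) from a ring-adjacent geographic neighbor
#'   after descent, in \[0, 1\].
#' @param trait_variance Brownian-motion variance of the latent trait per
#'   branch unit; leaf values are squashed into \[0, 1\] by the logistic
#'   function.
#' @param groups number of groups (provinces) the varieties are assigned
#'   to, as contiguous blocks of the tree's leaf order.
#' @param seed integer seed for [make_dataset].
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(n_varieties = 40, n_concepts = 100,
                              alphabet_size = 10, mutation_rate = 0.3,
                              replacement_rate = 0.25, borrowing_rate = 0,
                              trait_variance = 1, groups = 18, seed = 1) {
  stopifnot(n_varieties >= 2, n_concepts >= 1,
            alphabet_size >= 2, alphabet_size <= 26,
            mutation_rate >= 0, mutation_rate <= 1,
            replacement_rate >= 0, replacement_rate <= 1,
            borrowing_rate >= 0, borrowing_rate <= 1,
            trait_variance >= 0,
            groups >= 1, groups <= n_varieties)
  structure(list(n_varieties = as.integer(n_varieties),
                 n_concepts = as.integer(n_concepts),
                 alphabet_size = as.integer(alphabet_size),
                 mutation_rate = mutation_rate,
                 replacement_rate = replacement_rate,
                 borrowing_rate = borrowing_rate,
                 trait_variance = trait_variance,
                 groups = as.integer(groups),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a rooted ultrametric tree of descent
#'
#' Pure-birth (Yule) topology with the root-to-leaf height rescaled to 1 —
#' the simplest scaffold consistent with divergence by descent. Leaf
#' labels are `v001`, `v002`, ...
#'
#' @param n number of leaves (>= 2).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return an [ape] phylo object, ultrametric with height 1.
#' @export
simulate_tree <- function(n, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("v%03d", seq_len(n))
  tree
}

random_word <- function(alphabet) {
  paste(sample(alphabet, sample(3:8, 1L), replace = TRUE), collapse = "")
}

mutate_word <- function(word, p, alphabet) {
  ch <- strsplit(word, "", fixed = TRUE)[[1]]
  hit <- runif(length(ch)) < p
  if (any(hit))
    ch[hit] <- vapply(ch[hit], function(old)
      sample(setdiff(alphabet, old), 1L), character(1))
  paste(ch, collapse = "")
}

#' Evolve a lexicon along a tree
#'
#' An ancestral vocabulary of random words (one per concept, lengths 3-8
#' symbols) is placed at the root; along each branch of length L, each
#' concept's word is replaced by a brand-new word — founding a new,
#' globally unique cognate class — with probability
#' `min(1, replacement_rate * L)`, and otherwise each of its symbols is
#' substituted independently with probability `min(1, mutation_rate * L)`.
#' Two leaf forms share a cognate class if and only if they descend from
#' the same replacement event (or the root word) without replacement in
#' between.
#'
#' @param tree rooted phylo tree with branch lengths (see
#'   [simulate_tree]).
#' @param config a [simulation_config].
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return named list of cognate-coded [wordlist] objects, one per leaf,
#'   in tip-label order.
#' @export
evolve_lexicon <- function(tree, config, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  alphabet <- letters[seq_len(config$alphabet_size)]
  n <- length(tree$tip.label)
  cids <- sprintf("c%03d", seq_len(config$n_concepts))
  counter <- new.env(parent = emptyenv())
  counter$k <- config$n_concepts
  root_state <- list(
    words = vapply(cids, function(i) random_word(alphabet), character(1)),
    classes = stats::setNames(sprintf("k%06d", seq_along(cids)), cids))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  states <- vector("list", n + tree$Nnode)
  states[[n + 1L]] <- root_state
  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    st <- states[[parent]]
    p_rep <- min(1, config$replacement_rate * len)
    p_mut <- min(1, config$mutation_rate * len)
    replaced <- runif(config$n_concepts) < p_rep
    for (i in seq_len(config$n_concepts)) {
      if (replaced[i]) {
        st$words[i] <- random_word(alphabet)
        counter$k <- counter$k + 1L
        st$classes[i] <- sprintf("k%06d", counter$k)
      } else if (p_mut > 0) {
        st$words[i] <- mutate_word(st$words[i], p_mut, alphabet)
      }
    }
    states[[child]] <- st
  }
  out <- lapply(seq_len(n), function(tip) {
    st <- states[[tip]]
    wordlist(tree$tip.label[tip],
             forms = as.list(stats::setNames(unname(st$words), cids)),
             cognates = as.list(stats::setNames(unname(st$classes), cids)))
  })
  stats::setNames(out, tree$tip.label)
}

#' Apply horizontal borrowing between ring-adjacent varieties
#'
#' Geography is abstracted to a ring over the given variety order: each
#' variety's neighbors are its predecessor and successor (wrapping
#' around). Varieties are visited in ring order; for each concept,
#' with probability `borrowing_rate` the variety replaces its form and
#' cognate class by the current entry of a randomly chosen adjacent
#' neighbor. Updates are sequential, so a borrowed word can itself be
#' passed on within the same sweep. Every event is logged.
#'
#' @param wordlists named list of cognate-coded [wordlist] objects.
#' @param geography character vector ordering the varieties on the ring;
#'   defaults to the wordlist order.
#' @param config a [simulation_config] (uses `borrowing_rate`).
#' @param seed optional integer seed.
#' @return list with `wordlists` (same shape as input) and `events`, a
#'   data frame of borrowing events (receiver, donor, concept).
#' @export
apply_borrowing <- function(wordlists, geography = names(wordlists),
                            config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"),
            setequal(geography, names(wordlists)))
  if (!is.null(seed)) set.seed(seed)
  rate <- config$borrowing_rate
  events <- list()
  if (rate > 0 && length(wordlists) >= 2L) {
    nv <- length(geography)
    for (vi in seq_len(nv)) {
      v <- geography[vi]
      for (cc in concepts(wordlists[[v]])) {
        if (runif(1) < rate) {
          nb <- geography[1 + (vi - 1 + sample(c(-1L, 1L), 1L)) %% nv]
          if (!cc %in% concepts(wordlists[[nb]])) next
          wordlists[[v]]$forms[[cc]] <- wordlists[[nb]]$forms[[cc]]
          wordlists[[v]]$cognates[[cc]] <- wordlists[[nb]]$cognates[[cc]]
          events[[length(events) + 1L]] <-
            data.frame(receiver = v, donor = nb, concept = cc)
        }
      }
    }
  }
  list(wordlists = wordlists,
       events = if (length(events)) do.call(rbind, events)
       else data.frame(receiver = character(), donor = character(),
                       concept = character()))
}

#' Evolve a bounded trait on a tree by Brownian motion
#'
#' A latent trait starts at 0 at the root and takes independent Gaussian
#' increments with variance `trait_variance * branch length` along each
#' branch; leaf values are squashed into \[0, 1\] by the logistic
#' function. With zero variance every leaf sits at logistic(0) = 0.5.
#' The trait shares the tree with the lexicon but receives no causal
#' input from it — any correlation between trait differences and lexical
#' distances is pure common descent.
#'
#' @inheritParams evolve_lexicon
#' @return named numeric vector of leaf trait values in \[0, 1\], in
#'   tip-label order.
#' @export
evolve_trait <- function(tree, config, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  latent <- numeric(n + tree$Nnode)
  latent[n + 1L] <- 0
  for (e in seq_len(nrow(tree$edge))) {
    latent[tree$edge[e, 2]] <- latent[tree$edge[e, 1]] +
      rnorm(1, 0, sqrt(config$trait_variance * tree$edge.length[e]))
  }
  stats::setNames(plogis(latent[seq_len(n)]), tree$tip.label)
}

# tip labels in the order they appear across the tree drawing (cladewise
# edge traversal), so contiguous blocks correspond to clades where possible
tip_plot_order <- function(tree) {
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  tips <- edge[edge[, 2] <= length(tree$tip.label), 2]
  tree$tip.label[tips]
}

#' Generate a complete synthetic dataset
#'
#' Composes [simulate_tree], [evolve_lexicon], [apply_borrowing] and
#' [evolve_trait] under a single seed and assigns varieties to groups
#' (provinces) as contiguous blocks of the tree's leaf order, so groups
#' are geographically/cladistically coherent. Group trait values are the
#' mean of their member varieties' trait values.
#'
#' @param config a [simulation_config].
#' @return list of class `sim_dataset` with elements `wordlists` (cognate
#'   coded), `group_map`, `trait_table` (per group), `leaf_traits` (per
#'   variety), `tree` (true phylo), `borrowing_events` and `config`.
#' @examples
#' ds <- make_dataset(simulation_config(n_varieties = 8, groups = 4,
#'                                      n_concepts = 20, seed = 42))
#' ds$trait_table
#' @export
make_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- simulate_tree(config$n_varieties, seed = NULL)
  wl <- evolve_lexicon(tree, config, seed = NULL)
  geo <- tip_plot_order(tree)
  bor <- apply_borrowing(wl, geo, config, seed = NULL)
  leaf_traits <- evolve_trait(tree, config, seed = NULL)
  # contiguous blocks of the plot order, sizes as even as possible
  sizes <- rep(config$n_varieties %/% config$groups, config$groups)
  extra <- config$n_varieties %% config$groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  gids <- sprintf("P%02d", seq_len(config$groups))
  group_map <- stats::setNames(rep(gids, sizes), geo)
  trait_table <- vapply(split(leaf_traits[geo], rep(gids, sizes)),
                        mean, numeric(1))[gids]
  structure(list(wordlists = bor$wordlists, group_map = group_map,
                 trait_table = trait_table, leaf_traits = leaf_traits,
                 tree = tree, borrowing_events = bor$events,
                 config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", length(x$wordlists), "varieties,",
      length(x$trait_table), "groups,", x$config$n_concepts,
      "concepts, seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits the files the readers of this package consume: `wordlists.tsv`
#' (long TSV with cognate column), `groups.tsv`, `traits.csv`, the true
#' tree as `true_tree.nwk` and the borrowing event log as
#' `borrowing_events.json`.
#'
#' @param ds a `sim_dataset` from [make_dataset].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_wordlists(ds$wordlists, file.path(dir, "wordlists.tsv"))
  write_group_map(ds$group_map, file.path(dir, "groups.tsv"))
  write_trait_table(ds$trait_table, file.path(dir, "traits.csv"))
  ape::write.tree(ds$tree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(ds$borrowing_events,
                       file.path(dir, "borrowing_events.json"))
  invisible(dir)
}
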