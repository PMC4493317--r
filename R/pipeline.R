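#' Run the full distance-based analysis
#'
#' Orchestrates the pipeline: variety-level lexical distances
#' ([pairwise_matrix]) -> group-level aggregation
#' ([group_distance_matrix]) -> trait-difference matrix
#' ([trait_difference_matrix]) -> complete-case alignment
#' ([align_matrices]) -> permutation Mantel test ([mantel_test]) ->
#' UPGMA tree on the group lexical distances ([upgma]) with its top k
#' branches ([top_branches]). A structured report captures everything
#' needed to reproduce the run.
#'
#' @param wordlists named list of [wordlist] objects (cognate-coded when
#'   `measure = "cognate"`).
#' @param group_map named character vector, variety -> group.
#' @param traits named numeric vector in \[0, 1\], group -> trait value.
#' @param measure lexical distance measure: `"cognate"`, `"ldnd"` or
#'   `"ldn"`.
#' @param n_perm Mantel permutations (default 10000).
#' @param tail Mantel tail (default `"greater"`: more lexical distance
#'   goes with more trait difference).
#' @param k number of top tree branches to extract (capped at the number
#'   of groups).
#' @param seed integer seed for the permutation draw.
#' @param outdir optional directory; when given, all intermediate matrices,
#'   the Newick tree, branch assignments and the JSON report are written
#'   there.
#' @return a `run_report` (list) with fields `measure`, `n_varieties`,
#'   `groups_used`, `groups_dropped`, `mantel` (a `mantel_result`), `tree`
#'   (a `cluster_tree`), `branches`, `matrices` (variety/group/trait),
#'   `n_perm`, `tail`, `seed` and `version`.
#' @examples
#' ds <- make_dataset(simulation_config(n_varieties = 10, groups = 5,
#'                                      n_concepts = 30, seed = 3))
#' rep <- run_analysis(ds$wordlists, ds$group_map, ds$trait_table,
#'                     measure = "cognate", n_perm = 99, seed = 1)
#' rep$mantel
#' @export
run_analysis <- function(wordlists, group_map, traits,
                         measure = c("cognate", "ldnd", "ldn"),
                         n_perm = 10000,
                         tail = c("greater", "less", "two_sided"),
                         k = 4, seed = NULL, outdir = NULL) {
  measure <- match.arg(measure)
  tail <- match.arg(tail)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  }
  vmat <- stage("distances", pairwise_matrix(wordlists, measure))
  gmat <- stage("aggregation", group_distance_matrix(vmat, group_map))
  tmat <- stage("trait", trait_difference_matrix(traits))
  al <- stage("align", align_matrices(gmat, tmat))
  mt <- stage("mantel",
              mantel_test(al$a, al$b, n_perm = n_perm, tail = tail,
                          seed = seed))
  tree <- stage("clustering", upgma(al$a))
  kk <- min(k, nrow(al$a))
  branches <- stage("clustering", top_branches(tree, kk))
  report <- structure(list(
    measure = measure,
    n_varieties = length(wordlists),
    groups_used = rownames(al$a),
    groups_dropped = al$dropped,
    mantel = mt,
    tree = tree,
    branches = branches,
    matrices = list(variety = vmat, group = al$a, trait = al$b),
    n_perm = n_perm, tail = tail, k = kk, seed = seed,
    version = as.character(utils::packageVersion("lexmantel"))),
    class = "run_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("== lexmantel run ==\n")
  cat("measure:", x$measure, "|", x$n_varieties, "varieties ->",
      length(x$groups_used), "groups")
  if (length(x$groups_dropped))
    cat(" (dropped:", paste(x$groups_dropped, collapse = ", "), ")")
  cat("\n")
  print(x$mantel)
  cat("tree: UPGMA,", x$k, "top branches:",
      paste(vapply(x$branches, length, integer(1)), collapse = "/"),
      "leaves\n")
  invisible(x)
}

#' Write a run report and its artifacts to a directory
#'
#' Emits `variety_matrix.tsv`, `group_matrix.tsv`, `trait_matrix.tsv`
#' (via [write_matrix]), `tree.nwk`, `branches.tsv` and `report.json`.
#' The JSON report records measure, counts, dropped groups, the Mantel
#' result (r, p, permutations, tail, seed), branch memberships and the
#' package version — everything needed to reproduce the run.
#'
#' @param report a `run_report` from [run_analysis].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(report$matrices$variety, file.path(dir, "variety_matrix.tsv"))
  write_matrix(report$matrices$group, file.path(dir, "group_matrix.tsv"))
  write_matrix(report$matrices$trait, file.path(dir, "trait_matrix.tsv"))
  writeLines(to_newick(report$tree), file.path(dir, "tree.nwk"))
  write_branches(report$branches, file.path(dir, "branches.tsv"))
  json <- list(
    measure = report$measure,
    n_varieties = report$n_varieties,
    groups_used = report$groups_used,
    groups_dropped = report$groups_dropped,
    mantel = list(r = report$mantel$r_obs, p = report$mantel$p_value,
                  n_perm = report$mantel$n_perm, tail = report$mantel$tail,
                  method = report$mantel$method),
    branches = report$branches,
    k = report$k,
    seed = report$seed,
    version = report$version)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
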