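## Maximum-parsimony trees from the binary presence matrix, with the
## (variant-free) germline as outgroup root. With at most a handful of
## biopsies per lesion an exhaustive search over all rooted binary
## topologies is exact and dependency-free: every topology is scored by
## Fitch parsimony over the binary characters (unordered, homoplasy
## allowed), and a minimum-score tree is returned with ties broken by the
## lexicographically smallest canonical Newick string. Edge lengths count
## the state changes a minimum-change assignment places on each edge; the
## assignment prefers changes close to the root (acctran-style), so that on
## perfect-phylogeny input every truncal variant sits on the trunk.

## all rooted binary topologies on leaves 1..n; leaf = integer,
## internal node = list(left, right)
enumerate_topologies <- function(n) {
  trees <- list(1L)
  if (n == 1) return(trees)
  for (i in 2:n) {
    new <- list()
    for (t in trees) new <- c(new, insert_leaf(t, i))
    trees <- new
  }
  trees
}

insert_leaf <- function(t, leaf) {
  res <- list(list(t, leaf))          # attach above the current root
  if (is.list(t)) {
    for (s in insert_leaf(t[[1]], leaf)) res <- c(res, list(list(s, t[[2]])))
    for (s in insert_leaf(t[[2]], leaf)) res <- c(res, list(list(t[[1]], s)))
  }
  res
}

## Fitch score of one topology, vectorized over characters. pres is the
## variants x leaves logical matrix; state sets are bitmasks (1 = absent,
## 2 = present). The germline outgroup contributes a final intersection
## with {absent} at the root.
fitch_score <- function(topo, pres) {
  rec <- function(t) {
    if (!is.list(t)) {
      return(list(set = ifelse(pres[, t], 2L, 1L), score = 0L))
    }
    a <- rec(t[[1]])
    b <- rec(t[[2]])
    inter <- bitwAnd(a$set, b$set)
    list(set = ifelse(inter > 0L, inter, bitwOr(a$set, b$set)),
         score = a$score + b$score + sum(inter == 0L))
  }
  r <- rec(topo)
  r$score + sum(bitwAnd(r$set, 1L) == 0L)
}

## canonical form: children ordered by their label string under C-locale
## collation; returns the reordered topology and its label key
canonicalize <- function(topo, leaves) {
  if (!is.list(topo)) return(list(t = topo, key = leaves[topo]))
  a <- canonicalize(topo[[1]], leaves)
  b <- canonicalize(topo[[2]], leaves)
  first_a <- sort(c(a$key, b$key), method = "radix")[1] == a$key
  if (!first_a) {
    tmp <- a
    a <- b
    b <- tmp
  }
  list(t = list(a$t, b$t), key = paste0("(", a$key, ",", b$key, ")"))
}

#' Build a maximum-parsimony tumor tree
#'
#' Exhaustively enumerates all rooted binary topologies over the biopsies
#' (the germline outgroup, all characters absent, defines the root) and
#' returns a minimum Fitch-parsimony tree. Edge lengths are mutation
#' counts: the number of variants whose state change a minimum-change,
#' rootward-preferring assignment places on that edge; their sum equals the
#' parsimony score. The *trunk* is the edge from the germline root into the
#' most recent common ancestor of all biopsies; on compatible (perfect
#' phylogeny) input its length equals the truncal variant count.
#'
#' @param matrix A [presence_matrix()] with 2 to 8 biopsy columns (the
#'   exhaustive search bound; larger trees call for heuristic software).
#' @return A `tumor_tree` object: list with `patient_id`, `leaves`,
#'   `score`, `trunk_length`, `edges` (data.frame `edge` = clade label,
#'   `length`), `assignments` (data.frame `variant_key`, `edge` -- one row
#'   per state change, auditable for homoplastic variants) and `newick`.
#' @examples
#' pres <- matrix(c(TRUE, TRUE, TRUE, TRUE,
#'                  TRUE, TRUE, TRUE, FALSE,
#'                  TRUE, FALSE, FALSE, FALSE), 3, 4, byrow = TRUE,
#'                dimnames = list(c("v1", "v2", "v3"), paste0("B", 1:4)))
#' tr <- build_tree(presence_matrix("P03", pres))
#' tr$score
#' tr$newick
#' @export
build_tree <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  pres <- matrix$presence
  leaves <- colnames(pres)
  n <- length(leaves)
  if (n < 2) stop("need >= 2 biopsies to build a tree")
  if (n > 8) {
    stop("more than 8 biopsies: exhaustive search is infeasible, ",
         "use dedicated phylogenetics software")
  }
  if (nrow(pres) == 0) stop("no variants to build a tree from")

  best <- NULL
  best_score <- Inf
  best_key <- NULL
  for (topo in enumerate_topologies(n)) {
    sc <- fitch_score(topo, pres)
    if (sc > best_score) next
    cf <- canonicalize(topo, leaves)
    if (sc < best_score ||
        sort(c(cf$key, best_key), method = "radix")[1] != best_key) {
      best <- cf$t
      best_score <- sc
      best_key <- cf$key
    }
  }

  a <- assign_changes(best, pres, leaves)
  stopifnot(sum(a$edges$length) == best_score)
  trunk_label <- paste(sort(leaves, method = "radix"), collapse = "+")
  trunk_len <- a$edges$length[a$edges$edge == trunk_label]
  structure(list(patient_id = matrix$patient_id, leaves = leaves,
                 topology = best, score = best_score,
                 trunk_length = trunk_len,
                 edges = a$edges, assignments = a$assignments,
                 newick = render_newick(best, leaves, a$lengths)),
            class = "tumor_tree")
}

## Sankoff small parsimony on the chosen topology with the root fixed to
## the germline (all-absent) state; ties in the traceback pick the state
## unequal to the parent, which realises changes on the earliest possible
## (rootward) edge. Returns per-edge lengths and per-change assignments.
assign_changes <- function(topo, pres, leaves) {
  sank <- function(t) {
    if (!is.list(t)) {
      return(list(t = t,
                  c0 = ifelse(pres[, t], Inf, 0),
                  c1 = ifelse(pres[, t], 0, Inf)))
    }
    a <- sank(t[[1]])
    b <- sank(t[[2]])
    list(t = t, a = a, b = b,
         c0 = pmin(a$c0, a$c1 + 1) + pmin(b$c0, b$c1 + 1),
         c1 = pmin(a$c0 + 1, a$c1) + pmin(b$c0 + 1, b$c1))
  }
  root <- sank(topo)

  clade <- function(t) {
    lv <- if (!is.list(t)) leaves[t] else unlist(lapply(t, clade_leaves))
    paste(sort(lv, method = "radix"), collapse = "+")
  }
  clade_leaves <- function(t) {
    if (!is.list(t)) leaves[t] else unlist(lapply(t, clade_leaves))
  }

  edges <- list()
  assignments <- list()
  lengths <- list()
  walk <- function(node, parent_state) {
    cost0 <- node$c0 + (parent_state != 0L)
    cost1 <- node$c1 + (parent_state != 1L)
    state <- ifelse(cost1 < cost0, 1L,
                    ifelse(cost0 < cost1, 0L, 1L - parent_state))
    changed <- which(state != parent_state)
    label <- clade(node$t)
    edges[[length(edges) + 1L]] <<- data.frame(
      edge = label, length = length(changed), stringsAsFactors = FALSE)
    lengths[[label]] <<- length(changed)
    if (length(changed)) {
      assignments[[length(assignments) + 1L]] <<- data.frame(
        variant_key = rownames(pres)[changed],
        edge = label,
        change = ifelse(state[changed] == 1L, "gain", "loss"),
        stringsAsFactors = FALSE)
    }
    if (is.list(node$t)) {
      walk(node$a, state)
      walk(node$b, state)
    }
  }
  walk(root, rep(0L, nrow(pres)))
  list(edges = do.call(rbind, edges),
       assignments = if (length(assignments)) {
         do.call(rbind, assignments)
       } else {
         data.frame(variant_key = character(), edge = character(),
                    change = character(), stringsAsFactors = FALSE)
       },
       lengths = lengths)
}

render_newick <- function(topo, leaves, lengths) {
  clade_leaves <- function(t) {
    if (!is.list(t)) leaves[t] else unlist(lapply(t, clade_leaves))
  }
  rec <- function(t) {
    label <- paste(sort(clade_leaves(t), method = "radix"), collapse = "+")
    len <- lengths[[label]]
    if (!is.list(t)) {
      paste0(leaves[t], ":", len)
    } else {
      paste0("(", rec(t[[1]]), ",", rec(t[[2]]), "):", len)
    }
  }
  paste0("(", rec(topo), ",GL:0);")
}

#' Newick string of a tumor tree
#'
#' Branch lengths are mutation counts; the germline outgroup leaf is
#' labelled `GL`; child order is deterministic (alphabetical by clade).
#' The string parses with standard Newick readers.
#'
#' @param tree A `tumor_tree` from [build_tree()].
#' @return Newick string, semicolon-terminated.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "tumor_tree"))
  tree$newick
}

#' @export
print.tumor_tree <- function(x, ...) {
  cat(sprintf("tumor_tree: patient %s, %d biopsies, parsimony score %d\n",
              x$patient_id, length(x$leaves), x$score))
  cat(" ", x$newick, "\n")
  invisible(x)
}
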