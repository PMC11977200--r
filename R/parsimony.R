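# Minimum NOR relocation ("jump") counting on a species tree by unordered
# (uniform-cost) parsimony. States are chromosome labels; every
# chromosome-to-chromosome jump costs 1, reflecting direct relocation
# without intermediate states. Polytomies are handled natively by the
# Sankoff recursion rather than being resolved arbitrarily; on strictly
# binary trees the result coincides with Fitch counting. Leaves without a
# state (e.g. an outgroup with no homologous chromosome nomenclature) are
# pruned before counting, never imputed.

# cost a child subtree contributes to its parent being in each state:
# min(down[child, s], min(down[child, ]) + 1)
contrib_to_parent <- function(down_row) {
  pmin(down_row, min(down_row) + 1)
}

#' Minimum number of NOR relocations on a species tree
#'
#' Uniform-cost ancestral-state parsimony of the NOR-bearing chromosome over
#' a rooted species tree. Returns the minimum number of state changes, the
#' full most-parsimonious state set of every internal node, per-edge change
#' indicators (whether a change is forced on that edge in at least one / in
#' all most-parsimonious reconstructions), and one deterministic
#' most-parsimonious reconstruction (lexicographically smallest state at
#' each tie).
#'
#' @param tree Rooted `phylo` tree; polytomies allowed.
#' @param states Tibble with columns `species`, `nor_chromosome` (from
#'   [read_nor_states()]), or a named character vector.
#' @return A `nor_parsimony` object; see [tidy()], [glance()] and
#'   [classify_jumps()].
#' @examples
#' tr <- read_tree(karyomorph_example("nor_tree.nwk"))
#' st <- read_nor_states(karyomorph_example("nor_states.csv"))
#' fitch_parsimony(tr, st)
#' @export
fitch_parsimony <- function(tree, states) {
  if (is.data.frame(states)) {
    states <- setNames(states$nor_chromosome, states$species)
  }
  extra <- setdiff(names(states), tree$tip.label)
  if (length(extra) > 0) {
    abort_validation(sprintf("species in state table but not in tree: %s",
                             paste(extra, collapse = ", ")))
  }
  with_state <- intersect(tree$tip.label, names(states))
  if (length(with_state) == 0) {
    abort("no leaf carries a NOR state", class = "karyomorph_input_error")
  }
  if (length(with_state) < 2) {
    abort("at least two leaves must carry a state", class = "karyomorph_input_error")
  }
  stateless <- setdiff(tree$tip.label, with_state)
  if (length(stateless) > 0) {
    tree <- ape::drop.tip(tree, stateless, collapse.singles = TRUE)
  }
  S <- sort(unique(unname(states[tree$tip.label])))
  K <- length(S)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L

  edges <- ape::reorder.phylo(tree, "postorder")$edge
  children <- split(edges[, 2], edges[, 1])

  # bottom-up subtree costs
  down <- matrix(Inf, n_node, K, dimnames = list(NULL, S))
  tip_state <- states[tree$tip.label]
  for (v in seq_len(n_tip)) down[v, tip_state[v]] <- 0
  for (v in unique(edges[, 1])) down[v, ] <- 0  # filled below in postorder
  for (k in seq_len(nrow(edges))) {
    # accumulate child contributions as children complete (postorder order
    # guarantees a child's row is final before its parent edge is visited)
    v <- edges[k, 1]; c <- edges[k, 2]
    down[v, ] <- down[v, ] + contrib_to_parent(down[c, ])
  }
  min_changes <- min(down[root, ])

  # top-down costs of the rest of the tree
  up <- matrix(Inf, n_node, K)
  up[root, ] <- 0
  # visit parents before children
  for (k in rev(seq_len(nrow(edges)))) {
    v <- edges[k, 1]; c <- edges[k, 2]
    sib_contrib <- down[v, ] - contrib_to_parent(down[c, ])  # other children
    A <- up[v, ] + sib_contrib
    up[c, ] <- pmin(A, min(A) + 1)
  }

  node_sets <- lapply(seq_len(n_node), function(v) {
    S[down[v, ] + up[v, ] == min_changes]
  })

  # per-edge change indicators over all most-parsimonious reconstructions
  edge_info <- purrr::map_dfr(seq_len(nrow(edges)), function(k) {
    v <- edges[k, 1]; c <- edges[k, 2]
    A <- up[v, ] + (down[v, ] - contrib_to_parent(down[c, ]))
    same <- min(A + down[c, ])
    diff <- Inf
    if (K > 1) {
      for (a in seq_len(K)) {
        best_other <- min(down[c, -a]) + 1
        diff <- min(diff, A[a] + best_other)
      }
    }
    tibble(parent = v, child = c,
           change_in_some = isTRUE(diff == min_changes),
           change_in_all = isTRUE(same > min_changes))
  })

  # one deterministic MP reconstruction: lexicographic minimum at every tie
  recon <- character(n_node)
  recon[root] <- S[which(down[root, ] == min_changes)][1]
  for (k in rev(seq_len(nrow(edges)))) {
    v <- edges[k, 1]; c <- edges[k, 2]
    cost_c <- down[c, ] + (S != recon[v])
    recon[c] <- S[which(cost_c == min(cost_c))][1]
  }

  structure(list(min_changes = unname(min_changes), states = S, tree = tree,
                 node_sets = node_sets, edges = edge_info,
                 reconstruction = recon, n_leaves = n_tip),
            class = "nor_parsimony")
}

#' Classify inferred NOR jumps by subgenome
#'
#' Labels every state change of the deterministic most-parsimonious
#' reconstruction as intra-subgenome (e.g. 3L to 4L), inter-subgenome
#' (e.g. 4L to 6S), or `n/a` when either state lacks a subgenome suffix
#' (e.g. a diploid's "7").
#'
#' @param result A `nor_parsimony` object from [fitch_parsimony()].
#' @return A list with `jumps` (tibble: edge, `from`, `to`,
#'   `subgenome_class`) and counts `n_intra`, `n_inter`, `n_na`;
#'   `sum(jumps)` equals `min_changes`.
#' @export
classify_jumps <- function(result) {
  stopifnot(inherits(result, "nor_parsimony"))
  recon <- result$reconstruction
  edges <- result$edges
  changed <- edges[recon[edges$parent] != recon[edges$child], ]
  jumps <- changed %>%
    mutate(from = recon[.data$parent], to = recon[.data$child],
           from_sub = subgenome_of(.data$from), to_sub = subgenome_of(.data$to),
           subgenome_class = dplyr::case_when(
             .data$from_sub == "none" | .data$to_sub == "none" ~ "n/a",
             .data$from_sub == .data$to_sub ~ "intra",
             TRUE ~ "inter")) %>%
    select("parent", "child", "from", "to", "subgenome_class")
  list(jumps = jumps,
       n_intra = sum(jumps$subgenome_class == "intra"),
       n_inter = sum(jumps$subgenome_class == "inter"),
       n_na = sum(jumps$subgenome_class == "n/a"))
}

#' @export
print.nor_parsimony <- function(x, ...) {
  cat(sprintf("NOR parsimony over %d leaves, %d states (%s)\n",
              x$n_leaves, length(x$states), paste(x$states, collapse = ", ")))
  cat(sprintf("  minimum number of jumps: %d\n", x$min_changes))
  root_set <- x$node_sets[[x$n_leaves + 1L]]
  cat("  root state set:", paste(root_set, collapse = ", "), "\n")
  invisible(x)
}
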