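# Shared builders and independent oracles used across the suite.

table2_template <- function() {
  read_template(karyomorph_example("table2_template.csv"))
}

trop_map <- function() {
  read_marker_map(karyomorph_example("markers_tropicalis.csv"), role = "reference")
}

# measurement rows for one chromosome (two identical chromatids unless noise)
meas_rows <- function(metaphase, object, p, q) {
  tibble::tibble(metaphase_id = metaphase, object_id = object,
                 chromatid_index = 1:2, p_len = p, q_len = q)
}

# random karyotype template whose copy-weighted l_pct sums to exactly 100
random_template <- function(n_types = 6, copies = 2, seed = 1) {
  set.seed(seed)
  l <- runif(n_types, 1, 5)
  l <- l / sum(l) * (100 / copies)
  i <- runif(n_types, 8, 50)
  tpl <- tibble::tibble(
    type_label = sprintf("T%02d", seq_len(n_types)),
    l_pct_median = l,
    i_median = i,
    category = classify_chromosome(i),
    subgenome = "none")
  attr(tpl, "ploidy_copies") <- as.integer(copies)
  tpl
}

# exhaustive-minimum oracle for the assignment problem (one copy per type)
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost)
  perms <- gtools_permutations(n)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    tot <- sum(cost[cbind(seq_len(n), perms[r, ])])
    if (tot < best) best <- tot
  }
  best
}

# all permutations of 1..n without external dependencies
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# exhaustive-minimum oracle for unordered parsimony: enumerate every
# ancestral state assignment and count changed edges
brute_force_parsimony <- function(tree, states) {
  S <- sort(unique(unname(states[tree$tip.label])))
  E <- tree$edge
  nn <- tree$Nnode
  grid <- expand.grid(rep(list(S), nn), stringsAsFactors = FALSE)
  tipv <- unname(states[tree$tip.label])
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(tipv, unlist(grid[r, ], use.names = FALSE))
    ch <- sum(assign_all[E[, 1]] != assign_all[E[, 2]])
    if (ch < best) best <- ch
  }
  best
}

# random rooted tree with states drawn from a small alphabet
random_state_tree <- function(n_leaves, n_states, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
  states <- setNames(sample(paste0("s", seq_len(n_states)), n_leaves, replace = TRUE),
                     tree$tip.label)
  list(tree = tree, states = states)
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
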