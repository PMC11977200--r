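# Template-based chromosome identification: each measured chromosome of a
# metaphase is assigned to a karyotype-template type by globally optimal
# bipartite matching in normalized (l_pct, i) feature space, with template
# types duplicated once per ploidy copy.

# Square linear assignment problem by shortest augmenting paths
# (Jonker-Volgenant). Returns, for each row, the column it is assigned to.
# Deterministic: scan order breaks cost ties.
solve_lap <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1)      # column potentials, index 1 = dummy column
  p <- integer(n + 1)      # p[j]: row currently assigned to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq.int(2L, n + 1L)) assignment[p[j]] <- j - 1L
  assignment
}

#' Assign measured chromosomes to karyotype-template types
#'
#' Within each metaphase, every measured chromosome is matched to a template
#' type so that the total matching cost is minimal. The cost of pairing an
#' object with a type is the Euclidean distance between their `(l_pct, i)`
#' coordinates after scaling each axis by the dispersion (standard
#' deviation) of the template values on that axis; each type provides
#' `ploidy_copies` slots. The optimum is computed exactly (shortest
#' augmenting paths), so the result does not depend on input row order.
#'
#' An object is flagged ambiguous when the costs of its best and second-best
#' template types differ by less than `ambiguity_tol` (in normalized cost
#' units): morphologically similar chromosomes cannot be told apart reliably
#' by length and centromeric index alone.
#'
#' @param metrics Tibble from [compute_metrics()] (any number of metaphases).
#' @param template Karyotype template from [read_template()].
#' @param ambiguity_tol Ambiguity threshold, default 0.05.
#' @return A `karyo_assignment` tibble: `metaphase_id`, `object_id`,
#'   `assigned_type`, `cost`, `ambiguous`, plus a `total_cost` attribute
#'   (per-metaphase totals).
#' @export
assign_chromosomes <- function(metrics, template, ambiguity_tol = 0.05) {
  copies <- attr(template, "ploidy_copies") %||% 2L
  template <- template %>% arrange(.data$type_label)   # lexicographic slot order
  dup <- duplicated(template[, c("l_pct_median", "i_median")])
  if (any(dup)) {
    warn(sprintf("template has duplicate (l_pct, i) points (e.g. %s); assignment between them is arbitrary",
                 template$type_label[which(dup)[1]]))
  }
  sd_l <- stats::sd(template$l_pct_median)
  sd_i <- stats::sd(template$i_median)
  # template lengths renormalized so the copy-weighted total is exactly 100%,
  # matching the scale of measured l_pct (printed medians may sum slightly off)
  t_l <- template$l_pct_median * 100 / (sum(template$l_pct_median) * copies)
  slot_type <- rep(template$type_label, each = copies)
  slot_l <- rep(t_l, each = copies)
  slot_i <- rep(template$i_median, each = copies)

  res <- metrics %>%
    arrange(.data$metaphase_id, .data$object_id) %>%
    group_by(.data$metaphase_id) %>%
    dplyr::group_map(function(df, key) {
      n_obj <- nrow(df)
      if (n_obj != length(slot_type)) {
        abort(sprintf("metaphase %s: expected %d chromosomes (%d types x %d copies), found %d",
                      key$metaphase_id, length(slot_type),
                      nrow(template), copies, n_obj),
              class = "karyomorph_cardinality_error")
      }
      cost <- outer(df$l_pct / sd_l, slot_l / sd_l, "-")^2 +
        outer(df$i / sd_i, slot_i / sd_i, "-")^2
      cost <- sqrt(cost)
      sol <- solve_lap(cost)
      # ambiguity: distance gap between the two closest distinct types
      type_cost <- sqrt(outer(df$l_pct / sd_l, t_l / sd_l, "-")^2 +
                          outer(df$i / sd_i, template$i_median / sd_i, "-")^2)
      gaps <- apply(type_cost, 1, function(r) {
        s <- sort(r)
        s[2] - s[1]
      })
      tibble(metaphase_id = key$metaphase_id,
             object_id = df$object_id,
             assigned_type = slot_type[sol],
             cost = cost[cbind(seq_len(n_obj), sol)],
             ambiguous = gaps < ambiguity_tol)
    }) %>%
    bind_rows()
  totals <- res %>% group_by(.data$metaphase_id) %>%
    summarise(total_cost = sum(.data$cost), .groups = "drop")
  attr(res, "total_cost") <- totals
  class(res) <- c("karyo_assignment", class(res))
  res
}

#' Consensus karyotype across assigned metaphases
#'
#' Combines per-metaphase assignments into a species-level karyotype report:
#' the modal chromosome number (2n), per-type medians and quartiles
#' (delegating to [aggregate_karyotype()]), and a census of Levan categories
#' (counts of m/sm/st/a/t chromosome pairs). Metaphases whose chromosome
#' count deviates from the mode are listed as outliers rather than causing
#' failure.
#'
#' @param assignment A `karyo_assignment` from [assign_chromosomes()].
#' @param metrics The matching metrics tibble from [compute_metrics()].
#' @return A `karyo_consensus` list: `two_n`, `counts` (per metaphase),
#'   `outliers`, `summary` (a `karyo_summary`), `census`, and a
#'   template-shaped tibble `template` of per-type medians.
#' @export
consensus_karyotype <- function(assignment, metrics) {
  labelled <- metrics %>%
    left_join(as_tibble(assignment)[, c("metaphase_id", "object_id", "assigned_type")],
              by = c("metaphase_id", "object_id"))
  counts <- labelled %>% count(.data$metaphase_id, name = "n_chromosomes")
  two_n <- as.integer(names(sort(table(counts$n_chromosomes), decreasing = TRUE))[1])
  outliers <- counts %>% filter(.data$n_chromosomes != two_n)
  summary <- aggregate_karyotype(labelled)
  per_type <- summary %>%
    filter(.data$metric == "l_pct") %>% select("type", l_pct_median = "Q2", "category") %>%
    left_join(summary %>% filter(.data$metric == "i") %>% select("type", i_median = "Q2"),
              by = "type") %>%
    mutate(subgenome = subgenome_of(.data$type)) %>%
    rename(type_label = "type")
  census <- per_type %>% count(.data$category, name = "n_pairs")
  structure(list(two_n = two_n, counts = counts, outliers = outliers,
                 summary = summary, census = census, template = per_type),
            class = "karyo_consensus")
}

#' @export
print.karyo_consensus <- function(x, ...) {
  cat(sprintf("Consensus karyotype over %d metaphase(s): 2n = %d\n",
              nrow(x$counts), x$two_n))
  if (nrow(x$outliers) > 0) {
    cat(sprintf("  %d metaphase(s) deviate from the modal count\n", nrow(x$outliers)))
  }
  cat("Category census (haploid pairs): ",
      paste(sprintf("%d %s", x$census$n_pairs, x$census$category), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
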