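# Chromosome morphometrics: per-chromosome metrics from chromatid
# measurements, Levan classification, per-type aggregation across metaphases,
# and homeolog divergence statistics.

#' Average chromatid measurements into per-chromosome arm lengths
#'
#' Metaphase chromosomes consist of two sister chromatids; arm lengths are
#' measured per chromatid and averaged per physical chromosome before any
#' ratio is computed (ratios of averaged lengths are more stable than
#' averages of ratios). Objects represented by a single chromatid pass
#' through with a warning.
#'
#' @param measurements Tibble from [read_measurements()].
#' @return A tibble with one row per (metaphase_id, object_id) and columns
#'   `p`, `q` (mean chromatid arm lengths, pixels) and `n_chromatids`.
#' @examples
#' m <- tibble::tibble(metaphase_id = "m1", object_id = "c1",
#'                     chromatid_index = 1:2, p_len = c(10, 12), q_len = c(30, 28))
#' chromatids_to_chromosomes(m)
#' @export
chromatids_to_chromosomes <- function(measurements) {
  measurements <- validate_measurements(measurements)
  out <- measurements %>%
    group_by(.data$metaphase_id, .data$object_id) %>%
    summarise(p = mean(.data$p_len), q = mean(.data$q_len),
              n_chromatids = dplyr::n(), .groups = "drop")
  if (any(out$n_chromatids < 2)) {
    singles <- out %>% filter(.data$n_chromatids < 2)
    warn(sprintf("%d object(s) measured on a single chromatid (e.g. %s/%s); values passed through",
                 nrow(singles), singles$metaphase_id[1], singles$object_id[1]))
  }
  out
}

#' Compute chromosome metrics from arm lengths
#'
#' For each chromosome: relative length `l_pct = 100 (p + q) / total` where
#' `total` is the summed length of all chromosomes in the same metaphase;
#' arm ratios `r1 = p/q` and `r2 = q/p`; and the centromeric index
#' `i = 100 p / (p + q)` on the 0-50 scale (short arm as a percentage of the
#' chromosome). Arms are oriented so that p <= q; rows supplied with p > q
#' are swapped and flagged in `swapped` rather than rejected, since a
#' measurement table cannot encode arm identity beyond relative length.
#'
#' @param chromosomes Tibble with columns `metaphase_id`, `object_id`, `p`,
#'   `q` (from [chromatids_to_chromosomes()]), or raw measurements from
#'   [read_measurements()] (chromatids are averaged first).
#' @return The input with columns `l_pct`, `r1`, `r2`, `i`, `category`,
#'   `swapped` added.
#' @examples
#' ch <- tibble::tibble(metaphase_id = "m1", object_id = c("a", "b"),
#'                      p = c(1, 1), q = c(1, 3))
#' compute_metrics(ch)
#' @export
compute_metrics <- function(chromosomes) {
  if (all(c("p_len", "q_len", "chromatid_index") %in% names(chromosomes))) {
    chromosomes <- chromatids_to_chromosomes(chromosomes)
  }
  stopifnot(all(c("metaphase_id", "object_id", "p", "q") %in% names(chromosomes)))
  if (any(!(chromosomes$p > 0) | !(chromosomes$q > 0))) {
    abort_domain("arm lengths must be positive")
  }
  out <- chromosomes %>%
    mutate(swapped = .data$p > .data$q,
           p2 = pmin(.data$p, .data$q), q2 = pmax(.data$p, .data$q),
           p = .data$p2, q = .data$q2) %>%
    select(-"p2", -"q2") %>%
    group_by(.data$metaphase_id) %>%
    mutate(metaphase_total = sum(.data$p + .data$q)) %>%
    ungroup()
  if (any(out$metaphase_total <= 0)) abort_domain("metaphase total length must be positive")
  out %>%
    mutate(l_pct = 100 * (.data$p + .data$q) / .data$metaphase_total,
           r1 = .data$p / .data$q,
           r2 = .data$q / .data$p,
           i = 100 * .data$p / (.data$p + .data$q),
           category = classify_chromosome(.data$i)) %>%
    select(-"metaphase_total")
}

#' Classify a centromeric index into a Levan category
#'
#' Interval rule on the 0-50 centromeric-index scale: `i >= 37.5` is
#' metacentric (m), `25 <= i < 37.5` submetacentric (sm), `12.5 <= i < 25`
#' subtelocentric (st), `0 < i < 12.5` acrocentric (a), and `i = 0`
#' telocentric (t, no p arm). Lower bounds are inclusive.
#'
#' @param i Numeric vector of centromeric indices in \[0, 50\].
#' @return Character vector of categories (`"m"`, `"sm"`, `"st"`, `"a"`, `"t"`).
#' @examples
#' classify_chromosome(c(41.35, 35.85, 24.24, 5, 0))
#' @export
classify_chromosome <- function(i) {
  if (any(is.na(i)) || any(i < 0 | i > 50)) {
    abort_domain("centromeric index must lie in [0, 50]")
  }
  dplyr::case_when(
    i >= 37.5 ~ "m",
    i >= 25 ~ "sm",
    i >= 12.5 ~ "st",
    i > 0 ~ "a",
    TRUE ~ "t"
  )
}

#' Aggregate per-chromosome metrics into per-type medians and quartiles
#'
#' For every assigned chromosome type and each of the metrics `l_pct`, `r1`
#' and `i`: the median (Q2) and the lower/upper quartiles (Q1, Q3) across
#' metaphases, computed independently per metric (the median of `i` is not
#' derived from the median of `r1`). Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7). The per-type
#' `category` is assigned from the median `i`.
#'
#' @param metrics Tibble from [compute_metrics()] carrying an
#'   `assigned_type` column.
#' @return A `karyo_summary` tibble: one row per (type, metric) with columns
#'   `Q1`, `Q2`, `Q3`, `n`, `category`.
#' @export
aggregate_karyotype <- function(metrics) {
  if (is.null(metrics[["assigned_type"]]) || any(is.na(metrics$assigned_type))) {
    abort_validation("every chromosome must carry an assigned_type before aggregation")
  }
  long <- metrics %>%
    select("assigned_type", "l_pct", "r1", "i") %>%
    tidyr::pivot_longer(c("l_pct", "r1", "i"), names_to = "metric", values_to = "value")
  out <- long %>%
    group_by(type = .data$assigned_type, .data$metric) %>%
    summarise(Q1 = quantile(.data$value, 0.25, type = 7, names = FALSE),
              Q2 = median(.data$value),
              Q3 = quantile(.data$value, 0.75, type = 7, names = FALSE),
              n = dplyr::n(), .groups = "drop")
  med_i <- out %>% filter(.data$metric == "i") %>%
    mutate(category = classify_chromosome(.data$Q2)) %>%
    select("type", "category")
  out <- out %>% left_join(med_i, by = "type") %>% arrange(.data$type, .data$metric)
  class(out) <- c("karyo_summary", class(out))
  out
}

# pair homeologs by shared base numeral: 1L <-> 1S, 9_10L <-> 9_10S, 2a <-> 2b
homeolog_pairs <- function(types) {
  tibble(type = types,
         base = base_chromosome(types),
         sub = subgenome_of(types)) %>%
    filter(.data$sub != "none")
}

#' Interquartile-range overlap between homeologous chromosomes
#'
#' The extent of morphological divergence of each homeolog pair is measured
#' by whether their Q1-Q3 intervals overlap, and pairs are ranked by the gap
#' between the two intervals (0 when they overlap).
#'
#' @param summary A `karyo_summary` from [aggregate_karyotype()].
#' @param metrics Which metrics to compare (default `l_pct` and `i`).
#' @return Tibble with one row per (pair, metric): the two intervals,
#'   `disjoint`, `gap`, and `divergence_rank` within each metric.
#' @export
homeolog_divergence <- function(summary, metrics = c("l_pct", "i")) {
  pairs <- homeolog_pairs(unique(summary$type))
  orphan <- pairs %>% count(.data$base) %>% filter(.data$n != 2)
  if (nrow(orphan) > 0) {
    abort_validation(sprintf("unpaired homeolog type(s): %s",
                             paste(orphan$base, collapse = ", ")))
  }
  wide <- summary %>%
    filter(.data$metric %in% metrics) %>%
    mutate(base = base_chromosome(.data$type), sub = subgenome_of(.data$type)) %>%
    filter(.data$sub != "none")
  first_sub <- sort(unique(wide$sub))[1]
  out <- wide %>%
    mutate(side = ifelse(.data$sub == first_sub, "a", "b")) %>%
    select("base", "metric", "side", "Q1", "Q3") %>%
    tidyr::pivot_wider(names_from = "side", values_from = c("Q1", "Q3")) %>%
    mutate(disjoint = .data$Q3_a < .data$Q1_b | .data$Q3_b < .data$Q1_a,
           gap = pmax(0, pmax(.data$Q1_a - .data$Q3_b, .data$Q1_b - .data$Q3_a))) %>%
    group_by(.data$metric) %>%
    arrange(dplyr::desc(.data$gap), .data$base, .by_group = TRUE) %>%
    mutate(divergence_rank = row_number()) %>%
    ungroup() %>%
    rename(pair = "base")
  out
}

#' Homeolog divergence by one-way ANOVA with Tukey contrasts
#'
#' A single one-way ANOVA of the chosen metric across all chromosome-type
#' groups, followed by Tukey honest-significant-difference adjustment over
#' all pairwise contrasts; the result is then restricted to the homeolog
#' contrasts (1L-1S, ..., 9_10L-9_10S). Significance codes follow the usual
#' thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, else `ns`.
#'
#' @param metrics Tibble from [compute_metrics()] with `assigned_type`.
#' @param metric `"l_pct"` or `"i"`.
#' @return A `homeolog_anova` object; see [tidy()] and [glance()] methods.
#' @export
homeolog_anova <- function(metrics, metric = c("l_pct", "i")) {
  metric <- arg_match(metric)
  if (is.null(metrics[["assigned_type"]])) {
    abort_validation("metrics must carry an assigned_type column")
  }
  counts <- metrics %>% count(.data$assigned_type)
  small <- counts %>% filter(.data$n < 2)
  if (nrow(small) > 0) {
    abort(sprintf("fewer than 2 observations for group(s): %s",
                  paste(small$assigned_type, collapse = ", ")),
          class = "karyomorph_statistics_error")
  }
  df <- tibble(value = metrics[[metric]],
               type = factor(metrics$assigned_type))
  fit <- aov(value ~ type, data = df)
  anova_tab <- summary(fit)[[1]]
  tukey <- TukeyHSD(fit)$type
  contrasts <- tibble(contrast = rownames(tukey),
                      diff = tukey[, "diff"],
                      tukey_adj_p = tukey[, "p adj"])
  pairs <- homeolog_pairs(levels(df$type)) %>%
    group_by(.data$base) %>% filter(dplyr::n() == 2) %>%
    summarise(t1 = sort(.data$type)[1], t2 = sort(.data$type)[2], .groups = "drop")
  wanted <- c(paste(pairs$t2, pairs$t1, sep = "-"), paste(pairs$t1, pairs$t2, sep = "-"))
  hom <- contrasts %>%
    filter(.data$contrast %in% wanted) %>%
    mutate(pair = base_chromosome(sub("-.*$", "", .data$contrast)),
           significance = significance_code(.data$tukey_adj_p)) %>%
    select("pair", "contrast", "diff", "tukey_adj_p", "significance") %>%
    arrange(.data$pair)
  structure(list(metric = metric,
                 anova_F = anova_tab[1, "F value"],
                 anova_p = anova_tab[1, "Pr(>F)"],
                 df_between = anova_tab[1, "Df"], df_within = anova_tab[2, "Df"],
                 n = nrow(df), n_groups = nlevels(df$type),
                 comparisons = hom, fit = fit),
            class = "homeolog_anova")
}

significance_code <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' @export
print.homeolog_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s across %d chromosome types (n = %d)\n",
              x$metric, x$n_groups, x$n))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.3g\n", x$df_between, x$df_within,
              x$anova_F, x$anova_p))
  cat("Homeolog contrasts (Tukey-adjusted):\n")
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}
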