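# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.karyo_summary <- function(x, ...) as_tibble(x)

#' @export
tidy.karyo_assignment <- function(x, ...) as_tibble(x)

#' @export
glance.karyo_assignment <- function(x, ...) {
  totals <- attr(x, "total_cost")
  tibble(n_metaphases = nrow(totals),
         total_cost = sum(totals$total_cost),
         mean_cost = mean(x$cost),
         n_ambiguous = sum(x$ambiguous))
}

#' @export
tidy.homeolog_anova <- function(x, ...) x$comparisons

#' @export
glance.homeolog_anova <- function(x, ...) {
  tibble(metric = x$metric, statistic = x$anova_F, p.value = x$anova_p,
         df = x$df_between, df.residual = x$df_within,
         nobs = x$n, n_groups = x$n_groups)
}

#' @export
tidy.karyo_consensus <- function(x, ...) x$template

#' @export
glance.karyo_consensus <- function(x, ...) {
  census <- setNames(as.list(x$census$n_pairs), paste0("n_", x$census$category))
  dplyr::bind_cols(tibble(two_n = x$two_n, n_metaphases = nrow(x$counts),
                          n_outlier_metaphases = nrow(x$outliers)),
                   as_tibble(census))
}

#' @export
tidy.nor_parsimony <- function(x, ...) {
  labels <- c(x$tree$tip.label, rep(NA_character_, x$tree$Nnode))
  x$edges %>%
    mutate(child_label = labels[.data$child],
           parent_state = x$reconstruction[.data$parent],
           child_state = x$reconstruction[.data$child],
           parent_state_set = purrr::map_chr(.data$parent,
                                             ~ paste(x$node_sets[[.x]], collapse = "|")),
           child_state_set = purrr::map_chr(.data$child,
                                            ~ paste(x$node_sets[[.x]], collapse = "|")))
}

#' @export
glance.nor_parsimony <- function(x, ...) {
  jumps <- classify_jumps(x)
  tibble(min_changes = x$min_changes, n_leaves = x$n_leaves,
         n_states = length(x$states),
         n_intra_subgenome = jumps$n_intra,
         n_inter_subgenome = jumps$n_inter,
         n_subgenome_na = jumps$n_na)
}

#' @export
tidy.rdna_summary <- function(x, ...) {
  flags <- function(types, what) {
    tibble(chromosome = types, feature = rep(what, length(types)))
  }
  bind_rows(
    x$nor_locations %>% mutate(feature = "nor") %>%
      select("chromosome", "feature", "arm", "region"),
    flags(x$five_s_missing, "5S_missing"),
    flags(x$both_arm_5s, "5S_both_arms"),
    flags(x$colocalized, "28S_5S_colocalized"),
    flags(x$low_intensity, "low_intensity")
  )
}

#' @export
glance.rdna_summary <- function(x, ...) {
  tibble(nor_count = x$nor_count,
         n_types = x$n_types,
         n_5s_missing = length(x$five_s_missing),
         n_5s_both_arms = length(x$both_arm_5s),
         n_colocalized = length(x$colocalized),
         n_low_intensity = length(x$low_intensity))
}
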