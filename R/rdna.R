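# rDNA / NOR FISH pattern summarisation.

#' Summarise rDNA FISH signal patterns against a karyotype template
#'
#' From a FISH signal table: the number and locations of NORs (28S rDNA
#' loci, deduplicated by chromosome type), the chromosome types lacking any
#' 5S signal, types with 5S on both arms, types carrying both 28S and 5S
#' (co-localisation), and types flagged low-intensity.
#'
#' @param signals FISH signal tibble from [read_fish_signals()].
#' @param template Karyotype template giving the complete set of chromosome
#'   types.
#' @return An `rdna_summary` list with elements `nor_count`,
#'   `nor_locations` (tibble chromosome/arm/region), `five_s_missing`,
#'   `both_arm_5s`, `colocalized`, `low_intensity` (character vectors).
#' @examples
#' sig <- read_fish_signals(karyomorph_example("rdna_signals_pygmaeus.csv"))
#' tpl <- read_template(karyomorph_example("table2_template.csv"))
#' summarize_rdna(sig, tpl)
#' @export
summarize_rdna <- function(signals, template) {
  types <- template$type_label
  unknown <- setdiff(unique(signals$chromosome), types)
  if (length(unknown) > 0) {
    abort_validation(sprintf("signal on unknown chromosome label(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  nor_locations <- signals %>%
    filter(.data$probe == "28S") %>%
    distinct(.data$chromosome, .keep_all = TRUE) %>%
    select("chromosome", "arm", "region")
  five_s <- signals %>% filter(.data$probe == "5S")
  with_5s <- unique(five_s$chromosome)
  both_arm <- five_s %>%
    group_by(.data$chromosome) %>%
    summarise(both = any(.data$arm == "both") ||
                all(c("p", "q") %in% .data$arm), .groups = "drop") %>%
    filter(.data$both) %>% pull(.data$chromosome)
  coloc <- intersect(nor_locations$chromosome, with_5s)
  low <- signals %>% filter(.data$intensity == "low") %>%
    pull(.data$chromosome) %>% unique() %>% sort()
  structure(list(
    nor_count = nrow(nor_locations),
    nor_locations = nor_locations,
    five_s_missing = sort(setdiff(types, with_5s)),
    both_arm_5s = sort(both_arm),
    colocalized = sort(coloc),
    low_intensity = low,
    n_types = length(types)
  ), class = "rdna_summary")
}

#' @export
print.rdna_summary <- function(x, ...) {
  cat(sprintf("rDNA FISH summary over %d chromosome types\n", x$n_types))
  cat(sprintf("  NORs (28S): %d at %s\n", x$nor_count,
              paste(sprintf("(%s, %s, %s)", x$nor_locations$chromosome,
                            x$nor_locations$arm, x$nor_locations$region),
                    collapse = "; ")))
  cat("  5S missing from:", paste(x$five_s_missing, collapse = ", "), "\n")
  cat("  5S on both arms:", paste(x$both_arm_5s, collapse = ", "), "\n")
  cat("  28S/5S co-localised:", paste(x$colocalized, collapse = ", "), "\n")
  cat("  low-intensity:", paste(x$low_intensity, collapse = ", "), "\n")
  invisible(x)
}
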