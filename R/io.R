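# Readers and writers for the tabular and tree formats the pipeline touches.
# All readers validate fully: a malformed file raises a typed condition
# (karyomorph_schema_error / karyomorph_validation_error), never a partially
# constructed object. CSV is the default dialect; files with a .tsv extension
# are read tab-delimited. Lines starting with '#' are comments.

read_delim_auto <- function(path, col_types) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  reader <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) readr::read_tsv else readr::read_csv
  # missing columns are reported as typed schema errors downstream, not as
  # readr parser-name warnings
  suppressWarnings(reader(path, col_types = col_types, comment = "#",
                          progress = FALSE, show_col_types = FALSE))
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf("%s: missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
}

#' Read per-chromatid arm-length measurements
#'
#' Expects columns `metaphase_id`, `object_id`, `chromatid_index`, `p_len`,
#' `q_len`: one row per chromatid, arm lengths in pixels as measured on a
#' metaphase image. An object id identifies one physical chromosome within
#' its metaphase, so each object has at most two chromatid rows.
#'
#' @param path CSV (or TSV) file with a header row.
#' @return A tibble of validated measurements.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' writeLines(c("metaphase_id,object_id,chromatid_index,p_len,q_len",
#'              "m1,c1,1,10,30", "m1,c1,2,12,28"), tmp)
#' read_measurements(tmp)
#' @export
read_measurements <- function(path) {
  df <- read_delim_auto(path, readr::cols(
    metaphase_id = readr::col_character(),
    object_id = readr::col_character(),
    chromatid_index = readr::col_integer(),
    p_len = readr::col_double(),
    q_len = readr::col_double()
  ))
  check_columns(df, c("metaphase_id", "object_id", "chromatid_index", "p_len", "q_len"), path)
  validate_measurements(df, context = path)
}

validate_measurements <- function(df, context = "measurements") {
  df <- as_tibble(df)
  bad_len <- which(!(df$p_len > 0) | !(df$q_len > 0))
  if (length(bad_len) > 0) {
    abort_validation(sprintf("%s: nonpositive arm length in row(s) %s",
                             context, paste(head(bad_len, 5), collapse = ", ")))
  }
  bad_idx <- which(!df$chromatid_index %in% c(1L, 2L))
  if (length(bad_idx) > 0) {
    abort_validation(sprintf("%s: chromatid_index must be 1 or 2 (row %d)",
                             context, bad_idx[1]))
  }
  key <- paste(df$metaphase_id, df$object_id, df$chromatid_index)
  if (anyDuplicated(key)) {
    abort_validation(sprintf(
      "%s: duplicate (metaphase_id, object_id, chromatid_index) key in row %d",
      context, anyDuplicated(key)))
  }
  df
}

#' Write measurements back to CSV
#'
#' Inverse of [read_measurements()]; comment lines are not preserved.
#'
#' @param measurements Tibble as returned by [read_measurements()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  validate_measurements(measurements)
  readr::write_csv(measurements, path)
  invisible(path)
}

#' Read a species marker-locus map
#'
#' Columns: `species`, `gene`, `chromosome`, `arm` (p/q), `rank` (1-based
#' from the centromere outward along the arm, may be empty), `region`
#' (telomeric/pericentromeric/interstitial/unknown), `copy` (subgenome copy
#' tag: L/S/a/b, or `none` when the probe is not resolved to one copy).
#'
#' `(gene, copy)` must be unique, except that unresolved copies
#' (`copy == "none"`) may repeat across different chromosomes — the situation
#' of a probe hybridising to both homeologs.
#'
#' @param path CSV/TSV file.
#' @param role Map role in a comparison, `"reference"` or `"target"`.
#' @return A tibble of marker loci with a `role` attribute.
#' @examples
#' read_marker_map(karyomorph_example("markers_tropicalis.csv"))
#' @export
read_marker_map <- function(path, role = c("target", "reference")) {
  role <- arg_match(role)
  df <- read_delim_auto(path, readr::cols(
    species = readr::col_character(), gene = readr::col_character(),
    chromosome = readr::col_character(), arm = readr::col_character(),
    rank = readr::col_integer(), region = readr::col_character(),
    copy = readr::col_character()
  ))
  check_columns(df, c("species", "gene", "chromosome", "arm"), path)
  if (is.null(df[["rank"]])) df$rank <- NA_integer_
  if (is.null(df[["region"]])) df$region <- "unknown"
  if (is.null(df[["copy"]])) df$copy <- "none"
  validate_marker_map(df, context = path, role = role)
}

validate_marker_map <- function(df, context = "marker map", role = "target") {
  df <- as_tibble(df)
  df$region[is.na(df$region)] <- "unknown"
  df$copy[is.na(df$copy)] <- "none"
  bad_arm <- which(!df$arm %in% c("p", "q"))
  if (length(bad_arm) > 0) {
    abort_validation(sprintf("%s: unknown arm code '%s' in row %d (expected p or q)",
                             context, df$arm[bad_arm[1]], bad_arm[1]))
  }
  if (any(!is.na(df$rank) & df$rank < 1)) {
    abort_validation(sprintf("%s: rank must be >= 1 when present", context))
  }
  bad_region <- which(!df$region %in% c("telomeric", "pericentromeric", "interstitial", "unknown"))
  if (length(bad_region) > 0) {
    abort_validation(sprintf("%s: unknown region '%s' in row %d",
                             context, df$region[bad_region[1]], bad_region[1]))
  }
  if (any(is.na(df$chromosome) | df$chromosome == "")) {
    abort_validation(sprintf("%s: missing chromosome label", context))
  }
  tagged <- df[df$copy != "none", ]
  key <- paste(tagged$gene, tagged$copy)
  if (anyDuplicated(key)) {
    abort_validation(sprintf("%s: duplicate (gene, copy) entry: %s",
                             context, key[anyDuplicated(key)]))
  }
  untagged <- df[df$copy == "none", ]
  key2 <- paste(untagged$gene, untagged$chromosome)
  if (anyDuplicated(key2)) {
    abort_validation(sprintf("%s: duplicate unresolved-copy entry: %s",
                             context, key2[anyDuplicated(key2)]))
  }
  attr(df, "role") <- role
  df
}

#' Read a FISH signal table
#'
#' Columns: `probe` (28S, 5S or a gene symbol), `chromosome`, `arm`
#' (p/q/both), `region`, `intensity` (normal/low). `arm = "both"` is reserved
#' for probes reported per chromosome rather than per arm (e.g. a 5S signal
#' on both arms of one chromosome).
#'
#' @param path CSV/TSV file.
#' @return A tibble of signals.
#' @examples
#' read_fish_signals(karyomorph_example("rdna_signals_pygmaeus.csv"))
#' @export
read_fish_signals <- function(path) {
  df <- read_delim_auto(path, readr::cols(
    probe = readr::col_character(), chromosome = readr::col_character(),
    arm = readr::col_character(), region = readr::col_character(),
    intensity = readr::col_character()
  ))
  check_columns(df, c("probe", "chromosome", "arm", "region", "intensity"), path)
  validate_fish_signals(df, context = path)
}

validate_fish_signals <- function(df, context = "signals") {
  df <- as_tibble(df)
  bad_arm <- which(!df$arm %in% c("p", "q", "both"))
  if (length(bad_arm) > 0) {
    abort_validation(sprintf("%s: unknown arm code '%s' in row %d",
                             context, df$arm[bad_arm[1]], bad_arm[1]))
  }
  bad_int <- which(!df$intensity %in% c("normal", "low"))
  if (length(bad_int) > 0) {
    abort_validation(sprintf("%s: unknown intensity '%s' in row %d",
                             context, df$intensity[bad_int[1]], bad_int[1]))
  }
  df
}

#' Read a karyotype template
#'
#' A template lists, per haploid chromosome type, the reference medians of
#' relative length (`l_pct_median`, % of the haploid complement), centromeric
#' index (`i_median`, 0-50 scale) and the Levan `category`, plus a
#' `subgenome` tag. Extra columns (such as an `r1_median` arm ratio) are
#' preserved.
#'
#' The copy-weighted length medians should account for the whole metaphase:
#' `sum(l_pct_median) * ploidy_copies` is expected to be ~100% (a deviation
#' beyond 1 percentage point raises a warning, not an error — published
#' medians need not sum exactly). A category inconsistent with
#' [classify_chromosome()] applied to `i_median` also warns.
#'
#' @param path CSV/TSV file with columns `type_label`, `l_pct_median`,
#'   `i_median`, `category`, `subgenome`.
#' @param ploidy_copies Copies of each type per metaphase (2 in a
#'   biologically diploid karyotype).
#' @return A tibble with a `ploidy_copies` attribute.
#' @examples
#' read_template(karyomorph_example("table2_template.csv"))
#' @export
read_template <- function(path, ploidy_copies = 2L) {
  df <- read_delim_auto(path, readr::cols(
    type_label = readr::col_character(),
    l_pct_median = readr::col_double(),
    i_median = readr::col_double(),
    category = readr::col_character(),
    subgenome = readr::col_character(),
    .default = readr::col_double()
  ))
  check_columns(df, c("type_label", "l_pct_median", "i_median", "category"), path)
  if (is.null(df[["subgenome"]])) df$subgenome <- subgenome_of(df$type_label)
  validate_template(df, ploidy_copies = ploidy_copies, context = path)
}

validate_template <- function(df, ploidy_copies = 2L, context = "template") {
  df <- as_tibble(df)
  if (anyDuplicated(df$type_label)) {
    abort_validation(sprintf("%s: duplicate type_label '%s'",
                             context, df$type_label[anyDuplicated(df$type_label)]))
  }
  if (any(df$i_median <= 0 | df$i_median > 50)) {
    abort_validation(sprintf("%s: i_median must lie in (0, 50]", context))
  }
  total <- sum(df$l_pct_median) * ploidy_copies
  if (abs(total - 100) > 1) {
    warn(sprintf("%s: copy-weighted l_pct_median sums to %.2f%%, expected ~100%%",
                 context, total))
  }
  implied <- classify_chromosome(df$i_median)
  off <- which(implied != df$category)
  if (length(off) > 0) {
    warn(sprintf("%s: category of %s inconsistent with its i_median (printed %s, classifier %s)",
                 context, df$type_label[off[1]], df$category[off[1]], implied[off[1]]))
  }
  attr(df, "ploidy_copies") <- as.integer(ploidy_copies)
  df
}

#' Read a rooted species tree from a newick file
#'
#' @param path Newick file containing a single rooted tree. Polytomies are
#'   preserved.
#' @return An [ape::read.tree()] `phylo` object.
#' @examples
#' tr <- read_tree(karyomorph_example("nor_tree.nwk"))
#' ape::Ntip(tr)
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (sum(stringr::str_count(txt, "\\(")) != sum(stringr::str_count(txt, "\\)"))) {
    abort(sprintf("%s: unbalanced parentheses in newick string", path),
          class = "karyomorph_parse_error")
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    abort(sprintf("%s: could not parse newick tree", path),
          class = "karyomorph_parse_error")
  }
  if (anyDuplicated(tree$tip.label)) {
    abort_validation(sprintf("%s: duplicate leaf label '%s'",
                             path, tree$tip.label[anyDuplicated(tree$tip.label)]))
  }
  tree
}

#' Read a species-to-NOR-chromosome state table
#'
#' Columns `species`, `nor_chromosome`; at most one state per species.
#' Species absent from the table are treated as stateless and are pruned
#' before parsimony, never imputed.
#'
#' @param path CSV/TSV file.
#' @return A tibble with columns `species` and `nor_chromosome`.
#' @examples
#' read_nor_states(karyomorph_example("nor_states.csv"))
#' @export
read_nor_states <- function(path) {
  df <- read_delim_auto(path, readr::cols(
    species = readr::col_character(),
    nor_chromosome = readr::col_character()
  ))
  check_columns(df, c("species", "nor_chromosome"), path)
  if (anyDuplicated(df$species)) {
    abort_validation(sprintf("%s: more than one NOR state for species '%s'",
                             path, df$species[anyDuplicated(df$species)]))
  }
  as_tibble(df)
}
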