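# Rearrangement inference from FISH marker maps: a target species' marker
# placements are compared against a reference (ancestral-proxy) map to call
# translocations, end-to-end fusions (with fused-arm orientation and
# centromere fate) and pericentromeric/paracentric inversions. Resolution is
# arm-level; ranks (1-based from the centromere) refine orientation when
# present. Conflicting markers are reported, never silently dropped.

# subgenome copy a locus belongs to: explicit tag, else the chromosome suffix
effective_copy <- function(map) {
  ifelse(map$copy != "none", map$copy, subgenome_of(map$chromosome))
}

# numeric-aware chromosome ordering ("9" before "10", "9_10" by its prefix)
ref_order <- function(labels) {
  num <- suppressWarnings(as.numeric(stringr::str_extract(labels, "^[0-9]+")))
  order(num, labels)
}

#' Group reference markers into synteny groups
#'
#' One group per reference chromosome, genes ordered along the chromosome by
#' (arm, rank). Every reference gene belongs to exactly one group.
#'
#' @param reference A marker map from [read_marker_map()] used as the
#'   ancestral proxy (e.g. the diploid X. tropicalis map).
#' @return Tibble with columns `ref_chromosome`, `gene`, `arm`, `rank`.
#' @examples
#' trop <- read_marker_map(karyomorph_example("markers_tropicalis.csv"))
#' build_synteny_groups(trop)
#' @export
build_synteny_groups <- function(reference) {
  if (nrow(reference) == 0) abort_validation("reference marker map is empty")
  groups <- reference %>%
    mutate(ref_chromosome = base_chromosome(.data$chromosome)) %>%
    distinct(.data$gene, .data$ref_chromosome, .data$arm, .data$rank)
  multi <- groups %>% distinct(.data$gene, .data$ref_chromosome) %>%
    count(.data$gene) %>% filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort_validation(sprintf("gene(s) mapped to more than one reference chromosome: %s",
                             paste(multi$gene, collapse = ", ")))
  }
  groups %>%
    arrange(.data$ref_chromosome, .data$arm, .data$rank) %>%
    select("ref_chromosome", "gene", "arm", "rank")
}

# per-copy view of a target map with reference group annotations joined on
annotate_target <- function(groups, target) {
  target %>%
    mutate(copy_eff = effective_copy(target),
           target_base = base_chromosome(.data$chromosome)) %>%
    dplyr::inner_join(groups %>% rename(ref_arm = "arm", ref_rank = "rank"),
                      by = "gene")
}

#' Detect translocations of markers between synteny groups
#'
#' For every synteny group and subgenome copy, the group's genes present in
#' the target are partitioned by target chromosome. If a strict minority
#' (fewer than half of the present genes) maps to a different chromosome
#' than the group majority, a translocation moving those genes from the
#' reference chromosome to the minority destination is called. Exact half
#' splits are reported as `ambiguous_split`, not a directed call. Groups
#' whose genes are all absent from the target are skipped with a warning.
#'
#' @param groups Synteny groups from [build_synteny_groups()].
#' @param target Target species marker map.
#' @return Tibble of calls: `kind` (`translocation`/`ambiguous_split`/
#'   `none`), `copy`, `source_chromosome`, `dest_chromosome`, `genes`,
#'   `n_group`.
#' @export
detect_translocation <- function(groups, target) {
  ann <- annotate_target(groups, target)
  absent <- setdiff(unique(groups$ref_chromosome), unique(ann$ref_chromosome))
  if (length(absent) > 0) {
    warn(sprintf("synteny group(s) with no markers in target, skipped: %s",
                 paste(absent, collapse = ", ")))
  }
  calls <- ann %>%
    group_by(.data$copy_eff, .data$ref_chromosome) %>%
    dplyr::group_map(function(df, key) {
      tab <- sort(table(df$target_base), decreasing = TRUE)
      major <- names(tab)[1]
      n_present <- nrow(df)
      minors <- df %>% filter(.data$target_base != major)
      if (nrow(minors) == 0) {
        return(tibble(kind = "none", copy = key$copy_eff,
                      source_chromosome = key$ref_chromosome,
                      dest_chromosome = NA_character_, genes = "",
                      n_group = n_present))
      }
      minors %>% group_by(.data$chromosome) %>%
        dplyr::group_map(function(mdf, mkey) {
          kind <- if (nrow(mdf) * 2 < n_present) "translocation" else "ambiguous_split"
          tibble(kind = kind, copy = key$copy_eff,
                 source_chromosome = key$ref_chromosome,
                 dest_chromosome = mkey$chromosome,
                 genes = paste(sort(mdf$gene), collapse = ","),
                 n_group = n_present)
        }) %>% bind_rows()
    }) %>% bind_rows()
  calls %>% arrange(.data$copy, .data$source_chromosome)
}

#' Detect end-to-end fusions, fused-arm orientation and centromere fate
#'
#' Two reference chromosomes are called fused when, within one subgenome
#' copy, the majority of each group's markers co-occupy a single target
#' chromosome. Centromere fate follows the marker-block argument: the
#' ancestral chromosome whose markers are confined to ONE target arm while
#' spanning both of its ancestral arms carries an embedded (lost)
#' centromere; the other chromosome's centromere is retained and anchors
#' the target. When both candidates are one-arm-confined (a marker
#' contradicting the model can produce this), the chromosome with the larger
#' concordant block is called lost and the contradicting markers are
#' reported as conflicts. The fusing arm of the lost chromosome is the
#' ancestral arm of its most centromere-proximal marker; the fusing arm of
#' the retained chromosome is the ancestral arm of its markers on the fusion
#' side, defaulting to the target arm bearing the lost block when none are
#' observed there.
#'
#' @param groups Synteny groups from [build_synteny_groups()].
#' @param target Target species marker map.
#' @return Tibble of calls with columns `kind`, `copy`, `ref_chrom_1`,
#'   `ref_chrom_2`, `target_chromosome`, `fused_arm_1`, `fused_arm_2`,
#'   `centromere_lost`, `centromere_retained`, `genes`, `conflicts`,
#'   `confidence`.
#' @export
detect_fusion <- function(groups, target) {
  ann <- annotate_target(groups, target)
  out <- ann %>%
    group_by(.data$copy_eff) %>%
    dplyr::group_map(function(df, key) fusion_calls_one_copy(df, key$copy_eff)) %>%
    bind_rows()
  if (nrow(out) == 0) {
    out <- fusion_none_row("none")[0, ]
  }
  out
}

fusion_none_row <- function(copy) {
  tibble(kind = "none", copy = copy, ref_chrom_1 = NA_character_,
         ref_chrom_2 = NA_character_, target_chromosome = NA_character_,
         fused_arm_1 = NA_character_, fused_arm_2 = NA_character_,
         centromere_lost = NA_character_, centromere_retained = NA_character_,
         genes = "", conflicts = "", confidence = NA_character_)
}

fusion_calls_one_copy <- function(df, copy) {
  # modal target chromosome per reference group
  modal <- df %>%
    count(.data$ref_chromosome, .data$chromosome) %>%
    group_by(.data$ref_chromosome) %>%
    slice(which.max(.data$n)) %>%
    ungroup()
  shared <- modal %>% count(.data$chromosome) %>% filter(.data$n >= 2)
  if (nrow(shared) == 0) return(fusion_none_row(copy))
  purrr::map_dfr(shared$chromosome, function(chrom) {
    refs <- modal$ref_chromosome[modal$chromosome == chrom]
    refs <- refs[ref_order(refs)][1:2]
    blockA <- df %>% filter(.data$ref_chromosome == refs[1], .data$chromosome == chrom)
    blockB <- df %>% filter(.data$ref_chromosome == refs[2], .data$chromosome == chrom)
    fuse_call_from_blocks(refs, blockA, blockB, chrom, copy)
  })
}

# evidence that a chromosome's centromere is embedded in one target arm:
# markers confined to a single arm, ideally drawn from both ancestral arms
block_lost_score <- function(block) {
  arms <- table(block$arm)
  modal_n <- max(arms)
  one_arm <- length(arms) == 1
  spans <- length(unique(block$ref_arm[block$arm == names(arms)[which.max(arms)]])) > 1
  c(one_arm && spans, modal_n)
}

fuse_call_from_blocks <- function(refs, blockA, blockB, chrom, copy) {
  sA <- block_lost_score(blockA)
  sB <- block_lost_score(blockB)
  # prefer embedded-centromere signature, then block size, then label order
  lost_is_A <- if (sA[1] != sB[1]) sA[1] > sB[1] else sA[2] >= sB[2]
  lost_block <- if (lost_is_A) blockA else blockB
  ret_block <- if (lost_is_A) blockB else blockA
  lost <- if (lost_is_A) refs[1] else refs[2]
  retained <- if (lost_is_A) refs[2] else refs[1]

  arm_tab <- sort(table(lost_block$arm), decreasing = TRUE)
  fusion_arm <- names(arm_tab)[1]                       # target arm bearing the lost block
  # fused arm of the lost chromosome: ancestral arm of its most proximal marker
  on_f <- lost_block %>% filter(.data$arm == fusion_arm)
  arm_lost <- if (all(is.na(on_f$rank))) unique(on_f$ref_arm)[1] else
    on_f$ref_arm[which.min(on_f$rank)]
  # fused arm of the retained chromosome: its markers on the fusion side
  ret_on_f <- ret_block %>% filter(.data$arm == fusion_arm)
  arm_ret <- if (nrow(ret_on_f) > 0) {
    names(sort(table(ret_on_f$ref_arm), decreasing = TRUE))[1]
  } else {
    fusion_arm
  }
  # predicted target arm per marker under the fitted model
  other_arm <- setdiff(c("p", "q"), fusion_arm)
  pred_lost <- rep(fusion_arm, nrow(lost_block))
  pred_ret <- ifelse(ret_block$ref_arm == arm_ret, fusion_arm, other_arm)
  conflicts <- c(lost_block$gene[lost_block$arm != pred_lost],
                 ret_block$gene[ret_block$arm != pred_ret])
  support <- setdiff(c(lost_block$gene, ret_block$gene), conflicts)
  confidence <- if (length(conflicts) > 0 || nrow(blockA) < 2 || nrow(blockB) < 2)
    "low" else "normal"
  arms_by_ref <- if (lost_is_A) c(arm_lost, arm_ret) else c(arm_ret, arm_lost)
  tibble(kind = "fusion", copy = copy,
         ref_chrom_1 = refs[1], ref_chrom_2 = refs[2],
         target_chromosome = chrom,
         fused_arm_1 = arms_by_ref[1], fused_arm_2 = arms_by_ref[2],
         centromere_lost = lost, centromere_retained = retained,
         genes = paste(sort(support), collapse = ","),
         conflicts = paste(sort(conflicts), collapse = ","),
         confidence = confidence)
}

#' Detect inversions between homeologous chromosomes
#'
#' Homeologous copies of a gene occupying different arms of homeologous
#' chromosomes indicate a pericentromeric inversion (breakpoints flanking
#' the centromere move markers between arms); the inverted homeolog is the
#' copy whose arm differs from the outgroup. Copies on the same arm whose
#' rank order is exactly reversed indicate a paracentric inversion. Without
#' an outgroup placement the call is still emitted with polarity
#' `undetermined`.
#'
#' @param target Target species marker map carrying both homeolog copies.
#' @param outgroup Outgroup marker map used for polarity (may be `NULL`).
#' @return Tibble of calls: `kind`, `subtype`, `chromosome` (inverted
#'   homeolog), `genes`, `polarity_source`.
#' @export
detect_inversion <- function(target, outgroup = NULL) {
  t <- target %>%
    mutate(copy_eff = effective_copy(target),
           base = base_chromosome(.data$chromosome)) %>%
    filter(.data$copy_eff != "none")
  og <- if (!is.null(outgroup)) {
    outgroup %>% mutate(base = base_chromosome(.data$chromosome)) %>%
      distinct(.data$gene, .data$base, og_arm = .data$arm, og_rank = .data$rank,
               og_species = .data$species)
  } else {
    NULL
  }
  paired <- t %>%
    group_by(.data$gene, .data$base) %>%
    filter(dplyr::n() == 2) %>%
    ungroup()
  if (nrow(paired) == 0) return(inversion_empty())

  peri <- paired %>%
    group_by(.data$gene, .data$base) %>%
    filter(length(unique(.data$arm)) == 2) %>%
    ungroup()
  peri_calls <- if (nrow(peri) > 0) {
    if (!is.null(og)) {
      peri <- peri %>% left_join(og, by = c("gene", "base"))
    } else {
      peri$og_arm <- NA_character_
      peri$og_species <- NA_character_
    }
    peri %>%
      group_by(.data$base, .data$gene) %>%
      dplyr::group_map(function(df, key) {
        if (all(is.na(df$og_arm))) {
          inv <- df$chromosome[order(df$copy_eff)][2]  # deterministic fallback
          pol <- "undetermined"
        } else {
          differs <- df$arm != df$og_arm
          inv <- df$chromosome[differs][1]
          pol <- df$og_species[1]
        }
        tibble(base = key$base, gene = key$gene, chromosome = inv,
               polarity_source = pol)
      }) %>% bind_rows() %>%
      group_by(.data$chromosome, .data$polarity_source) %>%
      summarise(genes = paste(sort(.data$gene), collapse = ","), .groups = "drop") %>%
      mutate(kind = "inversion", subtype = "pericentromeric") %>%
      select("kind", "subtype", "chromosome", "genes", "polarity_source")
  } else {
    inversion_empty()
  }

  para_calls <- detect_paracentric(paired, og)
  out <- bind_rows(peri_calls, para_calls)
  if (nrow(out) == 0) {
    out <- tibble(kind = "none", subtype = NA_character_,
                  chromosome = NA_character_, genes = "",
                  polarity_source = NA_character_)
  }
  out
}

inversion_empty <- function() {
  tibble(kind = character(), subtype = character(), chromosome = character(),
         genes = character(), polarity_source = character())
}

# same-arm rank-order reversal between homeolog copies
detect_paracentric <- function(paired, og) {
  same_arm <- paired %>%
    group_by(.data$gene, .data$base) %>%
    filter(length(unique(.data$arm)) == 1) %>%
    ungroup()
  if (nrow(same_arm) == 0) return(inversion_empty())
  same_arm %>%
    group_by(.data$base, .data$arm) %>%
    dplyr::group_map(function(df, key) {
      copies <- sort(unique(df$copy_eff))
      if (length(copies) != 2) return(inversion_empty())
      w <- df %>% select("gene", "copy_eff", "rank", "chromosome") %>%
        tidyr::pivot_wider(names_from = "copy_eff",
                           values_from = c("rank", "chromosome"))
      r1 <- w[[paste0("rank_", copies[1])]]
      r2 <- w[[paste0("rank_", copies[2])]]
      ok <- !is.na(r1) & !is.na(r2)
      if (sum(ok) < 2) return(inversion_empty())
      o1 <- order(r1[ok]); o2 <- order(r2[ok])
      if (!identical(o1, rev(o2))) return(inversion_empty())
      # polarity: the copy whose order disagrees with the outgroup is inverted
      inv_copy <- copies[2]; pol <- "undetermined"
      if (!is.null(og)) {
        og_sub <- og %>% filter(.data$base == key$base, .data$gene %in% w$gene[ok])
        if (nrow(og_sub) >= 2 && !any(is.na(og_sub$og_rank))) {
          og_ord <- order(og_sub$og_rank[match(w$gene[ok], og_sub$gene)])
          inv_copy <- if (identical(og_ord, o1)) copies[2] else copies[1]
          pol <- og_sub$og_species[1]
        }
      }
      tibble(kind = "inversion", subtype = "paracentric",
             chromosome = w[[paste0("chromosome_", inv_copy)]][1],
             genes = paste(sort(w$gene[ok]), collapse = ","),
             polarity_source = pol)
    }) %>% bind_rows()
}
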