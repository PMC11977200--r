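# Seeded simulators for every input the pipeline consumes: metaphase
# measurement tables (with truth labels in a sidecar, never in the table),
# marker-map rearrangement scenarios with ground-truth call lists, and FISH
# signal tables with per-row dropout. Noise is multiplicative lognormal so
# arm lengths stay positive by construction.

# lognormal draws with a given mean and coefficient of variation
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate metaphase chromatid measurements from a karyotype template
#'
#' Emulates the measurement step of a karyotype study. Per metaphase, a
#' global pixel scale is drawn (lognormal around `scale_mean_px` with CV
#' `scale_cv`), standing in for slide-to-slide variation in image resolution
#' and chromosome condensation. Each template type contributes
#' `ploidy_copies` chromosomes whose true arm lengths derive from the
#' template's relative length and centromeric index
#' (`p = len * i/100`, `q = len * (1 - i/100)`, with length shares
#' normalised so the metaphase total is the drawn scale). Observed arms are
#' truth times lognormal noise with CV `arm_noise_cv`; each chromosome is
#' reported as two chromatids with additional within-chromosome noise
#' `chromatid_noise_cv`. Row order within a metaphase is shuffled so
#' identification cannot rely on ordering.
#'
#' @param template Karyotype template (see [read_template()]).
#' @param n_metaphases Number of metaphases (default 11, a typical
#'   karyotyping sample).
#' @param scale_mean_px Expected total metaphase length in pixels.
#' @param scale_cv Between-metaphase pixel-scale CV.
#' @param arm_noise_cv Per-arm multiplicative measurement noise CV.
#' @param chromatid_noise_cv Within-chromosome chromatid noise CV.
#' @param seed Integer seed; identical inputs give identical output.
#' @return List with `measurements` (tibble as read by
#'   [read_measurements()]) and `truth` (tibble `metaphase_id`, `object_id`,
#'   `type_label`).
#' @examples
#' tpl <- read_template(karyomorph_example("table2_template.csv"))
#' sim <- simulate_metaphases(tpl, n_metaphases = 2, seed = 1)
#' head(sim$measurements)
#' @export
simulate_metaphases <- function(template, n_metaphases = 11,
                                scale_mean_px = 10000, scale_cv = 0.2,
                                arm_noise_cv = 0.05, chromatid_noise_cv = 0.02,
                                seed = 1L) {
  if (any(c(scale_cv, arm_noise_cv, chromatid_noise_cv) < 0)) {
    abort_domain("noise CVs must be >= 0")
  }
  if (n_metaphases < 1) abort_domain("n_metaphases must be >= 1")
  if (any(template$i_median > 50 | template$i_median <= 0)) {
    abort_domain("template centromeric indices must lie in (0, 50]")
  }
  copies <- attr(template, "ploidy_copies") %||% 2L
  set.seed(seed)
  types <- rep(template$type_label, each = copies)
  # normalised length share of each chromosome copy (sums to 1)
  share <- rep(template$l_pct_median, each = copies)
  share <- share / sum(share)
  i_val <- rep(template$i_median, each = copies)
  n_chrom <- length(types)

  per_meta <- purrr::map(seq_len(n_metaphases), function(m) {
    s <- rlnorm_cv(1, scale_mean_px, scale_cv)
    len <- s * share
    p_true <- len * i_val / 100
    q_true <- len * (1 - i_val / 100)
    p_obs <- p_true * rlnorm_cv(n_chrom, 1, arm_noise_cv)
    q_obs <- q_true * rlnorm_cv(n_chrom, 1, arm_noise_cv)
    ord <- sample.int(n_chrom)
    meta_id <- sprintf("M%02d", m)
    obj_id <- sprintf("obj%02d", seq_len(n_chrom))
    meas <- tibble(
      metaphase_id = meta_id,
      object_id = rep(obj_id, each = 2L),
      chromatid_index = rep(1:2, times = n_chrom),
      p_len = rep(p_obs[ord], each = 2L) *
        rlnorm_cv(2L * n_chrom, 1, chromatid_noise_cv),
      q_len = rep(q_obs[ord], each = 2L) *
        rlnorm_cv(2L * n_chrom, 1, chromatid_noise_cv)
    )
    truth <- tibble(metaphase_id = meta_id, object_id = obj_id,
                    type_label = types[ord])
    list(meas = meas, truth = truth)
  })
  list(measurements = bind_rows(purrr::map(per_meta, "meas")),
       truth = bind_rows(purrr::map(per_meta, "truth")))
}

#' Simulate a rearranged marker map from a reference
#'
#' Duplicates a (haploid ancestral) reference map into two subgenome copies
#' and applies rearrangement specs in order, emitting the target map
#' together with the ground-truth call list. Supported specs:
#'
#' * `list(op = "translocate", gene =, dest =, copy =)` — move one gene to
#'   the pericentromeric region of chromosome `dest` in the given copy.
#' * `list(op = "fuse", chr_a =, arm_a =, chr_b =, arm_b =, retained =,
#'   copy =)` — end-to-end fusion of two chromosomes through the given
#'   arms; `retained` names the chromosome whose centromere persists. Rank
#'   arithmetic preserves marker adjacency: the lost chromosome's markers
#'   are appended to the retained chromosome's fusing arm, fusing-arm
#'   markers first (reversed, i.e. nearest the junction), then the markers
#'   of its far arm.
#' * `list(op = "invert", chromosome =, copy =)` — pericentromeric
#'   inversion flipping every marker of that chromosome copy to the
#'   opposite arm (order reversed).
#'
#' @param reference Marker map (e.g. the bundled X. tropicalis map).
#' @param scenario List of specs, applied in order. Empty list duplicates
#'   the reference unchanged.
#' @param copies Character vector of the two subgenome copy tags.
#' @param species Species name recorded in the output map.
#' @return List with `target` (marker-map tibble) and `truth` (tibble of
#'   expected calls: `kind`, `copy`, and kind-specific fields).
#' @export
simulate_marker_scenario <- function(reference, scenario = list(),
                                     copies = c("L", "S"),
                                     species = "synthetic") {
  target <- reference %>%
    tidyr::expand_grid(.copy = copies) %>%
    mutate(chromosome = paste0(base_chromosome(.data$chromosome), .data$.copy),
           copy = .data$.copy, species = species) %>%
    select(-".copy")
  truth <- list()
  for (spec in scenario) {
    op <- spec$op %||% abort_validation("scenario spec lacks an 'op' field")
    cp <- spec$copy %||% copies[2]
    if (op == "translocate") {
      idx <- which(target$gene == spec$gene & target$copy == cp)
      if (length(idx) != 1) {
        abort(sprintf("translocate: gene '%s' not found once in copy %s", spec$gene, cp),
              class = "karyomorph_scenario_error")
      }
      src <- base_chromosome(target$chromosome[idx])
      target$chromosome[idx] <- paste0(spec$dest, cp)
      target$arm[idx] <- "q"
      target$rank[idx] <- 1L
      target$region[idx] <- "pericentromeric"
      truth <- c(truth, list(tibble(kind = "translocation", copy = cp,
                                    source_chromosome = src,
                                    dest_chromosome = paste0(spec$dest, cp),
                                    genes = spec$gene)))
    } else if (op == "fuse") {
      lost <- setdiff(c(spec$chr_a, spec$chr_b), spec$retained)
      if (length(lost) != 1) {
        abort("fuse: 'retained' must name one of chr_a/chr_b",
              class = "karyomorph_scenario_error")
      }
      arm_of <- setNames(c(spec$arm_a, spec$arm_b), c(spec$chr_a, spec$chr_b))
      ret <- spec$retained
      new_label <- paste0(paste(c(spec$chr_a, spec$chr_b)[
        ref_order(c(spec$chr_a, spec$chr_b))], collapse = "_"), cp)
      in_ret <- base_chromosome(target$chromosome) == ret & target$copy == cp
      in_lost <- base_chromosome(target$chromosome) == lost & target$copy == cp
      if (!any(in_ret) && !any(in_lost)) {
        abort("fuse: neither chromosome has markers in that copy",
              class = "karyomorph_scenario_error")
      }
      f_arm <- arm_of[ret]   # target arm carrying the fusion
      base_rank <- suppressWarnings(
        max(0L, target$rank[in_ret & target$arm == f_arm], na.rm = TRUE))
      # lost chromosome: fusing-arm markers reversed (junction-proximal side
      # faces the retained chromosome), then far-arm markers outward
      lostdf <- target[in_lost, ]
      near <- lostdf[lostdf$arm == arm_of[lost], ]
      near <- near[order(-near$rank), ]
      far <- lostdf[lostdf$arm != arm_of[lost], ]
      far <- far[order(far$rank), ]
      stacked <- rbind(near, far)
      stacked$rank <- base_rank + seq_len(nrow(stacked))
      stacked$arm <- f_arm
      stacked$chromosome <- new_label
      target <- target[!in_lost, ]
      target$chromosome[base_chromosome(target$chromosome) == ret &
                          target$copy == cp] <- new_label
      target <- bind_rows(target, stacked)
      refs <- c(spec$chr_a, spec$chr_b)[ref_order(c(spec$chr_a, spec$chr_b))]
      arms <- unname(arm_of[refs])
      truth <- c(truth, list(tibble(kind = "fusion", copy = cp,
                                    ref_chrom_1 = refs[1], ref_chrom_2 = refs[2],
                                    target_chromosome = new_label,
                                    fused_arm_1 = arms[1], fused_arm_2 = arms[2],
                                    centromere_lost = lost,
                                    centromere_retained = ret)))
    } else if (op == "invert") {
      idx <- base_chromosome(target$chromosome) == spec$chromosome & target$copy == cp
      if (!any(idx)) {
        abort(sprintf("invert: no markers on chromosome '%s' copy %s",
                      spec$chromosome, cp),
              class = "karyomorph_scenario_error")
      }
      target$arm[idx] <- ifelse(target$arm[idx] == "p", "q", "p")
      target$region[idx] <- "pericentromeric"
      truth <- c(truth, list(tibble(kind = "inversion", copy = cp,
                                    chromosome = paste0(spec$chromosome, cp),
                                    genes = paste(sort(target$gene[idx]), collapse = ","))))
    } else {
      abort(sprintf("unknown scenario op '%s'", op),
            class = "karyomorph_scenario_error")
    }
  }
  target <- validate_marker_map(target, context = "simulated map")
  list(target = target,
       truth = if (length(truth) > 0) bind_rows(truth) else tibble(kind = character()))
}

#' Simulate a FISH signal table with dropout
#'
#' Starts from a full signal pattern (e.g. the bundled rDNA table) and drops
#' each row independently with probability `dropout_prob`, emulating
#' hybridisation failure of individual loci.
#'
#' @param pattern Signal tibble (see [read_fish_signals()]).
#' @param dropout_prob Per-row dropout probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A signal tibble.
#' @export
simulate_signals <- function(pattern, dropout_prob = 0, seed = 1L) {
  if (dropout_prob < 0 || dropout_prob > 1) abort_domain("dropout_prob must be in [0, 1]")
  set.seed(seed)
  keep <- runif(nrow(pattern)) >= dropout_prob
  pattern[keep, , drop = FALSE]
}
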