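test_that("synteny groups partition the reference by chromosome", {
  g <- build_synteny_groups(trop_map())
  expect_setequal(unique(g$ref_chromosome), c("2", "9", "10"))
  expect_setequal(g$gene[g$ref_chromosome == "2"], c("cept1", "gyg2"))
  expect_setequal(g$gene[g$ref_chromosome == "9"],
                  c("nomo3", "fn1", "ndufs1", "sf3b1"))
  expect_setequal(g$gene[g$ref_chromosome == "10"], c("bmp7", "sox9"))
  # singleton map -> singleton group; empty map -> error
  single <- validate_marker_map(tibble::tibble(
    species = "x", gene = "g", chromosome = "1", arm = "q",
    rank = 1L, region = "unknown", copy = "none"))
  expect_equal(nrow(build_synteny_groups(single)), 1)
  expect_error(build_synteny_groups(single[0, ]),
               class = "karyomorph_validation_error")
})

test_that("the mellotropicalis map yields the sf3b1 9-to-2 translocation in one subgenome", {
  g <- build_synteny_groups(trop_map())
  mel <- read_marker_map(karyomorph_example("markers_mellotropicalis.csv"))
  calls <- detect_translocation(g, mel)
  hit <- calls[calls$kind == "translocation", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$copy, "b")
  expect_equal(hit$source_chromosome, "9")
  expect_equal(hit$dest_chromosome, "2b")
  expect_equal(hit$genes, "sf3b1")
  # and no spurious fusion from the translocated gene sharing 2b
  fus <- detect_fusion(g, mel)
  expect_true(all(fus$kind == "none"))
})

test_that("the pygmaeus map yields no translocation and a q-q fusion per copy", {
  g <- build_synteny_groups(trop_map())
  pyg <- read_marker_map(karyomorph_example("markers_pygmaeus.csv"))
  expect_true(all(detect_translocation(g, pyg)$kind == "none"))
  fus <- detect_fusion(g, pyg)
  expect_equal(nrow(fus), 2)
  expect_equal(fus$kind, c("fusion", "fusion"))
  expect_setequal(fus$copy, c("L", "S"))
  expect_true(all(fus$ref_chrom_1 == "9" & fus$ref_chrom_2 == "10"))
  expect_true(all(fus$fused_arm_1 == "q" & fus$fused_arm_2 == "q"))
  expect_true(all(fus$centromere_lost == "9" & fus$centromere_retained == "10"))
  expect_true(all(fus$conflicts == "sox9"))
  expect_true(all(fus$confidence == "low"))
})

test_that("cept1/gyg2 homeolog arms give a pericentromeric inversion on 2S", {
  pyg <- read_marker_map(karyomorph_example("markers_pygmaeus.csv"))
  inv <- detect_inversion(pyg, trop_map())
  expect_equal(inv$kind, "inversion")
  expect_equal(inv$subtype, "pericentromeric")
  expect_equal(inv$chromosome, "2S")
  expect_equal(inv$genes, "cept1,gyg2")
  expect_equal(inv$polarity_source, "tropicalis")
  # without an outgroup the call survives with undetermined polarity
  inv2 <- detect_inversion(pyg, NULL)
  expect_equal(inv2$kind, "inversion")
  expect_equal(inv2$polarity_source, "undetermined")
})

test_that("a target identical to the reference produces no calls", {
  trop <- trop_map()
  g <- build_synteny_groups(trop)
  sc <- simulate_marker_scenario(trop, list())
  expect_true(all(detect_translocation(g, sc$target)$kind == "none"))
  expect_true(all(detect_fusion(g, sc$target)$kind == "none"))
  expect_true(all(detect_inversion(sc$target, trop)$kind == "none"))
})

test_that("calls are stable under row permutation and subgenome relabeling", {
  trop <- trop_map()
  g <- build_synteny_groups(trop)
  pyg <- read_marker_map(karyomorph_example("markers_pygmaeus.csv"))
  set.seed(8)
  perm <- pyg[sample.int(nrow(pyg)), ]
  expect_equal(as.data.frame(detect_fusion(g, perm)),
               as.data.frame(detect_fusion(g, pyg)))
  expect_equal(as.data.frame(detect_inversion(perm, trop)),
               as.data.frame(detect_inversion(pyg, trop)))
  # swapping L and S flips only the homeolog named
  swapped <- pyg
  swapped$chromosome <- chartr("LS", "SL", swapped$chromosome)
  swapped$copy <- chartr("LS", "SL", swapped$copy)
  inv_sw <- detect_inversion(swapped, trop)
  expect_equal(inv_sw$kind, "inversion")
  expect_equal(inv_sw$chromosome, "2L")
  expect_equal(inv_sw$genes, "cept1,gyg2")
})

test_that("all noise-free fusion geometries are recovered exactly", {
  trop <- trop_map()
  g <- build_synteny_groups(trop)
  for (retained in c("9", "10")) {
    for (arm_a in c("p", "q")) {
      for (arm_b in c("p", "q")) {
        sc <- simulate_marker_scenario(trop, list(list(
          op = "fuse", chr_a = "9", arm_a = arm_a, chr_b = "10",
          arm_b = arm_b, retained = retained, copy = "S")))
        call <- detect_fusion(g, sc$target)
        call <- call[call$copy == "S", ]
        tt <- sc$truth
        expect_equal(call$kind, "fusion")
        expect_equal(call$target_chromosome, tt$target_chromosome)
        expect_equal(call$fused_arm_1, tt$fused_arm_1)
        expect_equal(call$fused_arm_2, tt$fused_arm_2)
        expect_equal(call$centromere_lost, tt$centromere_lost)
        expect_equal(call$centromere_retained, tt$centromere_retained)
        expect_equal(call$conflicts, "")
        expect_equal(call$confidence, "normal")
      }
    }
  }
})

test_that("combined noise-free scenarios are recovered for every presence combination", {
  trop <- trop_map()
  g <- build_synteny_groups(trop)
  for (with_inv in c(FALSE, TRUE)) {
    for (with_trans in c(FALSE, TRUE)) {
      for (with_fus in c(FALSE, TRUE)) {
        ops <- list()
        if (with_inv) ops <- c(ops, list(list(op = "invert", chromosome = "2", copy = "S")))
        if (with_trans) ops <- c(ops, list(list(op = "translocate", gene = "sf3b1",
                                                dest = "2", copy = "S")))
        if (with_fus) ops <- c(ops, list(list(op = "fuse", chr_a = "9", arm_a = "q",
                                              chr_b = "10", arm_b = "q",
                                              retained = "10", copy = "S")))
        sc <- simulate_marker_scenario(trop, ops)
        tr_calls <- detect_translocation(g, sc$target)
        expect_equal(sum(tr_calls$kind == "translocation"), as.integer(with_trans))
        fu_calls <- detect_fusion(g, sc$target)
        expect_equal(sum(fu_calls$kind == "fusion"), as.integer(with_fus))
        inv_calls <- detect_inversion(sc$target, trop)
        expect_equal(sum(inv_calls$kind == "inversion" &
                           inv_calls$subtype == "pericentromeric" &
                           startsWith(inv_calls$chromosome, "2")),
                     as.integer(with_inv))
        if (with_trans) {
          hit <- tr_calls[tr_calls$kind == "translocation", ]
          expect_equal(hit$genes, "sf3b1")
          expect_equal(hit$source_chromosome, "9")
        }
        if (with_fus) {
          hit <- fu_calls[fu_calls$kind == "fusion", ]
          expect_equal(hit$centromere_lost, "9")
          expect_equal(c(hit$fused_arm_1, hit$fused_arm_2), c("q", "q"))
        }
      }
    }
  }
})

test_that("an exact half split is reported as ambiguous, not a translocation", {
  trop <- trop_map()
  g <- build_synteny_groups(trop)
  # move one of the two genes of group 2 -> a 1:1 split
  sc <- simulate_marker_scenario(trop, list(list(op = "translocate", gene = "gyg2",
                                                 dest = "9", copy = "S")))
  calls <- detect_translocation(g, sc$target)
  expect_true("ambiguous_split" %in% calls$kind)
  expect_false("translocation" %in% calls$kind)
})
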