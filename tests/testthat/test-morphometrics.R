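test_that("chromatid arms average into per-chromosome arms", {
  m <- meas_rows("m1", "c1", c(10, 12), c(30, 28))
  ch <- chromatids_to_chromosomes(m)
  expect_equal(ch$p, 11)
  expect_equal(ch$q, 29)

  ident <- meas_rows("m1", "c2", c(5, 5), c(5, 5))
  ch2 <- chromatids_to_chromosomes(ident)
  expect_equal(c(ch2$p, ch2$q), c(5, 5))

  # a lone chromatid passes through with a warning
  single <- tibble::tibble(metaphase_id = "m1", object_id = "c3",
                           chromatid_index = 1L, p_len = 7, q_len = 9)
  expect_warning(ch3 <- chromatids_to_chromosomes(single), "single chromatid")
  expect_equal(c(ch3$p, ch3$q), c(7, 9))
})

test_that("the chromatid mean always lies between the two chromatid values", {
  set.seed(11)
  for (k in 1:200) {
    v <- sort(runif(2, 1, 100))
    m <- meas_rows("m", "o", v, rev(v) + 100)
    ch <- chromatids_to_chromosomes(m)
    expect_gte(ch$p, v[1]); expect_lte(ch$p, v[2])
  }
})

test_that("chromosome metrics follow their closed forms", {
  # symmetric arms: two chromosomes of (1,1) -> each half the metaphase
  ch <- tibble::tibble(metaphase_id = "m", object_id = c("a", "b"),
                       p = c(1, 1), q = c(1, 1))
  r <- compute_metrics(ch)
  expect_equal(r$l_pct, c(50, 50))
  expect_equal(r$r1, c(1, 1))
  expect_equal(r$i, c(50, 50))

  # p=1, q=3 in a metaphase totalling 100 px
  ch2 <- tibble::tibble(metaphase_id = "m", object_id = c("a", "fill"),
                        p = c(1, 48), q = c(3, 48))
  r2 <- compute_metrics(ch2)
  expect_equal(r2$l_pct[1], 4)
  expect_equal(r2$r1[1], 1 / 3)
  expect_equal(r2$i[1], 25)

  # arm orientation: p > q is swapped and flagged
  ch3 <- tibble::tibble(metaphase_id = "m", object_id = "a", p = 3, q = 1)
  r3 <- compute_metrics(ch3)
  expect_true(r3$swapped)
  expect_equal(r3$i, 25)
})

test_that("i and r1 are consistent: i = 100 r1 / (1 + r1)", {
  # published 3L medians: r1 = 0.25 implies i = 20.00
  expect_equal(100 * 0.25 / 1.25, 20)
  set.seed(3)
  p <- runif(50, 1, 50); q <- p + runif(50, 0, 50)
  r <- compute_metrics(tibble::tibble(metaphase_id = "m",
                                      object_id = as.character(1:50), p = p, q = q))
  expect_equal(r$i, 100 * r$r1 / (1 + r$r1), tolerance = 1e-9)
  expect_equal(r$r1 * r$r2, rep(1, 50), tolerance = 1e-9)
})

test_that("the Levan classifier respects published examples and boundaries", {
  expect_equal(classify_chromosome(41.35), "m")
  expect_equal(classify_chromosome(35.85), "sm")
  expect_equal(classify_chromosome(24.24), "st")
  # inclusive lower bounds
  expect_equal(classify_chromosome(c(37.5, 25, 12.5, 5, 0)),
               c("m", "sm", "st", "a", "t"))
  expect_error(classify_chromosome(51), class = "karyomorph_domain_error")
  expect_error(classify_chromosome(-1), class = "karyomorph_domain_error")
})

test_that("classification is order-isomorphic in i", {
  set.seed(5)
  i <- sort(runif(300, 0, 50))
  cats <- classify_chromosome(i)
  level <- match(cats, c("t", "a", "st", "sm", "m"))
  expect_true(all(diff(level) >= 0))
})

test_that("the bundled template reproduces the published census and identities", {
  tpl <- table2_template()
  cats <- classify_chromosome(tpl$i_median)
  expect_equal(cats, tpl$category)   # all 18 printed categories
  census <- table(cats)
  expect_equal(as.integer(census[c("m", "sm", "st")]), c(10L, 1L, 7L))
  # i vs r1 identity holds within 0.5 on every row of printed medians
  expect_true(all(abs(tpl$i_median - 100 * tpl$r1_median / (1 + tpl$r1_median)) <= 0.5))
  # haploid relative lengths account for half the metaphase
  expect_equal(sum(tpl$l_pct_median), 50.01, tolerance = 1e-9)
})

test_that("relative lengths over a complete metaphase sum to 100", {
  set.seed(9)
  ch <- tibble::tibble(metaphase_id = rep(c("m1", "m2"), each = 10),
                       object_id = as.character(rep(1:10, 2)),
                       p = runif(20, 1, 20), q = runif(20, 20, 80))
  r <- compute_metrics(ch)
  sums <- tapply(r$l_pct, r$metaphase_id, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
})

test_that("aggregation uses type-7 quartiles computed per metric", {
  mk <- function(vals) {
    tibble::tibble(metaphase_id = as.character(seq_along(vals)),
                   object_id = "o", p = vals, q = vals * 3,
                   assigned_type = "1L")
  }
  m <- compute_metrics(mk(c(1, 2, 3, 4, 5)))
  # constant l_pct (one chromosome per metaphase) but i constant too; check n
  s <- aggregate_karyotype(m)
  expect_equal(unique(s$n), 5)
  # order statistics on a small sample, type-7 convention
  x <- c(1, 2, 3, 4, 5)
  expect_equal(quantile(x, c(.25, .5, .75), type = 7, names = FALSE), c(2, 3, 4))
  # single metaphase: medians equal the observations
  one <- compute_metrics(tibble::tibble(metaphase_id = "m", object_id = c("a", "b"),
                                        p = c(1, 2), q = c(3, 6)))
  one$assigned_type <- c("1L", "1S")
  s1 <- aggregate_karyotype(one)
  expect_equal(s1$Q1, s1$Q2)
  expect_equal(s1$Q2, s1$Q3)
  # category column comes from the median i
  expect_equal(unique(s1$category), "sm")
})

test_that("homeolog IQR divergence flags disjoint intervals and ranks by gap", {
  s <- tibble::tibble(
    type = c("8L", "8S", "7L", "7S"),
    metric = "l_pct",
    Q1 = c(2.41, 1.64, 2.35, 1.87),
    Q2 = c(2.5, 1.7, 2.4, 1.9),
    Q3 = c(2.58, 1.82, 2.53, 1.99),
    n = 11)
  d <- homeolog_divergence(s, metrics = "l_pct")
  d8 <- d[d$pair == "8", ]
  expect_true(d8$disjoint)
  expect_equal(d8$gap, 2.41 - 1.82, tolerance = 1e-12)
  expect_equal(d8$divergence_rank, 1L)  # 8 diverges more than 7
  # identical intervals: overlap, zero gap
  s2 <- tibble::tibble(type = c("1L", "1S"), metric = "l_pct",
                       Q1 = 1, Q2 = 2, Q3 = 3, n = 5)
  d2 <- homeolog_divergence(s2, metrics = "l_pct")
  expect_false(d2$disjoint)
  expect_equal(d2$gap, 0)
  # an orphan homeolog is an error naming the base
  s3 <- s[s$type != "7S", ]
  expect_error(homeolog_divergence(s3, metrics = "l_pct"), "7")
})

test_that("divergence ranking agrees with a brute-force gap sort", {
  set.seed(21)
  for (rep in 1:10) {
    n_pairs <- 5
    base <- as.character(seq_len(n_pairs))
    rows <- purrr::map_dfr(base, function(b) {
      c1 <- sort(runif(2, 0, 10)); c2 <- sort(runif(2, 0, 10))
      tibble::tibble(type = paste0(b, c("L", "S")), metric = "l_pct",
                     Q1 = c(c1[1], c2[1]), Q2 = c(mean(c1), mean(c2)),
                     Q3 = c(c1[2], c2[2]), n = 3)
    })
    d <- homeolog_divergence(rows, metrics = "l_pct")
    oracle <- d[order(-d$gap, d$pair), ]$pair
    expect_equal(d$pair[order(d$divergence_rank)], oracle)
  }
})

test_that("homeolog ANOVA flags shifted groups and spares identical ones", {
  set.seed(31)
  types <- paste0(rep(1:3, each = 2), c("L", "S"))
  base <- purrr::map_dfr(types, function(t) {
    tibble::tibble(assigned_type = t, l_pct = c(1, 2, 3), i = c(1, 2, 3))
  })
  fit <- homeolog_anova(base, "l_pct")
  expect_true(all(fit$comparisons$significance == "ns"))

  # two homeologs ten pooled SDs apart, n = 11 each
  shifted <- purrr::map_dfr(types, function(t) {
    mu <- if (t == "1L") 10 else 0
    tibble::tibble(assigned_type = t, l_pct = rnorm(11, mu, 1), i = rnorm(11, 25, 1))
  })
  fit2 <- homeolog_anova(shifted, "l_pct")
  expect_equal(fit2$comparisons$significance[fit2$comparisons$pair == "1"], "***")

  g <- glance(fit2)
  expect_true(g$statistic > 0 && g$p.value < 0.001)
  expect_error(homeolog_anova(base[base$assigned_type != "1L" |
                                     seq_len(nrow(base)) %in% 1, ], "l_pct"),
               class = "karyomorph_statistics_error")
})

test_that("significance codes map adjusted p-values by the standard thresholds", {
  expect_equal(karyomorph:::significance_code(c(0.0005, 0.004, 0.04, 0.2)),
               c("***", "**", "*", "ns"))
})
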