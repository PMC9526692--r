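cls <- rep(c("T8_GC", "T8_RPM", "T28_GC", "T28_RPM"), times = c(2, 3, 3, 3))

# build a 6-pair table with chosen significant RPM-vs-GC directions,
# for exercising the trend mapping in isolation
fake_pairs <- function(t8 = NA, t28 = NA, time_sig = FALSE) {
  combs <- t(combn(smg_test_classes(), 2))
  df <- data.frame(class_a = combs[, 1], class_b = combs[, 2],
                   diff = 0, p_adj = 1, higher = combs[, 1],
                   significant = FALSE, stringsAsFactors = FALSE)
  set_pair <- function(df, a, b, dir) {
    i <- which((df$class_a == a & df$class_b == b) |
                 (df$class_a == b & df$class_b == a))
    df$significant[i] <- TRUE
    df$p_adj[i] <- 0.01
    df$higher[i] <- if (dir == "up") b else a
    df
  }
  if (!is.na(t8)) df <- set_pair(df, "T8_GC", "T8_RPM", t8)
  if (!is.na(t28)) df <- set_pair(df, "T28_GC", "T28_RPM", t28)
  if (time_sig) df <- set_pair(df, "T8_GC", "T28_GC", "up")
  df
}

test_that("tukey_hsd returns 6 pair calls and finds nothing when means are equal", {
  # every class has mean 2, with within-class spread
  y <- c(1, 3, 1, 2, 3, 1, 2, 3, 1, 2, 3)
  res <- tukey_hsd(y, cls)
  expect_identical(nrow(res), 6L)
  expect_identical(
    nrow(unique(t(apply(res[, c("class_a", "class_b")], 1, sort)))), 6L)
  expect_identical(sum(res$significant), 0L)
  expect_true(all(res$p_adj == 1))
})

test_that("tukey_hsd matches the studentized-range oracle on fixed instances", {
  set.seed(3)
  for (i in 1:8) {
    y <- rnorm(11) + rep(c(0, 2, 0, 1), times = c(2, 3, 3, 3)) * (i %% 3)
    mine <- tukey_hsd(y, cls)
    orc <- oracle_tukey(y, cls)
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(mine$class_a, mine$class_b), key(orc$a, orc$b))
    expect_equal(mine$p_adj, orc$p[m], tolerance = 1e-6)
    expect_equal(abs(mine$diff), abs(orc$diff[m]), tolerance = 1e-10)
  }
})

test_that("trend classification maps pair directions to the eight categories", {
  expect_identical(classify_trend(fake_pairs(t8 = "down")), "down_T8_only")
  expect_identical(classify_trend(fake_pairs(t8 = "up")), "up_T8_only")
  expect_identical(classify_trend(fake_pairs(t28 = "down")), "down_T28_only")
  expect_identical(classify_trend(fake_pairs(t28 = "up")), "up_T28_only")
  expect_identical(classify_trend(fake_pairs(t8 = "down", t28 = "down")),
                   "down_both")
  expect_identical(classify_trend(fake_pairs(t8 = "up", t28 = "up")),
                   "up_both")
  expect_identical(classify_trend(fake_pairs(t8 = "up", t28 = "down")),
                   "mixed")
  expect_identical(classify_trend(fake_pairs(time_sig = TRUE)), "time_only")
  expect_identical(classify_trend(fake_pairs()), "time_only")
  expect_error(classify_trend(fake_pairs()[1:5, ]), "6 pair")
})

test_that("isoform de-duplication keeps the smallest-p record per base gene", {
  rec <- data.frame(gene = c("AAA", "BBB"), anova_p = c(0.01, 0.02))
  expect_identical(dedupe_isoforms(rec), rec)

  rec2 <- data.frame(gene = c("GENE1", "GENE1-2", "GENE2"),
                     anova_p = c(0.02, 0.001, 0.03))
  expect_message(out <- dedupe_isoforms(rec2), "1 redundant")
  expect_identical(out$gene, c("GENE1-2", "GENE2"))

  # 486 records with 5 redundant isoforms reduce to 481
  genes <- c(sprintf("G%03d", 1:481), paste0(sprintf("G%03d", 1:5), "-2"))
  rec3 <- data.frame(gene = genes, anova_p = seq(0.0001, 0.05,
                                                 length.out = 486))
  expect_message(out3 <- dedupe_isoforms(rec3), "481 retained")
  expect_identical(nrow(out3), 481L)
})

test_that("trend summary reports one-decimal percentages of the DAPG total", {
  s <- trend_summary(c(down_T8_only = 73, down_T28_only = 17,
                       down_both = 28, up_both = 16), total = 481)
  expect_equal(s$pct[s$category == "down_T8_only"], 15.2)
  expect_equal(s$pct[s$category == "down_T28_only"], 3.5)
  expect_equal(s$pct[s$category == "down_both"], 5.8)
  expect_equal(s$pct[s$category == "up_both"], 3.3)
  # category counts from a vector partition the significant set
  cats <- sample(trend_categories(), 50, replace = TRUE)
  s2 <- trend_summary(cats)
  expect_identical(sum(s2$n), 50L)
  expect_setequal(s2$category, trend_categories())
})

test_that("top_regulated ranks by mean RPM-GC difference with name tie-breaks", {
  x <- rbind(SPIKE = c(0, 0, -2, -2, -2, 0, 0, 0, -2, -2, -2),
             AAA = rep(0, 11), BBB = rep(0, 11))
  res <- top_regulated(x, cls, k = 1)
  expect_identical(res$down, "SPIKE")
  expect_identical(res$up, "AAA")  # ties broken alphabetically
  x2 <- rbind(DN = c(0, 0, -1, -1, -1, 0, 0, 0, -1, -1, -1),
              UP = c(0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1))
  res2 <- top_regulated(x2, cls, k = 1)
  expect_identical(res2$down, "DN")
  expect_identical(res2$up, "UP")
  expect_length(intersect(res2$down, res2$up), 0)
  expect_warning(top_regulated(x2, cls, k = 10), "fewer")
})

test_that("spiked simulation ranks the extreme truth genes at the top", {
  sim <- simulate_proteomics(proteomics_sim_spec(200, frac_dapg = 0.1,
                                                 effect_log2 = 2, seed = 14))
  ref <- average_reference(sim$matrix)
  m <- impute_gaussian(log2_transform(filter_valid(
    ratio_to_reference(sim$matrix, ref))), seed = 14)
  res <- top_regulated(m$values, m$classes, k = 5)
  truth <- sim$truth
  down_true <- truth$gene[truth$category %in% c("down_both")]
  up_true <- truth$gene[truth$category %in% c("up_both")]
  # both-timepoint spikes have the most extreme mean RPM-GC scores
  expect_true(all(res$down %in% truth$gene[truth$effect_t8 < 0 |
                                             truth$effect_t28 < 0]))
  expect_true(all(res$up %in% truth$gene[truth$effect_t8 > 0 |
                                           truth$effect_t28 > 0]))
})
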