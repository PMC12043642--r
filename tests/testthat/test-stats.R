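test_that("per-animal aggregation averages repeats", {
  raw <- data.frame(animal_id = rep(c("m1", "m2"), each = 3),
                    genotype = rep(c("wt", "ko"), each = 3),
                    value = c(400, 420, 440, 5, 5, 5))
  agg <- aggregate_per_animal(raw)
  expect_equal(sort(agg$value), c(5, 420))
  expect_equal(agg$n_repeats, c(3L, 3L))
  # matches a direct group-by oracle on simulated data
  set.seed(1)
  big <- data.frame(animal_id = rep(sprintf("a%02d", 1:12), each = 10),
                    genotype = rep(c("wt", "het", "ko"), each = 40),
                    value = rnorm(120))
  agg2 <- aggregate_per_animal(big)
  oracle <- tapply(big$value, big$animal_id, mean)
  expect_equal(agg2$value[order(agg2$animal_id)],
               as.numeric(oracle[order(names(oracle))]))
})

test_that("mean and SEM follow their definitions", {
  s <- summarize_mean_sem(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3))
  expect_equal(summarize_mean_sem(c(4, 4, 4, 4))$sem, 0)
  expect_error(summarize_mean_sem(5), "at least 2")
})

test_that("one-way F statistic matches the textbook sums of squares", {
  d <- data.frame(group = rep(c("A", "B", "C"), each = 3),
                  value = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  # independent oracle: explicit between/within mean squares
  gm <- mean(d$value)
  means <- tapply(d$value, d$group, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((d$value - means[d$group])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  st <- one_way_anova_tukey(d)
  expect_equal(st$anova$f, f_oracle)
  expect_equal(f_oracle, 27)
  expect_equal(st$anova$df, 2)
  expect_equal(st$anova$df_resid, 6)
  expect_equal(nrow(st$tukey), 3)            # all pairs
})

test_that("identical groups give F = 0 and p = 1", {
  d <- data.frame(group = rep(c("A", "B"), each = 3), value = rep(1:3, 2))
  st <- one_way_anova_tukey(d)
  expect_equal(st$anova$f, 0)
  expect_equal(st$anova$p, 1)
})

test_that("Tukey-adjusted p-values are never below unadjusted pairwise p", {
  set.seed(31)
  d <- data.frame(group = rep(c("A", "B", "C", "D"), each = 6),
                  value = rnorm(24) + rep(c(0, 0.5, 1, 1.5), each = 6))
  st <- one_way_anova_tukey(d)
  pt <- pairwise.t.test(d$value, d$group, p.adjust.method = "none")$p.value
  for (i in seq_len(nrow(st$tukey))) {
    a <- st$tukey$group_a[i]; b <- st$tukey$group_b[i]
    p_un <- if (!is.na(pt[a, b])) pt[a, b] else pt[b, a]
    expect_gte(st$tukey$adjusted_p[i] + 1e-12, p_un)
  }
})

test_that("F is invariant to row order and affine value rescaling", {
  set.seed(17)
  d <- data.frame(group = rep(c("A", "B", "C"), each = 5), value = rnorm(15))
  f0 <- one_way_anova_tukey(d)$anova$f
  d2 <- d[sample(nrow(d)), ]
  expect_equal(one_way_anova_tukey(d2)$anova$f, f0)
  d3 <- transform(d, value = 3.7 * value - 11)
  expect_equal(one_way_anova_tukey(d3)$anova$f, f0)
})

test_that("two-way ANOVA finds a planted genotype effect, not an interaction", {
  set.seed(23)
  n_sig <- 0L; p_int <- numeric(40)
  for (s in 1:40) {
    d <- expand.grid(rep_id = 1:6, group = c("wt", "ko"),
                     region = c("proximal", "distal"))
    d$value <- rnorm(nrow(d)) + ifelse(d$group == "ko", 2, 0)
    st <- two_way_anova_tukey(d)
    if (st$anova$p[st$anova$effect == "group"] < 0.05) n_sig <- n_sig + 1L
    p_int[s] <- st$anova$p[st$anova$effect == "group:region"]
  }
  expect_gte(n_sig, 36)                       # planted effect detected
  expect_gt(mean(p_int > 0.05), 0.85)         # no spurious interaction
})

test_that("two-way with all cell means equal gives near-zero F", {
  set.seed(3)
  d <- expand.grid(rep_id = 1:50, group = c("a", "b"), region = c("r", "s"))
  d$value <- rnorm(nrow(d), sd = 0.1) + 5
  st <- two_way_anova_tukey(d)
  expect_true(all(st$anova$f < 4))
  expect_true(all(st$anova$p > 0.01))
})

test_that("two-way Tukey compares genotypes within each region", {
  set.seed(5)
  d <- expand.grid(rep_id = 1:5, group = c("wt", "het", "ko"),
                   region = c("proximal", "distal"))
  d$value <- rnorm(nrow(d))
  st <- two_way_anova_tukey(d)
  expect_equal(nrow(st$tukey), 2 * choose(3, 2))
  expect_true(all(st$tukey$region %in% c("proximal", "distal")))
  expect_error(two_way_anova_tukey(d[d$group != "wt" | d$region != "distal", ]),
               "wt")
})

test_that("a single region level degenerates to the one-way analysis", {
  set.seed(7)
  d <- data.frame(group = rep(c("A", "B", "C"), each = 5),
                  region = "only", value = rnorm(15))
  expect_equal(two_way_anova_tukey(d)$anova$f, one_way_anova_tukey(d)$anova$f)
})

test_that("label permutation leaves the null p distribution unchanged", {
  ps <- ps_perm <- numeric(100)
  for (s in 1:100) {
    d <- simulate_group_data(c(0, 0, 0), c(1, 1, 1), c(8, 8, 8), seed = s)
    ps[s] <- one_way_anova_tukey(d, group = "group")$anova$p
    set.seed(s + 1000)
    d$group <- sample(d$group)
    ps_perm[s] <- one_way_anova_tukey(d, group = "group")$anova$p
  }
  expect_gt(suppressWarnings(ks.test(ps, ps_perm))$p.value, 0.01)
})
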