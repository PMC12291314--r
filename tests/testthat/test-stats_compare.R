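test_that("variability_stat is the (max - min)/max range statistic", {
  expect_equal(variability_stat(c(0.40, 0.57, 0.59, 1.08)),
               (1.08 - 0.40) / 1.08)
  expect_equal(variability_stat(c(1, 2, 4)), 0.75)
  expect_equal(variability_stat(c(3, 3, 3)), 0)
  expect_error(variability_stat(c(-2, -1)), "> 0")
  # scale invariance
  set.seed(5)
  m <- runif(6, 0.5, 3)
  expect_equal(variability_stat(10 * m), variability_stat(m))
})

test_that("variability works per variety from a tidy table with delta_V", {
  tab <- group_table(data.frame(
    variety = rep(c("A", "B"), each = 6),
    treatment = rep(rep(c("0h", "8h", "24h"), each = 2), 2),
    replicate = rep(1:2, 6), trait = "Pn",
    value = c(10, 10, 6, 6, 2, 2,   10, 10, 8, 8, 5, 5)))
  vb <- variability(tab, "Pn", varieties = c("A", "B"))
  expect_equal(vb$V_per_variety[["A"]], 0.8)
  expect_equal(vb$V_per_variety[["B"]], 0.5)
  expect_equal(vb$delta_V, 0.3)
})

test_that("LSD letters: identical groups share 'a'; separated groups split", {
  tab <- make_onetrait_table(c(10, 10, 10), n = 4, sd = 0.5, seed = 1)
  al <- one_way_anova_lsd(tab, "y", grouping = "treatment")
  expect_true(all(al$letters == "a"))

  tab2 <- make_onetrait_table(c(10, 10, 50), n = 4, sd = 1e-3, seed = 2)
  al2 <- one_way_anova_lsd(tab2, "y", grouping = "treatment")
  expect_equal(al2$letters, c("b", "b", "a"))  # 'a' on the largest mean
})

test_that("zero within-group variance degenerates cleanly", {
  tab <- make_onetrait_table(c(5, 5, 9), n = 3, sd = 0, seed = 3)
  al <- one_way_anova_lsd(tab, "y")
  expect_equal(al$letters[al$mean == 9], "a")
  expect_true(all(al$letters[al$mean == 5] == "b"))
  tab2 <- make_onetrait_table(c(5, 5, 5), n = 3, sd = 0, seed = 3)
  expect_true(all(one_way_anova_lsd(tab2, "y")$letters == "a"))
  expect_error(one_way_anova_lsd(make_onetrait_table(c(1, 2), n = 1), "y"),
               "n < 2")
})

# oracle: direct pairwise LSD decisions from first principles
lsd_decisions <- function(vals, alpha = 0.05) {
  k <- length(vals)
  n <- lengths(vals)
  m <- vapply(vals, mean, 0)
  mse <- sum(vapply(vals, function(v) sum((v - mean(v))^2), 0)) / (sum(n) - k)
  tc <- qt(1 - alpha / 2, sum(n) - k)
  outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
    i != j && abs(m[i] - m[j]) > tc * sqrt(mse * (1 / n[i] + 1 / n[j]))))
}

test_that("letter display satisfies the sharing biconditional (random fixtures)", {
  set.seed(99)
  for (rep in 1:20) {
    means <- runif(4, 0, 6)
    tab <- make_onetrait_table(means, n = 3, sd = runif(1, 0.2, 2))
    al <- one_way_anova_lsd(tab, "y")
    vals <- split(tab$value, factor(tab$treatment, levels = al$group))
    want <- lsd_decisions(vals)
    share <- function(a, b)
      length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(!share(al$letters[i], al$letters[j]), want[i, j],
                   label = sprintf("fixture %d pair %d-%d", rep, i, j))
  }
})

make_twoway_table <- function(cell_means, n = 3, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  va <- rownames(cell_means); tr <- colnames(cell_means)
  rows <- expand.grid(variety = va, treatment = tr, replicate = seq_len(n),
                      stringsAsFactors = FALSE)
  rows$trait <- "y"
  rows$value <- rnorm(nrow(rows),
                      cell_means[cbind(rows$variety, rows$treatment)], sd)
  group_table(rows)
}

test_that("two-way ANOVA: equal cell means give F = 0 for all effects", {
  cm <- matrix(7, 2, 4, dimnames = list(c("A", "B"), c("0h", "4h", "8h", "24h")))
  tab <- make_twoway_table(cm, n = 3, sd = 0)
  # add within-cell variation that leaves every cell mean at 7
  tab$value <- tab$value + rep(c(-1, 0, 1), each = 8)
  tw <- two_way_anova(tab, "y")
  expect_equal(tw$F[tw$effect != "Residuals"], rep(0, 3), tolerance = 1e-10)
  expect_true(all(tw$stars[tw$effect != "Residuals"] == "NS"))
})

test_that("two-way ANOVA detects a pure treatment effect and flags stars", {
  cm <- matrix(rep(c(0, 0, 0, 10), each = 2), 2, 4,
               dimnames = list(c("A", "B"), c("0h", "4h", "8h", "24h")))
  tab <- make_twoway_table(cm, n = 3, sd = 0.5, seed = 13)
  tw <- two_way_anova(tab, "y")
  expect_equal(tw$stars[tw$effect == "treatment"], "**")
  expect_true(all(tw$stars[tw$effect %in% c("variety", "variety x treatment")]
                  == "NS"))
  # missing cell -> usage error
  bad <- tab[!(tab$variety == "A" & tab$treatment == "4h"), ]
  bad <- as.data.frame(bad)
  expect_error(two_way_anova(structure(bad, class = c("group_table", "data.frame")),
                             "y"), "cell|lacks treatment")
})

test_that("two-way sums of squares decompose the total (balanced design)", {
  set.seed(31)
  for (r in 1:10) {
    cm <- matrix(rnorm(8, 5, 2), 2, 4,
                 dimnames = list(c("A", "B"), c("0h", "4h", "8h", "24h")))
    tab <- make_twoway_table(cm, n = 3, sd = 1)
    tw <- two_way_anova(tab, "y")
    expect_equal(sum(tw$SS), attr(tw, "SS_total"), tolerance = 1e-9)
  }
})

test_that("relative_profile divides treatment means by the control mean", {
  tab <- group_table(data.frame(
    variety = "A", treatment = rep(c("0h", "24h"), each = 3),
    replicate = rep(1:3, 2), trait = "ABS_RC",
    value = c(2.0, 2.0, 2.0, 2.3, 2.4, 2.38)))
  rel <- relative_profile(tab, "0h")
  expect_equal(rel$value[rel$treatment == "0h"], 1.0)
  expect_equal(rel$value[rel$treatment == "24h"], mean(c(2.3, 2.4, 2.38)) / 2)
  tab0 <- tab; tab0$value[1:3] <- 0
  expect_error(relative_profile(tab0, "0h"), "zero control")
})

test_that("correlation matrix matches the direct Pearson formulas", {
  set.seed(17)
  n_obs <- 8
  traits <- sprintf("t%d", 1:5)
  tab <- group_table(expand.grid(
    variety = "A", treatment = c("0h", "24h"), replicate = 1:4,
    trait = traits, stringsAsFactors = FALSE) |>
      transform(value = rnorm(2 * 4 * 5)))
  cm <- correlation_matrix(tab, traits)
  wide <- sapply(traits, function(tr) {
    s <- tab[tab$trait == tr, ]
    s$value[order(s$treatment, s$replicate)]
  })
  for (i in 1:4) for (j in (i + 1):5) {
    x <- wide[, i]; y <- wide[, j]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt((n_obs - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n_obs - 2)
    expect_equal(cm$r[i, j], r, tolerance = 1e-12)
    expect_equal(cm$p[i, j], p, tolerance = 1e-12)
  }
  expect_equal(diag(cm$r), rep(1, 5), ignore_attr = TRUE)
  expect_identical(cm$r, t(cm$r))
})

test_that("exact linear dependence, constant traits, and stars", {
  x <- 1:8
  tab <- group_table(rbind(
    data.frame(variety = "A", treatment = rep(c("0h", "24h"), 4),
               replicate = rep(1:4, each = 2), trait = "x", value = x),
    data.frame(variety = "A", treatment = rep(c("0h", "24h"), 4),
               replicate = rep(1:4, each = 2), trait = "y", value = 2 * x + 1),
    data.frame(variety = "A", treatment = rep(c("0h", "24h"), 4),
               replicate = rep(1:4, each = 2), trait = "flat", value = 5)))
  expect_warning(cm <- correlation_matrix(tab, c("x", "y", "flat")), "constant")
  expect_equal(cm$r["x", "y"], 1)
  expect_true(is.na(cm$r["x", "flat"]))
  expect_equal(p_stars(c(5e-4, 5e-3, 0.03, 0.07, 0.5)),
               c("***", "**", "*", "·", ""))
})
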