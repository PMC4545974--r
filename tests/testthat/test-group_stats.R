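test_that("Levene test: degenerate, null-calibrated, and powered cases", {
  # identical values in both groups: statistic 0
  lt <- levene_test(rep(c(1, 2), each = 4), rep(c("a", "b"), each = 4))
  expect_equal(lt$statistic, 0, tolerance = 1e-12)
  expect_equal(lt$p, 1, tolerance = 1e-9)
  expect_error(levene_test(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")

  # type-I calibration and power (moderate replicate counts here;
  # the acceptance suite runs the full 2000-replicate version)
  set.seed(61)
  rej_null <- mean(replicate(400, {
    levene_test(rnorm(60), rep(c("a", "b"), each = 30))$p < 0.05
  }))
  expect_gt(rej_null, 0.02); expect_lt(rej_null, 0.09)
  rej_het <- mean(replicate(200, {
    levene_test(c(rnorm(30, sd = 3), rnorm(30, sd = 1)),
                rep(c("a", "b"), each = 30))$p < 0.05
  }))
  expect_gt(rej_het, 0.9)
})

test_that("mixed ANOVA reduces to the pooled t test with two groups", {
  set.seed(62)
  d <- data.frame(participant_id = 1:50,
                  g = rep(c("a", "b"), c(22, 28)),
                  y = rnorm(50, sd = 2))
  a <- mixed_anova(d, "y", between = "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(a$F[a$effect == "g"], unname(tt$statistic)^2,
               tolerance = 1e-9)
  expect_equal(a$p[a$effect == "g"], tt$p.value, tolerance = 1e-9)
})

test_that("mixed ANOVA matches aov on a balanced split-plot design", {
  set.seed(63)
  dd <- expand.grid(participant_id = factor(1:24),
                    direction = c("open", "close"),
                    syllable = c("Bob", "pup"))
  dd$group <- rep(c("s", "c"), each = 12)[dd$participant_id]
  dd$sex <- rep(rep(c("m", "f"), each = 6), 2)[dd$participant_id]
  dd$y <- rnorm(nrow(dd)) + 0.8 * (dd$direction == "open") +
    0.5 * (dd$group == "s") * (dd$sex == "m")
  a <- mixed_anova(dd, "y", between = c("group", "sex"),
                   within = c("direction", "syllable"))
  fit <- aov(y ~ group * sex * direction * syllable +
               Error(participant_id / (direction * syllable)), data = dd)
  s <- summary(fit)
  pick <- function(tbl, term) {
    i <- trimws(rownames(tbl[[1]])) == term
    c(F = tbl[[1]][i, "F value"], p = tbl[[1]][i, "Pr(>F)"])
  }
  oracle <- rbind(
    group = pick(s[["Error: participant_id"]], "group"),
    `group:sex` = pick(s[["Error: participant_id"]], "group:sex"),
    direction = pick(s[["Error: participant_id:direction"]], "direction"),
    `sex:syllable` = pick(s[["Error: participant_id:syllable"]],
                          "sex:syllable"),
    `group:sex:direction:syllable` = pick(
      s[["Error: participant_id:direction:syllable"]],
      "group:sex:direction:syllable"))
  for (eff in rownames(oracle)) {
    expect_equal(a$F[a$effect == eff], unname(oracle[eff, "F"]),
                 tolerance = 1e-9, info = eff)
    expect_equal(a$p[a$effect == eff], unname(oracle[eff, "p"]),
                 tolerance = 1e-9, info = eff)
  }
})

test_that("mixed ANOVA handles degenerate and invalid inputs", {
  d <- data.frame(participant_id = 1:8, g = rep(c("a", "b"), 4),
                  y = rep(5, 8))
  a <- mixed_anova(d, "y", between = "g")
  expect_equal(a$F, 0, tolerance = 1e-9)
  # incomplete within cells are dropped listwise
  dd <- expand.grid(participant_id = 1:6, w = c("x", "z"))
  dd$g <- rep(c("a", "b"), 3)[dd$participant_id]
  dd$y <- rnorm(12)
  dd <- dd[-1, ]  # subject 1 loses one cell
  expect_message(mixed_anova(dd, "y", between = "g", within = "w"),
                 "incomplete")
  # >2-level within factors are not supported
  d3 <- expand.grid(participant_id = 1:6, w = c("x", "y", "z"))
  d3$y <- rnorm(18)
  expect_error(mixed_anova(d3, "y", within = "w"), "2 levels")
})

test_that("ANOVA results are invariant to observation order and affine dv scaling", {
  set.seed(64)
  dd <- expand.grid(participant_id = 1:20, direction = c("o", "c"))
  dd$group <- rep(c("s", "c"), 10)[dd$participant_id]
  dd$y <- rnorm(40)
  a0 <- mixed_anova(dd, "y", between = "group", within = "direction")
  perm <- dd[sample(nrow(dd)), ]
  a1 <- mixed_anova(perm, "y", between = "group", within = "direction")
  expect_equal(a1$F[order(a1$effect)], a0$F[order(a0$effect)],
               tolerance = 1e-9)
  dd$y2 <- 3.7 * dd$y - 11
  a2 <- mixed_anova(dd, "y2", between = "group", within = "direction")
  # affine rescaling changes the within 'direction' intercept test? No:
  # the shift cancels in difference scores and scaling cancels in F.
  expect_equal(a2$F, a0$F, tolerance = 1e-9)
})

test_that("Tukey-Kramer agrees with the t test for two equal-n groups", {
  set.seed(65)
  y <- rnorm(40); g <- rep(c("a", "b"), each = 20)
  tk <- tukey_kramer(y, g)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(abs(tk$diff), abs(diff(tapply(y, g, mean))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # q = t * sqrt(2) mapping
  expect_equal(tk$q, abs(unname(tt$statistic)) * sqrt(2),
               tolerance = 1e-9)
})

test_that("Tukey-Kramer: identical groups, size-1 exclusion, power", {
  y <- rep(c(3, 4), 8)
  g <- rep(c("a", "b", "c", "d"), each = 4)
  tk <- tukey_kramer(y, g)
  expect_equal(nrow(tk), 6L)
  expect_true(all(tk$p_adj > 0.999))
  expect_warning(tukey_kramer(c(y, 9), c(g, "e")), "size 1")
  # one cell shifted by 1 pooled SD, n = 25: high detection rate
  set.seed(66)
  hits <- mean(replicate(150, {
    yy <- rnorm(100); gg <- rep(c("a", "b", "c", "d"), each = 25)
    yy[gg == "d"] <- yy[gg == "d"] + 1
    tk <- tukey_kramer(yy, gg)
    all(tk$p_adj[tk$group1 == "d" | tk$group2 == "d"] < 0.05)
  }))
  expect_gt(hits, 0.6)
})

test_that("correlation tables: exact cases, missing data, constant columns", {
  d <- data.frame(a = 1:10, b = 2 * (1:10) + 3, c = -(1:10),
                  k = rep(1, 10))
  ct <- correlate_measures(d)
  expect_equal(ct$r["a", "b"], 1, tolerance = 1e-12)
  expect_equal(ct$r["a", "c"], -1, tolerance = 1e-12)
  expect_true(is.na(ct$r["a", "k"]))
  # pairwise deletion
  d$b[3] <- NA
  ct2 <- correlate_measures(d, c("a", "b"))
  expect_equal(ct2$n["a", "b"], 9)
  # null calibration: independent pairs have near-zero mean r
  set.seed(67)
  rs <- replicate(300, correlate_measures(
    data.frame(x = rnorm(53), y = rnorm(53)))$r["x", "y"])
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("therapy-history comparison is a pooled-variance t test", {
  set.seed(68)
  y <- rnorm(30); th <- rep(c(TRUE, FALSE), 15)
  res <- therapy_ttest(y, th)
  expect_equal(res$p.value,
               t.test(y ~ th, var.equal = TRUE)$p.value)
  expect_error(therapy_ttest(y, rep(TRUE, 30)), "2 levels")
})
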