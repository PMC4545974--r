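#' Levene's test for homogeneity of variance
#'
#' Classic Levene test on absolute deviations from the group means
#' (not the Brown-Forsythe median variant), as routinely run before
#' each between-group ANOVA to check the equal-variance assumption.
#' Thin wrapper over \code{car::leveneTest(center = mean)}.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @return List with \code{statistic} (F), \code{df} (numerator,
#'   denominator), \code{p}.
#' @export
levene_test <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("input error: need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("input error: every group needs at least 2 observations",
         call. = FALSE)
  lt <- car::leveneTest(values, groups, center = mean)
  stat <- unname(lt[1, "F value"]); p <- unname(lt[1, "Pr(>F)"])
  if (is.nan(stat)) { stat <- 0; p <- 1 }  # zero dispersion everywhere
  list(statistic = stat,
       df = c(lt[1, "Df"], lt[2, "Df"]),
       p = p)
}

# Per-subject contrast scores for a subset S of 2-level within factors:
# mean of dv weighted by the product of +/-1 codes of the factors in S
# (S empty -> plain subject mean). Assumes complete within cells.
within_contrast_scores <- function(dat, dv, subject, within, S) {
  w <- rep(1, nrow(dat))
  for (f in S) {
    lv <- levels(dat[[f]])
    w <- w * ifelse(dat[[f]] == lv[1], 1, -1)
  }
  agg <- aggregate(dat[[dv]] * w, by = list(subject = dat[[subject]]),
                   FUN = mean)
  names(agg)[2] <- "score"
  agg
}

#' Mixed-design (split-plot) ANOVA with 2-level within factors
#'
#' Univariate repeated-measures ANOVA with between-subject factors
#' (e.g. stuttering group and sex) and any number of two-level
#' within-subject factors (e.g. movement direction, syllable,
#' sentence). Each within-effect subset is tested on per-subject
#' difference scores and the between effects on per-subject means,
#' with Type-III (sum-to-zero) tests so unequal between-cell sizes are
#' handled on an unweighted-means basis. With two-level within factors
#' sphericity holds trivially, so no correction is needed. Subjects
#' with incomplete within cells are dropped listwise with a message.
#'
#' @param data Long-format data.frame.
#' @param dv Name of the dependent-variable column.
#' @param between Character vector of between-subject factor columns
#'   (may be empty).
#' @param within Character vector of within-subject factor columns
#'   (each must have exactly 2 levels; may be empty).
#' @param subject Name of the subject-identifier column.
#' @return Object of class \code{"anova_result"}: data.frame with
#'   \code{effect}, \code{F}, \code{df_num}, \code{df_den}, \code{p}.
#' @export
mixed_anova <- function(data, dv, between = character(),
                        within = character(), subject = "participant_id") {
  stopifnot(is.data.frame(data), dv %in% names(data),
            subject %in% names(data),
            all(between %in% names(data)),
            all(within %in% names(data)))
  dat <- data[, c(subject, between, within, dv)]
  dat <- dat[complete.cases(dat), ]
  for (f in c(between, within)) dat[[f]] <- factor(dat[[f]])
  for (f in within) {
    if (nlevels(dat[[f]]) != 2L)
      stop(sprintf(
        "within factor '%s' must have exactly 2 levels", f),
        call. = FALSE)
  }
  dat[[subject]] <- factor(dat[[subject]])

  n_cells <- max(1L, prod(vapply(within, function(f)
    nlevels(dat[[f]]), integer(1))))
  cnt <- table(dat[[subject]])
  incomplete <- names(cnt)[cnt != n_cells]
  if (length(incomplete)) {
    message(sprintf(
      "mixed_anova: dropping %d subject(s) with incomplete within cells",
      length(incomplete)))
    dat <- dat[!dat[[subject]] %in% incomplete, ]
    dat[[subject]] <- droplevels(dat[[subject]])
  }
  subj_between <- unique(dat[, c(subject, between), drop = FALSE])
  if (anyDuplicated(subj_between[[subject]]))
    stop("between factors vary within subject", call. = FALSE)
  if (length(between) &&
      any(table(subj_between[, between, drop = FALSE]) < 2L))
    stop("input error: each between cell needs at least 2 subjects",
         call. = FALSE)

  between_formula <- if (length(between))
    paste(between, collapse = " * ") else "1"
  contr <- if (length(between))
    setNames(rep(list("contr.sum"), length(between)), between) else NULL

  subsets <- list(character(0))
  for (f in within)
    subsets <- c(subsets, lapply(subsets, function(s) c(s, f)))

  rows <- list()
  for (S in subsets) {
    sc <- within_contrast_scores(dat, dv, subject, within, S)
    sdat <- merge(sc, subj_between, by.x = "subject", by.y = subject)
    fit <- lm(as.formula(paste("score ~", between_formula)),
              data = sdat, contrasts = contr)
    if (length(between)) {
      if (var(sdat$score) < 1e-25 * max(1, mean(sdat$score)^2)) {
        # no variance at all: every effect is 0/0, reported as F = 0
        labs <- attr(terms(as.formula(paste("~", between_formula))),
                     "term.labels")
        effs <- if (length(S))
          c(paste(S, collapse = ":"),
            vapply(labs, function(tm) paste(c(tm, S), collapse = ":"),
                   character(1)))
        else labs
        for (eff in effs)
          rows[[length(rows) + 1L]] <- data.frame(
            effect = eff, F = 0, df_num = 1L,
            df_den = nrow(sdat) - length(labs) - 1L, p = 1,
            stringsAsFactors = FALSE)
        next
      }
      a3 <- car::Anova(fit, type = 3)
      terms_keep <- setdiff(rownames(a3), "Residuals")
      df_den <- a3["Residuals", "Df"]
      for (tm in terms_keep) {
        eff <- if (tm == "(Intercept)") {
          if (!length(S)) next  # grand mean, not an effect
          paste(S, collapse = ":")
        } else if (!length(S)) tm else paste(c(tm, S), collapse = ":")
        Fv <- a3[tm, "F value"]; pv <- a3[tm, "Pr(>F)"]
        if (is.nan(Fv)) { Fv <- 0; pv <- 1 }  # 0/0: no variance anywhere
        rows[[length(rows) + 1L]] <- data.frame(
          effect = eff, F = Fv,
          df_num = a3[tm, "Df"], df_den = df_den,
          p = pv, stringsAsFactors = FALSE)
      }
    } else if (length(S)) {
      # no between factors: one-sample F on the contrast scores
      sm <- summary(fit)
      tval <- sm$coefficients["(Intercept)", "t value"]
      dfr <- fit$df.residual
      Fv <- tval^2; pv <- pf(Fv, 1, dfr, lower.tail = FALSE)
      if (is.nan(Fv)) { Fv <- 0; pv <- 1 }
      rows[[length(rows) + 1L]] <- data.frame(
        effect = paste(S, collapse = ":"), F = Fv,
        df_num = 1L, df_den = dfr, p = pv,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("anova_result", "data.frame"))
}

#' @export
print.anova_result <- function(x, ...) {
  cat("Mixed-design ANOVA\n")
  df <- as.data.frame(x)
  df$F <- sprintf("%.3f", df$F)
  df$p <- format.pval(df$p, digits = 3, eps = 1e-4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Tukey-Kramer post hoc comparisons (HSD for unequal n)
#'
#' All pairwise group comparisons using the studentized-range
#' distribution with the Tukey-Kramer unequal-n standard error
#' \code{sqrt(MSE/2 * (1/n_i + 1/n_j))}, where MSE is the pooled
#' within-group variance. Groups of size 1 are excluded with a
#' warning.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @return Object of class \code{"posthoc_result"}: data.frame with
#'   \code{group1}, \code{group2}, \code{diff} (mean1 - mean2),
#'   \code{se}, \code{q}, \code{p_adj}.
#' @export
tukey_kramer <- function(values, groups) {
  groups <- factor(groups)
  cnt <- table(groups)
  if (any(cnt < 2L)) {
    warning(sprintf("excluding %d group(s) of size 1",
                    sum(cnt < 2L)), call. = FALSE)
    keep <- groups %in% names(cnt)[cnt >= 2L]
    values <- values[keep]; groups <- droplevels(groups[keep])
    cnt <- table(groups)
  }
  k <- nlevels(groups)
  if (k < 2L) stop("need at least 2 groups of size >= 2", call. = FALSE)
  means <- tapply(values, groups, mean)
  vars <- tapply(values, groups, var)
  n <- as.numeric(cnt)
  df <- sum(n) - k
  mse <- sum((n - 1) * vars) / df
  pairs <- utils::combn(levels(groups), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    d <- means[[i]] - means[[j]]
    se <- sqrt(mse / 2 * (1 / cnt[[i]] + 1 / cnt[[j]]))
    q <- abs(d) / se
    c(diff = d, se = se, q = q,
      p_adj = ptukey(q, k, df, lower.tail = FALSE))
  })
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    t(res), stringsAsFactors = FALSE)
  attr(out, "mse") <- mse
  attr(out, "df") <- df
  structure(out, class = c("posthoc_result", "data.frame"))
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(sprintf("Tukey-Kramer pairwise comparisons (MSE %.4g, df %d)\n",
              attr(x, "mse"), attr(x, "df")))
  df <- as.data.frame(x)
  df$p_adj <- format.pval(df$p_adj, digits = 3, eps = 1e-4)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise Pearson correlations among participant measures
#'
#' Correlation table (r and two-sided p) among kinematic dependent
#' variables and clinical scores, with pairwise deletion of missing
#' data. A constant column yields \code{NA} for its correlations.
#'
#' @param records Data.frame of per-participant measures.
#' @param vars Columns to correlate (default: all numeric columns).
#' @return List with matrices \code{r}, \code{p}, \code{n}, of class
#'   \code{"correlation_table"}.
#' @export
correlate_measures <- function(records, vars = NULL) {
  if (is.null(vars))
    vars <- names(records)[vapply(records, is.numeric, logical(1))]
  stopifnot(length(vars) >= 2L)
  k <- length(vars)
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    x <- records[[vars[i]]]; y <- records[[vars[j]]]
    ok <- is.finite(x) & is.finite(y)
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = nmat),
            class = "correlation_table")
}

#' @export
print.correlation_table <- function(x, ...) {
  cat("Pearson correlations (pairwise complete)\n")
  print(round(x$r, 2))
  invisible(x)
}

#' Two-group comparison by therapy history
#'
#' Independent-samples (pooled-variance) t test of a kinematic measure
#' between participants with and without a therapy history.
#'
#' @param values Numeric measure.
#' @param therapy Logical (or two-level) grouping.
#' @return \code{htest} object from [stats::t.test()].
#' @export
therapy_ttest <- function(values, therapy) {
  g <- factor(therapy)
  if (nlevels(g) != 2L)
    stop("therapy must have exactly 2 levels", call. = FALSE)
  t.test(values ~ g, var.equal = TRUE)
}
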