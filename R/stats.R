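#' Group comparison with normality-routed test selection
#'
#' Mirrors the reporting convention of the source field: normality of each
#' group is assessed with the Lilliefors-corrected Kolmogorov-Smirnov test;
#' two normal groups are compared with Welch's t test, otherwise
#' Mann-Whitney; more than two normal groups with one-way ANOVA and
#' Bonferroni posthoc, otherwise Kruskal-Wallis with Dunn's posthoc.
#' Categorical 2x2 data (supplied as a matrix) use Fisher's exact test.
#' Groups smaller than 5 are routed non-parametrically (too small for a
#' meaningful normality verdict).
#'
#' @param samples named list of numeric vectors (one per group), or a 2x2
#'   count matrix for categorical data.
#' @param alternative "two.sided" (default), "less" or "greater", per the
#'   declared hypothesis direction (two-group and categorical comparisons
#'   only).
#' @param alpha significance level for the normality verdicts.
#' @return list of class `group_comparison`: `groups`, `normal` (per-group
#'   verdicts), `test` (name), `statistic`, `p_value`, `posthoc`
#'   (pairwise table or NULL).
#' @export
compare_groups <- function(samples, alternative = "two.sided",
                           alpha = 0.05) {
  if (is.matrix(samples)) {
    ft <- stats::fisher.test(samples, alternative = alternative)
    return(structure(list(groups = colnames(samples), normal = NA,
                          test = "Fisher exact",
                          statistic = NA_real_, p_value = ft$p.value,
                          posthoc = NULL), class = "group_comparison"))
  }
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples))) {
    names(samples) <- paste0("group", seq_along(samples))
  }
  n <- vapply(samples, length, integer(1))
  if (any(n < 3)) stop("each group needs n >= 3")

  normal <- vapply(samples, function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(FALSE)
    nortest::lillie.test(x)$p.value >= alpha
  }, logical(1))

  k <- length(samples)
  if (k == 2) {
    if (all(normal)) {
      ht <- stats::t.test(samples[[1]], samples[[2]],
                          alternative = alternative, var.equal = FALSE)
      test <- "Welch t"
    } else {
      ht <- stats::wilcox.test(samples[[1]], samples[[2]],
                               alternative = alternative, exact = FALSE)
      test <- "Mann-Whitney"
    }
    posthoc <- NULL
    stat <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    x <- unlist(samples, use.names = FALSE)
    g <- factor(rep(names(samples), n), levels = names(samples))
    if (all(normal)) {
      fit <- stats::aov(x ~ g)
      p <- summary(fit)[[1]][["Pr(>F)"]][1]
      stat <- summary(fit)[[1]][["F value"]][1]
      test <- "ANOVA + Bonferroni"
      pt <- stats::pairwise.t.test(x, g, p.adjust.method = "bonferroni",
                                   pool.sd = FALSE)
      posthoc <- posthoc_long(pt$p.value)
    } else {
      kw <- stats::kruskal.test(x, g)
      p <- kw$p.value
      stat <- unname(kw$statistic)
      test <- "Kruskal-Wallis + Dunn"
      posthoc <- dunn_test(x, g)
    }
  }
  structure(list(groups = names(samples), normal = normal, test = test,
                 statistic = stat, p_value = p, posthoc = posthoc),
            class = "group_comparison")
}

posthoc_long <- function(pmat) {
  out <- expand.grid(group1 = rownames(pmat), group2 = colnames(pmat),
                     stringsAsFactors = FALSE)
  out$p_adj <- as.vector(pmat)
  out[!is.na(out$p_adj), , drop = FALSE]
}

#' Dunn's posthoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the standard tie correction,
#' Bonferroni-adjusted two-sided p values.
#'
#' @param x numeric response.
#' @param g grouping factor.
#' @return data.frame with `group1`, `group2`, `z`, `p_adj`.
#' @export
dunn_test <- function(x, g) {
  g <- droplevels(as.factor(g))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(g)
  prs <- utils::combn(lv, 2)
  m <- ncol(prs)
  out <- lapply(seq_len(m), function(k) {
    a <- prs[1, k]; b <- prs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    data.frame(group1 = a, group2 = b, z = z,
               p_adj = min(1, 2 * stats::pnorm(-abs(z)) * m))
  })
  do.call(rbind, out)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Comparison of", length(x$groups), "groups:", x$test, "\n")
  if (!all(is.na(x$normal))) {
    cat("  normality:", paste0(x$groups, "=",
                               ifelse(x$normal, "normal", "non-normal"),
                               collapse = ", "), "\n")
  }
  cat("  p =", format.pval(x$p_value, digits = 3), "\n")
  if (!is.null(x$posthoc)) {
    cat("  posthoc:\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
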