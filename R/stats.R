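# Group-comparison statistics, following the routing convention of the
# analysis this package reproduces: data are first checked for normality
# (D'Agostino-Pearson omnibus for n >= 8, Shapiro-Wilk for smaller groups);
# normally distributed data are compared with Student's unpaired two-tailed
# t-test (2 groups) or ordinary one-way ANOVA with Tukey's post-test (> 2
# groups); otherwise Mann-Whitney or Kruskal-Wallis with Dunn's post-test.
# Fisher's exact test handles 2 x 2 contingency tables. Units of analysis
# are fish by default (cell-level values are first averaged per fish).

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) z statistics into K2 = z1^2 + z2^2, referred to
#' a chi-squared distribution with 2 df. Requires n >= 8.
#'
#' @param x Numeric vector.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson requires n >= 8")
  if (sd(x) == 0) stop("degenerate sample (zero variance)")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  # skewness
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis
  g2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (g2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  z2 <- ((1 - 2 / (9 * a)) -
         ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) *
    sqrt(9 * a / 2)
  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

normality_p <- function(x) {
  if (length(x) >= 8) dagostino_pearson(x)$p_value
  else shapiro.test(x)$p.value
}

#' Average cell-level measurements per fish
#'
#' One value per fish: the mean over that fish's cells. Fish with zero
#' cells are excluded (with a warning).
#'
#' @param measurements Data frame with columns `group`, `fish`, `value`
#'   (one row per cell); `NA` values count as missing cells.
#' @return Data frame with columns `group`, `fish`, `value` (one row per
#'   fish), of class `ls_grouped` with attribute `level = "fish"`.
#' @export
aggregate_per_fish <- function(measurements) {
  stopifnot(all(c("group", "fish", "value") %in% names(measurements)))
  keep <- is.finite(measurements$value)
  dropped_fish <- setdiff(unique(measurements$fish[!keep]),
                          unique(measurements$fish[keep]))
  if (length(dropped_fish))
    warning("fish with no usable cell values excluded: ",
            paste(dropped_fish, collapse = ", "))
  measurements <- measurements[keep, , drop = FALSE]
  agg <- aggregate(value ~ group + fish, measurements, mean)
  agg <- agg[order(agg$group, agg$fish), c("group", "fish", "value")]
  rownames(agg) <- NULL
  attr(agg, "level") <- "fish"
  class(agg) <- c("ls_grouped", class(agg))
  agg
}

#' Normality-routed comparison of two or more groups
#'
#' Takes the parametric route iff every group passes its normality test at
#' `alpha_normality` (D'Agostino-Pearson when n >= 8, Shapiro-Wilk
#' otherwise). Two groups: Student's unpaired two-tailed t-test or
#' Mann-Whitney. More than two: one-way ANOVA with Tukey's post-test, or
#' Kruskal-Wallis with Dunn's post-test (Bonferroni-adjusted).
#'
#' @param grouped Data frame with columns `group` and `value` (e.g. from
#'   [aggregate_per_fish()]); every group needs n >= 3.
#' @param alpha_normality Significance level of the normality gate.
#' @return List of class `ls_test_result`: `test`, `route`
#'   (`"parametric"`/`"nonparametric"`), `statistic`, `p_value`,
#'   `normality_p` (per group), `post_test` (data frame of pairwise
#'   comparisons, or `NULL`), `degenerate` flag.
#' @export
compare_groups <- function(grouped, alpha_normality = 0.05) {
  stopifnot(all(c("group", "value") %in% names(grouped)))
  grouped <- grouped[is.finite(grouped$value), , drop = FALSE]
  groups <- split(grouped$value, factor(grouped$group))
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3))
    stop("insufficient data: every group needs n >= 3 (got ",
         paste(ns, collapse = ", "), ")")
  if (all(vapply(groups, function(g) sd(g) == 0, logical(1))) &&
      length(unique(unlist(groups))) <= 1) {
    return(structure(list(test = "none", route = NA_character_,
                          statistic = NA_real_, p_value = NA_real_,
                          normality_p = NULL, post_test = NULL,
                          degenerate = TRUE),
                     class = "ls_test_result"))
  }
  if (any(vapply(groups, function(g) sd(g) == 0, logical(1)))) {
    # constant group: the normality gate is undefined; route nonparametric
    norm_p <- rep(NA_real_, k)
    parametric <- FALSE
  } else {
    norm_p <- vapply(groups, normality_p, numeric(1))
    parametric <- all(norm_p > alpha_normality)
  }
  route <- if (parametric) "parametric" else "nonparametric"
  post <- NULL
  if (k == 2) {
    if (parametric) {
      ht <- t.test(groups[[1]], groups[[2]], var.equal = TRUE)
      test <- "Student t (unpaired, two-tailed)"
    } else {
      ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
      test <- "Mann-Whitney"
    }
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    df <- data.frame(value = unlist(groups),
                     group = factor(rep(names(groups), ns)))
    if (parametric) {
      fit <- aov(value ~ group, data = df)
      tab <- summary(fit)[[1]]
      stat <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
      tk <- TukeyHSD(fit)$group
      post <- data.frame(comparison = rownames(tk),
                         estimate = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL)
      test <- "one-way ANOVA + Tukey"
    } else {
      ht <- kruskal.test(value ~ group, data = df)
      stat <- unname(ht$statistic); p <- ht$p.value
      post <- dunn_posttest(df$value, df$group)
      test <- "Kruskal-Wallis + Dunn"
    }
  }
  structure(list(test = test, route = route, statistic = stat, p_value = p,
                 normality_p = norm_p, post_test = post, degenerate = FALSE),
            class = "ls_test_result")
}

#' @export
print.ls_test_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate comparison (all values identical); no p-value emitted\n")
    return(invisible(x))
  }
  cat(sprintf("%s (%s route): statistic = %.4g, p = %.4g [%s]\n",
              x$test, x$route, x$statistic, x$p_value,
              significance_label(x$p_value)))
  if (!is.null(x$post_test)) {
    cat("Post-test:\n")
    print(x$post_test, row.names = FALSE)
  }
  invisible(x)
}

# Dunn's multiple-comparison post-test on pooled ranks with tie correction;
# two-sided z p-values, Bonferroni-adjusted over the k(k-1)/2 pairs.
dunn_posttest <- function(values, group) {
  group <- factor(group)
  r <- rank(values)
  n <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, group, mean)
  ns <- tapply(r, group, length)
  lev <- levels(group)
  k <- length(lev)
  out <- NULL
  n_pairs <- k * (k - 1) / 2
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ns[[i]] + 1 / ns[[j]]))
      z <- (mean_r[[i]] - mean_r[[j]]) / se
      p <- min(1, 2 * pnorm(-abs(z)) * n_pairs)
      out <- rbind(out, data.frame(
        comparison = paste(lev[j], lev[i], sep = "-"),
        estimate = z, p_adj = p))
    }
  }
  out
}

#' Fisher's exact test on a 2 x 2 contingency table
#'
#' Two-tailed exact p-value for `successes_a / n_a` vs `successes_b / n_b`.
#'
#' @param successes_a,n_a,successes_b,n_b Non-negative counts with
#'   `successes <= n`, `n >= 1`.
#' @return `ls_test_result` with the odds-ratio estimate as `statistic`.
#' @export
compare_proportions <- function(successes_a, n_a, successes_b, n_b) {
  counts <- c(successes_a, n_a, successes_b, n_b)
  if (any(counts < 0) || any(counts != round(counts)) ||
      successes_a > n_a || successes_b > n_b || n_a < 1 || n_b < 1)
    stop("invalid counts")
  tab <- matrix(c(successes_a, n_a - successes_a,
                  successes_b, n_b - successes_b), 2, byrow = TRUE)
  ht <- fisher.test(tab)
  structure(list(test = "Fisher exact", route = "exact",
                 statistic = unname(ht$estimate), p_value = ht$p.value,
                 normality_p = NULL, post_test = NULL, degenerate = FALSE),
            class = "ls_test_result")
}

#' Significance annotation in the standard convention
#'
#' `n.s.` for p > 0.05, then `*` (< 0.05), `**` (< 0.01), `***` (< 0.001),
#' `****` (< 0.0001).
#'
#' @param p A p-value (or vector).
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("n.a.")
    if (pi < 0.0001) "****"
    else if (pi < 0.001) "***"
    else if (pi < 0.01) "**"
    else if (pi < 0.05) "*"
    else "n.s."
  }, character(1))
}
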