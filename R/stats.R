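# Group-comparison decision tree: normality-routed parametric vs
# nonparametric testing, Dunn's post test, bud-count distributions and
# percent-change reporting.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness (D'Agostino 1970) and kurtosis
#' (Anscombe & Glynn 1983) into the K² statistic, chi-squared with 2 df
#' under normality. Requires n >= 8 for the kurtosis transformation to be
#' valid.
#'
#' @param x Numeric vector (n >= 8).
#' @return List with `statistic` (K²), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop_invalid("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) stop_invalid("zero variance: normality test undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness: Johnson SU transformation
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Wilson-Hilferty cube-root transformation
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  base <- (1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4)))
  cuberoot <- sign(base) * abs(base)^(1 / 3)
  z2 <- ((1 - 2 / (9 * a)) - cuberoot) / sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Dunn's multiple comparison post test
#'
#' Rank-based pairwise z tests after a Kruskal-Wallis test, with tie
#' correction and multiplicity adjustment over all pairs.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @param p_adjust Adjustment method for [stats::p.adjust()] (default
#'   `"bonferroni"`, the conventional choice for Dunn's test).
#' @return Tibble with `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  n_tot <- length(values)
  rk <- rank(values)
  lev <- unique(groups)
  if (length(lev) < 2) stop_invalid("Dunn's test needs >= 2 groups")
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n_tot - 1))
  pairs <- utils::combn(lev, 2)
  rows <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_corr) *
                 (1 / n_g[[i]] + 1 / n_g[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  res <- dplyr::bind_rows(rows)
  res$p_adjusted <- p.adjust(res$p_value, method = p_adjust)
  res
}

#' Normality-routed group comparison
#'
#' The decision tree used throughout the quantifications: every group is
#' first assessed with the D'Agostino-Pearson normality test; if all groups
#' are large enough (n >= `min_n_normality`) and none rejects normality at
#' `alpha_normality`, a parametric test is applied (two groups: Welch
#' t-test; more: one-way ANOVA). Otherwise — groups too small for the
#' normality test or any group non-normal — the nonparametric branch is
#' taken (two groups: Mann-Whitney U; more: Kruskal-Wallis with Dunn's
#' multiple comparison post test). The full decision trace is recorded.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 3),
#'   or a data frame with columns `group` and `value`.
#' @param alpha_normality Normality rejection level (default 0.05).
#' @param min_n_normality Smallest n for which the omnibus normality test
#'   is attempted (default 8; smaller groups route directly to the
#'   nonparametric branch).
#' @param p_adjust Adjustment method for Dunn's post test.
#' @return A `group_comparison` object: `test` (label), `statistic`,
#'   `p_value`, `normality` (per-group tibble), `posthoc` (Dunn table or
#'   `NULL`), `trace` (character), `groups`.
#' @export
choose_and_run_test <- function(groups, alpha_normality = 0.05,
                                min_n_normality = 8,
                                p_adjust = "bonferroni") {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups))) {
      stop_invalid("data frame input needs columns `group` and `value`")
    }
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2) stop_invalid("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups <- lapply(groups, function(g) g[is.finite(g)])
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3)) {
    stop_invalid("every group needs n >= 3 (got ",
                 paste(ns, collapse = ", "), ")")
  }
  trace <- character(0)
  all_ties <- all(vapply(groups, function(g) length(unique(g)) == 1,
                         logical(1)))
  if (all_ties) {
    warning("all groups are constant; routing nonparametric", call. = FALSE)
  }
  norm_tab <- tibble::tibble(
    group = names(groups), n = ns,
    k2 = NA_real_, p_normality = NA_real_)
  small <- ns < min_n_normality
  if (any(small)) {
    trace <- c(trace, sprintf(
      "group(s) %s have n < %d: too small for the normality test; routing nonparametric",
      paste(names(groups)[small], collapse = ", "), min_n_normality))
    normal <- FALSE
  } else if (all_ties) {
    trace <- c(trace, "constant data: normality undefined; routing nonparametric")
    normal <- FALSE
  } else if (any(vapply(groups, sd, numeric(1)) == 0)) {
    trace <- c(trace,
               "constant group: normality undefined; routing nonparametric")
    normal <- FALSE
  } else {
    for (i in seq_along(groups)) {
      dp <- dagostino_pearson(groups[[i]])
      norm_tab$k2[i] <- dp$statistic
      norm_tab$p_normality[i] <- dp$p_value
      trace <- c(trace, sprintf(
        "D'Agostino-Pearson %s: K2 = %.3f, p = %.4g (n = %d)",
        names(groups)[i], dp$statistic, dp$p_value, ns[i]))
    }
    normal <- all(norm_tab$p_normality > alpha_normality)
    trace <- c(trace, if (normal) {
      sprintf("all groups consistent with normality at alpha = %g: parametric branch",
              alpha_normality)
    } else {
      sprintf("normality rejected in >= 1 group at alpha = %g: nonparametric branch",
              alpha_normality)
    })
  }
  k <- length(groups)
  posthoc <- NULL
  if (normal) {
    if (k == 2) {
      ht <- t.test(groups[[1]], groups[[2]])
      test <- "t-test"; statistic <- unname(ht$statistic)
      p_value <- ht$p.value
    } else {
      df <- data.frame(value = unlist(groups),
                       group = factor(rep(names(groups), ns)))
      fit <- aov(value ~ group, data = df)
      s <- summary(fit)[[1]]
      test <- "one-way ANOVA"; statistic <- s[["F value"]][1]
      p_value <- s[["Pr(>F)"]][1]
    }
  } else {
    if (k == 2) {
      ht <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
      test <- "Mann-Whitney U"; statistic <- unname(ht$statistic)
      p_value <- ht$p.value
    } else {
      values <- unlist(groups)
      glab <- factor(rep(names(groups), ns))
      ht <- kruskal.test(values, glab)
      test <- "Kruskal-Wallis"; statistic <- unname(ht$statistic)
      p_value <- ht$p.value
      posthoc <- dunn_test(values, glab, p_adjust = p_adjust)
      trace <- c(trace, sprintf(
        "Dunn's post test over %d pairs (%s adjustment)",
        nrow(posthoc), p_adjust))
    }
  }
  trace <- c(trace, sprintf("%s: statistic = %.4g, p = %.4g",
                            test, statistic, p_value))
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 normality = norm_tab, posthoc = posthoc, trace = trace,
                 groups = groups),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison (normality-routed)\n")
  for (ln in x$trace) cat(" -", ln, "\n")
  if (!is.null(x$posthoc)) {
    cat("Post-hoc pairwise (Dunn):\n")
    print(as.data.frame(x$posthoc), row.names = FALSE)
  }
  invisible(x)
}

#' Organoid bud-count distributions
#'
#' Folds per-organoid bud counts into the categories 0, 1, 2, 3 and 4+,
#' computes the percentage of organoids per category within each region,
#' then averages region percentages per genotype x day.
#'
#' @param buds Data frame with columns `genotype`, `day`, `region`, `buds`
#'   (non-negative integer counts).
#' @return List with `regions` (per-region percentages) and `summary`
#'   (genotype x day means over regions); both have one row per category.
#' @export
bud_distribution <- function(buds) {
  need <- c("genotype", "day", "region", "buds")
  miss <- setdiff(need, names(buds))
  if (length(miss) > 0) {
    stop_invalid("bud table is missing column(s): ",
                 paste(miss, collapse = ", "))
  }
  if (any(buds$buds < 0) || any(buds$buds != round(buds$buds))) {
    stop_invalid("bud counts must be non-negative integers")
  }
  cats <- c("0", "1", "2", "3", "4+")
  buds$category <- factor(ifelse(buds$buds >= 4, "4+",
                                 as.character(buds$buds)), levels = cats)
  regions <- buds |>
    dplyr::group_by(.data$genotype, .data$day, .data$region) |>
    dplyr::group_modify(function(d, key) {
      tab <- table(d$category)
      tibble::tibble(category = cats,
                     n = as.integer(tab[cats]),
                     percentage = 100 * as.integer(tab[cats]) / nrow(d))
    }) |>
    dplyr::ungroup()
  summary <- regions |>
    dplyr::group_by(.data$genotype, .data$day, .data$category) |>
    dplyr::summarise(percentage = mean(.data$percentage),
                     n_regions = dplyr::n(), .groups = "drop")
  list(regions = regions, summary = summary)
}

#' Two-way genotype x day analysis of bud-category percentages
#'
#' Optional companion to [bud_distribution()]: a two-way ANOVA of one
#' category's region percentages on genotype and day.
#'
#' @param regions The `regions` tibble from [bud_distribution()].
#' @param category Which category to analyse (default `"0"`, no buds).
#' @return The fitted [stats::aov()] object.
#' @export
bud_anova <- function(regions, category = "0") {
  d <- regions[regions$category == category, ]
  if (nrow(d) == 0) stop_invalid("no rows for category '", category, "'")
  aov(percentage ~ genotype * factor(day), data = d)
}

#' Percent change between group means
#'
#' `100 * (mean(treated) - mean(control)) / mean(control)`; negative values
#' are reductions, and the formatted readout reports reductions as positive
#' percentages.
#'
#' @param control,treated Numeric vectors; control mean must be nonzero.
#' @return List with `percent_change` (signed), `ratio` and `formatted`.
#' @export
#' @examples
#' percent_change(c(95, 100, 105), c(40, 43, 46))$formatted
percent_change <- function(control, treated) {
  mc <- mean(control[is.finite(control)])
  mt <- mean(treated[is.finite(treated)])
  if (!is.finite(mc) || mc == 0) {
    stop_invalid("control mean is zero; percent change undefined")
  }
  pc <- 100 * (mt - mc) / mc
  list(percent_change = pc, ratio = mt / mc,
       formatted = if (pc < 0) sprintf("%.1f%% reduction", -pc)
       else sprintf("%.1f%% increase", pc))
}
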