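# Statistical layer: trends across actions, brain-behaviour correlations,
# group interaction tests, grand-average action-level correlations.

#' Pearson correlation with two-sided p value
#'
#' Standard product-moment correlation; p from the t distribution with
#' n - 2 degrees of freedom. Pairs with missing values are dropped.
#'
#' @param x,y numeric vectors.
#' @return list `r`, `p`, `n`; `r` is `NA` when either variable has zero
#'   variance or fewer than 3 complete pairs remain.
#' @export
pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Linear trend of a measure across actions
#'
#' Pooled observation-level Pearson correlation between the action index and
#' the measure (equivalently, the standardized slope of the simple
#' regression over all (infant, action) observations), plus the
#' least-squares slope per action step. Observations are pooled across
#' infants; no repeated-measures structure is modelled. Missing cells are
#' dropped pairwise.
#'
#' @param df data.frame with columns `action` and `value` (and optionally
#'   `group` when `group_by` is given).
#' @param measure label copied into the result.
#' @param group_by optional name of a grouping column; one result per level.
#' @return data.frame with `measure`, `group`, `r`, `p`, `n`, `slope`.
#' @export
trend_across_actions <- function(df, measure = "measure", group_by = NULL) {
  one <- function(d, label) {
    ok <- is.finite(d$action) & is.finite(d$value)
    # a measure constant across actions is a flat trend (r = 0, slope = 0),
    # not a missing one; p stays undefined
    if (sum(ok) >= 3L && stats::sd(d$value[ok]) == 0 &&
        stats::sd(d$action[ok]) > 0)
      return(data.frame(measure = measure, group = label, r = 0,
                        p = NA_real_, n = sum(ok), slope = 0))
    pe <- pearson(d$action, d$value)
    slope <- if (is.na(pe$r)) NA_real_ else
      pe$r * stats::sd(d$value[ok]) / stats::sd(d$action[ok])
    data.frame(measure = measure, group = label, r = pe$r, p = pe$p,
               n = pe$n, slope = slope)
  }
  if (is.null(group_by)) return(one(df, "all"))
  out <- lapply(split(df, df[[group_by]]), function(d)
    one(d, as.character(d[[group_by]][1L])))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-by-action interaction test
#'
#' Ordinary least squares `value ~ group + action + group:action`. The
#' interaction effect size is reported on an r scale as the signed square
#' root of the interaction term's partial R-squared,
#' `sign(b) * sqrt(t^2 / (t^2 + df))`, with its two-sided p value. Subgroup
#' analyses are conventionally run only when p <= 0.05 (or flagged
#' "nearly significant" when p <= 0.10); the returned `subgroup_justified`
#' and `nearly_significant` fields encode that rule.
#'
#' @param df data.frame with `value`, `action`, and a binary `group` column.
#' @param measure label for the output.
#' @return data.frame `measure`, `r_interaction`, `p`, `n`,
#'   `subgroup_justified`, `nearly_significant`.
#' @export
interaction_test <- function(df, measure = "measure") {
  df <- df[is.finite(df$value), , drop = FALSE]
  g <- factor(df$group)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  if (min(table(g)) == 0L) stop("both groups must be non-empty")
  fit <- stats::lm(value ~ group + action + group:action,
                   data = transform(df, group = g))
  sm <- summary(fit)$coefficients
  row <- grep(":action$", rownames(sm))
  if (length(row) != 1L || anyNA(sm[row, ]))
    stop("singular design: interaction term not estimable")
  tval <- sm[row, "t value"]
  dfres <- fit$df.residual
  r_int <- sign(tval) * sqrt(tval^2 / (tval^2 + dfres))
  p <- sm[row, "Pr(>|t|)"]
  data.frame(measure = measure, r_interaction = r_int, p = p,
             n = nrow(df),
             subgroup_justified = p <= 0.10,
             nearly_significant = p > 0.05 & p <= 0.10)
}

#' Correlation of grand-average WECS and FAS across the four actions
#'
#' Descriptive Pearson correlation over the four action-level cohort means
#' (n = 4 points). Because subtracting a constant (the action-1 baseline)
#' from all FAS means is an affine shift, the correlation is unchanged
#' under baseline subtraction.
#'
#' @param fas_by_action numeric length-4 vector of cohort mean FAS.
#' @param wecs_by_action numeric length-4 vector of cohort mean WECS.
#' @return list `r`, `p`, `n` (n = 4; missing input means give `NA`).
#' @export
grand_average_correlation <- function(fas_by_action, wecs_by_action) {
  if (length(fas_by_action) != 4L || length(wecs_by_action) != 4L)
    stop("expected exactly 4 action-level means per measure")
  if (anyNA(fas_by_action) || anyNA(wecs_by_action))
    return(list(r = NA_real_, p = NA_real_, n = 4L))
  pearson(wecs_by_action, fas_by_action)
}

#' Benjamini-Hochberg adjustment (optional, off by default in reports)
#' @param p numeric vector of p values.
#' @return adjusted p values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
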