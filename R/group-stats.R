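#' Group summary for a printed-table t-test
#'
#' @param mean group mean.
#' @param sd sample (n-1) standard deviation.
#' @param n group size (>= 2).
#' @return a `group_summary` list.
#' @export
group_summary <- function(mean, sd, n) {
  if (!is_count(n, min = 2L)) stop_invalid("n must be an integer >= 2")
  if (sd < 0) stop_invalid("sd must be non-negative")
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Two-sample t-test from group summaries
#'
#' Independent two-sample t-test computed from means, standard deviations
#' and sizes, as needed to recompute statistics from published summary
#' tables. The default is the pooled (Student) statistic
#' `t = (m1 - m2) / (s_p sqrt(1/n1 + 1/n2))` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)` and
#' `df = n1 + n2 - 2`; `welch = TRUE` uses the unpooled statistic with
#' Welch-Satterthwaite degrees of freedom. If both groups are degenerate
#' (sd 0) the statistic is 0 for equal means and +/-Inf otherwise (flagged).
#'
#' @param a,b `group_summary` objects (or lists with mean, sd, n).
#' @param welch use the Welch (unequal-variance) form.
#' @return list with `t`, `df`, `p` (two-sided), `welch`, `degenerate`.
#' @export
ttest_pooled <- function(a, b, welch = FALSE) {
  if (a$n + b$n < 3L) stop_invalid("need n1 + n2 >= 3")
  diff <- a$mean - b$mean
  if (a$sd == 0 && b$sd == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- a$n + b$n - 2
    return(list(t = t, df = df, p = if (diff == 0) 1 else 0,
                welch = welch, degenerate = TRUE))
  }
  if (welch) {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  } else {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  }
  t <- diff / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       welch = welch, degenerate = FALSE)
}

#' @rdname ttest_pooled
#' @param x,y raw sample vectors (each of size >= 2); summarised and passed
#'   through the identical formulas, so the two routes agree exactly.
#' @export
ttest_from_samples <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop_invalid("each sample needs >= 2 values")
  ttest_pooled(group_summary(mean(x), stats::sd(x), length(x)),
               group_summary(mean(y), stats::sd(y), length(y)),
               welch = welch)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for a family of `m` comparisons (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values p-values in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)` and must be at
#'   least that.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop_invalid("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop_invalid("family size m must be >= length(p_values)")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Factorial ANOVA with type-II sums of squares
#'
#' Fits a (by default fully crossed) linear model with sum-to-zero factor
#' coding and returns the type-II analysis-of-variance table: each term is
#' tested against the model containing all terms that do not include it,
#' respecting marginality. Aliased (rank-deficient) terms -- e.g. a factor
#' perfectly confounded with another -- are reported as rows with `NA`
#' statistics rather than dropped silently.
#'
#' @param data data frame in long format.
#' @param response name of the numeric response column.
#' @param factors character vector of 2 or 3 factor column names.
#' @param interactions include all interaction terms.
#' @return data frame: `term`, `sum_sq`, `df`, `statistic`, `p_value`,
#'   with a final `Residual` row.
#' @export
anova_type2 <- function(data, response, factors, interactions = TRUE) {
  stopifnot(is.data.frame(data), length(factors) >= 1L)
  if (!response %in% names(data)) stop_invalid("response column not found")
  if (!all(factors %in% names(data))) stop_invalid("factor column(s) not found")
  df <- data
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2L) stop_invalid("factor ", f, " needs >= 2 levels")
  }
  if (stats::sd(df[[response]]) < .Machine$double.eps^0.5) {
    ## constant response: every decomposition is identically zero
    labs <- if (interactions && length(factors) > 1L) {
      attr(stats::terms(stats::as.formula(
        paste("~", paste(factors, collapse = " * ")))), "term.labels")
    } else factors
    return(data.frame(term = c(labs, "Residual"),
                      sum_sq = 0,
                      df = NA_real_,
                      statistic = NA_real_, p_value = NA_real_))
  }
  op <- if (interactions) " * " else " + "
  form <- stats::as.formula(
    paste(response, "~", paste(factors, collapse = op)))
  contr <- stats::setNames(
    replicate(length(factors), stats::contr.sum, simplify = FALSE), factors)
  fit <- stats::lm(form, data = df, contrasts = contr)

  aliased_terms <- character(0)
  if (anyNA(stats::coef(fit))) {
    asn <- attr(stats::model.matrix(fit), "assign")
    labs <- attr(stats::terms(fit), "term.labels")
    bad <- unique(asn[is.na(stats::coef(fit))])
    aliased_terms <- labs[bad[bad > 0]]
    keep <- setdiff(labs, aliased_terms)
    ## drop aliased terms (and any term containing them) to restore full rank
    contains <- function(t1, t2) all(strsplit(t2, ":")[[1]] %in% strsplit(t1, ":")[[1]])
    keep <- keep[!vapply(keep, function(t1)
      any(vapply(aliased_terms, function(t2) contains(t1, t2), logical(1))),
      logical(1))]
    if (!length(keep)) stop_invalid("all terms aliased; nothing to test")
    form <- stats::as.formula(paste(response, "~", paste(keep, collapse = " + ")))
    fit <- stats::lm(form, data = df,
                     contrasts = contr[intersect(factors, all.vars(form))])
  }

  tab <- car::Anova(fit, type = 2)
  out <- data.frame(term = rownames(tab),
                    sum_sq = tab[["Sum Sq"]],
                    df = tab[["Df"]],
                    statistic = tab[["F value"]],
                    p_value = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  resid_row <- out$term == "Residuals"
  out$term[resid_row] <- "Residual"
  if (length(aliased_terms)) {
    out <- rbind(out[!resid_row, , drop = FALSE],
                 data.frame(term = aliased_terms, sum_sq = NA_real_,
                            df = NA_real_, statistic = NA_real_,
                            p_value = NA_real_),
                 out[resid_row, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
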