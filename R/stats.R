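#' Standardize values to z-scores
#'
#' @param values numeric vector, n >= 2 non-missing.
#' @return `(x - mean) / sd`, mean 0 and SD 1.
#' @export
standardize <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop_validation("need at least 2 non-missing values")
  s <- stats::sd(v)
  if (s == 0) stop_validation("cannot standardize: zero standard deviation")
  (values - mean(v)) / s
}

#' Fit the repeated-measures mixed model
#'
#' Linear mixed-effects model of a (standardized) physiological response on
#' temperature, CO2 level and their interaction as fixed effects, with a
#' per-animal random intercept accounting for repeated measurements and
#' inter-individual baselines. Random slopes are deliberately not
#' supported. Fitting uses REML; the likelihood-ratio test of the
#' interaction refits both models with ML.
#'
#' @param data data frame with columns `animal_id`, `temperature`,
#'   `co2_level` and the response.
#' @param response name of the response column (default `"value"`).
#' @param temperature_as treat temperature as `"factor"` (default; needed
#'   for all-pairwise contrasts) or `"numeric"` (per-step slope).
#' @return Object of class `activity_lmm`: list with the fitted `lme4`
#'   model (`model`), `fixed` (estimates and SEs), `random_intercept_sd`,
#'   `residual_sd`, `lrt_interaction` (chisq, df, p) and `singular`.
#' @export
fit_activity_lmm <- function(data, response = "value",
                             temperature_as = c("factor", "numeric")) {
  temperature_as <- match.arg(temperature_as)
  need <- c("animal_id", "temperature", "co2_level", response)
  if (!all(need %in% names(data)))
    stop_validation("`data` must have columns ", paste(need, collapse = ", "))
  if (length(unique(data$animal_id)) < 2)
    stop_validation("need at least 2 animals for a random intercept")
  d <- data
  d$.y <- d[[response]]
  d$temperature <- if (temperature_as == "factor")
    factor(d$temperature) else as.numeric(d$temperature)
  d$co2_level <- factor(d$co2_level)
  two_co2 <- nlevels(d$co2_level) > 1

  form <- if (two_co2)
    .y ~ temperature * co2_level + (1 | animal_id)
  else
    .y ~ temperature + (1 | animal_id)
  fit <- lme4::lmer(form, data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular)
    warning("singular fit: random-intercept variance estimated at zero")

  lrt <- NULL
  if (two_co2) {
    full_ml <- lme4::lmer(.y ~ temperature * co2_level + (1 | animal_id),
                          data = d, REML = FALSE)
    red_ml <- lme4::lmer(.y ~ temperature + co2_level + (1 | animal_id),
                         data = d, REML = FALSE)
    a <- stats::anova(red_ml, full_ml)
    lrt <- list(chisq = a$Chisq[2], df = a$Df[2],
                p = a[["Pr(>Chisq)"]][2])
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  sm <- summary(fit)$coefficients
  structure(list(
    model = fit,
    fixed = data.frame(term = rownames(sm),
                       estimate = sm[, "Estimate"],
                       se = sm[, "Std. Error"],
                       row.names = NULL),
    random_intercept_sd = vc$sdcor[vc$grp == "animal_id"],
    residual_sd = vc$sdcor[vc$grp == "Residual"],
    lrt_interaction = lrt,
    singular = singular,
    temperature_as = temperature_as),
    class = "activity_lmm")
}

#' @export
print.activity_lmm <- function(x, ...) {
  cat("Mixed model: response ~ temperature * co2_level + (1 | animal)\n")
  print(x$fixed, digits = 3)
  cat(sprintf("Random intercept SD %.3f, residual SD %.3f%s\n",
              x$random_intercept_sd, x$residual_sd,
              if (isTRUE(x$singular)) " (singular)" else ""))
  if (!is.null(x$lrt_interaction))
    cat(sprintf("Interaction LRT: chisq = %.2f (df %d), p = %.3g\n",
                x$lrt_interaction$chisq, x$lrt_interaction$df,
                x$lrt_interaction$p))
  invisible(x)
}

#' Tukey HSD all-pairwise contrasts of cell means
#'
#' All pairwise comparisons of the temperature-by-CO2 (or temperature-only)
#' cell means of a fitted mixed model, with studentized-range family
#' correction. Degrees of freedom follow the containment method reported in
#' the output metadata.
#'
#' @param fit an [fit_activity_lmm()] result (temperature as factor).
#' @param alpha family-wise significance level for the flag column.
#' @return Data frame of class `contrast_result`: `comparison`, `estimate`,
#'   `se`, `p_adj`, `significant`.
#' @export
tukey_pairwise <- function(fit, alpha = 0.05) {
  if (!inherits(fit, "activity_lmm"))
    stop_validation("`fit` must be an activity_lmm")
  if (fit$temperature_as != "factor")
    stop_validation("pairwise contrasts need temperature fitted as a factor")
  spec <- if ("co2_level" %in% names(fit$model@frame))
    ~ temperature * co2_level else ~ temperature
  em <- emmeans::emmeans(fit$model, spec)
  pr <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                        adjust = "tukey"))
  out <- data.frame(comparison = as.character(pr$contrast),
                    estimate = pr$estimate,
                    se = pr$SE,
                    p_adj = pr$p.value,
                    significant = pr$p.value < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Kruskal-Wallis rank test (ANOVA on ranks)
#'
#' Tie-corrected H statistic. The p value comes from the chi-square
#' approximation, or from exact enumeration of all rank assignments when
#' the total sample size is at most `exact_max`.
#'
#' @param values numeric observations.
#' @param groups group labels, same length as `values`.
#' @param exact_max maximum total n for exact enumeration (default 8).
#' @return list with `H`, `df`, `p` and `method`.
#' @export
kruskal_wallis <- function(values, groups, exact_max = 8) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop_validation("need at least 2 groups")
  n <- length(values)
  h <- .kw_h(values, groups)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1,
                method = "degenerate"))
  if (n <= exact_max) {
    perms <- .permutations(n)
    hs <- apply(perms, 1, function(ix) .kw_h(values[ix], groups))
    p <- mean(hs >= h - 1e-12)
    return(list(H = h, df = nlevels(groups) - 1L, p = p, method = "exact"))
  }
  df <- nlevels(groups) - 1L
  list(H = h, df = df, p = stats::pchisq(h, df, lower.tail = FALSE),
       method = "chi-square")
}

#' @keywords internal
.kw_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  rj <- tapply(r, groups, sum)
  nj <- tapply(r, groups, length)
  h <- 12 / (n * (n + 1)) * sum(rj^2 / nj) - 3 * (n + 1)
  ties <- table(values)
  cc <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (cc <= 0) return(0)
  h / cc
}

# all n! permutations of 1..n, one per row (n <= 8 in practice)
#' @keywords internal
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  res <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    res[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    res[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  res
}

#' Tamhane T2 post hoc test
#'
#' All pairwise Welch-type t comparisons without an equal-variance
#' assumption, with the conservative Sidak-style family adjustment of
#' Tamhane's T2 procedure: `p_adj = 1 - (1 - p)^m` over the m comparisons.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param alpha significance level for the flag column.
#' @return Data frame of class `contrast_result` with one row per pair:
#'   `comparison`, `estimate` (mean difference), `se`, `t`, `df`, `p_raw`,
#'   `p_adj`, `significant`.
#' @export
tamhane_t2 <- function(values, groups, alpha = 0.05) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  lv <- levels(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("groups with n < 2 excluded: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]
    groups <- droplevels(groups[keep])
    lv <- levels(groups)
  }
  if (length(lv) < 2) stop_validation("need at least 2 usable groups")
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- values[groups == pairs[1, j]]
    b <- values[groups == pairs[2, j]]
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(comparison = paste(pairs[1, j], "-", pairs[2, j]),
               estimate = mean(a) - mean(b),
               se = unname(tt$stderr),
               t = unname(tt$statistic),
               df = unname(tt$parameter),
               p_raw = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, 1 - (1 - out$p_raw)^m)
  out$significant <- out$p_adj < alpha
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney) test with mid-rank tie handling:
#' exact p for total n <= 10 without ties, normal approximation with tie
#' correction otherwise.
#'
#' @param a,b numeric samples.
#' @return list with `U` (Mann-Whitney statistic of the first sample), `p`
#'   and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop_validation("both samples must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b) <= 10) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  p <- wt$p.value
  if (is.nan(p)) p <- 1 # identical samples under the normal approximation
  list(U = unname(wt$statistic), p = p,
       method = if (exact) "exact" else "normal approximation")
}
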