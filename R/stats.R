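#' Fold change between two groups
#'
#' Ratio of group means, `mean(a) / mean(b)`. Treatment effects are usually
#' phrased as "x-fold decrease", i.e. (untreated mean)/(treated mean); the
#' returned value always puts `group_a` in the numerator and the attached
#' attributes give the display convention (`magnitude` >= 1 together with
#' `direction`).
#'
#' @param group_a,group_b numeric vectors of per-animal values.
#' @return The ratio `mean(a)/mean(b)` with attributes `direction`
#'   (`"increase"`/`"decrease"`) and `magnitude` (the >= 1 fold).
#' @export
#' @examples
#' fold_change(c(2, 2, 2), c(1, 1, 1)) # 2
fold_change <- function(group_a, group_b) {
  if (any(!is.finite(group_a)) || any(!is.finite(group_b)))
    stop("inputs must be finite", call. = FALSE)
  mb <- mean(group_b)
  if (mb == 0) stop("denominator group mean is zero", call. = FALSE)
  ratio <- mean(group_a) / mb
  structure(ratio,
            direction = if (ratio >= 1) "increase" else "decrease",
            magnitude = if (ratio >= 1) ratio else 1 / ratio)
}

# Per-group n / mean / s.e.m. summary shared by the comparison functions.
.group_summary <- function(values, groups) {
  lv <- levels(groups)
  data.frame(
    group = lv,
    n = as.integer(table(groups)[lv]),
    mean = as.numeric(tapply(values, groups, mean)[lv]),
    sem = as.numeric(tapply(values, groups, function(x)
      stats::sd(x) / sqrt(length(x)))[lv]),
    stringsAsFactors = FALSE)
}

.pairwise_grid <- function(lv) {
  cmb <- utils::combn(length(lv), 2L)
  data.frame(group_a = lv[cmb[2L, ]], group_b = lv[cmb[1L, ]],
             stringsAsFactors = FALSE)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Omnibus one-way ANOVA plus all pairwise contrasts adjusted with the
#' Tukey honest-significant-difference procedure (studentized-range
#' distribution). Raw pairwise p-values come from pooled-variance t tests.
#'
#' @param values numeric endpoint values.
#' @param groups group labels (coerced to factor), each group with n >= 2.
#' @param endpoint optional endpoint name carried into the output.
#' @return An object of class `group_comparison`: list with `endpoint`,
#'   `test = "anova_tukey"`, `statistic` (F), `p` (omnibus), `summary`
#'   (per-group n/mean/sem) and `contrasts` (data.frame with `group_a`,
#'   `group_b`, `diff`, `fold`, `p_raw`, `p_adj`).
#' @export
#' @examples
#' anova_tukey(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))$p
anova_tukey <- function(values, groups, endpoint = NA_character_) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("every group needs at least two observations", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1L]]
  Fstat <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  tk <- stats::TukeyHSD(fit)$groups

  summ <- .group_summary(values, groups)
  means <- stats::setNames(summ$mean, summ$group)
  ctr <- .pairwise_grid(levels(groups))
  key <- paste(ctr$group_a, ctr$group_b, sep = "-")
  raw <- stats::pairwise.t.test(values, groups, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  get_raw <- function(a, b) {
    if (!is.na(match(a, rownames(raw))) && !is.na(match(b, colnames(raw))) &&
        !is.na(raw[a, b])) raw[a, b] else raw[b, a]
  }
  ctr$diff <- means[ctr$group_a] - means[ctr$group_b]
  ctr$fold <- means[ctr$group_a] / means[ctr$group_b]
  ctr$p_raw <- mapply(get_raw, ctr$group_a, ctr$group_b)
  ctr$p_adj <- tk[key, "p adj"]
  rownames(ctr) <- NULL

  structure(list(endpoint = endpoint, test = "anova_tukey",
                 statistic = Fstat, p = p, summary = summ, contrasts = ctr),
            class = "group_comparison")
}

#' Kruskal-Wallis test with Dunn pairwise comparisons and BKY correction
#'
#' Rank-based omnibus test (tie-corrected H with a chi-square
#' approximation), followed by Dunn pairwise z tests on the mean ranks,
#' adjusted for multiple comparisons by the two-stage step-up false
#' discovery rate procedure ([bky_two_stage()]).
#'
#' @param values numeric endpoint values (total n >= 5).
#' @param groups group labels (coerced to factor).
#' @param q false discovery rate level for the pairwise adjustment.
#' @param endpoint optional endpoint name carried into the output.
#' @return An object of class `group_comparison` with `test =
#'   "kruskal_bky"`, `statistic` (H), `p` (omnibus), per-group `summary`,
#'   and `contrasts` with Dunn `p_raw`, BKY-adjusted `p_adj` and
#'   `rejected`.
#' @export
kruskal_wallis <- function(values, groups, q = 0.05,
                           endpoint = NA_character_) {
  groups <- droplevels(as.factor(groups))
  if (length(values) < 5L) stop("total n must be at least 5", call. = FALSE)
  if (nlevels(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)

  summ <- .group_summary(values, groups)
  means <- stats::setNames(summ$mean, summ$group)
  ctr <- .pairwise_grid(levels(groups))
  ctr$diff <- means[ctr$group_a] - means[ctr$group_b]
  ctr$fold <- means[ctr$group_a] / means[ctr$group_b]

  if (stats::var(values) == 0) {
    # all observations identical: no evidence of any difference
    H <- 0; p <- 1
    ctr$p_raw <- 1; ctr$p_adj <- 1; ctr$rejected <- FALSE
  } else {
    kt <- stats::kruskal.test(values, groups)
    H <- unname(kt$statistic); p <- kt$p.value

    # Dunn pairwise z statistics on mean ranks, with tie correction
    N <- length(values)
    r <- rank(values)
    rbar <- tapply(r, groups, mean)
    n_g <- table(groups)
    ties <- table(values)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    s2 <- N * (N + 1) / 12 - tie_term
    z <- (rbar[ctr$group_a] - rbar[ctr$group_b]) /
      sqrt(s2 * (1 / n_g[ctr$group_a] + 1 / n_g[ctr$group_b]))
    ctr$p_raw <- as.numeric(2 * stats::pnorm(-abs(z)))
    adj <- bky_two_stage(ctr$p_raw, q)
    ctr$p_adj <- adj$adjusted_p
    ctr$rejected <- adj$rejected
  }
  rownames(ctr) <- NULL
  structure(list(endpoint = endpoint, test = "kruskal_bky",
                 statistic = H, p = p, summary = summ, contrasts = ctr),
            class = "group_comparison")
}

# BH step-up rejection count at level alpha.
.bh_count <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (length(ok) == 0L) 0L else max(ok)
}

#' Two-stage step-up false discovery rate procedure
#'
#' The adaptive linear step-up procedure of Benjamini, Krieger and
#' Yekutieli: stage one applies Benjamini-Hochberg at the reduced level
#' `q' = q / (1 + q)` to estimate the number of true null hypotheses
#' `m0 = m - r1`; if `r1 = 0` nothing is rejected, if `m0 = 0` everything
#' is; otherwise stage two applies Benjamini-Hochberg at level
#' `q' * m / m0`. Reported adjusted values are the stage-two
#' Benjamini-Hochberg adjusted p-values scaled by `m0 / m` (capped at 1);
#' the rejection set always comes from the exact two-stage rule.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param q target false discovery rate in `(0, 1)`.
#' @return List with `rejected` (logical), `adjusted_p`, `m0`, and
#'   `alpha_stage2` (the level used in stage two, `NA` when stage two is
#'   not reached).
#' @export
#' @examples
#' bky_two_stage(c(0.001, 0.02, 0.4), q = 0.05)$rejected
bky_two_stage <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!is.finite(q) || q <= 0 || q >= 1)
    stop("`q` must lie in (0, 1)", call. = FALSE)
  m <- length(pvalues)
  qp <- q / (1 + q)

  r1 <- .bh_count(pvalues, qp)
  if (r1 == 0L) {
    return(list(rejected = rep(FALSE, m),
                adjusted_p = rep(1, m), m0 = m, alpha_stage2 = NA_real_))
  }
  m0 <- m - r1
  if (m0 == 0L) {
    return(list(rejected = rep(TRUE, m),
                adjusted_p = pmin(1, stats::p.adjust(pvalues, "BH") * 0),
                m0 = 0L, alpha_stage2 = NA_real_))
  }
  alpha2 <- qp * m / m0
  r2 <- .bh_count(pvalues, alpha2)
  thr <- if (r2 == 0L) -Inf else sort(pvalues)[r2]
  rejected <- pvalues <= thr
  adjusted <- pmin(1, stats::p.adjust(pvalues, "BH") * m0 / m)
  list(rejected = rejected, adjusted_p = adjusted, m0 = m0,
       alpha_stage2 = alpha2)
}

#' Pearson correlation with a two-sided t-test
#'
#' Pairwise-complete handling of missing values (dropped pairs are counted
#' in the result).
#'
#' @param x,y numeric vectors of the same length (>= 3 complete pairs).
#' @return An object of class `correlation_result`: list with
#'   `method = "pearson"`, `r`, `p`, `n`, `n_dropped`.
#' @export
#' @examples
#' pearson_corr(1:4, c(2, 1, 4, 3))$r # 0.6
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(method = "pearson", r = unname(ct$estimate),
                 p = ct$p.value, n = length(x), n_dropped = n_dropped),
            class = "correlation_result")
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept,
#' coefficient of determination and the two-sided p-value for a non-zero
#' slope, mirroring the layout of association tables
#' (`Y = slope * X + intercept`, r^2, p).
#'
#' @param x,y numeric vectors of the same length (>= 3 complete pairs;
#'   `x` must vary).
#' @return An object of class `correlation_result`: list with
#'   `method = "linreg"`, `slope`, `intercept`, `r2`, `p`, `n`,
#'   `n_dropped`.
#' @export
#' @examples
#' linreg(1:5, 2 * (1:5) + 1)$slope # 2
linreg <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant x: regression undefined",
                              call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- stats::coef(sm)
  structure(list(method = "linreg",
                 slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 r2 = sm$r.squared,
                 p = co["x", "Pr(>|t|)"],
                 n = length(x), n_dropped = n_dropped),
            class = "correlation_result")
}
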