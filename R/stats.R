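# Group-comparison statistics: one-way ANOVA with Dunnett's many-to-one
# post-hoc test (Monte-Carlo critical values of the correlated max-|t|
# null), and two-way ANOVA with Bonferroni-adjusted cell contrasts.
# Significance is assessed at alpha = 0.05 by default, with the usual
# reporting tiers (* p < 0.05, ** p < 0.01, *** p < 0.001).

#' Significance tier for a p value
#'
#' @param p p value(s).
#' @param alpha base significance level; default 0.05.
#' @return character: `"***"` (p < 0.001), `"**"` (p < 0.01), `"*"`
#'   (p < alpha), `"ns"` otherwise.
#' @export
significanceTier <- function(p, alpha = 0.05) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < alpha, "*", "ns")))
}

#' One-way analysis of variance
#'
#' Fits the one-way fixed-effects model via [stats::aov()] and returns the
#' omnibus F test. Degenerate inputs (zero between- and within-group
#' variance) are flagged rather than returning NaN: with equal constant
#' groups the F statistic is reported as 0 with `degenerate = TRUE`.
#'
#' @param values numeric observations.
#' @param groups factor (or coercible) of group labels, >= 2 levels.
#' @param alpha significance level; default 0.05.
#' @return data.frame with effect, F, df1, df2, p, significant, degenerate.
#' @examples
#' oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$F   # 13.5
#' @export
oneWayAnova <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least 2 groups are required")
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (length(values) <= nlevels(groups))
    stop("no residual degrees of freedom")
  ## catch the doubly-degenerate case (all groups one constant) up front:
  ## aov would return a 0/0 mean-square ratio polluted by rounding noise
  ssb <- sum(tapply(values, groups,
                    function(x) length(x) * (mean(x) - mean(values))^2))
  ssw <- sum(unlist(tapply(values, groups, function(x) (x - mean(x))^2)))
  scale <- mean(values^2) + 1
  if (ssb < 1e-12 * scale && ssw < 1e-12 * scale) {
    return(data.frame(effect = "group", F = 0,
                      df1 = nlevels(groups) - 1L,
                      df2 = length(values) - nlevels(groups),
                      p = 1, significant = FALSE, degenerate = TRUE))
  }
  tab <- stats::anova(stats::aov(values ~ groups))
  Fv <- tab[1, "F value"]; p <- tab[1, "Pr(>F)"]
  degenerate <- FALSE
  if (!is.finite(Fv)) {
    ## zero within-group variance with equal means
    degenerate <- TRUE
    Fv <- 0; p <- 1
  }
  data.frame(effect = "group", F = Fv,
             df1 = tab[1, "Df"], df2 = tab[2, "Df"],
             p = p, significant = is.finite(p) && p < alpha,
             degenerate = degenerate)
}

## Monte-Carlo sample of the Dunnett null: max over treatments of |t_j|,
## t_j = (mean_j - mean_0) / (s * sqrt(1/n_j + 1/n_0)) under H0, sharing
## one pooled variance estimate across contrasts (hence correlated).
.dunnettNullSample <- function(groupSizes, df, mcSamples = 1e5, seed = 1) {
  n0 <- groupSizes[1]; nt <- groupSizes[-1]
  withr::with_seed(seed, {
    z0 <- stats::rnorm(mcSamples, sd = 1 / sqrt(n0))
    s2 <- stats::rchisq(mcSamples, df) / df
    maxT <- rep(0, mcSamples)
    for (j in seq_along(nt)) {
      zj <- stats::rnorm(mcSamples, sd = 1 / sqrt(nt[j]))
      tj <- abs(zj - z0) / sqrt(s2 * (1 / nt[j] + 1 / n0))
      maxT <- pmax(maxT, tj)
    }
    maxT
  })
}

#' Monte-Carlo critical value for Dunnett's many-to-one test
#'
#' Samples the null distribution of the maximum absolute Dunnett statistic
#' (treatment-vs-control t statistics sharing one pooled variance, hence
#' correlated) and returns its upper `alpha` quantile. Seeded, so critical
#' values are reproducible; precision improves as `1/sqrt(mcSamples)`.
#'
#' @param groupSizes integer vector of group sizes, control first.
#' @param alpha family-wise error rate; default 0.05.
#' @param mcSamples Monte-Carlo sample size; default 1e5.
#' @param seed RNG seed.
#' @return list with `critical` (numeric) and `nullSample` (the sampled
#'   max-|t| values, reusable via [dunnettTest()]'s `nullSample` argument).
#' @export
dunnettCritical <- function(groupSizes, alpha = 0.05, mcSamples = 1e5,
                            seed = 1) {
  if (length(groupSizes) < 2L) stop("need a control and >= 1 treatment group")
  df <- sum(groupSizes) - length(groupSizes)
  if (df < 1L) stop("no pooled degrees of freedom")
  s <- .dunnettNullSample(groupSizes, df, mcSamples, seed)
  list(critical = unname(stats::quantile(s, 1 - alpha)), nullSample = s)
}

#' Dunnett's many-to-one comparisons against a control group
#'
#' Computes the Dunnett t statistic for every treatment group against the
#' control using the pooled within-group variance, and adjusts for the
#' family of correlated comparisons by referring each |t| to the
#' Monte-Carlo null distribution of the maximum |t| (see
#' [dunnettCritical()]): the adjusted p is the null probability that the
#' family maximum exceeds the observed statistic, which controls the
#' family-wise error rate at `alpha` exactly (up to Monte-Carlo error).
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @param control label of the control group.
#' @param alpha family-wise error rate; default 0.05.
#' @param mcSamples Monte-Carlo sample size for the null; default 1e5.
#' @param seed RNG seed for the null sampling.
#' @param nullSample optional precomputed null sample from
#'   [dunnettCritical()] for the same design (group sizes), to amortize the
#'   Monte-Carlo cost over many datasets.
#' @return data.frame with one row per treatment group: comparison, estimate
#'   (mean difference), t, df, pRaw (unadjusted two-sided), pAdj (max-|t|
#'   adjusted), significant, tier; attribute `critical` holds the critical
#'   value.
#' @export
dunnettTest <- function(values, groups, control, alpha = 0.05,
                        mcSamples = 1e5, seed = 1, nullSample = NULL) {
  groups <- factor(groups)
  if (!control %in% levels(groups)) stop("control group not found")
  groups <- stats::relevel(groups, control)
  ns <- as.integer(table(groups))
  k <- nlevels(groups)
  if (k < 2L) stop("need at least one treatment group")
  df <- sum(ns) - k
  if (df < 1L)
    stop("no pooled degrees of freedom (all groups of size 1)")
  means <- tapply(values, groups, mean)
  ss <- tapply(values, groups, function(x) sum((x - mean(x))^2))
  s2 <- sum(ss) / df
  trt <- levels(groups)[-1]
  est <- means[trt] - means[control]
  se <- sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  tstat <- if (s2 > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  if (is.null(nullSample))
    nullSample <- .dunnettNullSample(ns, df, mcSamples, seed)
  crit <- unname(stats::quantile(nullSample, 1 - alpha))
  pAdj <- vapply(abs(tstat), function(t0) mean(nullSample >= t0), numeric(1))
  pRaw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  pAdj <- pmax(pAdj, pRaw)   # adjusted p can never undercut the raw p
  out <- data.frame(
    comparison = paste(trt, "-", control),
    estimate = as.numeric(est), t = as.numeric(tstat), df = df,
    pRaw = as.numeric(pRaw), pAdj = as.numeric(pAdj),
    significant = as.numeric(pAdj) < alpha,
    tier = significanceTier(as.numeric(pAdj), alpha),
    row.names = NULL)
  attr(out, "critical") <- crit
  out
}

#' Two-way ANOVA with Bonferroni-adjusted cell contrasts
#'
#' Fits the two-factor model with interaction. For balanced designs the
#' classical sequential decomposition applies unchanged; unbalanced designs
#' use Type-II sums of squares via [car::Anova()], a choice that only
#' matters off the balanced designs typical of these assays. Requested cell
#' contrasts (pairs of factorA:factorB cells) are tested with t statistics
#' on the pooled residual error and Bonferroni-multiplied p values
#' (`p.adjust`), so a single contrast is unadjusted by construction.
#'
#' @param values numeric observations.
#' @param factorA,factorB factors (or coercible), completely crossed: every
#'   cell non-empty.
#' @param contrasts list of character length-2 vectors naming cell pairs as
#'   `"Alevel:Blevel"`; `NULL` for no post-hoc contrasts.
#' @param alpha significance level; default 0.05.
#' @return list with `anova` (data.frame: effect, F, df1, df2, p,
#'   significant, tier) and `contrasts` (data.frame: comparison, estimate,
#'   t, df, pRaw, pAdj, significant, tier), plus `type` ("balanced" or
#'   "type-II").
#' @export
twoWayAnovaBonferroni <- function(values, factorA, factorB, contrasts = NULL,
                                  alpha = 0.05) {
  fa <- factor(factorA); fb <- factor(factorB)
  if (length(values) != length(fa) || length(values) != length(fb))
    stop("values and factors must have equal length")
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("both factors need at least 2 levels")
  cells <- table(fa, fb)
  if (any(cells == 0)) stop("empty cell in the two-way layout")
  dat <- data.frame(y = values, A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = dat)
  balanced <- length(unique(as.vector(cells))) == 1L
  if (balanced) {
    tab <- stats::anova(fit)
    an <- data.frame(effect = c("A", "B", "A:B"),
                     F = tab[1:3, "F value"], df1 = tab[1:3, "Df"],
                     df2 = tab["Residuals", "Df"], p = tab[1:3, "Pr(>F)"])
  } else {
    tab <- car::Anova(fit, type = 2)
    an <- data.frame(effect = c("A", "B", "A:B"),
                     F = tab[1:3, "F value"], df1 = tab[1:3, "Df"],
                     df2 = tab["Residuals", "Df"], p = tab[1:3, "Pr(>F)"])
  }
  an$significant <- an$p < alpha
  an$tier <- significanceTier(an$p, alpha)
  rownames(an) <- NULL
  ctr <- NULL
  if (!is.null(contrasts)) {
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    cellKey <- paste(fa, fb, sep = ":")
    cellMeans <- tapply(values, cellKey, mean)
    cellN <- tapply(values, cellKey, length)
    rows <- lapply(contrasts, function(ct) {
      if (length(ct) != 2L || !all(ct %in% names(cellMeans)))
        stop("each contrast must name two existing 'Alevel:Blevel' cells")
      est <- cellMeans[ct[1]] - cellMeans[ct[2]]
      se <- sqrt(mse * (1 / cellN[ct[1]] + 1 / cellN[ct[2]]))
      t0 <- est / se
      data.frame(comparison = paste(ct[1], "-", ct[2]),
                 estimate = as.numeric(est), t = as.numeric(t0),
                 df = fit$df.residual,
                 pRaw = 2 * stats::pt(abs(t0), fit$df.residual,
                                      lower.tail = FALSE))
    })
    ctr <- do.call(rbind, rows)
    ctr$pAdj <- stats::p.adjust(ctr$pRaw, method = "bonferroni")
    ctr$significant <- ctr$pAdj < alpha
    ctr$tier <- significanceTier(ctr$pAdj, alpha)
    rownames(ctr) <- NULL
  }
  list(anova = an, contrasts = ctr,
       type = if (balanced) "balanced" else "type-II")
}
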