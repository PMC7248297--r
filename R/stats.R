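#' Container for one statistical test
#'
#' @param statistic test statistic (t, chi-squared, or F).
#' @param df degrees of freedom (single value or c(df1, df2)).
#' @param p p-value in (0, 1] (NA allowed for degenerate flagged cases).
#' @param estimate effect estimate (mean difference, delta brain score...).
#' @param ci optional length-2 confidence interval.
#' @param method short description.
#' @param flag optional character flag for degenerate inputs.
#' @return Object of class `test_result`.
#' @export
test_result <- function(statistic, df, p, estimate = NA_real_, ci = NULL,
                        method = "", flag = NULL) {
  structure(list(statistic = statistic, df = df, p = p, estimate = estimate,
                 ci = ci, method = method, flag = flag),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g",
              x$method, x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p))
  if (!is.na(x$estimate)) cat(sprintf(", estimate = %.4g", x$estimate))
  if (!is.null(x$flag)) cat(sprintf("  [%s]", x$flag))
  cat("\n")
  invisible(x)
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed pooled t-test with df = n1 + n2 - 2, accepting either raw
#' vectors or per-group summary statistics `list(n =, mean =, sd =)` —
#' the form needed to re-test printed baseline demographic tables.
#'
#' @param x,y numeric vectors, or lists with elements n, mean, sd.
#' @return A [test_result()] with the mean difference as estimate. When
#'   both groups are constant and equal, t = 0 and p = 1 with a flag.
#' @export
two_sample_t <- function(x, y) {
  summ <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("n", "mean", "sd") %in% names(v)))
      v
    } else list(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
  a <- summ(x); b <- summ(y)
  if (a$n < 2 || b$n < 2) stop("need n >= 2 per group", call. = FALSE)
  if (a$sd < 0 || b$sd < 0) stop("sd must be >= 0", call. = FALSE)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  est <- a$mean - b$mean
  if (sp2 == 0) {
    if (est == 0)
      return(test_result(0, df, 1, 0, method = "pooled two-sample t",
                         flag = "zero variance in both groups"))
    return(test_result(sign(est) * Inf, df, NA_real_, est,
                       method = "pooled two-sample t",
                       flag = "zero variance in both groups"))
  }
  tstat <- est / sqrt(sp2 * (1 / a$n + 1 / b$n))
  p <- 2 * stats::pt(-abs(tstat), df)
  test_result(tstat, df, p, est, method = "pooled two-sample t")
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction, df = 1 (the SPSS "Pearson Chi-Square" line
#' used for baseline gender tables).
#'
#' @param counts 2x2 matrix of counts (or something coercible).
#' @return A [test_result()].
#' @export
chi_square_2x2 <- function(counts) {
  tab <- as.matrix(counts)
  stopifnot(identical(dim(tab), c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: a table margin is zero", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result(unname(ct$statistic), unname(ct$parameter), ct$p.value,
              method = "Pearson chi-squared (2x2, no continuity correction)")
}

#' Two-tailed paired t-test
#'
#' @param before,after equal-length numeric vectors (>= 2 pairs).
#' @return A [test_result()]; the estimate is the mean difference
#'   (after - before). Zero-variance differences are flagged: t = 0 and
#'   p = 1 when all differences are zero, otherwise statistic and p are
#'   degenerate (signed Inf / NA).
#' @export
paired_t <- function(before, after) {
  stopifnot(length(before) == length(after), length(before) >= 2)
  d <- after - before
  est <- mean(d)
  if (stats::sd(d) == 0) {
    if (est == 0)
      return(test_result(0, length(d) - 1, 1, 0, method = "paired t",
                         flag = "zero-variance differences"))
    return(test_result(sign(est) * Inf, length(d) - 1, NA_real_, est,
                       method = "paired t",
                       flag = "zero-variance differences"))
  }
  ht <- stats::t.test(after, before, paired = TRUE)
  test_result(unname(ht$statistic), unname(ht$parameter), ht$p.value, est,
              ci = unname(ht$conf.int), method = "paired t")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Mixed-design repeated-measures ANCOVA
#'
#' Tests the within-subject main effect of time and the group x time
#' interaction on a longitudinal outcome, with between-subject covariates
#' of no interest partialled out: a repeated-measures general linear model
#' with Type III sums of squares, subjects as the error stratum for
#' within-subject effects (fitted via [car::Anova()] on a multivariate
#' linear model, the SPSS GLM repeated-measures construction: the between
#' factor is sum-coded and covariates are centered, so within-subject
#' effects are evaluated at the covariate means).
#' Greenhouse-Geisser epsilons are computed and reported but the
#' uncorrected tests are returned.
#'
#' @param data long data frame, one row per scan.
#' @param outcome name of the outcome column.
#' @param subject,within,between column names (defaults subject_id,
#'   timepoint, group).
#' @param covariates character vector of between-subject covariate
#'   columns; two-level character/factor covariates (e.g. gender M/F) are
#'   coded 0/1.
#' @return List of class `mixed_anova` with [test_result()] elements
#'   `time`, `interaction` and `group`, the full univariate table, and
#'   Greenhouse-Geisser epsilons.
#' @export
mixed_anova <- function(data, outcome, subject = "subject_id",
                        within = "timepoint", between = "group",
                        covariates = c("age", "gender", "education")) {
  need <- c(outcome, subject, within, between, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  data[[within]] <- factor(data[[within]])
  data[[between]] <- factor(data[[between]])
  tps <- levels(data[[within]])
  tab <- table(data[[subject]], data[[within]])
  bad <- rownames(tab)[apply(tab != 1, 1, any)]
  if (length(bad))
    stop("incomplete time points for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (cv in covariates) {
    v <- data[[cv]]
    if (!is.numeric(v)) {
      f <- factor(v)
      if (nlevels(f) != 2)
        stop(sprintf("covariate '%s' is non-numeric with %d levels; only 2-level factors are coded 0/1",
                     cv, nlevels(f)), call. = FALSE)
      data[[cv]] <- as.numeric(f) - 1
    }
  }
  # subject-level frame with one outcome column per time point
  subjects <- unique(data[[subject]])
  wide <- do.call(rbind, lapply(subjects, function(s) {
    d <- data[data[[subject]] == s, , drop = FALSE]
    row <- d[match(tps[1], d[[within]]), c(between, covariates), drop = FALSE]
    y <- d[[outcome]][match(tps, d[[within]])]
    names(y) <- paste0(".y", seq_along(tps))
    cbind(row, as.data.frame(as.list(y)))
  }))
  rownames(wide) <- NULL
  ycols <- paste0(".y", seq_along(tps))
  Y <- as.matrix(wide[, ycols])
  df_time <- length(tps) - 1
  df_err_t <- (nrow(wide) - nlevels(wide[[between]]) - length(covariates)) *
    df_time
  if (stats::var(as.vector(Y)) < .Machine$double.eps * 100) {
    z <- function() test_result(0, c(df_time, df_err_t), 1,
                                method = "mixed ANCOVA (Type III)",
                                flag = "constant outcome")
    return(structure(list(time = z(), interaction = z(),
                          group = test_result(0, c(1, nrow(wide) - 2), 1,
                                              method = "mixed ANCOVA (Type III)",
                                              flag = "constant outcome"),
                          table = NULL, gg_epsilon = NA_real_),
                     class = "mixed_anova"))
  }
  # SPSS-style construction: sum-to-zero coding for the between factor and
  # covariates centered, so within-subject effects are evaluated at the
  # covariate means.
  for (cv in covariates) wide[[cv]] <- wide[[cv]] - mean(wide[[cv]])
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op), add = TRUE)
  rhs <- paste(c(between, covariates), collapse = " + ")
  mod <- stats::lm(stats::as.formula(
    paste0("cbind(", paste(ycols, collapse = ","), ") ~ ", rhs)), data = wide)
  idata <- data.frame(.time = factor(tps, levels = tps))
  av <- car::Anova(mod, idata = idata, idesign = ~.time, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  grab <- function(rn) {
    i <- match(rn, rownames(ut))
    test_result(ut[i, "F value"], c(ut[i, "num Df"], ut[i, "den Df"]),
                ut[i, "Pr(>F)"], method = "mixed ANCOVA (Type III)")
  }
  gg <- tryCatch(s$pval.adjustments[, "GG eps"], error = function(e) NA_real_)
  structure(list(time = grab(".time"),
                 interaction = grab(paste0(between, ":.time")),
                 group = grab(between),
                 table = ut, gg_epsilon = gg),
            class = "mixed_anova")
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design repeated-measures ANCOVA (Type III SS)\n")
  cat("  time:        "); print(x$time)
  cat("  group:time:  "); print(x$interaction)
  cat("  group:       "); print(x$group)
  if (!all(is.na(x$gg_epsilon)))
    cat(sprintf("  Greenhouse-Geisser epsilon (reported, not applied): %s\n",
                paste(signif(x$gg_epsilon, 4), collapse = ", ")))
  invisible(x)
}
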