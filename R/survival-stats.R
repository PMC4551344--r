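#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator of the survival function; censored subjects leave
#' the risk set after their time.  The median is reported as the first time
#' at which survival drops to 0.5 or below, and is NA when the curve never
#' reaches 0.5.  Backed by \code{survival::survfit}.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return list with \code{time}, \code{surv}, \code{nRisk}, \code{nEvent},
#'   \code{median}.
#' @examples
#' kmEstimate(c(2, 5, 7, 9), c(1, 1, 0, 1))$median
#' @export
kmEstimate <- function(time, event) {
    if (!length(time)) stop("empty input")
    if (any(time <= 0)) stop("times must be positive")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]]
           else NA_real_
    list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
         nEvent = fit$n.event, median = med)
}

#' Log-rank test between survival curves
#'
#' Standard observed-minus-expected log-rank on the pooled event-time grid,
#' chi-square with (groups - 1) degrees of freedom; tied events at a time
#' are handled in one step with the hypergeometric variance.  Backed by
#' \code{survival::survdiff}.
#'
#' @param time,event pooled survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    if (nlevels(droplevels(group)) < 2) stop("need at least 2 non-empty groups")
    if (!any(event == 1)) stop("no events")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    df <- length(sd$n) - 1
    list(chisq = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Continuity-corrected chi-square:
#' N (max(|ad - bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d)), compared to the
#' chi-square distribution with 1 df.  All four margins must be positive.
#'
#' @param table 2x2 integer matrix (rows = groups, columns = outcome
#'   yes/no), or a length-4 vector (a, b, c, d) filled by row.
#' @return list with \code{chisq} and \code{p}.
#' @examples
#' yatesChi2(matrix(c(0, 8, 3, 0), 2, 2, byrow = TRUE))
#' @export
yatesChi2 <- function(table) {
    if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
    if (!all(dim(table) == c(2, 2)) || any(table < 0))
        stop("a 2x2 table of nonnegative counts is required")
    if (any(rowSums(table) == 0) || any(colSums(table) == 0))
        stop("all margins must be positive")
    ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
    list(chisq = unname(ct$statistic), p = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Rank-sum test; exact p-value for small samples (min(n, m) <= 8 without
#' ties), otherwise the tie-corrected normal approximation with continuity
#' correction.  Two-sided.  If every value across both samples is tied the
#' test is degenerate: U equals its null mean and p = 1, with a warning.
#'
#' @param x,y numeric samples (both non-empty).
#' @return list with \code{U} (statistic for \code{x}) and \code{p}.
#' @export
mannWhitneyU <- function(x, y) {
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    if (length(unique(c(x, y))) == 1) {
        warning("all values tied across both samples; p = 1")
        return(list(U = length(x) * length(y) / 2, p = 1))
    }
    ties <- any(duplicated(c(x, y)))
    exact <- !ties && min(length(x), length(y)) <= 8
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks, with a two-sided p-value from the
#' t-approximation (appropriate with ties).
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanRho <- function(x, y) {
    if (length(x) != length(y) || length(x) < 3)
        stop("x and y must have equal length >= 3")
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        stop("zero rank variance")
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    list(rho = unname(ct$estimate), p = unname(ct$p.value))
}
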