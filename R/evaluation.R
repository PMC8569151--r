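#' Signed percentage error of an estimate
#'
#' \eqn{100 (manual - estimated) / manual}. The sign is kept: a positive value
#' means under-estimation.
#'
#' @param manual ground-measured trait values (nonzero).
#' @param estimated model estimates of the same length.
#' @return signed percentages.
#' @export
error_percent <- function(manual, estimated) {
  if (length(manual) != length(estimated)) stop("length mismatch")
  if (any(manual == 0)) stop("manual trait value of 0: percentage undefined")
  100 * (manual - estimated) / manual
}

#' Goodness-of-fit metrics for a trait model
#'
#' Computes R-squared, RMSE, ASE, AIC, BIC and PRESS for predictions of a
#' model with \code{p} parameters. The information criteria use the SSE
#' forms \eqn{AIC = n \log(SSE/n) + 2p} and \eqn{BIC = n \log(SSE/n) +
#' p \log n}; PRESS is the sum of squared leave-one-out prediction residuals,
#' computed by the hat-matrix closed form \eqn{e_i / (1 - h_{ii})} when a
#' design matrix is supplied and skipped (NA) otherwise.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param p number of model parameters (including the intercept); must be
#'   < n.
#' @param design optional model matrix (n x p, including the intercept
#'   column) of the linear fit that produced \code{predicted}; enables PRESS.
#' @return a list of class \code{fit_metrics}: n, p, r2, rmse, ase, aic, bic,
#'   press.
#' @export
fit_metrics <- function(observed, predicted, p, design = NULL) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch")
  if (n <= p) stop("need n > p")
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("observed values have zero variance")
  res <- observed - predicted
  sse <- sum(res^2)
  press <- NA_real_
  if (!is.null(design)) {
    design <- as.matrix(design)
    if (nrow(design) != n) stop("design row count mismatch")
    qr_x <- qr(design)
    h <- rowSums(qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]^2)
    press <- sum((res / (1 - h))^2)
  }
  structure(list(n = n, p = p,
                 r2 = 1 - sse / sst,
                 rmse = sqrt(sse / (n - p)),
                 ase = sse / n,
                 aic = n * log(sse / n) + 2 * p,
                 bic = n * log(sse / n) + p * log(n),
                 press = press),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf(paste0("<fit_metrics> n=%d p=%d R2=%.4f RMSE=%.4g ASE=%.4g ",
                     "AIC=%.2f BIC=%.2f PRESS=%.4g\n"),
              x$n, x$p, x$r2, x$rmse, x$ase, x$aic, x$bic, x$press))
  invisible(x)
}

#' Validation error statistics
#'
#' Mean error (mu), sample standard deviation of the error (sigma), and
#' R-squared of the regression of observed on predicted. The error is defined
#' as predicted minus observed.
#'
#' @param observed,predicted numeric vectors of equal length >= 3.
#' @return a list of class \code{validation_stats}: mean_error, sd_error, r2.
#' @export
validation_stats <- function(observed, predicted) {
  n <- length(observed)
  if (length(predicted) != n) stop("length mismatch")
  if (n < 3L) stop("need at least 3 pairs")
  err <- predicted - observed
  r2 <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    if (all(err == err[1])) 1 else 0  # constant-shift degenerate case
  } else {
    stats::cor(observed, predicted)^2
  }
  structure(list(mean_error = mean(err), sd_error = stats::sd(err), r2 = r2),
            class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("<validation_stats> mu=%.4g sigma=%.4g R2=%.4f\n",
              x$mean_error, x$sd_error, x$r2))
  invisible(x)
}

#' Pearson correlation with precondition checks
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return the sample Pearson coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' Two-sided paired t-test
#'
#' @param a,b numeric vectors of equal length >= 2; the differences must have
#'   nonzero variance.
#' @return a list with \code{t}, \code{df} and \code{p_value}.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences")
  ht <- stats::t.test(d)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' One-way ANOVA with Tukey HSD letter grouping
#'
#' Runs a one-way analysis of variance of \code{values} on \code{group},
#' followed by Tukey-Kramer all-pairwise comparisons at level \code{alpha}
#' and a compact letter display (insert-and-absorb): groups sharing a letter
#' are not significantly different.
#'
#' @param values numeric trait values.
#' @param group grouping factor (e.g. genotype), >= 2 levels with >= 2
#'   values each.
#' @param alpha familywise significance level.
#' @return a list of class \code{tukey_grouping}: \code{f}, \code{p_value},
#'   \code{means} (per-group means, decreasing), \code{letters} (named
#'   character vector), \code{comparisons} (the TukeyHSD table), \code{alpha}.
#' @export
anova_tukey <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 values")
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  means <- sort(tapply(values, group, mean), decreasing = TRUE)
  lv <- names(means)
  # non-significant pairs at alpha
  ns <- matrix(TRUE, length(lv), length(lv), dimnames = list(lv, lv))
  for (cmp in rownames(tk)) {
    pair <- strsplit(cmp, "-", fixed = TRUE)[[1]]
    sig <- tk[cmp, "p adj"] < alpha
    ns[pair[1], pair[2]] <- ns[pair[2], pair[1]] <- !sig
  }
  # compact letter display: grow maximal non-significant sets in mean order
  sets <- list()
  for (g in lv) {
    placed <- FALSE
    for (i in seq_along(sets)) {
      if (all(ns[g, sets[[i]]])) {
        sets[[i]] <- c(sets[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb sets contained in another
  keep <- !vapply(seq_along(sets), function(i)
    any(vapply(seq_along(sets), function(j)
      i != j && all(sets[[i]] %in% sets[[j]]), TRUE)), TRUE)
  sets <- sets[keep]
  letters_out <- stats::setNames(rep("", length(lv)), lv)
  for (i in seq_along(sets))
    letters_out[sets[[i]]] <- paste0(letters_out[sets[[i]]], letters[i])
  structure(list(f = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
                 means = means, letters = letters_out, comparisons = tk,
                 alpha = alpha),
            class = "tukey_grouping")
}

#' @export
print.tukey_grouping <- function(x, ...) {
  cat(sprintf("<tukey_grouping> F=%.3f p=%.4g (alpha=%.2f)\n",
              x$f, x$p_value, x$alpha))
  for (g in names(x$means))
    cat(sprintf("  %-16s %8.3f  %s\n", g, x$means[g], x$letters[g]))
  invisible(x)
}

#' Cubic regression of pod yield on a trait
#'
#' Fits \eqn{yield = c_0 + c_1 t + c_2 t^2 + c_3 t^3} by OLS and reports the
#' coefficients, R-squared and the overall model F-test p-value with a
#' significance flag at alpha.
#'
#' @param trait numeric trait values (LAI or LG), >= 5 points, non-constant.
#' @param yield pod yields of the same length.
#' @param alpha significance level for the model flag.
#' @return a list of class \code{yield_fit}: coefficients (length 4), r2,
#'   model_p, significant.
#' @export
fit_yield_cubic <- function(trait, yield, alpha = 0.05) {
  if (length(trait) != length(yield)) stop("length mismatch")
  if (length(trait) < 5L) stop("need at least 5 points")
  if (stats::sd(trait) == 0) stop("constant trait: degenerate design")
  if (stats::sd(yield) == 0) {
    # constant response: nothing to explain
    return(structure(list(coefficients = c(yield[1], 0, 0, 0), r2 = 0,
                          model_p = NA_real_, significant = FALSE),
                     class = "yield_fit"))
  }
  fit <- stats::lm(yield ~ poly(trait, 3, raw = TRUE))
  sm <- summary(fit)
  model_p <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                     lower.tail = FALSE))
  structure(list(coefficients = unname(stats::coef(fit)),
                 r2 = sm$r.squared, model_p = model_p,
                 significant = isTRUE(model_p < alpha)),
            class = "yield_fit")
}

#' @export
print.yield_fit <- function(x, ...) {
  cat(sprintf("<yield_fit> yield = %.4g %+.4g t %+.4g t^2 %+.4g t^3 (R2=%.3f, p=%.3g%s)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4], x$r2, x$model_p,
              if (x$significant) " *" else ""))
  invisible(x)
}
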