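#' Linear trait model over vegetation indices
#'
#' Two functional forms are supported. In \code{"sum"} mode the trait is an
#' affine combination of the named indices,
#' \eqn{t = c_0 + \sum_i c_i VI_i}; in \code{"product"} mode a single weight
#' multiplies the product of the named indices,
#' \eqn{t = c_0 + w \prod_i VI_i}.
#'
#' @param trait "LAI" (dimensionless) or "LG" (cm).
#' @param mode "sum" or "product".
#' @param predictor_names ordered VI names (see \code{\link{vi_names}}).
#' @param coefficients per-predictor weights in sum mode; a single weight in
#'   product mode.
#' @param intercept trait-unit intercept.
#' @return an object of class \code{linear_trait_model}.
#' @export
linear_trait_model <- function(trait, mode, predictor_names, coefficients,
                               intercept) {
  mode <- match.arg(mode, c("sum", "product"))
  predictor_names <- as.character(predictor_names)
  bad <- setdiff(predictor_names, vi_names())
  if (length(bad))
    stop(sprintf("unknown predictor(s): %s", paste(bad, collapse = ", ")))
  coefficients <- as.numeric(coefficients)
  if (mode == "sum" && length(coefficients) != length(predictor_names))
    stop("sum mode needs one coefficient per predictor")
  if (mode == "product" && (length(coefficients) != 1L ||
                            length(predictor_names) < 1L))
    stop("product mode needs exactly one weight and at least one predictor")
  structure(list(trait = trait, mode = mode,
                 predictor_names = predictor_names,
                 coefficients = coefficients,
                 intercept = as.numeric(intercept)),
            class = "linear_trait_model")
}

#' @export
print.linear_trait_model <- function(x, ...) {
  if (x$mode == "sum") {
    terms <- paste(sprintf("%+.4g*%s", x$coefficients,
                           toupper(x$predictor_names)), collapse = " ")
  } else {
    terms <- sprintf("%+.4g*(%s)", x$coefficients,
                     paste(toupper(x$predictor_names), collapse = "*"))
  }
  cat(sprintf("<linear_trait_model> %s = %s %+.4g\n", x$trait, terms,
              x$intercept))
  invisible(x)
}

# Published frozen estimators. reg1/reg2 estimate LAI, reg3/reg4 estimate LG.
.frozen_models <- list(
  reg1 = list(trait = "LAI", mode = "sum",
              predictor_names = c("bgi", "ppr", "ngrdi", "ncpi", "nppr"),
              coefficients = c(28.82, 13.77, -7.91, 14.88, 25.86),
              intercept = -39.74),
  reg2 = list(trait = "LAI", mode = "product",
              predictor_names = c("bgi", "ppr", "nppr", "ngrdi", "ncpi"),
              coefficients = 505.84, intercept = 0.134),
  reg3 = list(trait = "LG", mode = "sum",
              predictor_names = c("nppr", "ncpi", "ngrdi", "ppr"),
              coefficients = c(254.26, 136.76, -92.73, -82.78),
              intercept = -144.24),
  reg4 = list(trait = "LG", mode = "product",
              predictor_names = c("ppr", "nppr", "ngrdi", "ncpi"),
              coefficients = 3372.55, intercept = 19.96)
)

#' Published frozen LAI/LG estimators
#'
#' \describe{
#'   \item{reg1}{LAI = 28.82 BGI + 13.77 PPR - 7.91 NGRDI + 14.88 NCPI +
#'     25.86 NPPR - 39.74 (sum mode)}
#'   \item{reg2}{LAI = 505.84 (BGI PPR NPPR NGRDI NCPI) + 0.134 (product mode)}
#'   \item{reg3}{LG = 254.26 NPPR + 136.76 NCPI - 92.73 NGRDI - 82.78 PPR -
#'     144.24 (sum mode)}
#'   \item{reg4}{LG = 3372.55 (PPR NPPR NGRDI NCPI) + 19.96 (product mode)}
#' }
#'
#' @param model_id one of "reg1", "reg2", "reg3", "reg4".
#' @return a \code{linear_trait_model}.
#' @export
frozen_model <- function(model_id) {
  if (!model_id %in% names(.frozen_models))
    stop(sprintf("unknown model id '%s'; available: %s", model_id,
                 paste(names(.frozen_models), collapse = ", ")))
  do.call(linear_trait_model, .frozen_models[[model_id]])
}

#' Estimate a trait from vegetation indices
#'
#' Negative estimates are returned unclamped; a \code{below_zero} attribute
#' flags them.
#'
#' @param vi data.frame (or single-row list) holding the model's predictors.
#' @param model a \code{linear_trait_model}.
#' @return numeric trait estimates with attribute \code{below_zero}.
#' @export
estimate_trait <- function(vi, model) {
  stopifnot(inherits(model, "linear_trait_model"))
  vi <- as.data.frame(vi)
  missing_p <- setdiff(model$predictor_names, names(vi))
  if (length(missing_p))
    stop(sprintf("missing predictor(s): %s", paste(missing_p, collapse = ", ")))
  x <- as.matrix(vi[, model$predictor_names, drop = FALSE])
  est <- if (model$mode == "sum") {
    model$intercept + drop(x %*% model$coefficients)
  } else {
    model$intercept + model$coefficients * apply(x, 1L, prod)
  }
  attr(est, "below_zero") <- est < 0
  est
}

#' Fit a linear trait model by ordinary least squares
#'
#' In product mode the single regressor is the rowwise product of the named
#' indices; in sum mode each index enters as its own regressor.
#'
#' @param table data.frame holding the predictors and the trait column.
#' @param trait name of the response column (also stored as trait label).
#' @param predictors VI names to use.
#' @param mode "sum" or "product".
#' @return a \code{linear_trait_model} with an attribute \code{fit} (the lm).
#' @export
fit_linear_trait_model <- function(table, trait, predictors,
                                   mode = c("sum", "product")) {
  mode <- match.arg(mode)
  if (!trait %in% names(table)) stop(sprintf("no column '%s'", trait))
  missing_p <- setdiff(predictors, names(table))
  if (length(missing_p))
    stop(sprintf("missing predictor(s): %s", paste(missing_p, collapse = ", ")))
  y <- table[[trait]]
  if (mode == "sum") {
    x <- as.matrix(table[, predictors, drop = FALSE])
  } else {
    x <- matrix(apply(as.matrix(table[, predictors, drop = FALSE]), 1L, prod),
                ncol = 1, dimnames = list(NULL, "product"))
  }
  p <- ncol(x) + 1L
  if (nrow(x) <= p) stop("need more rows than parameters")
  df <- data.frame(.y = y, x)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("rank-deficient design: collinear predictors")
  cf <- stats::coef(fit)
  model <- linear_trait_model(
    trait = trait, mode = mode, predictor_names = predictors,
    coefficients = if (mode == "sum") unname(cf[colnames(x)]) else unname(cf[2]),
    intercept = unname(cf[1]))
  attr(model, "fit") <- fit
  model
}

#' Forward-backward stepwise predictor selection by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate that
#' most improves AIC, then drops any retained predictor whose removal improves
#' AIC, stopping when no move helps. The AIC used is the SSE form
#' \eqn{n \log(SSE/n) + 2p}; on (numerically) perfect fits the SSE is floored
#' at machine precision relative to the response's total sum of squares so the
#' penalty term still discriminates model sizes.
#'
#' @param table data.frame holding candidate columns and the trait column.
#' @param trait response column name.
#' @param candidates candidate predictor names (default all six VIs).
#' @return a list of class \code{stepwise_result} with \code{selected}
#'   (ordered retained predictors) and \code{criterion_path} (AIC after each
#'   accepted step, starting at the null model).
#' @export
stepwise_select <- function(table, trait, candidates = vi_names()) {
  if (!trait %in% names(table)) stop(sprintf("no column '%s'", trait))
  missing_p <- setdiff(candidates, names(table))
  if (length(missing_p))
    stop(sprintf("missing candidate(s): %s", paste(missing_p, collapse = ", ")))
  y <- table[[trait]]
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("response has zero variance")
  aic_of <- function(vars) {
    x <- cbind(`(Intercept)` = 1,
               as.matrix(table[, vars, drop = FALSE]))
    fit <- stats::lm.fit(x, y)
    sse <- sum(fit$residuals^2)
    sse <- max(sse, .Machine$double.eps * sst)
    n * log(sse / n) + 2 * ncol(x)
  }
  current <- character(0)
  cur_aic <- aic_of(current)
  path <- cur_aic
  repeat {
    improved <- FALSE
    # forward: best single addition
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      add_aic <- vapply(pool, function(v) aic_of(c(current, v)), 0)
      if (min(add_aic) < cur_aic - 1e-8) {
        current <- c(current, pool[which.min(add_aic)])
        cur_aic <- min(add_aic)
        path <- c(path, cur_aic)
        improved <- TRUE
      }
    }
    # backward: any single drop that helps
    repeat {
      if (length(current) < 1L) break
      drop_aic <- vapply(seq_along(current),
                         function(i) aic_of(current[-i]), 0)
      if (min(drop_aic) < cur_aic - 1e-8) {
        current <- current[-which.min(drop_aic)]
        cur_aic <- min(drop_aic)
        path <- c(path, cur_aic)
        improved <- TRUE
      } else break
    }
    if (!improved) break
  }
  structure(list(selected = current, criterion_path = path),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat(sprintf("<stepwise_result> retained {%s} in %d steps (final AIC %.3f)\n",
              paste(toupper(x$selected), collapse = ", "),
              length(x$criterion_path) - 1L, utils::tail(x$criterion_path, 1)))
  invisible(x)
}

#' Linear trait model JSON round trip
#'
#' @param model a \code{linear_trait_model}.
#' @param path JSON file path.
#' @return \code{path} (write) or a \code{linear_trait_model} (read).
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(trait = model$trait, mode = model$mode,
         predictor_names = model$predictor_names,
         coefficients = model$coefficients, intercept = model$intercept),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  linear_trait_model(obj$trait, obj$mode, obj$predictor_names,
                     obj$coefficients, obj$intercept)
}
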