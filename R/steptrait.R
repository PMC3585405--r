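#' Stepwise regression of a phenotype on module eigenvalues
#'
#' Mixed (forward with backward elimination) stepwise selection on partial-F
#' p-values: at each step the candidate with the smallest partial p enters
#' if its Bonferroni-adjusted p (raw p times the number of candidates
#' examined at that step) clears `p_enter` — the adjustment keeps the
#' false-entry rate near `p_enter` regardless of how many modules compete,
#' where an unadjusted minimum-p rule would admit a noise module almost
#' surely once dozens of candidates are screened. After every entry,
#' retained terms whose unadjusted partial p has risen above `p_leave` are
#' eliminated, worst first. Ties are broken by smaller p then
#' lexicographically smaller term id, so the path is deterministic. Rows
#' with missing phenotype are dropped.
#'
#' @param y numeric phenotype vector, one value per line (NA dropped).
#' @param me candidate predictors: a [module_eigenvalues()] object or a
#'   samples x predictors numeric matrix with column names.
#' @param p_enter entry threshold on the partial-F p-value (default 0.05).
#' @param p_leave stay threshold (default 0.10; must be >= `p_enter`).
#' @return An object of class `stepwise_model`: list with `terms` (selected
#'   ids, entry order), `coefficients`, `history` (data.frame step, term,
#'   action, p), `y`, `X` (design columns of the selected terms),
#'   `p_enter`, `p_leave`.
#' @export
stepwise_select <- function(y, me, p_enter = 0.05, p_leave = 0.10) {
  X <- if (inherits(me, "module_eigenvalues")) t(me$scores) else as.matrix(me)
  if (is.null(colnames(X))) stop("predictors must be named")
  if (p_leave < p_enter) stop("p_leave must be >= p_enter")
  keep <- is.finite(y)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  terms <- character()
  hist <- list()
  step <- 0L
  fit_terms <- function(sel) {
    if (!length(sel)) return(stats::lm(y ~ 1))
    df <- data.frame(.y = y, X[, sel, drop = FALSE], check.names = FALSE)
    stats::lm(.y ~ ., data = df)
  }
  partial_p <- function(sel) {
    # p-value of each term's partial F (= squared t) in the model with all of sel
    sm <- summary(fit_terms(sel))$coefficients
    stats::setNames(sm[-1L, 4L], sel)
  }
  repeat {
    cand <- setdiff(colnames(X), terms)
    if (!length(cand) || n <= length(terms) + 2L) break
    entry_p <- vapply(cand, function(id) partial_p(c(terms, id))[[id]], 0)
    ord <- order(entry_p, cand)
    best <- cand[ord[1L]]
    if (min(entry_p[[best]] * length(cand), 1) > p_enter) break
    terms <- c(terms, best)
    step <- step + 1L
    hist[[length(hist) + 1L]] <- data.frame(step = step, term = best,
                                            action = "enter",
                                            p = entry_p[[best]])
    # backward elimination until all retained terms satisfy the stay rule
    repeat {
      if (length(terms) < 2L) break
      pp <- partial_p(terms)
      worst <- names(pp)[order(-pp, names(pp))][1L]
      if (pp[[worst]] <= p_leave) break
      terms <- setdiff(terms, worst)
      step <- step + 1L
      hist[[length(hist) + 1L]] <- data.frame(step = step, term = worst,
                                              action = "remove",
                                              p = pp[[worst]])
    }
  }
  fit <- fit_terms(terms)
  structure(list(terms = terms, coefficients = stats::coef(fit),
                 history = if (length(hist)) do.call(rbind, hist) else
                   data.frame(step = integer(), term = character(),
                              action = character(), p = numeric()),
                 y = y, X = X[, terms, drop = FALSE],
                 p_enter = p_enter, p_leave = p_leave),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("stepwise_model: %d term(s) retained of %d step(s)\n",
              length(x$terms), nrow(x$history)))
  if (length(x$terms)) cat("  ", paste(x$terms, collapse = ", "), "\n")
  invisible(x)
}

#' Partial sum-of-squares ANOVA table for a fitted stepwise model
#'
#' One row per retained term with its partial (Type III) sum of squares —
#' the increase in error SS when that term alone is removed — the F ratio
#' against the full-model mean squared error, its p-value, and the signed
#' t ratio (`t^2 = F` for these 1-DF terms). An `Error` row carries the
#' residual DF/SS and a `Model` row carries the corrected total DF/SS along
#' with the whole-model F and adjusted R-squared.
#'
#' @param model a [stepwise_select()] fit (at least one retained term).
#' @return An object of class `anova_table`: data.frame with columns
#'   `source`, `df`, `ss`, `f_ratio`, `p_value`, `t_ratio`, plus attributes
#'   `adj_r2` and `model_f`.
#' @export
partial_anova <- function(model) {
  stopifnot(inherits(model, "stepwise_model"))
  if (!length(model$terms)) stop("intercept-only model has no terms to test")
  y <- model$y
  X <- model$X
  n <- length(y)
  fit <- stats::lm(.y ~ ., data = data.frame(.y = y, X, check.names = FALSE))
  if (fit$rank < ncol(X) + 1L) stop("rank-deficient design")
  sse <- sum(stats::resid(fit)^2)
  df_err <- n - ncol(X) - 1L
  mse <- sse / df_err
  sm <- summary(fit)$coefficients
  rows <- lapply(model$terms, function(tm) {
    keep <- setdiff(model$terms, tm)
    drop_fit <- if (length(keep))
      stats::lm(.y ~ ., data = data.frame(.y = y, X[, keep, drop = FALSE],
                                          check.names = FALSE))
    else stats::lm(y ~ 1)
    ss <- sum(stats::resid(drop_fit)^2) - sse
    f <- ss / mse
    data.frame(source = tm, df = 1L, ss = ss, f_ratio = f,
               p_value = stats::pf(f, 1L, df_err, lower.tail = FALSE),
               t_ratio = sm[tm, 3L], stringsAsFactors = FALSE)
  })
  ss_tot <- sum((y - mean(y))^2)
  df_tot <- n - 1L
  tab <- rbind(do.call(rbind, rows),
               data.frame(source = "Error", df = df_err, ss = sse,
                          f_ratio = NA, p_value = NA, t_ratio = NA),
               data.frame(source = "Model", df = df_tot, ss = ss_tot,
                          f_ratio = model_f(sse, df_err, ss_tot, df_tot),
                          p_value = stats::pf(
                            model_f(sse, df_err, ss_tot, df_tot),
                            df_tot - df_err, df_err, lower.tail = FALSE),
                          t_ratio = NA))
  rownames(tab) <- NULL
  structure(tab, class = c("anova_table", "data.frame"),
            adj_r2 = adjusted_r2(sse, df_err, ss_tot, df_tot),
            model_f = model_f(sse, df_err, ss_tot, df_tot))
}

#' Adjusted R-squared from error and corrected-total rows
#'
#' `1 - (ss_err / df_err) / (ss_tot / df_tot)`: one minus the ratio of the
#' error mean square to the corrected-total mean square.
#'
#' @param ss_err,df_err residual sum of squares and degrees of freedom.
#' @param ss_tot,df_tot corrected total sum of squares and degrees of
#'   freedom (n - 1).
#' @return adjusted R-squared.
#' @examples
#' adjusted_r2(229601.4, 173, 539795.71, 184)  # 0.548
#' @export
adjusted_r2 <- function(ss_err, df_err, ss_tot, df_tot) {
  if (df_err <= 0 || df_tot <= 0) stop("degrees of freedom must be positive")
  if (ss_err < 0 || ss_tot < 0) stop("sums of squares must be non-negative")
  1 - (ss_err / df_err) / (ss_tot / df_tot)
}

#' Whole-model F ratio from error and corrected-total rows
#'
#' `((ss_tot - ss_err) / (df_tot - df_err)) / (ss_err / df_err)`: the model
#' mean square over the error mean square.
#'
#' @inheritParams adjusted_r2
#' @return model F; `Inf` (with a warning) when the fit is exact.
#' @examples
#' model_f(229601.4, 173, 539795.71, 184)  # 21.2477
#' @export
model_f <- function(ss_err, df_err, ss_tot, df_tot) {
  if (df_tot <= df_err) stop("df_tot must exceed df_err")
  if (ss_err == 0) {
    warning("exact fit: model F is infinite")
    return(Inf)
  }
  ((ss_tot - ss_err) / (df_tot - df_err)) / (ss_err / df_err)
}

#' Write an ANOVA table as TSV
#'
#' Columns mirror the conventional report layout (Source, DF, SS, F-ratio,
#' p-value, t-ratio), with the adjusted R-squared echoed on the Model row.
#'
#' @param tab a [partial_anova()] result.
#' @param path output path.
#' @export
write_anova <- function(tab, path) {
  df <- as.data.frame(tab)
  df$adj_r2 <- c(rep(NA, nrow(df) - 1L), attr(tab, "adj_r2"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
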