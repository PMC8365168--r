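## Generation-trend fitting: value ~ generation with a random intercept per
## chain, REML estimation, Satterthwaite-approximated t-tests for the fixed
## effects (lmerTest). Single-chain tables degrade to ordinary least
## squares with a flag.

#' Build a tidy measure table
#'
#' @param chain_id,generation,measure,value Equal-length vectors; one row
#'   per observation.
#' @param unit Optional unit strings.
#' @param whistle_id Optional per-observation grouping id.
#' @return data.frame with the canonical column order.
#' @export
measure_table <- function(chain_id, generation, measure, value,
                          unit = NA_character_, whistle_id = NA_character_) {
  d <- data.frame(chain_id = as.character(chain_id),
                  generation = as.integer(generation),
                  whistle_id = as.character(whistle_id),
                  measure = as.character(measure),
                  unit = as.character(unit),
                  value = as.numeric(value), stringsAsFactors = FALSE)
  stopifnot(all(is.finite(d$value) | is.na(d$value)))
  d
}

satterthwaite_row <- function(model, term) {
  co <- summary(model)$coefficients
  if (!term %in% rownames(co)) stop("term not in model: ", term)
  co[term, , drop = TRUE]
}

new_trend_fit <- function(measure, term, est, sem, df, t, p, ranvar, resvar,
                          n, method, flags = character(0), model = NULL) {
  structure(list(measure = measure, term = term, slope = unname(est),
                 sem = unname(sem), df = unname(df), t = unname(t),
                 p_value = unname(p), random_intercept_variance = ranvar,
                 residual_variance = resvar, n_obs = n, method = method,
                 flags = flags, model = model),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s ~ generation [%s]\n", x$measure, x$method))
  cat(sprintf("  b = %.4g +/- %.4g SEM, df = %.2f, t = %.3f, P = %.4g\n",
              x$slope, x$sem, x$df, x$t, x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.trend_fit <- function(object, ...) {
  data.frame(measure = object$measure, term = object$term, b = object$slope,
             sem = object$sem, df = object$df, t = object$t,
             p = object$p_value,
             ranint_var = object$random_intercept_variance,
             resid_var = object$residual_variance, n = object$n_obs,
             method = object$method,
             flags = paste(object$flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' @export
coef.trend_fit <- function(object, ...) c(slope = object$slope)

#' Fit a per-generation trend for one measure
#'
#' REML linear mixed-effects fit of `value ~ generation + (1 | chain_id)`
#' with Satterthwaite degrees of freedom for the generation slope. With a
#' single chain the model degrades to ordinary least squares (flagged
#' `ols_fallback`); a measure with zero variance returns a degenerate fit
#' with slope 0 (flagged `degenerate`).
#'
#' @param table A measure table (see [measure_table()]).
#' @param measure Measure name to fit.
#' @return A `trend_fit` object.
#' @export
fit_generation_trend <- function(table, measure) {
  d <- table[table$measure == measure & !is.na(table$value), , drop = FALSE]
  if (!nrow(d)) stop("no rows for measure: ", measure)
  if (length(unique(d$generation)) < 3L)
    stop("need data from at least 3 generations for measure: ", measure)
  if (var(d$value) == 0)
    return(new_trend_fit(measure, "generation", 0, NA_real_, NA_real_,
                         NA_real_, NA_real_, 0, 0, nrow(d), "degenerate",
                         "degenerate"))
  if (length(unique(d$chain_id)) < 2L) {
    m <- stats::lm(value ~ generation, data = d)
    sm <- suppressWarnings(summary(m))  # perfect fits are legitimate here
    co <- sm$coefficients["generation", ]
    return(new_trend_fit(measure, "generation", co[1], co[2],
                         m$df.residual, co[3], co[4], NA_real_,
                         sm$sigma^2, nrow(d), "ols",
                         "ols_fallback", m))
  }
  m <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ generation + (1 | chain_id), data = d,
                   REML = TRUE)))
  co <- satterthwaite_row(m, "generation")
  vc <- as.data.frame(lme4::VarCorr(m))
  ranvar <- vc$vcov[vc$grp == "chain_id"][1]
  resvar <- vc$vcov[vc$grp == "Residual"][1]
  flags <- if (lme4::isSingular(m)) "singular_fit" else character(0)
  new_trend_fit(measure, "generation", co["Estimate"], co["Std. Error"],
                co["df"], co["t value"], co["Pr(>|t|)"], ranvar, resvar,
                nrow(d), "lmm_satterthwaite", flags, m)
}

#' Fit a generation-by-dataset interaction model
#'
#' For paired designs such as actual vs shuffled intervals:
#' `value ~ generation * dataset + (1 | chain_id)`, returning
#' Satterthwaite-tested fixed effects for generation, dataset and their
#' interaction.
#'
#' @param table A measure table with an extra `dataset` column (two
#'   levels).
#' @param measure Measure name to fit.
#' @return Named list of three `trend_fit` objects: `generation`,
#'   `dataset`, `interaction`.
#' @export
fit_interaction_trend <- function(table, measure) {
  d <- table[table$measure == measure & !is.na(table$value), , drop = FALSE]
  if (!nrow(d)) stop("no rows for measure: ", measure)
  if (!"dataset" %in% names(d)) stop("table needs a 'dataset' column")
  d$dataset <- factor(d$dataset)
  if (nlevels(d$dataset) != 2L) stop("'dataset' must have exactly 2 levels")
  m <- suppressMessages(suppressWarnings(
    lmerTest::lmer(value ~ generation * dataset + (1 | chain_id), data = d,
                   REML = TRUE)))
  co <- summary(m)$coefficients
  terms <- rownames(co)
  ds_term <- grep("^dataset", terms, value = TRUE)
  int_term <- grep(":", terms, value = TRUE)
  vc <- as.data.frame(lme4::VarCorr(m))
  ranvar <- vc$vcov[vc$grp == "chain_id"][1]
  resvar <- vc$vcov[vc$grp == "Residual"][1]
  flags <- if (lme4::isSingular(m)) "singular_fit" else character(0)
  mk <- function(term, label) {
    r <- co[term, ]
    new_trend_fit(measure, label, r["Estimate"], r["Std. Error"], r["df"],
                  r["t value"], r["Pr(>|t|)"], ranvar, resvar, nrow(d),
                  "lmm_satterthwaite", flags, m)
  }
  list(generation = mk("generation", "generation"),
       dataset = mk(ds_term[1], "dataset"),
       interaction = mk(int_term[1], "generation:dataset"))
}

#' Trend report over all measures of a table
#'
#' @param table A measure table.
#' @param measures Measure names (default: all with >= 3 generations of
#'   data; others are skipped with a warning).
#' @return data.frame with one row per measure: `measure, b, sem, df, t, p,
#'   n, method, flags`.
#' @export
trend_report <- function(table, measures = NULL) {
  if (is.null(measures)) measures <- unique(table$measure)
  rows <- list()
  for (ms in measures) {
    d <- table[table$measure == ms & !is.na(table$value), , drop = FALSE]
    if (length(unique(d$generation)) < 3L) {
      warning("skipping measure with < 3 generations of data: ", ms)
      next
    }
    f <- fit_generation_trend(table, ms)
    s <- summary(f)
    rows[[length(rows) + 1L]] <-
      data.frame(measure = ms, b = s$b, sem = s$sem, df = s$df, t = s$t,
                 p = s$p, n = s$n, method = s$method, flags = s$flags,
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(measure = character(), b = numeric(), sem = numeric(),
                      df = numeric(), t = numeric(), p = numeric(),
                      n = integer(), method = character(),
                      flags = character()))
  do.call(rbind, rows)
}
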