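#' 2x2 contingency tables
#'
#' Cell layout: rows are exposure yes/no, columns outcome yes/no, so `a` =
#' exposed with outcome, `b` = exposed without, `c` = unexposed with, `d` =
#' unexposed without.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return a `table2x2` matrix.
#' @export
table2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    validation_error("2x2 cells must be non-negative integers")
  m <- matrix(as.numeric(cells), nrow = 2, byrow = TRUE,
              dimnames = list(exposure = c("yes", "no"),
                              outcome = c("yes", "no")))
  if (sum(m) < 1) validation_error("2x2 table must have at least one count")
  structure(m, class = c("table2x2", "matrix"))
}

association_result <- function(statistic_name, estimate, p_value,
                               effect_size_phi = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               df = NA, f_statistic = NA_real_,
                               label = statistic_name,
                               diverging_ci = FALSE) {
  structure(list(statistic_name = statistic_name, label = label,
                 estimate = estimate, effect_size_phi = effect_size_phi,
                 ci_low = ci_low, ci_high = ci_high, df = df,
                 f_statistic = f_statistic, p_value = p_value,
                 diverging_ci = diverging_ci),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

#' @export
format.association_result <- function(x, ...) {
  flag <- if (!is.na(x$p_value) && x$p_value >= 0.05 && x$p_value < 0.10)
    " (borderline)" else ""
  ci <- if (!is.na(x$ci_low))
    sprintf(" [95%% CI %.3g, %.3g]", x$ci_low, x$ci_high) else ""
  phi <- if (!is.na(x$effect_size_phi))
    sprintf(", phi = %.3g", x$effect_size_phi) else ""
  fs <- if (!is.na(x$f_statistic))
    sprintf(", F(%s) = %.4g", paste(x$df, collapse = ","), x$f_statistic)
  else ""
  sprintf("%s: %.4g%s%s%s, P = %.3g%s", x$label, x$estimate, ci, phi, fs,
          x$p_value, flag)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction (the phi effect size
#' `sqrt(chi2 / N)` is consistent with the uncorrected statistic only), df =
#' 1, upper-tail p from the chi-square(1) distribution.
#'
#' @param t a `table2x2` (or 2x2 matrix of counts).
#' @return an `association_result` with `estimate` = chi-square and
#'   `effect_size_phi`.
#' @examples
#' chi_square_2x2(table2x2(20, 5, 5, 20))  # chi-square 18, phi 0.6
#' @export
chi_square_2x2 <- function(t) {
  m <- unclass(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    degenerate_error("2x2 table has a zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  chi2 <- unname(ht$statistic)
  association_result("chi_square", chi2, unname(ht$p.value),
                     effect_size_phi = sqrt(chi2 / sum(m)), df = 1,
                     label = sprintf("Pearson chi-square (1, N = %d)", sum(m)))
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad / bc`; CI on the log scale, `exp(log OR +/- 1.96 *
#' sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell is a degenerate table unless
#' `continuity = TRUE`, which adds 0.5 to every cell (Haldane-Anscombe).
#'
#' @param t a `table2x2`.
#' @param continuity add 0.5 to all cells when any cell is zero.
#' @return an `association_result` with `estimate` = OR.
#' @examples
#' odds_ratio_2x2(table2x2(30, 10, 10, 30))  # OR = 9
#' @export
odds_ratio_2x2 <- function(t, continuity = FALSE) {
  m <- unclass(t)
  if (any(m == 0)) {
    if (!continuity)
      degenerate_error("2x2 table has a zero cell; enable continuity or collect more data")
    m <- m + 0.5
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  se <- sqrt(sum(1 / m))
  association_result("odds_ratio", or,
                     p_value = 2 * stats::pnorm(-abs(log(or) / se)),
                     ci_low = exp(log(or) - 1.96 * se),
                     ci_high = exp(log(or) + 1.96 * se),
                     label = "odds ratio")
}

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors, length >= 3, non-constant.
#' @return an `association_result` with `estimate` = r and the two-sided p
#'   from the t distribution on n - 2 df.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) value_error("x and y must have equal length")
  if (length(x) < 3) value_error("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    value_error("constant vector: correlation undefined")
  ht <- stats::cor.test(x, y, method = "pearson")
  association_result("pearson_r", unname(ht$estimate), unname(ht$p.value),
                     ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
                     df = unname(ht$parameter), label = "Pearson r")
}

#' Simple linear regression slope with F test
#'
#' Least-squares slope of `y` on `x`, with the overall F statistic on
#' (1, n - 2) df and its p value.
#'
#' @param x,y numeric vectors, length >= 3, `var(x) > 0`.
#' @return an `association_result` with `estimate` = slope `b`, `f_statistic`
#'   and `df = c(1, n - 2)`.
#' @export
ols_slope <- function(x, y) {
  if (length(x) != length(y)) value_error("x and y must have equal length")
  if (length(x) < 3) value_error("need at least 3 observations")
  if (stats::var(x) == 0) value_error("constant x: slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  b <- unname(stats::coef(fit)[2])
  fstat <- unname(sm$fstatistic)
  association_result("ols", b,
                     p_value = stats::pf(fstat[1], fstat[2], fstat[3],
                                         lower.tail = FALSE),
                     ci_low = stats::confint(fit)[2, 1],
                     ci_high = stats::confint(fit)[2, 2],
                     df = c(fstat[2], fstat[3]), f_statistic = fstat[1],
                     label = "OLS slope b")
}

#' H-index quartile labels
#'
#' Quartile membership by the empirical 25/50/75 percentiles; values tied
#' with a boundary go to the lower quartile, so equal H-indices always share
#' a label.
#'
#' @param h numeric vector of H-indices, length >= 4.
#' @return integer vector of labels 1-4.
#' @examples
#' h_index_quartiles(c(1, 2, 3, 4))
#' @export
h_index_quartiles <- function(h) {
  if (length(h) < 4) value_error("need at least 4 H-indices to quartile")
  q <- stats::quantile(h, c(0.25, 0.5, 0.75), names = FALSE)
  1L + (h > q[1]) + (h > q[2]) + (h > q[3])
}

#' Logistic regression with Wald intervals
#'
#' Maximum-likelihood logistic regression (fitted by iteratively reweighted
#' least squares via [stats::glm()]) of a binary outcome on binary and/or
#' factor predictors, reporting one adjusted odds ratio (AOR) with a Wald 95%
#' confidence interval per non-baseline term. Rows with missing values in the
#' outcome or any predictor are dropped listwise. Complete separation (a
#' fitted probability pinned at 0 or 1) raises a classed warning and flags the
#' affected results with `diverging_ci = TRUE`.
#'
#' @param data data frame containing outcome and predictors.
#' @param outcome name of the binary (0/1 or logical) outcome column.
#' @param predictors character vector of predictor column names. Factor
#'   predictors expand to indicator terms against their first level.
#' @return list of `association_result` (one per non-baseline term), with the
#'   underlying `glm` fit in `attr(, "fit")`.
#' @examples
#' d <- data.frame(y = rep(c(0, 1), each = 20),
#'                 x = rep(c(0, 1, 0, 1), times = c(15, 5, 8, 12)))
#' logistic_fit(d, "y", "x")
#' @export
logistic_fit <- function(data, outcome, predictors) {
  if (length(predictors) < 1) value_error("at least one predictor required")
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    validation_error(sprintf("column(s) absent from data: %s",
                             paste(missing_cols, collapse = ", ")))
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  y <- d[[outcome]]
  if (length(unique(y)) != 2)
    value_error("outcome must have both levels present after listwise deletion")

  form <- stats::as.formula(paste(
    sprintf("`%s`", outcome), "~",
    paste(sprintf("`%s`", predictors), collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, data = d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged) value_error("logistic fit did not converge")
  cf <- stats::coef(fit)
  if (anyNA(cf))
    value_error(sprintf("rank-deficient model: term(s) %s inestimable",
                        paste(names(cf)[is.na(cf)], collapse = ", ")))
  # glm does not always warn under complete separation on small data; a
  # fitted probability pinned at 0/1 is the definitive symptom
  mu <- stats::fitted(fit)
  separated <- separated || any(mu < 1e-7) || any(mu > 1 - 1e-7)
  if (separated)
    warning(warningCondition(
      "complete or quasi-complete separation: Wald intervals diverge",
      class = "climsens_separation_warning"))

  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  out <- lapply(terms, function(tm) {
    est <- sm[tm, "Estimate"]
    se <- sm[tm, "Std. Error"]
    association_result("logistic", exp(est),
                       p_value = sm[tm, "Pr(>|z|)"],
                       ci_low = exp(est - 1.96 * se),
                       ci_high = exp(est + 1.96 * se),
                       label = sprintf("AOR %s", tm),
                       diverging_ci = separated)
  })
  names(out) <- terms
  attr(out, "fit") <- fit
  attr(out, "n") <- nrow(d)
  out
}

# Merge profiles + attributes into one analysis frame.
analysis_frame <- function(profiles, attributes) {
  df <- as.data.frame(profiles)
  if (!setequal(attributes$pathogen_id, df$pathogen_id))
    consistency_error("profiles and attributes cover different rosters")
  attributes <- attributes[match(df$pathogen_id, attributes$pathogen_id), ,
                           drop = FALSE]
  df <- cbind(df, attributes[, setdiff(names(attributes), "pathogen_id"),
                             drop = FALSE])
  df$sensitive <- as.integer(df$n_drivers >= 1)
  df$n_routes <- lengths(df$route_list)
  df$zoonotic <- ifelse(df$host_class == "unknown", NA_integer_,
                        as.integer(df$host_class == "zoonotic"))
  for (route in transmission_routes()) {
    nm <- route_column(route)
    df[[nm]] <- vapply(df$route_list, function(r) as.integer(route %in% r),
                       integer(1))
  }
  df$rain_driver <- vapply(df$positive_drivers,
                           function(d) as.integer("rainfall" %in% d),
                           integer(1))
  df$cc_driver <- vapply(df$positive_drivers,
                         function(d) as.integer("climate change" %in% d),
                         integer(1))
  df$n_primary <- vapply(df$positive_drivers,
                         function(d) sum(d %in% primary_drivers()), integer(1))
  df$n_secondary <- vapply(df$positive_drivers,
                           function(d) sum(d %in% secondary_drivers()),
                           integer(1))
  df$h_quartile <- factor(h_index_quartiles(df$h_index), levels = 1:4)
  df
}

route_column <- function(route) {
  paste0("route_", gsub("[^a-z]+", "_", route))
}

count_2x2 <- function(exposure, outcome) {
  keep <- !is.na(exposure) & !is.na(outcome)
  e <- exposure[keep] == 1
  o <- outcome[keep] == 1
  table2x2(sum(e & o), sum(e & !o), sum(!e & o), sum(!e & !o))
}

# Backward elimination: start from the given predictors, drop the weakest
# term while any has p >= alpha. Factor predictors are kept or dropped whole
# (minimum p over their indicator terms decides).
backward_select <- function(data, outcome, predictors, alpha = 0.05) {
  preds <- predictors
  repeat {
    if (!length(preds)) return(list(predictors = character(0), results = NULL))
    res <- logistic_fit(data, outcome, preds)
    pmin_by_pred <- vapply(preds, function(p) {
      terms <- grep(paste0("^`?", p), names(res))
      min(vapply(res[terms], function(r) r$p_value, numeric(1)))
    }, numeric(1))
    if (all(pmin_by_pred < alpha))
      return(list(predictors = preds, results = res))
    preds <- preds[-which.max(pmin_by_pred)]
  }
}

#' Run the full battery of climate-sensitivity association models
#'
#' Fits, on one cohort, every inferential question the assessment asks:
#' \describe{
#'   \item{zoonotic}{2x2 association of zoonotic status with any-driver
#'     sensitivity (Pearson chi-square, phi), plus odds ratios of sensitivity
#'     for zoonotic vs human-only and zoonotic vs animal-only pathogens.
#'     Pathogens with unknown host class are dropped listwise.}
#'   \item{route models}{univariable logistic regressions of zoonotic status
#'     on direct (non-sexual) contact, waterborne and foodborne transmission,
#'     then a multivariable model built by entering the univariably
#'     significant (p < 0.05) routes and backward-dropping terms with
#'     p >= 0.05.}
#'   \item{emergence}{two multivariable logistic models of emerging status --
#'     on rainfall-driver evidence plus H-index quartiles, and on
#'     climate-change-driver evidence plus H-index quartiles -- and a 2x2
#'     test of emerging status against any-driver sensitivity.}
#'   \item{counts}{Pearson correlations of the number of transmission routes
#'     with the number of climate drivers (all, primary-only,
#'     secondary-only), and the least-squares regression of the number of
#'     reporting countries on the number of drivers.}
#' }
#'
#' @param profiles a `climsens_profiles` object.
#' @param attributes validated attribute table for the same roster.
#' @return a `climsens_assoc` list of `association_result` objects and fitted
#'   models; see `print()` for a compact report.
#' @export
climate_associations <- function(profiles, attributes) {
  df <- analysis_frame(profiles, attributes)

  known <- df[!is.na(df$zoonotic), , drop = FALSE]
  zoo_tab <- count_2x2(known$zoonotic, known$sensitive)
  zoo_chi <- chi_square_2x2(zoo_tab)
  vs_human <- known[known$host_class %in% c("zoonotic", "human-only"), ]
  vs_animal <- known[known$host_class %in% c("zoonotic", "animal-only"), ]
  or_vs_human <- odds_ratio_2x2(count_2x2(vs_human$zoonotic,
                                          vs_human$sensitive),
                                continuity = TRUE)
  or_vs_human$label <- "OR sensitive, zoonotic vs human-only"
  or_vs_animal <- odds_ratio_2x2(count_2x2(vs_animal$zoonotic,
                                           vs_animal$sensitive),
                                 continuity = TRUE)
  or_vs_animal$label <- "OR sensitive, zoonotic vs animal-only"

  # an inestimable component (e.g. a driver nobody has, on a small cohort)
  # is reported as NULL rather than aborting the whole battery
  try_fit <- function(expr) tryCatch(expr,
                                     climsens_error = function(e) NULL)

  route_preds <- route_column(c("direct nonsexual contact", "waterborne",
                                "foodborne"))
  univariable <- lapply(route_preds, function(p)
    try_fit(logistic_fit(known, "zoonotic", p)))
  names(univariable) <- route_preds
  uni_p <- vapply(univariable, function(r)
    if (is.null(r)) NA_real_ else r[[1]]$p_value, numeric(1))
  enter <- route_preds[!is.na(uni_p) & uni_p < 0.05]
  multi <- backward_select(known, "zoonotic", enter)

  emerging_rain <- try_fit(logistic_fit(df, "emerging",
                                        c("rain_driver", "h_quartile")))
  emerging_cc <- try_fit(logistic_fit(df, "emerging",
                                      c("cc_driver", "h_quartile")))
  emerging_chi <- try_fit(chi_square_2x2(count_2x2(df$emerging,
                                                   df$sensitive)))

  structure(list(
    zoonotic_table = zoo_tab,
    zoonotic_chi_square = zoo_chi,
    or_vs_human = or_vs_human,
    or_vs_animal = or_vs_animal,
    zoonotic_univariable = univariable,
    zoonotic_multivariable = multi$results,
    zoonotic_multivariable_predictors = multi$predictors,
    emerging_rain = emerging_rain,
    emerging_climate_change = emerging_cc,
    emerging_chi_square = emerging_chi,
    routes_vs_drivers_r = pearson_correlation(df$n_routes, df$n_drivers),
    routes_vs_primary_r = pearson_correlation(df$n_routes, df$n_primary),
    routes_vs_secondary_r = pearson_correlation(df$n_routes, df$n_secondary),
    countries_on_drivers = ols_slope(df$n_drivers, df$n_countries),
    n = nrow(df),
    n_host_known = nrow(known)
  ), class = "climsens_assoc")
}

#' @export
print.climsens_assoc <- function(x, ...) {
  cat("Climate-sensitivity association models",
      sprintf("(N = %d; host class known for %d)\n", x$n, x$n_host_known))
  cat("\nZoonotic status vs any-driver sensitivity\n")
  cat("  ", format(x$zoonotic_chi_square), "\n")
  cat("  ", format(x$or_vs_human), "\n")
  cat("  ", format(x$or_vs_animal), "\n")
  cat("\nZoonotic ~ transmission route (univariable)\n")
  for (r in x$zoonotic_univariable)
    cat("  ", if (is.null(r)) "not estimable" else format(r[[1]]), "\n")
  cat("\nZoonotic ~ transmission route (multivariable, backward-selected)\n")
  if (is.null(x$zoonotic_multivariable)) {
    cat("   no route retained\n")
  } else {
    for (r in x$zoonotic_multivariable) cat("  ", format(r), "\n")
  }
  cat("\nEmerging ~ rainfall driver + H-index quartiles\n")
  for (r in x$emerging_rain %||% list("not estimable"))
    cat("  ", if (is.character(r)) r else format(r), "\n")
  cat("\nEmerging ~ climate-change driver + H-index quartiles\n")
  for (r in x$emerging_climate_change %||% list("not estimable"))
    cat("  ", if (is.character(r)) r else format(r), "\n")
  cat("\nEmerging vs any-driver sensitivity\n")
  cat("  ", if (is.null(x$emerging_chi_square)) "not estimable"
      else format(x$emerging_chi_square), "\n")
  cat("\nCounts\n")
  cat("   routes vs drivers:", format(x$routes_vs_drivers_r), "\n")
  cat("   countries on drivers:", format(x$countries_on_drivers), "\n")
  invisible(x)
}

# Flatten a climsens_assoc into a plain data frame (one row per result),
# convenient for JSON reports.
#' @export
as.data.frame.climsens_assoc <- function(x, ...) {
  rows <- list()
  add <- function(group, r) {
    if (is.null(r)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, label = r$label, statistic = r$statistic_name,
      estimate = r$estimate, ci_low = r$ci_low, ci_high = r$ci_high,
      phi = r$effect_size_phi, p_value = r$p_value,
      stringsAsFactors = FALSE)
  }
  add("zoonotic_2x2", x$zoonotic_chi_square)
  add("zoonotic_2x2", x$or_vs_human)
  add("zoonotic_2x2", x$or_vs_animal)
  for (nm in names(x$zoonotic_univariable)) {
    u <- x$zoonotic_univariable[[nm]]
    if (!is.null(u)) add("zoonotic_univariable", u[[1]])
  }
  for (r in x$zoonotic_multivariable %||% list())
    add("zoonotic_multivariable", r)
  for (r in x$emerging_rain %||% list()) add("emerging_rain", r)
  for (r in x$emerging_climate_change %||% list())
    add("emerging_climate_change", r)
  add("emerging_2x2", x$emerging_chi_square)
  add("counts", x$routes_vs_drivers_r)
  add("counts", x$routes_vs_primary_r)
  add("counts", x$routes_vs_secondary_r)
  add("counts", x$countries_on_drivers)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
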