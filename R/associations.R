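#' Group summaries with omnibus and post-hoc tests
#'
#' Per-group mean +/- SD for continuous variables (count and percent for
#' categorical), with an omnibus p-value — Student's t-test for two groups,
#' one-way ANOVA for more, Pearson chi-square (no continuity correction)
#' for categorical — and Bonferroni-adjusted pairwise comparisons when
#' there are more than two groups.
#'
#' @param cohort data.frame.
#' @param grouping name of the grouping column (e.g. `"al_group"`,
#'   `"tilt_class"`, `"rotation_class"`).
#' @param variables columns to summarize; defaults to all columns except
#'   the grouping and identifier columns.
#' @return list of class `group_summary`: `table` (data.frame of formatted
#'   summaries and p-values), `pairwise` (named list of Bonferroni-adjusted
#'   pairwise p matrices), `groups`, `n`.
#' @export
summarize_groups <- function(cohort, grouping, variables = NULL) {
  if (!grouping %in% names(cohort)) stop("grouping column not found: ", grouping)
  gr <- factor(cohort[[grouping]])
  if (nlevels(gr) < 2) stop("need >= 2 non-empty groups")
  if (any(table(gr) == 0)) stop("empty group level in ", grouping)
  if (is.null(variables))
    variables <- setdiff(names(cohort),
                         c(grouping, "subject_id", "source_id",
                           "exclusion_reason"))
  rows <- list(); pairwise <- list()
  for (v in variables) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      cells <- tapply(x, gr, function(z)
        sprintf("%.2f ± %.2f", mean(z), stats::sd(z)))
      if (nlevels(gr) == 2) {
        sp <- split(x, gr)
        p <- if (stats::sd(x) == 0) 1 else
          tryCatch(stats::t.test(sp[[1]], sp[[2]], var.equal = TRUE)$p.value,
                   error = function(e) NA_real_)
      } else {
        p <- stats::anova(stats::lm(x ~ gr))[["Pr(>F)"]][1]
        pw <- stats::pairwise.t.test(x, gr, p.adjust.method = "bonferroni",
                                     pool.sd = TRUE)
        pairwise[[v]] <- pw$p.value
      }
    } else {
      tab <- table(x, gr)
      cells <- apply(tab, 2, function(cl)
        paste(sprintf("%s: %d (%.1f%%)", rownames(tab), cl,
                      100 * cl / sum(cl)), collapse = "; "))
      p <- tryCatch(
        stats::chisq.test(tab, correct = FALSE)$p.value,
        warning = function(w)
          suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
        error = function(e) NA_real_)
    }
    rows[[v]] <- data.frame(variable = v, t(cells), p = p,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, pairwise = pairwise, groups = levels(gr),
                 n = as.integer(table(gr))),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Groups:", paste(sprintf("%s (n=%d)", x$groups, x$n), collapse = ", "),
      "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Normality check (Kolmogorov-Smirnov)
#'
#' Lilliefors-corrected one-sample KS test against a normal distribution
#' with parameters estimated from the sample (the common "K-S test" of
#' statistical packages). `method = "ks"` instead runs the fixed-parameter
#' KS test with the sample mean/SD plugged in, which is anti-conservative.
#'
#' @param x numeric vector, n >= 5.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return list with `statistic` and `p.value`.
#' @export
normality_check <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant column: normality undefined")
  res <- if (method == "lilliefors") nortest::lillie.test(x)
  else suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

# Single-predictor fit; returns an effect-estimate row.
fit_one <- function(cohort, outcome, term, family) {
  df <- cohort[, c(outcome, term)]
  names(df) <- c(".y", ".x")
  if (is.character(df$.x)) df$.x <- factor(df$.x)
  if (family == "logistic") {
    fit <- suppressWarnings(
      stats::glm(.y ~ .x, data = df, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    if (nrow(sm) < 2 || !is.finite(sm[2, 2]) || sm[2, 2] > 100)
      return(data.frame(term = term, estimate = NA_real_, conf_low = NA_real_,
                        conf_high = NA_real_, std_beta = NA_real_,
                        p = NA_real_, model = "logistic", separation = TRUE,
                        stringsAsFactors = FALSE))
    b <- sm[2, 1]; se <- sm[2, 2]; p <- sm[2, 4]
    data.frame(term = term, estimate = exp(b),
               conf_low = exp(b - 1.959964 * se),
               conf_high = exp(b + 1.959964 * se),
               std_beta = NA_real_, p = p, model = "logistic",
               separation = FALSE, stringsAsFactors = FALSE)
  } else {
    fit <- stats::lm(.y ~ .x, data = df)
    sm <- summary(fit)$coefficients
    b <- sm[2, 1]; se <- sm[2, 2]; p <- sm[2, 4]
    xv <- if (is.factor(df$.x)) as.numeric(df$.x) - 1 else df$.x
    data.frame(term = term, estimate = b,
               conf_low = b - stats::qt(0.975, fit$df.residual) * se,
               conf_high = b + stats::qt(0.975, fit$df.residual) * se,
               std_beta = b * stats::sd(xv) / stats::sd(df$.y),
               p = p, model = "linear", separation = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Univariate screening of candidate predictors
#'
#' Fits each candidate alone against the outcome (logistic for a binary
#' tilt outcome, ordinary least squares for continuous rotation) and
#' selects those with p < `level` for the multivariate model. The
#' collinearity rule removes spherical equivalent and radial peripapillary
#' capillary densities from the multivariate candidate set (axial length
#' and superficial density stand in for them).
#'
#' @param cohort data.frame.
#' @param outcome outcome column name; character/factor outcomes are
#'   treated as binary (logistic), numeric as continuous (linear).
#' @param candidates character vector of predictor columns.
#' @param level screening significance level.
#' @param collinearity_exclude regex of terms never passed to the
#'   multivariate model.
#' @return list of class `univariate_screen`: `estimates` (one row per
#'   candidate), `selected` (character vector).
#' @export
univariate_screen <- function(cohort, outcome, candidates, level = 0.10,
                              collinearity_exclude = "^SE$|_RPC$|^RPC") {
  y <- cohort[[outcome]]
  family <- if (is.numeric(y)) "linear" else "logistic"
  if (family == "logistic") {
    y <- factor(y)
    if (nlevels(y) != 2) stop("binary outcome must have exactly 2 levels")
    # second factor level is the modeled event; for tilt_class the levels
    # sort as non_tilted < tilted, so the event is the tilted disc
    cohort[[outcome]] <- as.numeric(y == levels(y)[2])
  }
  est <- do.call(rbind, lapply(candidates, function(tm)
    fit_one(cohort, outcome, tm, family)))
  if (any(est$separation, na.rm = TRUE))
    warning("separation in logistic fit; term(s) dropped: ",
            paste(est$term[est$separation], collapse = ", "))
  ok <- !est$separation & is.finite(est$p) & est$p < level
  selected <- est$term[ok]
  selected <- selected[!grepl(collinearity_exclude, selected)]
  structure(list(estimates = est, selected = selected, level = level,
                 model = family), class = "univariate_screen")
}

effect_rows <- function(fit, model, data) {
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)[-1]
  ci <- suppressMessages(stats::confint.default(fit))
  out <- lapply(terms, function(tm) {
    b <- sm[tm, 1]; p <- sm[tm, 4]
    if (model == "logistic") {
      data.frame(term = tm, estimate = exp(b), conf_low = exp(ci[tm, 1]),
                 conf_high = exp(ci[tm, 2]), std_beta = NA_real_, p = p,
                 model = model, stringsAsFactors = FALSE)
    } else {
      mv <- stats::model.matrix(fit)[, tm]
      data.frame(term = tm, estimate = b, conf_low = ci[tm, 1],
                 conf_high = ci[tm, 2],
                 std_beta = b * stats::sd(mv) / stats::sd(fit$model[[1]]),
                 p = p, model = model, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Multivariate logistic model for disc tilt
#'
#' Maximum-likelihood logistic regression of tilted-disc status on the
#' selected predictors, reporting odds ratios with Wald 95% CIs.
#'
#' @param cohort data.frame with a binary tilt outcome column.
#' @param predictors character vector of predictor columns.
#' @param outcome outcome column (default `tilt_class`; the modeled event
#'   is the tilted level).
#' @return list of class `model_fit`: `terms` (effect estimates), `r2`
#'   (McFadden pseudo-R^2), `n`, `fit`.
#' @export
fit_tilt_logistic <- function(cohort, predictors, outcome = "tilt_class") {
  y <- cohort[[outcome]]
  if (!is.numeric(y)) y <- as.numeric(y == "tilted")
  df <- cohort[, predictors, drop = FALSE]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  df$.y <- y
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge (",
                           length(predictors), " predictors, n = ", nrow(df), ")")
  r2 <- 1 - fit$deviance / fit$null.deviance
  structure(list(terms = effect_rows(fit, "logistic", df), r2 = r2,
                 adj_r2 = NA_real_, n = nrow(df), fit = fit),
            class = "model_fit")
}

#' Stepwise linear model for disc rotation
#'
#' Forward-backward stepwise ordinary least squares with p-value criteria
#' (entry p < `enter`, removal p >= `remove`), the convention of classic
#' statistical packages. Reports unstandardized B with 95% CI, standardized
#' beta, R-squared and adjusted R-squared. If no candidate survives, an
#' empty model with R-squared 0 is returned.
#'
#' @param cohort data.frame.
#' @param candidates character vector of candidate predictor columns.
#' @param outcome continuous outcome column (default `rotation_deg`).
#' @param enter entry significance level.
#' @param remove removal significance level.
#' @return list of class `model_fit` with `terms`, `r2`, `adj_r2`, `n`,
#'   `selected`, `fit`.
#' @export
fit_rotation_stepwise <- function(cohort, candidates,
                                  outcome = "rotation_deg",
                                  enter = 0.05, remove = 0.10) {
  df <- cohort[, c(outcome, candidates)]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  names(df)[1] <- ".y"
  included <- character(0)
  pool <- candidates
  repeat {
    changed <- FALSE
    # forward: best candidate by its p-value when added
    if (length(pool)) {
      addp <- vapply(pool, function(tm) {
        fit <- stats::lm(stats::reformulate(c(included, tm), ".y"), data = df)
        sm <- summary(fit)$coefficients
        rows <- grep(paste0("^", tm), rownames(sm))
        min(sm[rows, 4])
      }, numeric(1))
      if (min(addp) < enter) {
        best <- names(which.min(addp))
        included <- c(included, best)
        pool <- setdiff(pool, best)
        changed <- TRUE
      }
    }
    # backward: drop worst included term while p >= remove
    while (length(included)) {
      fit <- stats::lm(stats::reformulate(included, ".y"), data = df)
      sm <- summary(fit)$coefficients
      worst_p <- vapply(included, function(tm)
        max(sm[grep(paste0("^", tm), rownames(sm)), 4]), numeric(1))
      if (max(worst_p) >= remove) {
        drop <- names(which.max(worst_p))
        included <- setdiff(included, drop)
        pool <- union(pool, drop)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (!length(included)) {
    return(structure(list(terms = data.frame(), r2 = 0, adj_r2 = 0,
                          n = nrow(df), selected = character(0), fit = NULL),
                     class = "model_fit"))
  }
  fit <- stats::lm(stats::reformulate(included, ".y"), data = df)
  sm <- summary(fit)
  structure(list(terms = effect_rows(fit, "linear", df),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 n = nrow(df), selected = included, fit = fit),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  lab <- if (length(x$terms) && any(x$terms$model == "logistic"))
    "OR" else "B"
  cat(sprintf("Model fit (n = %d), R2 = %.3f%s\n", x$n, x$r2,
              if (is.finite(x$adj_r2)) sprintf(", adj R2 = %.3f", x$adj_r2)
              else ""))
  if (length(x$terms)) {
    tt <- x$terms
    cat(sprintf("  %-12s %s = %8.3f  [%8.3f, %8.3f]  p = %.4g\n",
                tt$term, lab, tt$estimate, tt$conf_low, tt$conf_high, tt$p),
        sep = "")
  } else cat("  (empty model)\n")
  invisible(x)
}

#' Build the full report table set
#'
#' Runs the complete association chain on a cohort table and returns the
#' five standard tables: axial-length-group summary, tilt-group summary,
#' rotation-group summary, logistic tilt model (univariate + multivariate)
#' and stepwise rotation model (univariate + multivariate).
#'
#' @param cohort cohort data.frame with biometry, derived indices,
#'   morphometry and 12 per-layer sector density columns.
#' @param screen_level univariate screening level.
#' @return list of class `cohort_report` with elements `al_summary`,
#'   `tilt_summary`, `rotation_summary`, `tilt_model`, `rotation_model`,
#'   `tilt_screen`, `rotation_screen`, `prevalence`.
#' @export
build_report <- function(cohort, screen_level = 0.10) {
  dens_cols <- grep("^[SINT]_(DVD|SVD|RPC)$", names(cohort), value = TRUE)
  need <- c("AL", "IOP", "RLP", "sex", "tilt_class", "rotation_deg",
            "rotation_class", "al_group", "tilt_ratio", dens_cols)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "))
  summary_vars <- c("age", "sex", "rotation_deg", "tilt_ratio", "AL", "CCT",
                    "ACD", "LT", "RLP", "SE", "IOP", "MOPP", dens_cols)
  summary_vars <- intersect(summary_vars, names(cohort))
  tilt_cands <- c(dens_cols[grepl("DVD|SVD", dens_cols)], "sex", "AL",
                  "ACD", "RLP", "IOP", "rotation_deg")
  rot_cands <- c(dens_cols[grepl("DVD|SVD", dens_cols)], "sex", "AL",
                 "ACD", "RLP", "IOP", "tilt_ratio")
  scr_t <- univariate_screen(cohort, "tilt_class",
                             intersect(tilt_cands, names(cohort)),
                             level = screen_level)
  scr_r <- univariate_screen(cohort, "rotation_deg",
                             intersect(rot_cands, names(cohort)),
                             level = screen_level)
  tilt_model <- if (length(scr_t$selected))
    fit_tilt_logistic(cohort, scr_t$selected) else
      structure(list(terms = data.frame(), r2 = 0, adj_r2 = NA_real_,
                     n = nrow(cohort), fit = NULL), class = "model_fit")
  rot_model <- fit_rotation_stepwise(cohort, scr_r$selected)
  structure(list(
    al_summary = summarize_groups(cohort, "al_group", summary_vars),
    tilt_summary = summarize_groups(cohort, "tilt_class", summary_vars),
    rotation_summary = summarize_groups(cohort, "rotation_class",
                                        summary_vars),
    tilt_model = tilt_model, rotation_model = rot_model,
    tilt_screen = scr_t, rotation_screen = scr_r,
    prevalence = c(
      tilted = mean(cohort$tilt_class == "tilted"),
      non_rotation = mean(cohort$rotation_class == "non_rotation"),
      inferior = mean(cohort$rotation_class == "inferior"),
      superior = mean(cohort$rotation_class == "superior"))
  ), class = "cohort_report")
}

#' Percentage of a count within a denominator
#'
#' Small helper used in reports: `100 * count / total`, optionally rounded
#' to one decimal as printed in cohort tables.
#'
#' @param count,total counts.
#' @param digits decimals to round to (NULL = no rounding).
#' @return percent.
#' @export
proportion_pct <- function(count, total, digits = 1) {
  p <- 100 * count / total
  if (!is.null(digits)) p <- round_half_up(p, digits)
  p
}
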