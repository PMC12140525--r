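# Case-control and age-at-onset burden association: logistic and linear
# models of the homozygosity metrics, onset stratification (early onset
# < 45 years), per-group age-at-onset imputation, and Bonferroni correction.

EOPD_AGE <- 45

#' Impute missing age at onset by group mean
#'
#' Replaces each case's missing age at onset with the mean observed case age
#' at onset of its group (ancestry label by default); controls are left
#' untouched. An `aao_imputed` flag column records the substitutions.
#'
#' @param sample_sheet sample sheet tibble.
#' @param group_col column defining the imputation groups.
#' @return Updated sample sheet with an `aao_imputed` column.
#' @export
impute_missing_aao <- function(sample_sheet, group_col = "ancestry_label") {
  sheet <- sample_sheet
  sheet$aao_imputed <- FALSE
  is_case <- sheet$phenotype == "case"
  for (grp in unique(sheet[[group_col]][is_case])) {
    in_grp <- is_case & sheet[[group_col]] == grp
    obs <- sheet$age_at_onset[in_grp]
    if (all(is.na(obs))) {
      abort(sprintf("group '%s' has no observed age at onset to impute from", grp))
    }
    fill <- in_grp & is.na(sheet$age_at_onset)
    sheet$age_at_onset[fill] <- mean(obs, na.rm = TRUE)
    sheet$aao_imputed[fill] <- TRUE
  }
  sheet
}

# Rows and 0/1 outcome for one contrast. EOPD: onset < 45; LOPD: onset >= 45.
contrast_frame <- function(sheet, contrast, eopd_age = EOPD_AGE) {
  onset <- sheet$age_at_onset
  eopd <- sheet$phenotype == "case" & !is.na(onset) & onset < eopd_age
  lopd <- sheet$phenotype == "case" & !is.na(onset) & onset >= eopd_age
  ctrl <- sheet$phenotype == "control"
  band <- function(lo, hi) {
    sheet$phenotype == "case" & !is.na(onset) & onset >= lo & onset < hi
  }
  pick <- switch(contrast,
    all = list(one = sheet$phenotype == "case", zero = ctrl),
    eopd_vs_controls = list(one = eopd, zero = ctrl),
    lopd_vs_controls = list(one = lopd, zero = ctrl),
    eopd_vs_lopd = list(one = eopd, zero = lopd),
    onset_lt35_vs_controls = list(one = band(-Inf, 35), zero = ctrl),
    onset_35_44_vs_controls = list(one = band(35, 45), zero = ctrl),
    onset_45_54_vs_controls = list(one = band(45, 55), zero = ctrl),
    onset_55_65_vs_controls = list(one = band(55, 65.0000001), zero = ctrl),
    onset_gt65_vs_controls = list(one = band(65.0000001, Inf), zero = ctrl),
    aao = list(one = sheet$phenotype == "case" & !is.na(onset), zero = logical(nrow(sheet))),
    abort(sprintf("unknown contrast '%s'", contrast))
  )
  keep <- pick$one | pick$zero
  data.frame(row = which(keep), y = as.integer(pick$one[keep]))
}

#' Fit one burden-association model
#'
#' Fits a maximum-likelihood logistic regression of case status (or a linear
#' regression of age at onset) on one homozygosity metric plus covariates,
#' and reports the metric's coefficient with its standard error and two-sided
#' Wald p-value. For `eopd_vs_lopd`, early-onset cases are coded 1 and
#' late-onset 0. Separation or a singular design yields a flagged failure
#' row, not an error.
#'
#' @param metrics tibble from [summarize_roh()].
#' @param sample_sheet sample sheet tibble.
#' @param pcs optional principal-component tibble from [compute_pcs()].
#' @param outcome `"case_status"` or `"aao"`.
#' @param predictor metric column name (`"s_roh_kb"`, `"n_roh"`,
#'   `"av_roh_kb"`, `"f_roh"`).
#' @param contrast subset/contrast name; see [run_association_battery()].
#' @param covariates subset of `c("age", "sex")`; for age-at-onset models the
#'   default drops `age` since onset is the outcome.
#' @param n_pcs how many PC columns of `pcs` to adjust for.
#' @return Object of class `roh_assoc` with `tidy()`/`glance()` methods.
#' @export
fit_model <- function(metrics, sample_sheet, pcs = NULL,
                      outcome = c("case_status", "aao"),
                      predictor = "f_roh",
                      contrast = "all",
                      covariates = if (match.arg(outcome) == "aao") "sex"
                                   else c("age", "sex"),
                      n_pcs = if (is.null(pcs)) 0L else sum(grepl("^PC", names(pcs)))) {
  outcome <- match.arg(outcome)
  sheet <- sample_sheet
  if (outcome == "aao") contrast <- "aao"
  cf <- contrast_frame(sheet, contrast)
  df <- sheet[cf$row, , drop = FALSE]
  df$.y <- if (outcome == "aao") df$age_at_onset else cf$y
  df <- left_join(df, metrics, by = "sample_id")
  if (!is.null(pcs) && n_pcs > 0) df <- left_join(df, pcs, by = "sample_id")
  df$.x <- df[[predictor]]
  terms <- ".x"
  if ("age" %in% covariates) terms <- c(terms, "age_at_sampling")
  if ("sex" %in% covariates) {
    n_known <- sum(df$sex %in% c("male", "female"))
    if (n_known < nrow(df)) {
      inform(sprintf("dropping %d sample(s) with unknown sex", nrow(df) - n_known))
      df <- df[df$sex %in% c("male", "female"), , drop = FALSE]
    }
    df$.sex <- as.integer(df$sex == "female")
    if (length(unique(df$.sex)) > 1) terms <- c(terms, ".sex")
  }
  if (n_pcs > 0) terms <- c(terms, paste0("PC", seq_len(n_pcs)))
  use <- complete.cases(df[c(".y", terms)])
  df <- df[use, , drop = FALSE]
  spec <- list(outcome = outcome, predictor = predictor, contrast = contrast,
               covariates = covariates, n_pcs = n_pcs)
  fail <- function(msg) {
    structure(list(spec = spec, beta = NA_real_, se = NA_real_,
                   p_value = NA_real_, n_used = nrow(df),
                   failed = TRUE, message = msg, fit = NULL),
              class = "roh_assoc")
  }
  if (nrow(df) == 0 || length(unique(df$.y)) < 2) {
    return(fail("outcome has fewer than 2 distinct values in this subset"))
  }
  if (sd(df$.x) == 0) return(fail("singular design: predictor is constant"))
  form <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    suppressWarnings(
      if (outcome == "case_status") {
        glm(form, data = df, family = binomial(),
            control = stats::glm.control(epsilon = 1e-12, maxit = 50))
      } else {
        lm(form, data = df)
      }
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || anyNA(coef(fit)[".x"])) return(fail("model fit failed"))
  separated <- outcome == "case_status" && !fit$converged
  beta <- coef(fit)[[".x"]]
  se <- sqrt(diag(vcov(fit))[[".x"]])
  z <- beta / se
  p <- if (outcome == "case_status") 2 * pnorm(-abs(z))
       else 2 * stats::pt(-abs(z), df = fit$df.residual)
  structure(list(spec = spec, beta = beta, se = se, p_value = p,
                 n_used = nrow(df), failed = separated,
                 message = if (separated) "possible separation: fit did not converge" else NA_character_,
                 fit = fit),
            class = "roh_assoc")
}

#' @export
print.roh_assoc <- function(x, ...) {
  cat(sprintf("<roh_assoc> %s ~ %s (%s)\n", x$spec$outcome, x$spec$predictor,
              x$spec$contrast))
  cat(sprintf("  beta = %.6g  se = %.6g  p = %.3g  n = %d%s\n",
              x$beta, x$se, x$p_value, x$n_used,
              if (isTRUE(x$failed)) paste0("  [", x$message, "]") else ""))
  invisible(x)
}

#' Tidy an association fit
#' @param x a `roh_assoc` object.
#' @param ... unused.
#' @return One-row tibble with term, estimate, std.error, p.value.
#' @method tidy roh_assoc
#' @export
tidy.roh_assoc <- function(x, ...) {
  tibble(term = x$spec$predictor, estimate = x$beta, std.error = x$se,
         p.value = x$p_value)
}

#' Glance at an association fit
#' @param x a `roh_assoc` object.
#' @param ... unused.
#' @return One-row tibble with outcome, contrast, n, convergence flag.
#' @method glance roh_assoc
#' @export
glance.roh_assoc <- function(x, ...) {
  tibble(outcome = x$spec$outcome, contrast = x$spec$contrast,
         n_used = x$n_used, failed = isTRUE(x$failed))
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m` for `m` tests — e.g. 0.05 / 9 for the nine length-threshold
#' ranges, or 0.05 divided by the number of case-enriched ROH pools per
#' ancestry group.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests, at least 1.
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(m) || any(m < 1)) abort("m must be >= 1")
  alpha / m
}

#' Run the full burden-association battery
#'
#' Fits every (contrast x predictor x recessive-gene-exclusion) cell:
#' logistic models for the eight case-control contrasts (all, early onset,
#' late onset, early vs late onset, each with and without segments near known
#' recessive Parkinson's disease genes) and the five onset age bands, plus
#' linear age-at-onset models. Each row carries the family-wise Bonferroni
#' alpha (0.05 divided by the number of fitted models).
#'
#' @param segments segment tibble from [call_roh_cohort()].
#' @param sample_sheet sample sheet tibble.
#' @param pcs optional PC tibble.
#' @param recessive_regions optional gene-region tibble; when supplied, the
#'   battery is doubled with metrics recomputed after
#'   [exclude_gene_regions()].
#' @param predictors metric columns to test.
#' @param contrasts contrast names; defaults to the four primary contrasts,
#'   the five onset bands, and the age-at-onset model.
#' @param autosome_kb denominator for F_ROH.
#' @param alpha family-wise error rate for the Bonferroni column.
#' @return Tibble of class `roh_battery`: one row per fitted model with
#'   `contrast`, `predictor`, `excl_recessive`, `beta`, `se`, `p_value`,
#'   `n_used`, `bonferroni_alpha`, `significant`, `note`.
#' @export
run_association_battery <- function(segments, sample_sheet, pcs = NULL,
                                    recessive_regions = NULL,
                                    predictors = c("s_roh_kb", "n_roh",
                                                   "av_roh_kb", "f_roh"),
                                    contrasts = c("all", "eopd_vs_controls",
                                                  "lopd_vs_controls",
                                                  "eopd_vs_lopd",
                                                  "onset_lt35_vs_controls",
                                                  "onset_35_44_vs_controls",
                                                  "onset_45_54_vs_controls",
                                                  "onset_55_65_vs_controls",
                                                  "onset_gt65_vs_controls",
                                                  "aao"),
                                    autosome_kb = AUTOSOME_KB,
                                    alpha = 0.05) {
  ids <- sample_sheet$sample_id
  variants <- list(`FALSE` = segments)
  if (!is.null(recessive_regions)) {
    variants$`TRUE` <- exclude_gene_regions(segments, recessive_regions)
  }
  rows <- list()
  for (excl in names(variants)) {
    mets <- summarize_roh(variants[[excl]], sample_ids = ids,
                          autosome_kb = autosome_kb)
    for (ctr in contrasts) {
      for (pred in predictors) {
        fit <- fit_model(mets, sample_sheet, pcs,
                         outcome = if (ctr == "aao") "aao" else "case_status",
                         predictor = pred, contrast = ctr)
        rows[[length(rows) + 1L]] <- tibble(
          contrast = ctr, predictor = pred,
          excl_recessive = as.logical(excl),
          beta = fit$beta, se = fit$se, p_value = fit$p_value,
          n_used = fit$n_used,
          note = if (isTRUE(fit$failed)) fit$message else NA_character_
        )
      }
    }
  }
  out <- bind_rows(rows)
  m <- sum(!is.na(out$p_value))
  out$bonferroni_alpha <- bonferroni_threshold(alpha, max(m, 1))
  out$significant <- !is.na(out$p_value) & out$p_value < out$bonferroni_alpha
  class(out) <- c("roh_battery", class(out))
  out
}
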