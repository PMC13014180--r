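#' @title Case-control effect maps and the axis-contraction test
#' @description Standardized per-sulcus group effects from ordinary least
#'   squares with configurable covariates, Bonferroni/nominal significance
#'   flags, covariate residualization, and the linear/complex contraction
#'   test fit as a random-intercept mixed model.
#' @name group_effects
NULL

#' Run the complexity pipeline on a simulated or loaded cohort
#'
#' Builds one SPN per subject, the mean control SPN, its eigen-fold index
#' (oriented by `reference_axis` if supplied, else by the annotation anchor),
#' and per-subject Fisher-Z complexity scores.
#'
#' @param cohort list with `phenotypes` and `covariates` as returned by
#'   [simulate_cohort()] (or assembled from files).
#' @param include_diagonal passed to [complexity_scores()].
#' @param reference optional [eigen_fold_index()] to use instead of the one
#'   derived from this cohort's controls.
#' @param sulci sulcus ordering.
#' @param loo_controls score each control against the eigen-fold index of
#'   the mean SPN excluding that control (default TRUE when the reference is
#'   cohort-derived). Without this, controls are scored against a template
#'   they contributed to, inflating their coherence relative to cases — a
#'   bias that mimics axis contraction in case-control contrasts.
#' @return list with `spns`, `mean_control_spn`, `efi` and `scores` (long
#'   data.frame: subject, sulcus, r, fisher_z).
#' @export
cohort_complexity <- function(cohort, include_diagonal = FALSE,
                              reference = NULL, sulci = NULL,
                              loo_controls = is.null(reference)) {
  covs <- cohort$covariates
  if (is.null(sulci)) sulci <- unique(cohort$phenotypes$sulcus)
  spns <- cohort_spns(cohort$phenotypes, covs$subject, sulci = sulci)
  controls <- covs$subject[covs$group == "control"]
  mspn <- mean_spn(spns[controls])
  efi <- if (is.null(reference)) eigen_fold_index(mspn) else reference
  n_ctrl <- length(controls)
  scores <- do.call(rbind, lapply(names(spns), function(s) {
    efi_s <- efi
    if (loo_controls && is.null(reference) && s %in% controls && n_ctrl > 2) {
      loo <- (unclass(mspn) * n_ctrl - unclass(spns[[s]])) / (n_ctrl - 1)
      diag(loo) <- 1
      efi_s <- eigen_fold_index(structure(loo, class = class(mspn)))
    }
    cs <- complexity_scores(spns[[s]], efi_s, include_diagonal)
    cs$subject <- s
    cs
  }))
  list(spns = spns, mean_control_spn = mspn, efi = efi,
       scores = scores[, c("subject", "sulcus", "r", "fisher_z")])
}

# build the covariate design matrix (no intercept column; lm adds it)
.covariate_frame <- function(covariates, covariates_used) {
  out <- list()
  for (cv in covariates_used) {
    if (!cv %in% names(covariates)) {
      stop("covariate '", cv, "' not found", call. = FALSE)
    }
    v <- covariates[[cv]]
    out[[cv]] <- if (cv %in% c("sex", "site")) factor(v) else as.numeric(v)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Standardized group effect for one sulcus
#'
#' Fits `z(value) ~ group + covariates` by OLS, where the response is
#' standardized to mean 0 / SD 1 across all included individuals (cases and
#' controls pooled), so the group coefficient is a standardized effect size.
#'
#' @param values numeric response, one per subject, aligned with
#'   `covariates` rows.
#' @param covariates data.frame including a `group` column
#'   (`"case"`/`"control"`) plus any covariate columns.
#' @param covariates_used character vector of covariate column names
#'   (may be empty).
#' @return one-row data.frame: beta1, se, p, n, covariates.
#' @export
fit_sulcus_effect <- function(values, covariates,
                              covariates_used = c("age", "TTV", "EN",
                                                  "sex", "site")) {
  stopifnot(length(values) == nrow(covariates))
  keep <- is.finite(values)
  values <- values[keep]
  covariates <- covariates[keep, , drop = FALSE]
  grp <- factor(covariates$group, levels = c("control", "case"))
  if (nlevels(droplevels(grp)) < 2) stop("both groups required", call. = FALSE)
  z <- (values - mean(values)) / .sd_checked(values, "response")
  df <- data.frame(.z = z, .group = grp)
  if (length(covariates_used)) {
    df <- cbind(df, .covariate_frame(covariates, covariates_used))
  }
  fit <- stats::lm(.z ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)$coefficients
  row <- grep("^\\.groupcase$", rownames(sm))
  data.frame(beta1 = sm[row, 1], se = sm[row, 2], p = sm[row, 4],
             n = length(z),
             covariates = paste(covariates_used, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Per-sulcus effect map for one cohort and phenotype
#'
#' @param values_long data.frame with columns `subject`, `sulcus`, `value`
#'   (e.g. Fisher-Z complexity, or a raw phenotype pulled from the long
#'   table).
#' @param covariates per-subject covariate table including `group`.
#' @param covariates_used covariate columns entering the model; drop `"TTV"`
#'   for the TTV-sensitivity variant.
#' @param cohort cohort id recorded in the output.
#' @param alpha base significance level (default 0.05).
#' @return data.frame (class `effect_map`), one row per sulcus: beta1, se, p,
#'   n, `bonferroni` (p < alpha / n_sulci) and `nominal` (p < alpha) flags.
#' @export
effect_map <- function(values_long, covariates,
                       covariates_used = c("age", "TTV", "EN", "sex", "site"),
                       cohort = "cohort", alpha = 0.05) {
  sulci <- unique(values_long$sulcus)
  rows <- lapply(sulci, function(s) {
    d <- values_long[values_long$sulcus == s, , drop = FALSE]
    v <- d$value[match(covariates$subject, d$subject)]
    r <- fit_sulcus_effect(v, covariates, covariates_used)
    r$sulcus <- s
    r
  })
  out <- do.call(rbind, rows)
  out$cohort <- cohort
  out$bonferroni <- out$p < alpha / length(sulci)
  out$nominal <- out$p < alpha
  out <- out[, c("cohort", "sulcus", "beta1", "se", "p", "n",
                 "bonferroni", "nominal", "covariates")]
  class(out) <- c("effect_map", "data.frame")
  out
}

#' Residualize per-sulcus scores for all covariates except group
#'
#' @param values_long data.frame: subject, sulcus, value.
#' @param covariates per-subject covariate table.
#' @param covariates_used covariate columns (group must not be among them).
#' @return `values_long` with `value` replaced by per-sulcus OLS residuals.
#' @export
residualize <- function(values_long, covariates,
                        covariates_used = c("age", "TTV", "EN",
                                            "sex", "site")) {
  if ("group" %in% covariates_used) {
    stop("group must not be residualized out", call. = FALSE)
  }
  out <- values_long
  for (s in unique(values_long$sulcus)) {
    idx <- which(values_long$sulcus == s)
    d <- values_long[idx, , drop = FALSE]
    cv <- covariates[match(d$subject, covariates$subject), , drop = FALSE]
    df <- data.frame(.y = d$value)
    if (length(covariates_used)) {
      cf <- .covariate_frame(cv, covariates_used)
      const <- vapply(cf, function(x) length(unique(x)) < 2, logical(1))
      if (any(const)) {
        stop("degenerate covariate column: ",
             paste(names(cf)[const], collapse = ", "), call. = FALSE)
      }
      df <- cbind(df, cf)
    }
    fit <- stats::lm(.y ~ ., data = df)
    if (anyNA(stats::coef(fit))) stop("rank-deficient design", call. = FALSE)
    out$value[idx] <- stats::residuals(fit)
  }
  out
}

#' Linear/complex axis contraction test
#'
#' For each sulcal class (linear, complex), fits the mixed model
#' `resid ~ group + (1 | subject)` by REML and evaluates a one-sided Wald z
#' test of the group effect in the direction predicted by axis contraction:
#' complexity increases for the linear class (beta1 > 0) and decreases for
#' the complex class (beta1 < 0). Contraction is declared when both one-sided
#' p-values fall below `alpha`.
#'
#' @param resid_long residualized scores: subject, sulcus, value.
#' @param classes named character vector, sulcus -> `"linear"`/`"complex"`.
#' @param covariates per-subject table supplying `group`.
#' @param alpha declaration level (default 0.05).
#' @return list of class `contraction_result`: beta_linear, p_linear,
#'   beta_complex, p_complex, random-intercept variances, `contraction`
#'   flag, and `fallback` notes for degenerate fits.
#' @export
contraction_test <- function(resid_long, classes, covariates, alpha = 0.05) {
  stopifnot(all(unique(resid_long$sulcus) %in% names(classes)))
  grp <- covariates$group[match(resid_long$subject, covariates$subject)]
  resid_long$.group <- factor(grp, levels = c("control", "case"))
  fit_class <- function(cls) {
    d <- resid_long[classes[resid_long$sulcus] == cls, , drop = FALSE]
    if (length(unique(d$sulcus)) < 1) stop("empty class: ", cls)
    one_per_subject <- max(table(d$subject)) == 1L
    fallback <- NULL
    if (one_per_subject) {
      # single observation per subject: the random intercept is not
      # identifiable and the model degenerates to OLS (variance 0)
      fit <- stats::lm(value ~ .group, data = d)
      beta <- stats::coef(fit)[".groupcase"]
      se <- summary(fit)$coefficients[".groupcase", 2]
      vc <- 0
      fallback <- "single observation per subject; OLS fallback"
    } else {
      fit <- suppressMessages(lme4::lmer(
        value ~ .group + (1 | subject), data = d, REML = TRUE,
        control = lme4::lmerControl(check.conv.singular = "ignore")))
      cf <- summary(fit)$coefficients
      beta <- cf[".groupcase", "Estimate"]
      se <- cf[".groupcase", "Std. Error"]
      vc <- as.numeric(lme4::VarCorr(fit)$subject[1, 1])
      if (lme4::isSingular(fit)) {
        warning("singular random-intercept fit for class '", cls,
                "'; variance reported as 0", call. = FALSE)
        vc <- 0
      }
    }
    z <- beta / se
    list(beta = unname(beta), se = unname(se), z = unname(z),
         var_subject = vc, fallback = fallback)
  }
  lin <- fit_class("linear")
  cpl <- fit_class("complex")
  p_linear <- stats::pnorm(lin$z, lower.tail = FALSE)
  p_complex <- stats::pnorm(cpl$z, lower.tail = TRUE)
  structure(list(
    beta_linear = lin$beta, se_linear = lin$se, p_linear = p_linear,
    beta_complex = cpl$beta, se_complex = cpl$se, p_complex = p_complex,
    var_subject_linear = lin$var_subject,
    var_subject_complex = cpl$var_subject,
    contraction = (p_linear < alpha) && (p_complex < alpha),
    alpha = alpha,
    fallback = c(linear = lin$fallback, complex = cpl$fallback)
  ), class = "contraction_result")
}
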