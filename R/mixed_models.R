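#' Standardize covariates within declared strata
#'
#' Z-scores covariate columns of a trial table, optionally within outcome
#' groups (the avoid-window convention: the window-specific head-speed
#' covariate is standardized separately by outcome so that marginal means
#' at covariate zero compare outcomes at their own typical movement
#' level). A covariate that is constant within a stratum, or a stratum of
#' size one, is set to 0 with a warning.
#'
#' @param table data frame with one row per trial/event per unit.
#' @param covariates character vector of covariate column names.
#' @param by_outcome logical; standardize within levels of `outcome_col`.
#' @param outcome_col grouping column name (default `"outcome"`).
#' @return `table` with the named columns replaced by their standardized
#'   values.
#' @export
standardize_covariates <- function(table, covariates, by_outcome = FALSE,
                                   outcome_col = "outcome") {
  miss <- setdiff(covariates, names(table))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  groups <- if (by_outcome) {
    if (!outcome_col %in% names(table))
      stop("outcome column '", outcome_col, "' not found", call. = FALSE)
    as.character(table[[outcome_col]])
  } else rep("all", nrow(table))
  for (cv in covariates) {
    v <- table[[cv]]
    if (all(is.na(v))) stop("covariate '", cv, "' is all missing", call. = FALSE)
    for (g in unique(groups)) {
      i <- groups == g
      s <- stats::sd(v[i])
      if (sum(i) < 2L || is.na(s) || s == 0) {
        warning(sprintf("covariate '%s' constant (or single row) in stratum '%s'; set to 0",
                        cv, g), call. = FALSE)
        v[i] <- 0
      } else {
        v[i] <- (v[i] - mean(v[i])) / s
      }
    }
    table[[cv]] <- v
  }
  table
}

#' Build a windowed mixed-model design
#'
#' Assembles the model specification used for every analysis window: the
#' response regressed on the full interaction of the declared factors,
#' each covariate entering with its own factor-interaction block, and
#' nested random intercepts (sessions within subjects, or neurons within
#' subjects). Baseline-window models must not include the baseline dF/F
#' covariate (the response is the baseline).
#'
#' @param table trial table (long format, one row per trial x unit).
#' @param response response column name (a window area-rate in dF/F z
#'   units).
#' @param factors character vector of fixed-factor column names; their
#'   full interaction is fit.
#' @param covariates character vector of covariate column names (already
#'   standardized); each enters as `(factor interaction) * covariate`.
#' @param random random-effects grouping as `c(subject, nested_unit)`,
#'   default `c("subject", "session")` giving `(1|subject/session)`.
#' @param window window name recorded on the design; `"baseline"`
#'   triggers the baseline-covariate validation.
#' @param baseline_dff name of the baseline dF/F covariate for the
#'   validation (default `"baseline_dff"`).
#' @return A `model_design` list: `formula`, `data`, `window`,
#'   `n_groups` (random-intercept group counts per level).
#' @export
build_model <- function(table, response, factors, covariates = character(0),
                        random = c("subject", "session"),
                        window = "post_cs", baseline_dff = "baseline_dff") {
  needed <- c(response, factors, covariates, random)
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("column(s) not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (window == "baseline" && baseline_dff %in% covariates)
    stop("baseline-window models must exclude the baseline dF/F covariate",
         call. = FALSE)
  for (f in factors) table[[f]] <- factor(table[[f]])
  for (g in random) table[[g]] <- factor(table[[g]])
  fblock <- paste0("(", paste(factors, collapse = " * "), ")")
  fixed <- if (length(covariates))
    paste(c(fblock, paste(fblock, covariates, sep = " * ")), collapse = " + ")
  else fblock
  rnd <- sprintf("(1 | %s/%s)", random[1L], random[2L])
  fml <- stats::as.formula(paste(response, "~", fixed, "+", rnd))
  n_subj <- length(unique(table[[random[1L]]]))
  n_nested <- nrow(unique(table[, random, drop = FALSE]))
  structure(list(formula = fml, data = table, window = window,
                 factors = factors, covariates = covariates,
                 random = random,
                 n_groups = stats::setNames(c(n_subj, n_nested), random)),
            class = "model_design")
}

#' Fit a windowed mixed model and compute marginal means
#'
#' REML fit of the design's formula (delegated to `lmerTest`/`lme4`, with
#' Satterthwaite degrees of freedom), estimated marginal means of each
#' factor-cell at average (standardized-zero) covariate values, and
#' pairwise contrasts with Holm adjustment (Tukey HSD selectable).
#' Singular fits are flagged, not silenced.
#'
#' @param design a [build_model()] design.
#' @param specs factor(s) for the marginal means; defaults to the full
#'   factor crossing of the design.
#' @param adjust multiplicity adjustment for the pairwise contrasts:
#'   `"holm"` (default) or `"tukey"`.
#' @return An `emm_result` list: `fit` (the `lmerMod`), `emmeans` (data
#'   frame of cell means), `contrasts` (data frame with adjusted
#'   p-values), `adjust`, `singular` (logical diagnostic flag),
#'   `formula`.
#' @export
fit_and_emm <- function(design, specs = NULL, adjust = c("holm", "tukey")) {
  stopifnot(inherits(design, "model_design"))
  adjust <- match.arg(adjust)
  fit <- lmerTest::lmer(design$formula, data = design$data, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (is.null(specs))
    specs <- stats::as.formula(paste("~", paste(design$factors,
                                                collapse = " * ")))
  emm <- emmeans::emmeans(fit, specs = specs, lmer.df = "satterthwaite")
  ctr <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  structure(list(fit = fit,
                 emmeans = as.data.frame(emm),
                 contrasts = as.data.frame(ctr),
                 adjust = adjust, singular = singular,
                 formula = design$formula),
            class = "emm_result")
}

#' Likelihood-ratio test between nested fixed-effect specifications
#'
#' Refits both models by maximum likelihood and compares them, the
#' chi-squared reporting style used for fixed effects. The reduced model
#' must be nested in the full one (fewer fixed-effect terms, same random
#' structure).
#'
#' @param full,reduced `emm_result` or `lmerMod` objects.
#' @return List: `chisq`, `df`, `p`.
#' @export
lrt_fixed <- function(full, reduced) {
  f <- if (inherits(full, "emm_result")) full$fit else full
  r <- if (inherits(reduced, "emm_result")) reduced$fit else reduced
  npar_f <- length(lme4::fixef(f))
  npar_r <- length(lme4::fixef(r))
  if (npar_r >= npar_f)
    stop("models are not nested: the reduced model must have fewer fixed effects",
         call. = FALSE)
  fm <- lme4::refitML(f)
  rm_ <- lme4::refitML(r)
  chisq <- max(0, 2 * (as.numeric(stats::logLik(fm)) -
                         as.numeric(stats::logLik(rm_))))
  df <- npar_f - npar_r
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}
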