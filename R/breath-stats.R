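#' Sham-corrected least-squares means from a crossover ANCOVA
#'
#' Fits, for a single analyte, the linear mixed model
#' \deqn{y = \mu + sequence + period + product + \beta\,sham + subject(sequence) + \epsilon}
#' on the product-arm masses with the paired sham mass as covariate, and
#' returns per-product least-squares means: marginal means balanced over
#' sequence and period, evaluated at the mean sham value. The null tested is
#' that the sham-corrected mean differs from zero.
#'
#' The mixed model is fitted by REML with Satterthwaite degrees of freedom.
#' When the residual variance degenerates (e.g. noise-free data) or the
#' mixed fit fails, a fixed-effects fallback without the subject term is
#' used; a constant sham covariate is dropped from the model.
#'
#' @param sessions A `breath_sessions` data.frame (one row per subject,
#'   period and analyte).
#' @param analyte Analyte name to analyse.
#' @param level Confidence level for the interval. Default 0.95.
#'
#' @return A data.frame of class `ancova_result` with columns `analyte`,
#'   `product`, `n`, `ls_mean`, `ci_low`, `ci_high`, `p_value`, `status`
#'   (`"OK"` or `"BELOW_MDL"`) and an attribute `method` naming the fit used.
#' @export
fit_sham_ancova <- function(sessions, analyte, level = 0.95) {
  d <- sessions[sessions$analyte == analyte, , drop = FALSE]
  if (nrow(d) == 0) stop("no sessions for analyte '", analyte, "'")

  # design validation: one record per subject per product, full sequences
  tab <- table(d$subject_id, d$product)
  if (any(tab != 1))
    stop("singular design: every subject needs exactly one record per product")
  per_seq <- tapply(d$subject_id, d$sequence, function(x) length(unique(x)))
  if (any(per_seq < 2))
    stop("fewer than 2 subjects per sequence; cannot estimate")
  seq_prod <- table(d$sequence, d$product)
  if (any(seq_prod == 0))
    stop("singular design: a product is missing from a sequence")

  products <- sort(unique(d$product))
  n_sub <- length(unique(d$subject_id))

  # fully censored in both arms: report below-MDL, do not fit
  if (all(d$censored_sham) && all(d$censored_product)) {
    out <- data.frame(
      analyte = analyte, product = products, n = n_sub,
      ls_mean = 0, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, status = "BELOW_MDL", stringsAsFactors = FALSE
    )
    class(out) <- c("ancova_result", "data.frame")
    attr(out, "method") <- "none"
    return(out)
  }

  d$y <- d$product_value_ug
  d$sham <- d$sham_value_ug
  d$sequence <- factor(d$sequence)
  d$period <- factor(d$period)
  d$product <- factor(d$product)
  d$subject_id <- factor(d$subject_id)
  use_sham <- stats::sd(d$sham) > 1e-12

  fixed <- if (use_sham) y ~ sequence + period + product + sham
           else y ~ sequence + period + product

  fit <- NULL
  method <- "lmm_satterthwaite"
  mixed <- stats::update(fixed, . ~ . + (1 | subject_id))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(mixed, data = d)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    # degenerate residual variance breaks the df machinery; fall back
    ok <- tryCatch(is.finite(stats::sigma(fit)) && stats::sigma(fit) > 1e-8 &&
                     all(is.finite(as.numeric(as.matrix(stats::vcov(fit))))),
                   error = function(e) FALSE)
    if (!ok) fit <- NULL
  }
  if (is.null(fit)) {
    method <- "lm_fallback"
    fit <- stats::lm(fixed, data = d)
  }

  # summary.lm warns about "essentially perfect fit" on noise-free data
  em <- suppressWarnings(
    emmeans::emmeans(fit, "product", lmer.df = "satterthwaite"))
  es <- suppressWarnings(
    summary(em, infer = c(TRUE, TRUE), level = level, adjust = "none"))

  out <- data.frame(
    analyte = analyte, product = as.character(es$product), n = n_sub,
    ls_mean = es$emmean, ci_low = es$lower.CL, ci_high = es$upper.CL,
    p_value = es$p.value, status = "OK", stringsAsFactors = FALSE
  )
  # zero-residual fits report exact means; p-value for mean > 0 is then 0
  zero_se <- !is.na(es$SE) & es$SE < 1e-10
  out$p_value[zero_se] <- ifelse(abs(out$ls_mean[zero_se]) > 1e-10, 0, 1)
  rownames(out) <- NULL
  class(out) <- c("ancova_result", "data.frame")
  attr(out, "method") <- method
  out
}

# Table-style reporting: two decimals for factors >= 0.1, two significant
# figures below that
round_emission_factor <- function(x) {
  ifelse(is.na(x), NA_real_, ifelse(abs(x) >= 0.1, round(x, 2), signif(x, 2)))
}

#' Convert a least-squares mean to a per-mg emission factor
#'
#' Divides the sham-corrected LS mean mass exhaled over a 10-puff session by
#' the reference e-liquid mass consumed during that session, giving the
#' emission factor in ug exhaled per mg consumed. Reported values follow the
#' table convention (two decimals, or two significant figures below 0.1);
#' full precision is retained in `factor_full`.
#'
#' @param ls_mean Sham-corrected LS mean (ug per 10 puffs).
#' @param consumption Reference e-liquid consumption (mg); must be positive.
#' @param analyte Optional analyte label carried into the output.
#'
#' @return A data.frame with columns `analyte`, `factor` (rounded),
#'   `factor_full`, `reference_consumption_mg`.
#' @export
#'
#' @examples
#' emission_factor(168.83, 40)  # 4.22 ug/mg
emission_factor <- function(ls_mean, consumption, analyte = NA_character_) {
  if (any(!is.finite(consumption)) || any(consumption <= 0))
    stop("`consumption` must be positive")
  full <- ls_mean / consumption
  data.frame(
    analyte = analyte, factor = round_emission_factor(full),
    factor_full = full, reference_consumption_mg = consumption,
    stringsAsFactors = FALSE
  )
}

#' Estimate per-mg emission factors for one product from session data
#'
#' Runs the sham-corrected ANCOVA for every analyte, extracts the LS mean of
#' the chosen product, and divides by the collection-specific reference
#' consumption. Analytes censored in every sham and product sample are
#' reported with factor exactly 0 and status `BELOW_MDL` rather than the
#' positive artifact MDL substitution would produce.
#'
#' @param sessions A `breath_sessions` data.frame.
#' @param product Product whose LS means feed the factors. Default `"C"`
#'   (the mentholated mid-NBW product used for scenario modeling).
#' @param consumption Named reference consumptions (mg) per collection,
#'   default `c("1" = 40, "2" = 41)` (rounded product-C session means).
#' @param below_mdl_policy `"zero"` (default) maps fully censored analytes
#'   to factor 0; `"mdl_upper_bound"` instead reports MDL/consumption as a
#'   conservative upper bound (status still `BELOW_MDL`).
#' @param mdl Named MDL vector, only used by the upper-bound policy.
#'
#' @return A data.frame of class `emission_factors` with columns `analyte`,
#'   `product`, `ls_mean`, `ci_low`, `ci_high`, `p_value`, `factor`,
#'   `factor_full`, `reference_consumption_mg`, `status`.
#' @export
estimate_emission_factors <- function(sessions, product = "C",
                                      consumption = c("1" = 40, "2" = 41),
                                      below_mdl_policy = c("zero", "mdl_upper_bound"),
                                      mdl = default_mdl()) {
  below_mdl_policy <- match.arg(below_mdl_policy)
  analytes <- unique(sessions$analyte)
  colls <- sessions$collection[match(analytes, sessions$analyte)]
  rows <- lapply(seq_along(analytes), function(i) {
    a <- analytes[[i]]
    res <- fit_sham_ancova(sessions, a)
    r <- res[res$product == product, , drop = FALSE]
    if (nrow(r) != 1) stop("product '", product, "' absent for ", a)
    cons <- consumption[[as.character(colls[[i]])]]
    if (r$status == "BELOW_MDL") {
      full <- if (below_mdl_policy == "zero") 0 else mdl[[a]] / cons
      ef <- data.frame(analyte = a, factor = round_emission_factor(full),
                       factor_full = full, reference_consumption_mg = cons,
                       stringsAsFactors = FALSE)
    } else {
      ef <- emission_factor(r$ls_mean, cons, a)
    }
    cbind(ef[, c("analyte", "factor", "factor_full",
                 "reference_consumption_mg")],
          r[, c("product", "ls_mean", "ci_low", "ci_high", "p_value",
                "status")],
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("emission_factors", "data.frame")
  out
}

#' Run the full ANCOVA over all analytes
#'
#' Convenience wrapper returning the stacked [fit_sham_ancova()] results for
#' every analyte present in `sessions` (the "summary of estimates" table).
#'
#' @inheritParams estimate_emission_factors
#' @return A data.frame of class `ancova_result`.
#' @export
fit_all_ancova <- function(sessions) {
  out <- do.call(rbind, lapply(unique(sessions$analyte), function(a)
    fit_sham_ancova(sessions, a)))
  rownames(out) <- NULL
  class(out) <- c("ancova_result", "data.frame")
  out
}
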