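#' Default per-product true exhaled masses (ug per 10 puffs)
#'
#' Means used by the synthetic generator for each analyte under each product.
#' Menthol is nonzero only for the mentholated products; the two carbonyls
#' acetaldehyde and acrolein are zero everywhere (they are not detectable in
#' exhaled breath under these puffing conditions, so the generator emits pure
#' background which the detection limit then censors).
#'
#' @return A numeric matrix, analytes in rows, products A--D in columns.
#' @export
default_true_means <- function() {
  m <- rbind(
    nicotine         = c(89.44, 195.70, 168.83, 182.65),
    propylene_glycol = c(1678.4, 1199.7, 3354.5, 2511.0),
    glycerin         = c(5972.3, 6099.5, 6484.7, 5366.8),
    menthol          = c(0, 0, 21.11, 31.01),
    formaldehyde     = c(0.25, 0.25, 0.34, 0.30),
    acetaldehyde     = c(0, 0, 0, 0),
    acrolein         = c(0, 0, 0, 0)
  )
  colnames(m) <- c("A", "B", "C", "D")
  m
}

#' Default e-liquid consumption per collection session (mg)
#'
#' Mean and SD of e-liquid mass consumed during one 10-puff collection,
#' per product and per trapping collection.
#'
#' @return A data.frame with columns `product`, `collection`, `mean_mg`,
#'   `sd_mg`.
#' @export
default_consumption <- function() {
  data.frame(
    product = rep(c("A", "B", "C", "D"), times = 2),
    collection = rep(1:2, each = 4),
    mean_mg = c(35.2, 33.7, 40.2, 36.7, 35.6, 36.3, 41.2, 37.9),
    sd_mg = c(8.70, 11.37, 12.6, 12.32, 11.53, 11.94, 14.58, 12.4),
    stringsAsFactors = FALSE
  )
}

#' Default minimum detectable levels (ug per collection)
#'
#' Per-analyte detection limits applied to both sham and product samples.
#' Chosen so that, at the default generation means and variability, menthol
#' is censored in roughly half of all sessions (every non-mentholated
#' session) and formaldehyde in roughly one sixth, while the abundant
#' carriers are essentially never censored and the two carbonyls always are.
#'
#' @return Named numeric vector of MDLs in ug.
#' @export
default_mdl <- function() {
  c(nicotine = 1, propylene_glycol = 20, glycerin = 50, menthol = 2,
    formaldehyde = 0.15, acetaldehyde = 0.5, acrolein = 0.5)
}

#' Parameters for the synthetic exhaled-breath generator
#'
#' @param true_means Matrix of per-analyte-per-product mean exhaled masses
#'   (ug per 10 puffs), as from [default_true_means()].
#' @param cv_between Between-subject coefficient of variation of the shared
#'   multiplicative subject effect. Default 0.8.
#' @param cv_within Within-subject (residual) coefficient of variation.
#'   Default 0.9.
#' @param sham_background Named vector of mean background masses (ug) in a
#'   sham collection; defaults to zero for all analytes except formaldehyde,
#'   whose endogenous breath background is comparable to the product signal.
#' @param mdl Named vector of minimum detectable levels (ug), as from
#'   [default_mdl()].
#' @param consumption Consumption table as from [default_consumption()].
#' @param seed Integer seed; the generated dataset is a deterministic
#'   function of the seed.
#'
#' @return An object of class `generation_params`.
#' @export
generation_params <- function(true_means = default_true_means(),
                              cv_between = 0.8,
                              cv_within = 0.9,
                              sham_background = c(formaldehyde = 0.30),
                              mdl = default_mdl(),
                              consumption = default_consumption(),
                              seed = 1L) {
  if (any(!is.finite(true_means)) || any(true_means < 0))
    stop("true means must be finite and nonnegative")
  if (!is.numeric(cv_between) || cv_between < 0 || !is.numeric(cv_within) ||
      cv_within < 0)
    stop("coefficients of variation must be nonnegative")
  if (any(mdl <= 0)) stop("MDLs must be positive")
  if (any(sham_background < 0)) stop("sham backgrounds must be nonnegative")
  if (any(consumption$mean_mg <= 0) || any(consumption$sd_mg < 0))
    stop("consumption means must be positive and SDs nonnegative")
  bg <- stats::setNames(rep(0, nrow(true_means)), rownames(true_means))
  bg[names(sham_background)] <- sham_background
  structure(
    list(true_means = true_means, cv_between = cv_between,
         cv_within = cv_within, sham_background = bg, mdl = mdl,
         consumption = consumption, seed = as.integer(seed)),
    class = "generation_params"
  )
}

#' Substitute values below the minimum detectable level
#'
#' Values below the MDL are replaced by the MDL itself and flagged as
#' censored; values at or above the MDL pass through unchanged.
#'
#' @param value Numeric vector of measured masses (ug).
#' @param mdl Positive detection limit(s) (ug), recycled against `value`.
#'
#' @return A list with components `value` (censored values) and `censored`
#'   (logical flags).
#' @export
#'
#' @examples
#' apply_mdl_censoring(c(0.01, 0.05, 1.3), 0.05)
apply_mdl_censoring <- function(value, mdl) {
  if (any(!is.finite(mdl)) || any(mdl <= 0))
    stop("`mdl` must be positive and finite")
  if (any(!is.finite(value))) stop("`value` must be finite")
  list(value = pmax(value, mdl), censored = value < mdl)
}

# mean-preserving lognormal multiplier: E[exp(Z)] = 1 for given CV
rlnorm_mult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

# normal truncated at zero via inverse CDF (deterministic under the RNG)
rtnorm_pos <- function(n, mean, sd) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  p0 <- stats::pnorm(0, mean, sd)
  u <- p0 + stats::runif(n) * (1 - p0)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic exhaled-breath crossover dataset
#'
#' Simulates one paired sham/product breath collection per subject, period
#' and analyte. Product values are lognormal around the configured true mean
#' plus background, with a multiplicative subject effect shared across all of
#' that subject's sessions for the analyte; sham values are lognormal around
#' the background alone. Both arms are then censored at the analyte's MDL,
#' and e-liquid consumption is drawn from a normal truncated at zero.
#'
#' Generation is keyed by subject, so the output does not depend on the
#' ordering of rows in `design$subjects`, and is bit-identical for a given
#' seed.
#'
#' @param design A [study_design()].
#' @param params A [generation_params()].
#'
#' @return A data.frame of class `breath_sessions` with columns
#'   `subject_id`, `sequence`, `period`, `product`, `collection`, `analyte`,
#'   `sham_value_ug`, `product_value_ug`, `censored_sham`,
#'   `censored_product`, `consumed_mg`.
#' @export
generate_study <- function(design, params) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "generation_params"))
  analytes <- design$analytes$analyte
  if (!all(analytes %in% rownames(params$true_means)))
    stop("true-mean matrix is missing analytes: ",
         paste(setdiff(analytes, rownames(params$true_means)), collapse = ", "))
  if (!all(analytes %in% names(params$mdl)))
    stop("MDL vector is missing analytes")

  subjects <- design$subjects[order(design$subjects$subject_id), , drop = FALSE]
  n_sub <- nrow(subjects)
  n_per <- nchar(design$sequences[[1]])

  # full grid, subject-major so the draw layout is reproducible
  grid <- expand.grid(
    analyte = analytes, period = seq_len(n_per),
    subject_id = subjects$subject_id,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$subject_id, grid$period, match(grid$analyte, analytes)), ]
  grid$sequence <- subjects$sequence[match(grid$subject_id, subjects$subject_id)]
  grid$product <- sequence_product(grid$sequence, grid$period)
  grid$collection <- design$analytes$collection[match(grid$analyte,
                                                      design$analytes$analyte)]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  # subject x analyte shared multiplicative effect
  u <- matrix(rlnorm_mult(n_sub * length(analytes), params$cv_between),
              nrow = n_sub, dimnames = list(subjects$subject_id, analytes))
  grid$subj_mult <- u[cbind(grid$subject_id, grid$analyte)]

  n <- nrow(grid)
  bg <- params$sham_background[grid$analyte]
  mu <- params$true_means[cbind(grid$analyte, grid$product)]
  grid$raw_product <- (mu + bg) * grid$subj_mult * rlnorm_mult(n, params$cv_within)
  grid$raw_sham <- bg * grid$subj_mult * rlnorm_mult(n, params$cv_within)

  mdl <- params$mdl[grid$analyte]
  cp <- apply_mdl_censoring(grid$raw_product, mdl)
  cs <- apply_mdl_censoring(grid$raw_sham, mdl)

  # consumption: one draw per subject x period x collection
  cons_key <- unique(grid[, c("subject_id", "period", "product", "collection")])
  cons_key <- cons_key[order(cons_key$subject_id, cons_key$period,
                             cons_key$collection), ]
  ctab <- params$consumption
  idx <- match(paste(cons_key$product, cons_key$collection),
               paste(ctab$product, ctab$collection))
  if (anyNA(idx)) stop("consumption table is missing a product/collection row")
  cons_key$consumed_mg <- rtnorm_pos(nrow(cons_key),
                                     ctab$mean_mg[idx], ctab$sd_mg[idx])

  out <- data.frame(
    subject_id = grid$subject_id, sequence = grid$sequence,
    period = grid$period, product = grid$product,
    collection = grid$collection, analyte = grid$analyte,
    sham_value_ug = cs$value, product_value_ug = cp$value,
    censored_sham = cs$censored, censored_product = cp$censored,
    stringsAsFactors = FALSE
  )
  key <- paste(out$subject_id, out$period, out$collection)
  out$consumed_mg <- cons_key$consumed_mg[
    match(key, paste(cons_key$subject_id, cons_key$period, cons_key$collection))]
  rownames(out) <- NULL
  class(out) <- c("breath_sessions", "data.frame")
  out
}

#' Write or read a breath-sessions table as CSV
#'
#' One flat CSV dialect is used throughout: comma separated, UTF-8, header
#' row, `.` decimal, units embedded in column names.
#'
#' @param sessions A `breath_sessions` data.frame.
#' @param path File path.
#' @return `read_sessions()` returns a `breath_sessions` data.frame;
#'   `write_sessions()` returns `path` invisibly.
#' @export
write_sessions <- function(sessions, path) {
  utils::write.csv(as.data.frame(sessions), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sessions
#' @export
read_sessions <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sequence", "period", "product", "collection",
            "analyte", "sham_value_ug", "product_value_ug", "censored_sham",
            "censored_product", "consumed_mg")
  missing <- setdiff(need, names(out))
  if (length(missing))
    stop("sessions file is missing columns: ", paste(missing, collapse = ", "))
  class(out) <- c("breath_sessions", "data.frame")
  out
}
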