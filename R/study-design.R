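#' Analyte registry for the two exhaled-breath trapping collections
#'
#' Collection 1 traps the e-liquid carriers and flavorants (nicotine,
#' propylene glycol, glycerin, menthol); collection 2 traps the carbonyls
#' (formaldehyde, acetaldehyde, acrolein), which require derivatization and
#' are therefore sampled in a separate breath session.
#'
#' @return A data.frame with columns `analyte` and `collection` (1 or 2).
#' @export
evp_analytes <- function() {
  data.frame(
    analyte = c("nicotine", "propylene_glycol", "glycerin", "menthol",
                "formaldehyde", "acetaldehyde", "acrolein"),
    collection = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Default product panel for the crossover design
#'
#' Four cartridge-based e-liquids labelled A--D, differing in nicotine by
#' weight (NBW) and mentholation. These drive which analytes have nonzero
#' true exhaled masses in the synthetic generator (menthol only for
#' mentholated products).
#'
#' @return A data.frame with columns `product`, `nicotine_by_weight`
#'   (mass fraction) and `mentholated` (logical).
#' @export
default_products <- function() {
  data.frame(
    product = c("A", "B", "C", "D"),
    nicotine_by_weight = c(0.025, 0.040, 0.035, 0.040),
    mentholated = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Construct a crossover study design
#'
#' Defines a balanced four-period crossover: subjects are assigned in equal
#' numbers to product-order sequences (a Williams-square set by default), and
#' each subject uses one product per period with paired sham/product breath
#' collections for every analyte.
#'
#' @param n_subjects Total number of subjects; must be a multiple of the
#'   number of sequences. Default 32.
#' @param sequences Character vector of product orderings; each must be a
#'   permutation of the product labels. Default `c("ABDC","BCAD","CDBA","DACB")`.
#' @param products Product table as from [default_products()].
#' @param analytes Analyte/collection table as from [evp_analytes()].
#'
#' @return An object of class `study_design`: a list with the validated
#'   components plus `subjects_per_sequence` and a per-subject assignment
#'   table `subjects` (columns `subject_id`, `sequence`).
#' @export
study_design <- function(n_subjects = 32L,
                         sequences = c("ABDC", "BCAD", "CDBA", "DACB"),
                         products = default_products(),
                         analytes = evp_analytes()) {
  n_subjects <- as.integer(n_subjects)
  n_seq <- length(sequences)
  if (n_subjects < n_seq || n_subjects %% n_seq != 0L)
    stop("`n_subjects` must be a positive multiple of the number of sequences")
  if (!all(c("product", "mentholated") %in% names(products)))
    stop("`products` must have columns 'product' and 'mentholated'")
  labels <- sort(products$product)
  for (s in sequences) {
    if (nchar(s) != length(labels) ||
        !identical(sort(strsplit(s, "")[[1]]), labels))
      stop("sequence '", s, "' is not a permutation of the product labels")
  }
  if (anyDuplicated(analytes$analyte))
    stop("each analyte must belong to exactly one collection")
  if (!all(analytes$collection %in% c(1L, 2L)))
    stop("analyte collections must be 1 or 2")

  spp <- n_subjects %/% n_seq
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    sequence = rep(sequences, each = spp),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_subjects = n_subjects, sequences = sequences,
         subjects_per_sequence = spp, products = products,
         analytes = analytes, subjects = subjects),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Crossover study design\n")
  cat("  subjects: ", x$n_subjects, " (", x$subjects_per_sequence,
      " per sequence)\n", sep = "")
  cat("  sequences:", paste(x$sequences, collapse = ", "), "\n")
  cat("  products: ", paste(x$products$product, collapse = ", "), "\n")
  cat("  analytes: ", nrow(x$analytes), "in 2 collections\n")
  invisible(x)
}

# product used by a subject on a given period, from the sequence string
sequence_product <- function(sequence, period) {
  substr(sequence, period, period)
}
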