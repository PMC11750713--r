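#' The 12 ordered substitution classes
#'
#' Every single-nucleotide substitution is one of 12 ordered ref>alt classes
#' (e.g. `"C>T"` and `"G>A"` are distinct classes; strand collapsing is not
#' applied because panel targets are defined on the reference strand).
#'
#' @return Character vector of length 12, e.g. `"A>C"`, `"A>G"`, ...
#' @export
#' @examples
#' substitution_classes()
substitution_classes <- function() {
  bases <- c("A", "C", "G", "T")
  cls <- as.vector(t(outer(bases, bases, function(r, a) paste0(r, ">", a))))
  cls[substr(cls, 1, 1) != substr(cls, 3, 3)]
}

#' Substitution class of a ref/alt pair
#'
#' @param ref,alt Single bases in `A`,`C`,`G`,`T`; `ref != alt`. Vectorized.
#' @return Character vector of class labels (`"ref>alt"`).
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !(ref %in% c("A", "C", "G", "T")) | !(alt %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("ref and alt must be single bases in {A,C,G,T}; offending entries: ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "))
  }
  if (any(ref == alt)) stop("ref and alt must differ (got e.g. ",
                            paste0(ref[ref == alt][1], ">", alt[ref == alt][1]), ")")
  paste0(ref, ">", alt)
}

#' Estimate the 12-class substitution background error model
#'
#' The background error rate of each substitution class is the ratio of the
#' aggregated alt-supporting unique-molecule count to the aggregated total
#' unique-molecule count across a cohort of healthy (tumor-free) plasma
#' samples, floored at `rate_floor` so that downstream Poisson noise means
#' never degenerate to zero.
#'
#' @param background_observations data.frame with columns `class` (one of
#'   [substitution_classes()]), `alt_molecules`, `total_molecules`, and
#'   optionally `sample` (a sample identifier); one row per sample per class.
#' @param rate_floor Minimum reportable per-molecule error rate (> 0).
#' @return An object of class `substitution_error_model`: list with `rates`
#'   (named numeric, 12 classes), `n_background_samples`, `rate_floor`.
#' @export
#' @examples
#' obs <- data.frame(class = substitution_classes(),
#'                   alt_molecules = 5, total_molecules = 1e6)
#' estimate_substitution_error_model(obs)
estimate_substitution_error_model <- function(background_observations,
                                              rate_floor = 1e-8) {
  stopifnot(is.data.frame(background_observations),
            all(c("class", "alt_molecules", "total_molecules") %in%
                  names(background_observations)))
  if (!is.numeric(rate_floor) || length(rate_floor) != 1L || rate_floor <= 0)
    stop("rate_floor must be a single positive number")
  obs <- background_observations
  cls <- substitution_classes()
  unknown <- setdiff(unique(obs$class), cls)
  if (length(unknown))
    stop("unknown substitution class(es): ", paste(unknown, collapse = ", "))
  missing_cls <- setdiff(cls, unique(obs$class))
  if (length(missing_cls))
    stop("no background observations for class(es): ",
         paste(missing_cls, collapse = ", "))
  if (any(obs$alt_molecules < 0) || any(obs$alt_molecules > obs$total_molecules))
    stop("alt_molecules must lie in [0, total_molecules]")

  tot <- tapply(obs$total_molecules, obs$class, sum)[cls]
  alt <- tapply(obs$alt_molecules, obs$class, sum)[cls]
  zero <- names(tot)[tot == 0]
  if (length(zero))
    stop("zero total molecules for class(es): ", paste(zero, collapse = ", "))
  rates <- pmax(as.numeric(alt) / as.numeric(tot), rate_floor)
  names(rates) <- cls
  if (any(rates >= 0.01))
    stop("estimated background rate >= 1% for class(es) ",
         paste(cls[rates >= 0.01], collapse = ", "),
         "; not a plausible consensus-level background")
  n_samples <- if ("sample" %in% names(obs)) {
    length(unique(obs$sample))
  } else {
    max(table(obs$class))
  }
  structure(list(rates = rates,
                 n_background_samples = as.integer(n_samples),
                 rate_floor = rate_floor),
            class = "substitution_error_model")
}

#' Look up per-molecule error rates for ref/alt pairs
#'
#' @param model A `substitution_error_model`.
#' @param ref,alt Base vectors (see [substitution_class()]).
#' @return Numeric vector of per-molecule background error rates.
#' @export
error_rate_for <- function(model, ref, alt) {
  stopifnot(inherits(model, "substitution_error_model"))
  unname(model$rates[substitution_class(ref, alt)])
}

#' @export
print.substitution_error_model <- function(x, ...) {
  cat("Substitution background error model (", x$n_background_samples,
      " background samples, floor ", format(x$rate_floor), ")\n", sep = "")
  print(signif(x$rates, 3))
  invisible(x)
}
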