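#' Build an age-frequency composition from catch records
#'
#' Converts specimen-level catch records into integer age classes, either
#' from recorded ages (`mode = "observed"`) or from total lengths via the
#' inverted VBGF (`mode = "convert"`). Fractional ages are binned by
#' `floor()`, so a shark in its third year belongs to age class 2.
#' Lengths at or above `L_inf` cannot be converted; they are excluded and
#' counted in `n_unconvertible` rather than silently dropped.
#'
#' @param records Data frame of catch records with columns `length_cm` and
#'   optionally `age` (see [read_catch_csv()]).
#' @param g A [growth_params()] object (needed for `mode = "convert"`).
#' @param mode `"convert"` (lengths to ages, default) or `"observed"`.
#' @param t_mat Age at maturity (yr) used to compute the juvenile fraction
#'   (fraction of specimens with age class `< floor(t_mat)`); optional.
#'
#' @return An object of class `age_frequency`: list with `counts` (named
#'   integer vector over age classes), `modal_age`, `juvenile_fraction`,
#'   `n`, `n_unconvertible` and `provenance`.
#' @examples
#' rec <- data.frame(length_cm = c(40, 45, 60))
#' build_age_frequency(rec, growth_params(136.4, 0.077, -3.27))
#' @export
build_age_frequency <- function(records, g = NULL,
                                mode = c("convert", "observed"),
                                t_mat = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records))
  if (mode == "observed") {
    if (is.null(records$age)) stop("records carry no age column")
    ages <- records$age
    ok <- is.finite(ages) & ages >= 0
    provenance <- "observed"
  } else {
    stopifnot(inherits(g, "growth_params"))
    if (is.null(records$length_cm)) stop("records carry no length_cm column")
    ok <- convertible_lengths(records$length_cm, g)
    ages <- rep(NA_real_, nrow(records))
    ages[ok] <- age_at_length(records$length_cm[ok], g)
    ages[ok & ages < 0] <- 0  # lengths below the age-0 mean round up
    ok <- ok & ages >= 0
    provenance <- "length-converted"
  }
  if (!any(ok)) stop("no convertible records")
  cls <- floor(ages[ok])
  tab <- table(factor(cls, levels = seq(min(cls), max(cls))))
  counts <- setNames(as.integer(tab), names(tab))
  modal <- as.integer(names(counts)[which.max(counts)])
  juv <- if (!is.null(t_mat))
    sum(counts[as.integer(names(counts)) < floor(t_mat)]) / sum(counts)
  else NA_real_
  structure(list(counts = counts, modal_age = modal,
                 juvenile_fraction = juv, n = sum(counts),
                 n_unconvertible = sum(!ok), provenance = provenance),
            class = "age_frequency")
}

#' Construct an age frequency from binned counts
#'
#' For compositions that arrive already binned (or for synthetic
#' compositions built in code) rather than as specimen records. Counts may
#' be non-integer (e.g. effort-weighted).
#'
#' @param counts Numeric vector of counts named by integer age class.
#' @param t_mat Optional maturity age for the juvenile fraction.
#' @param provenance Provenance label.
#' @return An `age_frequency` object, as from [build_age_frequency()].
#' @examples
#' age_frequency(c("2" = 100, "3" = 61, "4" = 37))
#' @export
age_frequency <- function(counts, t_mat = NULL, provenance = "binned") {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  ages <- as.integer(names(counts))
  stopifnot(!anyNA(ages))
  counts <- setNames(as.numeric(counts), ages)
  juv <- if (!is.null(t_mat))
    sum(counts[ages < floor(t_mat)]) / sum(counts)
  else NA_real_
  structure(list(counts = counts,
                 modal_age = ages[which.max(counts)],
                 juvenile_fraction = juv, n = sum(counts),
                 n_unconvertible = 0L, provenance = provenance),
            class = "age_frequency")
}

#' @export
print.age_frequency <- function(x, ...) {
  cat("Age frequency (", x$provenance, "), n = ", x$n,
      if (x$n_unconvertible) paste0(" (+", x$n_unconvertible,
                                    " unconvertible)"), "\n", sep = "")
  print(x$counts)
  cat("modal age:", x$modal_age,
      if (is.finite(x$juvenile_fraction))
        sprintf(" juvenile fraction: %.3f", x$juvenile_fraction), "\n")
  invisible(x)
}

new_Z_estimate <- function(method, Z, se = NA_real_, details = list()) {
  structure(c(list(method = method, Z = Z, se = se), details),
            class = "Z_estimate")
}

#' @export
print.Z_estimate <- function(x, ...) {
  cat(sprintf("Z = %.4g /yr (se %.3g) by %s\n", x$Z, x$se, x$method))
  invisible(x)
}

#' Catch-curve estimate of total mortality
#'
#' Ordinary least-squares regression of log numbers-at-age on age over the
#' descending limb of the catch curve; \eqn{Z} is minus the slope. The
#' default limb runs from the modal age (taken as the age of full
#' recruitment to the gear) to the last age class with a count of at least
#' 2; both bounds can be overridden. Zero counts inside the range are
#' dropped with a warning.
#'
#' @param freq An [build_age_frequency()] result.
#' @param start_age,end_age Optional integer bounds of the fitted limb.
#' @return A `Z_estimate` with the regression standard error and the ages
#'   used.
#' @export
catch_curve_Z <- function(freq, start_age = NULL, end_age = NULL) {
  stopifnot(inherits(freq, "age_frequency"))
  ages <- as.integer(names(freq$counts))
  counts <- as.numeric(freq$counts)
  if (is.null(start_age)) start_age <- freq$modal_age
  if (is.null(end_age)) end_age <- max(ages[counts >= 2])
  use <- ages >= start_age & ages <= end_age
  if (any(counts[use] <= 0)) {
    warning("dropping age classes with non-positive counts inside the limb")
    use <- use & counts > 0
  }
  if (sum(use) < 3)
    stop("fewer than 3 usable age classes on the descending limb")
  fit <- lm(log(counts[use]) ~ ages[use])
  Z <- -unname(coef(fit)[2])
  # suppress the "essentially perfect fit" note on noiseless compositions
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  new_Z_estimate("catch_curve_age", Z, se,
                 list(ages_used = ages[use]))
}

#' Beverton & Holt age-based total mortality
#'
#' \eqn{Z = 1 / (\bar t - t')} where \eqn{\bar t} is the mean age of fully
#' recruited fish and \eqn{t'} the age at full recruitment. The mean age is
#' computed over age classes `>= t_prime` using class midpoints
#' (`age + 0.5`) by default, which reduces the discretisation bias of
#' integer binning.
#'
#' @inheritParams catch_curve_Z
#' @param t_prime Age at full recruitment (yr); defaults to the modal age.
#' @param midpoint Use class midpoints for the mean age (default `TRUE`).
#' @return A `Z_estimate`. A mean age at or below `t_prime` is degenerate
#'   and raises an error.
#' @export
bh_Z_age <- function(freq, t_prime = NULL, midpoint = TRUE) {
  stopifnot(inherits(freq, "age_frequency"))
  if (is.null(t_prime)) t_prime <- freq$modal_age
  ages <- as.integer(names(freq$counts))
  use <- ages >= t_prime
  counts <- as.numeric(freq$counts)[use]
  mids <- ages[use] + if (midpoint) 0.5 else 0
  tbar <- sum(mids * counts) / sum(counts)
  if (tbar <= t_prime) stop("mean age at or below t'; Z unbounded")
  new_Z_estimate("bh_age", 1 / (tbar - t_prime), NA_real_,
                 list(t_bar = tbar, t_prime = t_prime))
}

#' Beverton & Holt length-based total mortality
#'
#' \eqn{Z = k (L_\infty - \bar L) / (\bar L - L')} with \eqn{\bar L} the
#' mean length of fish at least as long as `L_prime`, the smallest length
#' at full recruitment.
#'
#' @param records Catch records data frame with `length_cm`.
#' @param g A [growth_params()] object.
#' @param L_prime Smallest fully recruited length (cm).
#' @return A `Z_estimate`.
#' @export
bh_Z_length <- function(records, g, L_prime) {
  stopifnot(inherits(g, "growth_params"), is.data.frame(records))
  L <- records$length_cm[records$length_cm >= L_prime]
  if (!length(L)) stop("no records at or above L_prime")
  Lbar <- mean(L)
  if (Lbar <= L_prime || Lbar >= g$L_inf)
    stop("mean length outside (L_prime, L_inf); Z undefined")
  new_Z_estimate("bh_length", g$k * (g$L_inf - Lbar) / (Lbar - L_prime),
                 NA_real_, list(L_bar = Lbar, L_prime = L_prime))
}

#' Summarise a catch sample
#'
#' Composition report: sample size, length range, modal age (interpreted as
#' the age of fishing recruitment), fraction of the catch at the modal age,
#' juvenile fraction, and sex ratio.
#'
#' @inheritParams bh_Z_length
#' @param t_mat Age at maturity (yr) for the juvenile fraction.
#' @return A list of class `catch_summary`.
#' @export
summarize_catch <- function(records, g = NULL, t_mat = NULL) {
  stopifnot(is.data.frame(records))
  if (!nrow(records))
    return(structure(list(n = 0), class = "catch_summary"))
  freq <- build_age_frequency(records, g, t_mat = t_mat)
  sexes <- if (!is.null(records$sex)) table(records$sex) else NULL
  structure(list(
    n = nrow(records),
    length_range = range(records$length_cm),
    modal_age = freq$modal_age,
    modal_fraction = max(freq$counts) / freq$n,
    juvenile_fraction = freq$juvenile_fraction,
    sex_ratio_F = if (!is.null(sexes) && "F" %in% names(sexes))
      unname(sexes["F"]) / sum(sexes) else NA_real_,
    n_unconvertible = freq$n_unconvertible
  ), class = "catch_summary")
}

#' @export
print.catch_summary <- function(x, ...) {
  if (x$n == 0) { cat("empty catch sample\n"); return(invisible(x)) }
  cat(sprintf("n = %d, lengths %.1f-%.1f cm, modal age %d (%.1f%% of catch)\n",
              x$n, x$length_range[1], x$length_range[2], x$modal_age,
              100 * x$modal_fraction))
  if (is.finite(x$juvenile_fraction))
    cat(sprintf("juvenile fraction: %.1f%%\n", 100 * x$juvenile_fraction))
  if (is.finite(x$sex_ratio_F))
    cat(sprintf("proportion female: %.2f\n", x$sex_ratio_F))
  invisible(x)
}
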