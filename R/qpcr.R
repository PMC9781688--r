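#' Read a Ct measurement table
#'
#' Expects CSV columns `sample_id`, `assay`, `replicate`, `ct`; optional
#' `rna_input_ng` and `dilution_factor`. Undetected reactions may be encoded
#' as `"ND"`, an empty cell, or any Ct at or beyond `max_cycles`; all are
#' normalized to an `undetected` flag with `ct = NA`.
#'
#' @param path Path to the CSV file.
#' @param max_cycles Cycle count of the protocol; Ct values at or beyond it
#'   are treated as below the detection limit. Default 40.
#' @return A tibble with a logical `undetected` column added.
#' @export
read_ct_csv <- function(path, max_cycles = 40) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "assay", "replicate", "ct")
  if (!all(need %in% names(x))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ct_chr <- as.character(x$ct)
  nd <- is.na(ct_chr) | toupper(trimws(ct_chr)) %in% c("ND", "UNDETECTED", "")
  ct <- suppressWarnings(as.numeric(ct_chr))
  nd <- nd | (!is.na(ct) & ct >= max_cycles)
  ct[nd] <- NA_real_
  if (any(!nd & (is.na(ct) | ct <= 0))) {
    stop("Ct values must be positive numbers, 'ND', or empty", call. = FALSE)
  }
  x$ct <- ct
  x$undetected <- nd
  x
}

#' Relative expression by the comparative delta-Ct method
#'
#' For each sample, computes `delta_ct = mean(Ct target) - mean(Ct reference)`
#' across replicates, with the spread propagated as
#' `sqrt(sd_target^2 + sd_reference^2)` (spreads are replicate standard
#' deviations and are labelled as such). A higher delta-Ct means lower
#' expression relative to the reference assay. Undetected replicates (Ct at
#' or beyond the protocol's cycle count, or explicit `ND`) are propagated,
#' never imputed: any undetected replicate in a group renders that group's
#' delta-Ct undefined and the result is flagged.
#'
#' @param data Ct tibble from [read_ct_csv()] or with the same columns
#'   (`sample_id`, `assay`, `replicate`, `ct`; optional logical `undetected`).
#' @param target Assay name of the target transcript.
#' @param reference Assay name of the reference (housekeeping) transcript.
#' @param max_cycles Detection limit in cycles. Default 40.
#' @return A tibble per sample: `sample_id`, `target`, `reference`,
#'   `delta_ct`, `delta_ct_sd`, `n_target`, `n_reference`, `flag`
#'   (`"ok"`, `"target below detection limit"`, or
#'   `"reference below detection limit"`).
#' @export
delta_ct <- function(data, target, reference, max_cycles = 40) {
  if (!"undetected" %in% names(data)) {
    data$undetected <- is.na(data$ct) | data$ct >= max_cycles
    data$ct[data$undetected] <- NA_real_
  }
  grp <- function(df, assay) df[df$assay == assay, , drop = FALSE]
  samples <- unique(data$sample_id)
  purrr::map(samples, function(s) {
    d <- data[data$sample_id == s, , drop = FALSE]
    tg <- grp(d, target)
    rf <- grp(d, reference)
    if (nrow(tg) == 0) stop("no '", target, "' measurements for sample ", s, call. = FALSE)
    if (nrow(rf) == 0) stop("no '", reference, "' measurements for sample ", s, call. = FALSE)
    flag <- if (any(tg$undetected)) "target below detection limit"
            else if (any(rf$undetected)) "reference below detection limit"
            else "ok"
    if (flag == "ok") {
      dct <- mean(tg$ct) - mean(rf$ct)
      sd_t <- if (nrow(tg) > 1) stats::sd(tg$ct) else 0
      sd_r <- if (nrow(rf) > 1) stats::sd(rf$ct) else 0
      dsd <- sqrt(sd_t^2 + sd_r^2)
    } else {
      dct <- NA_real_
      dsd <- NA_real_
    }
    tibble::tibble(sample_id = s, target = target, reference = reference,
                   delta_ct = dct, delta_ct_sd = dsd,
                   n_target = nrow(tg), n_reference = nrow(rf), flag = flag)
  }) |> dplyr::bind_rows()
}

#' Fold difference between two delta-Ct values
#'
#' The comparative (2^-ddCt) form: `2^-(delta_ct_a - delta_ct_b)`. A fold of
#' 0.5 means condition `a` expresses half as much as condition `b`.
#'
#' @param delta_ct_a,delta_ct_b Numeric delta-Ct values (vectorized).
#' @return Fold difference(s), always positive.
#' @export
fold_difference <- function(delta_ct_a, delta_ct_b) {
  if (anyNA(delta_ct_a) || anyNA(delta_ct_b)) {
    stop("fold difference undefined: delta-Ct inputs contain undetected (NA) values",
         call. = FALSE)
  }
  2^(-(delta_ct_a - delta_ct_b))
}

#' Amplification efficiency from a dilution series
#'
#' Fits the standard curve `Ct ~ log10(relative input)` by least squares and
#' converts the slope `m` to percent efficiency `(10^(-1/m) - 1) * 100`: a
#' perfect doubling per cycle gives slope -3.3219 and 100% efficiency.
#'
#' @param dilution_series Tibble/data frame with columns `log10_input` (log10
#'   relative template input) and `ct` (mean Ct at that input); at least 3
#'   points with distinct inputs.
#' @return An object of class `amp_efficiency` with elements `slope`,
#'   `intercept`, `efficiency_percent`, `r_squared`, `n`, `fit` (the `lm`
#'   object). Has [generics::tidy()] and [generics::glance()] methods.
#' @export
amplification_efficiency <- function(dilution_series) {
  need <- c("log10_input", "ct")
  if (!all(need %in% names(dilution_series))) {
    stop("dilution series needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  ds <- dilution_series[stats::complete.cases(dilution_series[need]), , drop = FALSE]
  if (nrow(ds) < 3) stop("need at least 3 dilution points", call. = FALSE)
  if (length(unique(ds$log10_input)) < 2) {
    stop("singular fit: all dilution inputs are identical", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10_input, data = ds)
  slope <- unname(stats::coef(fit)[["log10_input"]])
  structure(
    list(slope = slope,
         intercept = unname(stats::coef(fit)[["(Intercept)"]]),
         efficiency_percent = (10^(-1 / slope) - 1) * 100,
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n = nrow(ds),
         fit = fit),
    class = "amp_efficiency"
  )
}

#' @export
print.amp_efficiency <- function(x, ...) {
  cat(sprintf("<amp_efficiency> slope %.4f, efficiency %.1f%%, R^2 %.4f (n = %d)\n",
              x$slope, x$efficiency_percent, x$r_squared, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the standard-curve coefficients
#'
#' @param x An `amp_efficiency` object.
#' @param ... Unused.
#' @return A tibble with one row per model term: `term`, `estimate`,
#'   `std.error`.
#' @method tidy amp_efficiency
#' @export
tidy.amp_efficiency <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std.error = unname(s[, 2]))
}

#' One-row summary of a standard curve
#'
#' @param x An `amp_efficiency` object.
#' @param ... Unused.
#' @return A tibble: `slope`, `intercept`, `efficiency_percent`, `r_squared`,
#'   `n`.
#' @method glance amp_efficiency
#' @export
glance.amp_efficiency <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 efficiency_percent = x$efficiency_percent,
                 r_squared = x$r_squared, n = x$n)
}
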