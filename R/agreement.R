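# Agreement statistics: modified Bland-Altman against a reference, limits of
# agreement, Lin's concordance correlation coefficient, ordinary least
# squares, and the method-by-method comparison table.

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` using population
#' (n-denominator) moments by default, penalizing both correlation loss and
#' location/scale shift.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param population use n-denominator moments (Lin's original); `FALSE`
#'   uses n-1.
#' @return the coefficient, in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y, population = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  k <- if (population) n else n - 1L
  mx <- mean(x); my <- mean(y)
  sx2 <- sum((x - mx)^2) / k
  sy2 <- sum((y - my)^2) / k
  sxy <- sum((x - mx) * (y - my)) / k
  if (sx2 == 0 && sy2 == 0) stop("both sequences constant: concordance undefined")
  den <- sx2 + sy2 + (mx - my)^2
  2 * sxy / den
}

#' Ordinary least squares line
#'
#' @param x,y numeric vectors; `x` must not be constant.
#' @return `list(slope, intercept)`.
#' @export
regress <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) stop("need >= 2 equal-length pairs")
  if (stats::var(x) == 0) stop("constant x: regression undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]))
}

#' Modified Bland-Altman analysis against a reference
#'
#' Differences are `method - reference` and are plotted/analyzed against the
#' reference (not the pair mean). Reports the bias (mean difference), the SD
#' of the differences (n-1), the 95% limits of agreement
#' (`bias -/+ 1.96 SD`), Lin's concordance coefficient, the least-squares
#' line of method on reference, and a two-sided one-sample t-test of the
#' differences against zero.
#'
#' @param method_values,reference_values numeric vectors of equal length
#'   (>= 2), e.g. infarct fractions in % of LV mass.
#' @param loa_multiplier multiplier for the limits of agreement.
#' @return an object of class `lge_agreement`.
#' @export
bland_altman <- function(method_values, reference_values, loa_multiplier = 1.96) {
  x <- as.numeric(reference_values)
  y <- as.numeric(method_values)
  if (length(x) != length(y)) stop("method and reference must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  p <- if (sd_diff == 0) {
    if (bias == 0) 1 else 0
  } else {
    unname(stats::t.test(d, mu = 0)$p.value)
  }
  ccc <- tryCatch(lin_ccc(x, y), error = function(e) NA_real_)
  reg <- tryCatch(regress(x, y), error = function(e)
    list(slope = NA_real_, intercept = NA_real_))
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - loa_multiplier * sd_diff,
         loa_high = bias + loa_multiplier * sd_diff,
         loa_multiplier = loa_multiplier,
         ccc = ccc, slope = reg$slope, intercept = reg$intercept,
         p_value = p, n = length(x), differences = d, reference = x,
         method = y),
    class = "lge_agreement"
  )
}

#' @export
print.lge_agreement <- function(x, ...) {
  cat(sprintf("<lge_agreement> n = %d\n", x$n))
  cat(sprintf("  bias %.3f +- %.3f, LoA [%.3f, %.3f], p = %.3g%s\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$p_value,
              if (is.finite(x$p_value) && x$p_value < 0.05) " *" else ""))
  cat(sprintf("  CCC %.3f, fit y = %.2fx %+.2f\n", x$ccc, x$slope, x$intercept))
  invisible(x)
}

#' Bland-Altman plot (difference vs reference)
#'
#' @param x an `lge_agreement`.
#' @param xlab,ylab,main usual graphics labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot.lge_agreement <- function(x, xlab = "Reference infarct size (% LV)",
                               ylab = "Method - reference (%-pts LV)",
                               main = NULL, ...) {
  graphics::plot(x$reference, x$differences, xlab = xlab, ylab = ylab,
                 main = main, pch = 19, ...)
  graphics::abline(h = x$bias, lwd = 2)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

methods_for_convention <- function(convention) {
  all <- c("ewa", "heiberg08", "fwhm", "2sd", "3sd", "5sd", "6sd", "otsu", "fact")
  all
}

not_designed_for <- function(method, convention) {
  convention == "PSIR" && method %in% c("heiberg08", "fwhm")
}

#' Compare quantification methods over a set of phantom cases
#'
#' Runs each method on each case (using the case's contours and auto-drawn
#' ROIs), takes the phantom ground truth as the reference, and tabulates the
#' agreement statistics per method -- one row per method, with CCC, the
#' regression line, bias, SD, limits of agreement and the bias p-value.
#' Methods not designed for the case convention (Heiberg-08 and zero-anchored
#' FWHM on PSIR) are flagged `not designed` and left unevaluated.
#'
#' @param cases list of [phantom_case] objects (>= 2), all with the same
#'   signal convention.
#' @param methods method names as in [quantify_infarct()].
#' @param csv optional path to write the table as CSV.
#' @param ... passed to [quantify_infarct()].
#' @return a `data.frame`, one row per method; fractions are attached as the
#'   `"fractions"` attribute (methods x cases), the truth as `"reference"`.
#' @export
compare_all <- function(cases, methods = methods_for_convention(NULL),
                        csv = NULL, ...) {
  if (length(cases) < 2L) stop("need at least 2 cases")
  conv <- unique(vapply(cases, function(cs) cs$stack$convention, ""))
  if (length(conv) != 1L) stop("cases mix IR and PSIR conventions")
  truth <- vapply(cases, function(cs) cs$truth_fraction_pct, 0)
  frac <- matrix(NA_real_, length(methods), length(cases),
                 dimnames = list(methods, NULL))
  rows <- lapply(methods, function(m) {
    if (not_designed_for(m, conv)) {
      return(data.frame(method = m, convention = conv, n = length(cases),
                        ccc = NA, slope = NA, intercept = NA, bias = NA,
                        sd = NA, loa_low = NA, loa_high = NA, p_value = NA,
                        note = "not designed", stringsAsFactors = FALSE))
    }
    f <- vapply(cases, function(cs) {
      quantify_infarct(cs$stack, cs$contours, cs$rois, method = m,
                       mask = cs$mask, ...)$fraction_pct
    }, 0)
    frac[m, ] <<- f
    ba <- bland_altman(f, truth)
    data.frame(method = m, convention = conv, n = length(cases),
               ccc = ba$ccc, slope = ba$slope, intercept = ba$intercept,
               bias = ba$bias, sd = ba$sd_diff, loa_low = ba$loa_low,
               loa_high = ba$loa_high, p_value = ba$p_value, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fractions") <- frac
  attr(out, "reference") <- truth
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
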