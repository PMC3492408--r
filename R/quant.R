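#' Specific binding from paired densitometry records
#'
#' Specific probe binding of a lane/band is the streptavidin fluorescence
#' (800 nm) normalised to total-protein stain (700 nm), with the
#' ATP-competed lane subtracted as the non-specific estimate:
#' \deqn{(F_{800}/F_{700})_{noATP} - (F_{800}/F_{700})_{ATP}}
#'
#' A negative value (competed signal exceeding uncompeted) is returned
#' as-is with a warning rather than clamped, so anomalies remain visible.
#'
#' @param noatp,atp Each a list/one-row data frame with \code{F800} and
#'   \code{F700} for the uncompeted and ATP-competed measurement of the
#'   same band.
#' @return Specific binding value (dimensionless ratio difference).
#' @export
#' @examples
#' specific_signal(list(F800 = 800, F700 = 400), list(F800 = 200, F700 = 400))
specific_signal <- function(noatp, atp) {
  grab <- function(x, nm) {
    v <- x[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop("specific_signal(): missing ", nm, call. = FALSE)
    }
    as.numeric(v)
  }
  f700a <- grab(noatp, "F700"); f700b <- grab(atp, "F700")
  if (f700a <= 0 || f700b <= 0) {
    stop("specific_signal(): F700 must be positive", call. = FALSE)
  }
  val <- grab(noatp, "F800") / f700a - grab(atp, "F800") / f700b
  if (val < 0) {
    warning("specific_signal(): negative specific binding (",
            signif(val, 3), "): competed signal exceeds uncompeted",
            call. = FALSE)
  }
  val
}

#' Normalise a competition series to fractional binding
#'
#' Applies \eqn{y = (F - F_0) / F_{max}} per record, where \eqn{F} is the
#' probe signal, \eqn{F_0} a background signal and \eqn{F_{max}} the
#' signal with no competitor added.
#'
#' @param records Tibble with \code{atp_mM} and signal column \code{F}
#'   (optionally \code{replicate}).
#' @param f0 Background signal; default: the minimum observed signal
#'   (the most-competed lane), overridable since background definition is
#'   assay-dependent.
#' @param fmax Saturating signal; default: mean signal of the
#'   \code{atp_mM == 0} records (must then be present).
#' @return Tibble \code{atp_mM}, \code{y}, \code{replicate}.
#' @export
normalize_curve <- function(records, f0 = NULL, fmax = NULL) {
  stopifnot(all(c("atp_mM", "F") %in% names(records)))
  if (any(records$atp_mM < 0)) stop("normalize_curve(): negative concentration",
                                    call. = FALSE)
  if (is.null(f0)) f0 <- min(records$F)
  if (is.null(fmax)) {
    if (!any(records$atp_mM == 0)) {
      stop("normalize_curve(): no atp_mM == 0 record to define fmax",
           call. = FALSE)
    }
    fmax <- mean(records$F[records$atp_mM == 0])
  }
  if (fmax <= 0) stop("normalize_curve(): fmax must be positive", call. = FALSE)
  tibble::tibble(
    atp_mM = records$atp_mM,
    y = (records$F - f0) / fmax,
    replicate = if ("replicate" %in% names(records)) records$replicate else 1L
  )
}

#' Fit a one-site competition-binding IC50
#'
#' Unweighted least-squares fit of the one-site competition model
#' \deqn{y = 1 / (1 + (c / IC_{50})^h)}
#' to a normalised concentration-response curve, by Levenberg-Marquardt.
#' The Hill slope \eqn{h} is fixed at 1 by default (normalised data on
#' [0, 1], single class of sites); \code{hill = "free"} fits it. The
#' starting IC50 is the geometric mean of the non-zero concentrations, so
#' the fit is deterministic given the data.
#'
#' @param curve Tibble with \code{atp_mM} and \code{y} (e.g. from
#'   [normalize_curve()] or [simulate_curve()]); replicate rows are simply
#'   pooled.
#' @param hill \code{"fixed"} (h = 1) or \code{"free"}.
#' @return Object of class \code{ic50_fit}: list with \code{ic50_mM},
#'   \code{se}, \code{hill}, \code{hill_se}, \code{rss}, \code{n_points},
#'   \code{fit} (the underlying \code{nls} object).
#' @export
#' @examples
#' cc <- tibble::tibble(atp_mM = 10^seq(-2, 1, length.out = 8))
#' cc$y <- 1 / (1 + cc$atp_mM / 2)
#' fit_ic50(cc)
fit_ic50 <- function(curve, hill = c("fixed", "free")) {
  hill <- match.arg(hill)
  stopifnot(all(c("atp_mM", "y") %in% names(curve)))
  d <- tibble::tibble(c = curve$atp_mM, y = curve$y)
  if (any(!is.finite(d$y)) || any(d$c < 0)) {
    stop("fit_ic50(): non-finite response or negative concentration",
         call. = FALSE)
  }
  nz <- unique(d$c[d$c > 0])
  if (length(nz) < 4L) {
    stop("fit_ic50(): need >= 4 distinct non-zero concentrations, have ",
         length(nz), call. = FALSE)
  }
  if (diff(range(d$y)) < 0.1) {
    stop("fit_ic50(): degenerate flat curve (response range ",
         signif(diff(range(d$y)), 2), ")", call. = FALSE)
  }
  start_ic50 <- exp(mean(log(nz)))
  fit <- tryCatch({
    if (hill == "fixed") {
      minpack.lm::nlsLM(y ~ 1 / (1 + c / ic50), data = d,
                        start = list(ic50 = start_ic50),
                        lower = c(ic50 = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ 1 / (1 + (c / ic50)^h), data = d,
                        start = list(ic50 = start_ic50, h = 1),
                        lower = c(ic50 = 1e-9, h = 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) {
    stop("fit_ic50(): nonlinear fit failed to converge: ",
         conditionMessage(e), "\n  n = ", nrow(d), " points, start IC50 = ",
         signif(start_ic50, 4), " mM", call. = FALSE)
  })
  sm <- summary(fit)$coefficients
  structure(
    list(
      ic50_mM = unname(sm["ic50", "Estimate"]),
      se = unname(sm["ic50", "Std. Error"]),
      hill = if (hill == "fixed") 1 else unname(sm["h", "Estimate"]),
      hill_se = if (hill == "fixed") NA_real_ else unname(sm["h", "Std. Error"]),
      hill_mode = hill,
      rss = sum(stats::residuals(fit)^2),
      n_points = nrow(d),
      fit = fit,
      data = d
    ),
    class = "ic50_fit"
  )
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat("<ic50_fit> one-site competition model, Hill slope ",
      if (x$hill_mode == "fixed") "fixed at 1" else
        paste0("fitted = ", signif(x$hill, 3)), "\n", sep = "")
  cat("  IC50 = ", signif(x$ic50_mM, 3), " +/- ", signif(x$se, 2),
      " mM  (", x$n_points, " points, RSS = ", signif(x$rss, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Tidy an IC50 fit
#' @param x An \code{ic50_fit}.
#' @param ... Unused.
#' @return Tibble of terms with estimates and standard errors.
#' @method tidy ic50_fit
#' @export
tidy.ic50_fit <- function(x, ...) {
  out <- tibble::tibble(term = "ic50_mM", estimate = x$ic50_mM,
                        std.error = x$se)
  if (x$hill_mode == "free") {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "hill", estimate = x$hill, std.error = x$hill_se))
  }
  out
}

#' One-row summary of an IC50 fit
#' @param x An \code{ic50_fit}.
#' @param ... Unused.
#' @return Tibble with \code{ic50_mM}, \code{se}, \code{hill}, \code{rss},
#'   \code{n_points}.
#' @method glance ic50_fit
#' @export
glance.ic50_fit <- function(x, ...) {
  tibble::tibble(ic50_mM = x$ic50_mM, se = x$se, hill = x$hill,
                 rss = x$rss, n_points = x$n_points)
}

#' Plot a competition curve with its fitted model
#'
#' @param object An \code{ic50_fit}.
#' @param ... Unused.
#' @return A ggplot: points on a log concentration axis, fitted one-site
#'   curve, dashed reference at the fitted IC50.
#' @method autoplot ic50_fit
#' @export
autoplot.ic50_fit <- function(object, ...) {
  d <- object$data[object$data$c > 0, ]
  grid <- tibble::tibble(c = exp(seq(log(min(d$c)), log(max(d$c)),
                                     length.out = 200)))
  grid$y <- 1 / (1 + (grid$c / object$ic50_mM)^object$hill)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$c, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$ic50_mM, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[ATP] (mM)", y = "normalised binding y",
                  title = sprintf("IC50 = %.3g ± %.2g mM",
                                  object$ic50_mM, object$se)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
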