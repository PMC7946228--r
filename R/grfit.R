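#' Growth-rate-corrected response (GR) transform
#'
#' \code{GR = 2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1}: the ratio of
#' treated to control growth rates over the assay window, mapped so that 1
#' means untreated growth, 0 cytostasis and values down to -1 net cell
#' loss. Unlike relative viability, GR does not conflate slow growth with
#' drug effect, so potency estimates are comparable between fast- and
#' slow-growing cell lines.
#'
#' @param x0 baseline cell measure (> 0)
#' @param x_ctrl vehicle endpoint measure (must exceed \code{x0}: GR is
#'   undefined without control growth)
#' @param x_c treated endpoint measure (> 0)
#' @return GR value(s) in \code{(-1, Inf)}
#' @export
gr_transform <- function(x0, x_ctrl, x_c) {
  stopifnot(all(x0 > 0), all(x_c > 0))
  if (any(x_ctrl <= x0)) {
    stop("GR undefined: control endpoint does not exceed baseline")
  }
  2^(log2(x_c / x0) / log2(x_ctrl / x0)) - 1
}

# internal: GR 4PL with upper asymptote fixed at 1
.gr_curve <- function(conc, gr_inf, gec50, hill) {
  gr_inf + (1 - gr_inf) / (1 + (conc / gec50)^hill)
}

#' Fit a four-parameter log-logistic GR dose-response curve
#'
#' Least-squares fit of \code{GR(c) = GRinf + (1 - GRinf) / (1 +
#' (c / GEC50)^h)} with bounds \code{GRinf} in \code{[-1, 1]}, \code{h} in
#' \code{[0.1, 5]} and \code{GEC50} within two decades of the tested
#' range, using bounded Levenberg-Marquardt with multi-start over a
#' log-spaced GEC50 grid. Replicate observations enter the loss jointly.
#' The sigmoid is compared with the flat (constant-GR) model by an F-test;
#' when the sigmoid is not significantly better at \code{alpha_flat} the
#' fit is flagged non-converged, the asymptotes collapse to the mean GR
#' and GR50 is the \code{Inf} sentinel.
#'
#' @param concentrations dose vector in nM (> 0); >= 4 distinct values
#' @param gr observed GR values, same length
#' @param alpha_flat significance level of the flat-model F-test
#'   (default 0.05)
#' @return object of class \code{gr_fit}: list with \code{gr_inf, gec50,
#'   hill, gr50, converged, residual}
#' @export
fit_gr_curve <- function(concentrations, gr, alpha_flat = 0.05) {
  stopifnot(length(concentrations) == length(gr), all(concentrations > 0))
  .check_finite(gr, "GR values")
  if (length(unique(concentrations)) < 4) {
    stop("need at least 4 distinct concentrations")
  }
  n <- length(gr)
  lo_g <- min(concentrations) / 100
  hi_g <- max(concentrations) * 100
  # starts stay inside the tested range: outside it the sigmoid is flat in
  # GEC50 and the Jacobian singular
  g_starts <- 10^seq(log10(min(concentrations)), log10(max(concentrations)),
                     length.out = 9)
  lower <- c(gr_inf = -1, lgec50 = log10(lo_g), hill = 0.1)
  upper <- c(gr_inf = 1, lgec50 = log10(hi_g), hill = 5)
  d <- data.frame(conc = concentrations, gr = gr)
  gi0 <- max(-1, min(1, min(gr)))
  best <- NULL
  for (g0 in g_starts) {
    for (h0 in c(0.5, 1, 2)) {
      st <- c(gr_inf = gi0, lgec50 = log10(g0), hill = h0)
      fit <- tryCatch(
        minpack.lm::nlsLM(
          gr ~ gr_inf + (1 - gr_inf) / (1 + (conc / 10^lgec50)^hill),
          data = d, start = as.list(st), lower = lower, upper = upper,
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        sse <- sum(stats::residuals(fit)^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(coef = stats::coef(fit), sse = sse)
        }
      }
    }
  }
  mean_gr <- mean(gr)
  sse_flat <- sum((gr - mean_gr)^2)
  flat_fit <- function() {
    structure(list(gr_inf = mean_gr, gec50 = NA_real_, hill = NA_real_,
                   gr50 = Inf, converged = FALSE, residual = sse_flat),
              class = "gr_fit")
  }
  if (is.null(best)) return(flat_fit())
  # F-test: does the 3-parameter sigmoid beat the 1-parameter flat model?
  df2 <- n - 3
  if (df2 > 0 && best$sse < sse_flat) {
    fstat <- ((sse_flat - best$sse) / 2) / max(best$sse / df2, 1e-300)
    p_flat <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  } else {
    p_flat <- 1
  }
  if (p_flat >= alpha_flat) return(flat_fit())
  co <- best$coef
  out <- structure(list(gr_inf = unname(co["gr_inf"]),
                        gec50 = unname(10^co["lgec50"]),
                        hill = unname(co["hill"]),
                        gr50 = NA_real_, converged = TRUE,
                        residual = best$sse),
                   class = "gr_fit")
  out$gr50 <- gr50_from_fit(out)
  out
}

#' GR50: concentration at which the fitted GR curve crosses 0.5
#'
#' Solved analytically from the fitted parameters:
#' \code{GR50 = GEC50 * ((1 - GRinf) / (0.5 - GRinf) - 1)^(1 / h)}. When
#' the lower asymptote does not fall below 0.5 the curve never crosses it
#' and the \code{Inf} sentinel is returned (reported downstream as
#' "> max tested concentration" rather than extrapolated).
#'
#' @param fit a \code{gr_fit}
#' @return concentration in nM, or \code{Inf}
#' @export
gr50_from_fit <- function(fit) {
  stopifnot(inherits(fit, "gr_fit"))
  if (!fit$converged || fit$gr_inf >= 0.5) return(Inf)
  fit$gec50 * ((1 - fit$gr_inf) / (0.5 - fit$gr_inf) - 1)^(1 / fit$hill)
}

#' Evaluate a fitted GR curve
#'
#' @param object a \code{gr_fit}
#' @param conc concentrations (nM)
#' @param ... unused
#' @return predicted GR values
#' @export
predict.gr_fit <- function(object, conc, ...) {
  if (!object$converged) return(rep(object$gr_inf, length(conc)))
  .gr_curve(conc, object$gr_inf, object$gec50, object$hill)
}

#' @export
print.gr_fit <- function(x, ...) {
  cat("GR dose-response fit\n")
  cat(sprintf("  GRinf = %.4f  GEC50 = %s nM  h = %s\n", x$gr_inf,
              format(x$gec50, digits = 4), format(x$hill, digits = 4)))
  cat(sprintf("  GR50 = %s nM  converged = %s  SSE = %.3g\n",
              format(x$gr50, digits = 4), x$converged, x$residual))
  invisible(x)
}

#' Fit GR curves for every cell line x compound in a GR-assay table
#'
#' Accepts either raw endpoint counts (\code{x0, x_ctrl, x_c}) — which are
#' GR-transformed first — or a pre-transformed \code{gr} column.
#'
#' @param assay data.frame with \code{cell_line, compound,
#'   concentration_nM} and either counts or \code{gr}
#' @param alpha_flat flat-model test level (default 0.05)
#' @return data.frame: \code{cell_line, compound, gr_inf, gec50_nM, hill,
#'   gr50_nM, converged, residual}
#' @export
fit_gr_table <- function(assay, alpha_flat = 0.05) {
  if (!"gr" %in% names(assay)) {
    assay$gr <- gr_transform(assay$x0, assay$x_ctrl, assay$x_c)
  }
  key <- interaction(assay$cell_line, assay$compound, drop = TRUE)
  rows <- lapply(split(assay, key), function(g) {
    f <- fit_gr_curve(g$concentration_nM, g$gr, alpha_flat = alpha_flat)
    data.frame(cell_line = g$cell_line[1], compound = g$compound[1],
               gr_inf = f$gr_inf, gec50_nM = f$gec50, hill = f$hill,
               gr50_nM = f$gr50, converged = f$converged,
               residual = f$residual, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
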