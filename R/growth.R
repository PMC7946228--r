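#' Confluence change over a time window
#'
#' Confluence at \code{t1} minus confluence at \code{t0}, with linear
#' interpolation between adjacent samples (sampling is typically every 3 h
#' while windows start at 40 h). Duplicated sample rows are averaged, so
#' the result is invariant to row duplication and ordering.
#'
#' @param series data.frame for one condition with \code{time_h} and
#'   \code{confluence_pct}
#' @param t0,t1 window endpoints in hours; must lie within the series span
#' @return change in percentage points of confluence
#' @export
window_delta <- function(series, t0, t1) {
  stopifnot(all(c("time_h", "confluence_pct") %in% names(series)), t1 > t0)
  v <- stats::approx(series$time_h, series$confluence_pct, xout = c(t0, t1),
                     ties = mean, rule = 1)$y
  if (anyNA(v)) {
    stop(sprintf("window [%g, %g] h lies outside the sampled span [%g, %g] h",
                 t0, t1, min(series$time_h), max(series$time_h)))
  }
  v[2] - v[1]
}

# internal: per (concentration, replicate) window deltas for one
# cell line x compound group
.window_deltas <- function(curves, t0, t1) {
  key <- interaction(curves$concentration_nM, curves$replicate, drop = TRUE)
  parts <- split(curves, key)
  data.frame(
    concentration_nM = vapply(parts, function(g) g$concentration_nM[1],
                              numeric(1)),
    replicate = vapply(parts, function(g) g$replicate[1], numeric(1)),
    delta = vapply(parts, window_delta, numeric(1), t0 = t0, t1 = t1),
    row.names = NULL)
}

#' Lowest concentration significantly reducing growth in the 40-72 h window
#'
#' Fits a one-way linear model of the 40-72 h confluence change on
#' concentration group and forms least-square-mean contrasts of each dose
#' against vehicle (one-sided for a decrease, Holm-adjusted). Returns the
#' lowest concentration with adjusted p below \code{alpha}, or NA when no
#' dose qualifies. With replicate-identical (noise-free) data the residual
#' variance vanishes and the t statistics are undefined; the call then
#' falls back to an exact comparison of group means.
#'
#' @param curves long confluence data.frame for one cell line x compound,
#'   with a vehicle arm (\code{concentration_nM == 0}) and >= 2 replicates
#'   per concentration
#' @param alpha significance level (default 0.05)
#' @param window two-element window in hours (default \code{c(40, 72)})
#' @return concentration in nM, or NA
#' @export
growth_reducing_concentration <- function(curves, alpha = 0.05,
                                          window = c(40, 72)) {
  if (!any(curves$concentration_nM == 0)) {
    stop("vehicle (0 nM) series are required")
  }
  d <- .window_deltas(curves, window[1], window[2])
  reps <- table(d$concentration_nM)
  if (any(reps < 2)) stop("need >= 2 replicates per concentration")
  doses <- sort(unique(d$concentration_nM[d$concentration_nM > 0]))
  d$grp <- factor(d$concentration_nM, levels = c(0, doses))
  fit <- stats::lm(delta ~ grp, data = d)
  if (stats::sigma(fit) < 1e-8) {
    mu <- tapply(d$delta, d$grp, mean)
    sig <- mu[-1] < mu[1] - 1e-9
  } else {
    emm <- emmeans::emmeans(fit, "grp")
    ct <- emmeans::contrast(emm, method = "trt.vs.ctrl", ref = 1)
    s <- summary(ct, adjust = "holm", side = "<")
    sig <- s$p.value < alpha
  }
  if (!any(sig)) return(NA_real_)
  doses[which(sig)[1]]
}

#' Minimal growth-arresting concentration from the 96-120 h window
#'
#' Per concentration, takes the median across replicates of the 96-120 h
#' confluence change and returns the minimal concentration whose median
#' change is below \code{delta_max} percentage points (default 3), the
#' operational definition of stable growth arrest. NA when no
#' concentration qualifies.
#'
#' @param curves long confluence data.frame for one cell line x compound
#' @param delta_max arrest threshold in percentage points (default 3)
#' @param window two-element window in hours (default \code{c(96, 120)})
#' @return concentration in nM, or NA
#' @export
growth_arresting_concentration <- function(curves, delta_max = 3,
                                           window = c(96, 120)) {
  d <- .window_deltas(curves, window[1], window[2])
  d <- d[d$concentration_nM > 0, , drop = FALSE]
  if (nrow(d) == 0) stop("no drug-treated series supplied")
  med <- tapply(d$delta, d$concentration_nM, stats::median)
  doses <- as.numeric(names(med))
  ord <- order(doses)
  qual <- med[ord] < delta_max
  if (!any(qual)) return(NA_real_)
  doses[ord][which(qual)[1]]
}

#' Classify reversibility of growth arrest after drug withdrawal
#'
#' Reversible when the (replicate-median) confluence gain over the 72 h
#' following withdrawal reaches \code{min_regrowth} percentage points
#' (default 3, mirroring the arrest criterion); irreversible otherwise.
#'
#' @param curves long confluence data.frame for one condition, with a
#'   \code{withdrawal_at} column or the \code{withdrawal_at} argument set;
#'   must extend >= 72 h past withdrawal
#' @param min_regrowth regrowth threshold in percentage points (default 3)
#' @param withdrawal_at withdrawal time in hours (default: taken from the
#'   data)
#' @return logical flag
#' @export
classify_reversibility <- function(curves, min_regrowth = 3,
                                   withdrawal_at = NULL) {
  if (is.null(withdrawal_at)) {
    withdrawal_at <- unique(curves$withdrawal_at[!is.na(curves$withdrawal_at)])
    if (length(withdrawal_at) != 1) {
      stop("withdrawal time missing or ambiguous")
    }
  }
  if (max(curves$time_h) < withdrawal_at + 72) {
    stop("series must extend at least 72 h past withdrawal")
  }
  d <- .window_deltas(curves, withdrawal_at, withdrawal_at + 72)
  stats::median(d$delta) >= min_regrowth
}

#' Categorize an apoptotic-fraction increase
#'
#' Percentage-point increase of the apoptotic fraction over matched
#' vehicle control: above 15 is strong, above 5 (and at most 15) moderate,
#' otherwise none. Boundaries are strict.
#'
#' @param apoptotic_increase_pct numeric vector of percentage-point
#'   increases
#' @return factor with levels \code{none < moderate < strong}
#' @export
classify_apoptosis <- function(apoptotic_increase_pct) {
  out <- ifelse(apoptotic_increase_pct > 15, "strong",
                ifelse(apoptotic_increase_pct > 5, "moderate", "none"))
  factor(out, levels = c("none", "moderate", "strong"), ordered = TRUE)
}

#' Keep conditions with a meaningful cell-cycle phase shift
#'
#' Retains rows whose largest phase increase (\code{G1}, \code{S},
#' \code{G2} columns, percentage points vs control) exceeds 5.
#'
#' @param summaries data.frame with columns \code{G1, S, G2}
#' @return filtered data.frame (possibly empty)
#' @export
cell_cycle_shift_filter <- function(summaries) {
  stopifnot(all(c("G1", "S", "G2") %in% names(summaries)))
  if (nrow(summaries) == 0) return(summaries)
  mx <- pmax(summaries$G1, summaries$S, summaries$G2)
  summaries[mx > 5, , drop = FALSE]
}

#' Kinetic concentration calls for every cell line x compound
#'
#' Applies \code{\link{growth_reducing_concentration}} and
#' \code{\link{growth_arresting_concentration}} per group, plus
#' \code{\link{classify_reversibility}} when withdrawal data are present.
#'
#' @param curves long confluence data.frame covering one or more cell
#'   line x compound groups
#' @param alpha significance level for the growth-reduction contrast
#' @param arrest_delta arrest threshold (percentage points)
#' @param regrowth_delta reversibility threshold (percentage points)
#' @return data.frame: one row per group with both concentrations and the
#'   reversibility flag (NA when no withdrawal arm exists)
#' @export
kinetic_calls <- function(curves, alpha = 0.05, arrest_delta = 3,
                          regrowth_delta = 3) {
  key <- interaction(curves$cell_line, curves$compound, drop = TRUE)
  rows <- lapply(split(curves, key), function(g) {
    red <- growth_reducing_concentration(g, alpha = alpha)
    arr <- growth_arresting_concentration(g, delta_max = arrest_delta)
    rev_flag <- NA
    has_wd <- "withdrawal_at" %in% names(g) && any(!is.na(g$withdrawal_at))
    if (has_wd && !is.na(arr)) {
      ga <- g[g$concentration_nM == arr, , drop = FALSE]
      if (nrow(ga) > 0) {
        rev_flag <- tryCatch(
          classify_reversibility(ga, min_regrowth = regrowth_delta),
          error = function(e) NA)
      }
    }
    data.frame(cell_line = g$cell_line[1], compound = g$compound[1],
               growth_reducing_conc = red, growth_arresting_conc = arr,
               reversible = rev_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
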