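#' Normalize raw plate signals to plate controls
#'
#' Per plate, computes the median positive-control (BzCl, full kill) and
#' median negative-control (DMSO, no effect) signal and normalizes every
#' well as \code{(signal - median_pos) / (median_neg - median_pos)}.
#' Values may transiently exceed \code{[0, 1]}; clipping happens only in
#' the constrained smoothing step so plate QC can see over-unity wells.
#'
#' @param wells plate wells data.frame with at least \code{plate_id, role,
#'   signal}
#' @return the input with a \code{viability} column appended
#' @export
normalize_plate <- function(wells) {
  stopifnot(all(c("plate_id", "role", "signal") %in% names(wells)))
  out <- vector("list", length(unique(wells$plate_id)))
  i <- 0L
  for (pid in unique(wells$plate_id)) {
    w <- wells[wells$plate_id == pid, , drop = FALSE]
    neg <- w$signal[w$role == "neg_ctrl"]
    pos <- w$signal[w$role == "pos_ctrl"]
    if (length(neg) < 2 || length(pos) < 2) {
      stop(sprintf("plate %s needs at least 2 wells of each control role", pid))
    }
    m_neg <- stats::median(neg)
    m_pos <- stats::median(pos)
    if (m_neg == m_pos) {
      stop(sprintf("plate %s fails QC: control medians are equal", pid))
    }
    w$viability <- (w$signal - m_pos) / (m_neg - m_pos)
    i <- i + 1L
    out[[i]] <- w
  }
  do.call(rbind, out)
}

#' z'-factor of a plate's control separation
#'
#' \code{1 - 3 (sd_pos + sd_neg) / |mu_neg - mu_pos|} with sample SDs.
#' At most 1; equals 1 only in the zero-variance limit. Values above 0.5
#' conventionally indicate an acceptable assay window.
#'
#' @param pos_signals,neg_signals control signal vectors (length >= 2)
#' @return dimensionless score
#' @export
zprime <- function(pos_signals, neg_signals) {
  stopifnot(length(pos_signals) >= 2, length(neg_signals) >= 2)
  mu_p <- mean(pos_signals); mu_n <- mean(neg_signals)
  if (mu_p == mu_n) stop("z'-factor undefined: control means are equal")
  1 - 3 * (stats::sd(pos_signals) + stats::sd(neg_signals)) / abs(mu_n - mu_p)
}

#' Strictly standardized mean difference (SSMD) of plate controls
#'
#' \code{(mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2)}; a strong kill
#' control sitting far below the negative control yields a large negative
#' beta. \code{|beta| >= 3} marks strong separation.
#'
#' @param pos_signals,neg_signals control signal vectors (length >= 2)
#' @return dimensionless score
#' @export
ssmd <- function(pos_signals, neg_signals) {
  stopifnot(length(pos_signals) >= 2, length(neg_signals) >= 2)
  s2 <- stats::var(pos_signals) + stats::var(neg_signals)
  if (s2 == 0) stop("SSMD undefined: both control groups have zero variance")
  (mean(pos_signals) - mean(neg_signals)) / sqrt(s2)
}

#' Per-plate quality-control summary
#'
#' @param wells plate wells data.frame
#' @return data.frame with one row per plate: control moments, z'-factor,
#'   SSMD and pass flags (\code{z' > 0.5}, \code{|SSMD| >= 3})
#' @export
plate_qc <- function(wells) {
  rows <- lapply(unique(wells$plate_id), function(pid) {
    w <- wells[wells$plate_id == pid, , drop = FALSE]
    neg <- w$signal[w$role == "neg_ctrl"]
    pos <- w$signal[w$role == "pos_ctrl"]
    zp <- tryCatch(zprime(pos, neg), error = function(e) NA_real_)
    b <- tryCatch(ssmd(pos, neg), error = function(e) NA_real_)
    data.frame(plate_id = pid,
               mu_neg = mean(neg), sd_neg = stats::sd(neg),
               mu_pos = mean(pos), sd_pos = stats::sd(pos),
               z_prime = zp, ssmd = b,
               pass_zprime = isTRUE(zp > 0.5),
               pass_ssmd = isTRUE(abs(b) >= 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# internal: L1-optimal isotonic (non-decreasing) fit via pool-adjacent-
# violators with block medians
.pav_l1_isotonic <- function(y) {
  n <- length(y)
  blocks <- vector("list", n)
  medv <- numeric(n)
  lens <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    blocks[[nb]] <- y[i]
    medv[nb] <- y[i]
    lens[nb] <- 1L
    while (nb > 1L && medv[nb] < medv[nb - 1L]) {
      blocks[[nb - 1L]] <- c(blocks[[nb - 1L]], blocks[[nb]])
      lens[nb - 1L] <- lens[nb - 1L] + lens[nb]
      nb <- nb - 1L
      medv[nb] <- stats::median(blocks[[nb]])
    }
  }
  rep(medv[seq_len(nb)], lens[seq_len(nb)])
}

#' Qualitatively constrained smoothing of a viability profile
#'
#' Projects raw normalized viabilities onto the closest (least absolute
#' deviation) curve that is non-increasing in concentration and bounded in
#' \code{[0, 1]} — the limiting behaviour of a median-quantile monotone
#' smoothing spline when the number of support points is small and the
#' roughness penalty negligible. Implemented as pool-adjacent-violators
#' antitonic regression with block medians followed by clipping (which
#' preserves L1 optimality for this separable convex problem). Inputs that
#' already satisfy both constraints are returned unchanged; the operation
#' is idempotent.
#'
#' @param viability_raw raw normalized viabilities (length >= 3)
#' @param concentrations strictly ascending concentrations (nM), same length
#' @return non-increasing viabilities in \code{[0, 1]}
#' @export
smooth_profile <- function(viability_raw, concentrations) {
  if (length(viability_raw) < 3) {
    stop("smoothing needs at least 3 concentrations")
  }
  stopifnot(length(viability_raw) == length(concentrations))
  .check_ascending(concentrations)
  .check_finite(viability_raw, "viabilities")
  fit <- rev(.pav_l1_isotonic(rev(viability_raw)))
  pmin(1, pmax(0, fit))
}

#' Combined-viability score: area under the log-dose viability curve
#'
#' Trapezoidal integral of viability over log10 concentration. With the
#' standard five 10-fold concentrations (1 nM to 10 uM) each panel has unit
#' width, so the score runs from 0 (complete kill at every dose) to 4 (no
#' effect at any dose); reducing viability to 50% at the middle dose and to
#' 0 at the two highest scores 2.
#'
#' @param viability smoothed viability fractions
#' @param concentrations strictly ascending concentrations (nM)
#' @return score in \code{[0, k - 1]} for k 10-fold-spaced doses
#' @export
auc_score <- function(viability, concentrations) {
  stopifnot(length(viability) == length(concentrations),
            length(viability) >= 2)
  if (is.unsorted(concentrations, strictly = TRUE)) {
    stop("concentrations must be sorted ascending")
  }
  .check_finite(viability, "viabilities")
  lx <- log10(concentrations)
  sum(diff(lx) * (utils::head(viability, -1) + utils::tail(viability, -1)) / 2)
}

#' Build smoothed viability profiles and AUC scores from normalized wells
#'
#' Groups normalized drug wells by cell line and compound, averages
#' replicate wells within a concentration, applies
#' \code{\link{smooth_profile}} and scores each profile with
#' \code{\link{auc_score}}.
#'
#' @param norm_wells output of \code{\link{normalize_plate}}
#' @return long data.frame: \code{cell_line, compound, concentration_nM,
#'   viability_raw, viability_smoothed, auc} (the AUC repeats within a
#'   profile)
#' @export
viability_profiles <- function(norm_wells) {
  d <- norm_wells[norm_wells$role == "drug", , drop = FALSE]
  stopifnot(nrow(d) > 0, "viability" %in% names(d))
  key <- interaction(d$cell_line, d$compound, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    agg <- stats::aggregate(viability ~ concentration_nM, data = g, FUN = mean)
    agg <- agg[order(agg$concentration_nM), ]
    sm <- smooth_profile(agg$viability, agg$concentration_nM)
    data.frame(cell_line = g$cell_line[1], compound = g$compound[1],
               concentration_nM = agg$concentration_nM,
               viability_raw = agg$viability, viability_smoothed = sm,
               auc = auc_score(sm, agg$concentration_nM),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compound x cell line AUC matrix from viability profiles
#'
#' @param profiles output of \code{\link{viability_profiles}}
#' @return numeric matrix, compounds in rows, cell lines in columns; NA
#'   marks untested pairs
#' @export
auc_matrix <- function(profiles) {
  u <- unique(profiles[, c("compound", "cell_line", "auc")])
  compounds <- sort(unique(u$compound))
  lines <- sort(unique(u$cell_line))
  m <- matrix(NA_real_, length(compounds), length(lines),
              dimnames = list(compounds, lines))
  m[cbind(u$compound, u$cell_line)] <- u$auc
  m
}

#' Select screening hits from an AUC matrix
#'
#' A compound is a hit when its combined-viability AUC is at or below the
#' threshold (default half the 5-dose scale, i.e. viability reduced to at
#' least 50% over the tested range) in at least \code{min_lines} cell
#' lines. Untested (NA) entries are ignored. Hits are ranked by their
#' minimum AUC, ties broken by the number of qualifying lines.
#'
#' @param auc_mat compound x cell line AUC matrix
#' @param threshold AUC cutoff, inclusive (default 2)
#' @param min_lines minimum number of qualifying cell lines (default 1)
#' @return data.frame: \code{compound, min_auc, n_lines_hit}, ranked
#' @export
select_hits <- function(auc_mat, threshold = 2, min_lines = 1) {
  if (length(auc_mat) == 0 || nrow(auc_mat) == 0) {
    return(data.frame(compound = character(0), min_auc = numeric(0),
                      n_lines_hit = integer(0), stringsAsFactors = FALSE))
  }
  n_hit <- apply(auc_mat, 1, function(x) sum(x <= threshold, na.rm = TRUE))
  min_auc <- apply(auc_mat, 1, function(x)
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE))
  keep <- which(n_hit >= min_lines & !is.na(min_auc))
  out <- data.frame(compound = rownames(auc_mat)[keep],
                    min_auc = min_auc[keep],
                    n_lines_hit = as.integer(n_hit[keep]),
                    stringsAsFactors = FALSE)
  out[order(out$min_auc, -out$n_lines_hit), , drop = FALSE]
}
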