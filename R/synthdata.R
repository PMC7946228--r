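#' Generate one 384-well screening plate with controls and noise
#'
#' Lays out drug wells (one compound x concentration per well, optionally
#' replicated), negative-control (DMSO) wells and positive-control (BzCl)
#' wells on a single plate seeded with one cell line, then draws raw
#' luminescence signals. The expected signal of a drug well is
#' \code{pos_level + v * (neg_level - pos_level)} where \code{v} is the
#' truth's expected normalized viability, so full kill sits at the
#' positive-control floor and no effect at the negative-control level.
#' Noise is multiplicative lognormal with the requested coefficient of
#' variation (plate reads are positive and right-skewed).
#'
#' @param truths list of \code{\link{screen_truth}} objects, all for the
#'   same cell line
#' @param concentrations ascending dose series in nM (default five 10-fold
#'   steps, 1 nM to 10 uM)
#' @param n_neg,n_pos number of DMSO / BzCl control wells (default 16 each)
#' @param n_reps drug wells per compound x concentration (default 1)
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 disables noise)
#' @param neg_level expected DMSO signal (arbitrary units, default 1000)
#' @param pos_frac positive-control floor as a fraction of \code{neg_level}
#'   (default 0.01)
#' @param plate_id plate identifier
#' @param seed integer seed; identical seed and inputs give identical wells
#' @return data.frame of wells with columns \code{plate_id, well, row, col,
#'   role, compound, concentration_nM, cell_line, signal}
#' @export
gen_plate <- function(truths, concentrations = 10^(0:4),
                      n_neg = 16, n_pos = 16, n_reps = 1,
                      noise_cv = 0.05, neg_level = 1000, pos_frac = 0.01,
                      plate_id = "P1", seed = 1) {
  stopifnot(length(truths) >= 1, noise_cv >= 0, n_neg >= 2, n_pos >= 2,
            n_reps >= 1, neg_level > 0, pos_frac >= 0, pos_frac < 1)
  .check_ascending(concentrations)
  lines <- unique(vapply(truths, `[[`, character(1), "cell_line"))
  if (length(lines) != 1L) stop("all truths on one plate must share a cell line")
  n_drug <- length(truths) * length(concentrations) * n_reps
  n_wells <- n_drug + n_neg + n_pos
  if (n_wells > 384L) {
    stop(sprintf("layout needs %d wells but a 384-well plate holds 384", n_wells))
  }

  pos_level <- neg_level * pos_frac
  exp_sig <- numeric(0); role <- character(0)
  compound <- character(0); conc <- numeric(0)
  for (tr in truths) {
    v <- true_viability(tr, concentrations)
    for (r in seq_len(n_reps)) {
      exp_sig <- c(exp_sig, pos_level + v * (neg_level - pos_level))
      role <- c(role, rep("drug", length(concentrations)))
      compound <- c(compound, rep(tr$compound, length(concentrations)))
      conc <- c(conc, concentrations)
    }
  }
  exp_sig <- c(exp_sig, rep(neg_level, n_neg), rep(pos_level, n_pos))
  role <- c(role, rep("neg_ctrl", n_neg), rep("pos_ctrl", n_pos))
  compound <- c(compound, rep(NA_character_, n_neg + n_pos))
  conc <- c(conc, rep(NA_real_, n_neg + n_pos))

  if (noise_cv > 0) {
    set.seed(child_seed(seed, paste0("plate:", plate_id)))
    sdlog <- sqrt(log(1 + noise_cv^2))
    mult <- exp(stats::rnorm(n_wells, mean = -sdlog^2 / 2, sd = sdlog))
  } else {
    mult <- rep(1, n_wells)
  }
  signal <- exp_sig * mult

  idx <- seq_len(n_wells) - 1L
  row_i <- idx %/% 24L + 1L
  col_i <- idx %% 24L + 1L
  data.frame(plate_id = plate_id,
             well = paste0(LETTERS[row_i], col_i),
             row = LETTERS[row_i], col = col_i,
             role = role, compound = compound, concentration_nM = conc,
             cell_line = lines, signal = signal,
             stringsAsFactors = FALSE)
}

# internal: logistic confluence at time t from start c0 with exponential rate r
.logistic_conf <- function(t, c0, K, r) {
  K * c0 / (c0 + (K - c0) * exp(-r * t))
}

#' Generate confluence time series under a growth truth
#'
#' Simulates percent-confluence trajectories for one cell line x compound
#' across a dose series (0 nM = vehicle). Growth is logistic with intrinsic
#' exponential rate \code{log(2) * baseline_rate} scaled by the truth's
#' per-concentration rate multiplier. When \code{withdrawal_at} is set and
#' the truth is flagged reversible, the rate reverts to baseline after that
#' time; irreversible conditions keep the suppressed rate. Observation
#' noise is additive Gaussian, truncated to \code{[0, 100]}.
#'
#' @param truth a \code{\link{growth_truth}}; its \code{drug_effect} must
#'   name every non-zero concentration requested
#' @param concentrations doses in nM; include 0 for the vehicle arm
#' @param t_grid sampling times in hours, strictly increasing (default
#'   every 3 h over 0-120 h)
#' @param n_reps replicates per condition (default 3)
#' @param withdrawal_at drug-withdrawal time in hours, or NULL
#' @param noise_sd additive noise SD in percentage points (default 1)
#' @param seed integer seed
#' @return long data.frame: \code{cell_line, compound, concentration_nM,
#'   replicate, time_h, confluence_pct, withdrawal_at}
#' @export
gen_growth_curves <- function(truth, concentrations = c(0, 10^(0:4)),
                              t_grid = seq(0, 120, by = 3), n_reps = 3,
                              withdrawal_at = NULL, noise_sd = 1, seed = 1) {
  stopifnot(inherits(truth, "growth_truth"), n_reps >= 1, noise_sd >= 0)
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("time grid must be strictly increasing")
  }
  r0 <- log(2) * truth$baseline_rate
  K <- truth$carrying_capacity
  known <- as.numeric(names(truth$drug_effect))
  out <- vector("list", length(concentrations) * n_reps)
  i <- 0L
  set.seed(child_seed(seed, paste0("growth:", truth$cell_line, ":", truth$compound)))
  for (conc in concentrations) {
    if (conc == 0) {
      m <- 1
    } else {
      j <- which(abs(known - conc) < 1e-9)
      if (length(j) != 1L) {
        stop(sprintf("no rate multiplier defined for %g nM", conc))
      }
      m <- unname(truth$drug_effect[j])
    }
    r_drug <- r0 * m
    if (!is.null(withdrawal_at) && truth$reversible && conc > 0) {
      cw <- .logistic_conf(withdrawal_at, truth$c0, K, r_drug)
      conf <- ifelse(t_grid <= withdrawal_at,
                     .logistic_conf(t_grid, truth$c0, K, r_drug),
                     .logistic_conf(t_grid - withdrawal_at, cw, K, r0))
    } else {
      conf <- .logistic_conf(t_grid, truth$c0, K, r_drug)
    }
    for (rep_i in seq_len(n_reps)) {
      obs <- conf
      if (noise_sd > 0) {
        obs <- pmin(100, pmax(0, conf + stats::rnorm(length(conf), sd = noise_sd)))
      }
      i <- i + 1L
      out[[i]] <- data.frame(cell_line = truth$cell_line,
                             compound = truth$compound,
                             concentration_nM = conc, replicate = rep_i,
                             time_h = t_grid, confluence_pct = obs,
                             withdrawal_at = if (is.null(withdrawal_at))
                               NA_real_ else withdrawal_at,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Generate endpoint counts for a growth-rate-corrected viability assay
#'
#' For each truth and concentration, emits baseline (\code{x0}), vehicle
#' endpoint (\code{x_ctrl = x0 * 2^(t_end / division_time)}) and treated
#' endpoint counts such that the GR transform of the noise-free counts
#' equals the truth's expected GR value at that concentration.
#'
#' @param truths list of \code{\link{gr_truth}} objects
#' @param concentrations dose series in nM (default seven 10-fold steps,
#'   0.1 nM to 100 uM)
#' @param division_time control doubling time in hours (> 0, default 24)
#' @param t_end assay endpoint in hours (> 0, default 72)
#' @param x0 baseline count (default 1000)
#' @param noise_cv lognormal CV applied to the treated endpoint (default 0)
#' @param seed integer seed
#' @return data.frame: \code{cell_line, compound, concentration_nM, x0,
#'   x_ctrl, x_c}
#' @export
gen_gr_assay <- function(truths, concentrations = 10^seq(-1, 5),
                         division_time = 24, t_end = 72, x0 = 1000,
                         noise_cv = 0, seed = 1) {
  stopifnot(division_time > 0, t_end > 0, x0 > 0, noise_cv >= 0)
  .check_ascending(concentrations)
  n_div <- t_end / division_time
  x_ctrl <- x0 * 2^n_div
  rows <- lapply(truths, function(tr) {
    stopifnot(inherits(tr, "gr_truth"))
    g <- true_gr(tr, concentrations)
    # invert the GR transform: x_c realizing GR = g given control growth
    x_c <- x0 * 2^(n_div * log2(1 + g))
    data.frame(cell_line = tr$cell_line, compound = tr$compound,
               concentration_nM = concentrations,
               x0 = x0, x_ctrl = x_ctrl, x_c = x_c,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (noise_cv > 0) {
    set.seed(child_seed(seed, "gr_assay"))
    sdlog <- sqrt(log(1 + noise_cv^2))
    out$x_c <- out$x_c *
      exp(stats::rnorm(nrow(out), mean = -sdlog^2 / 2, sd = sdlog))
  }
  out
}

#' Generate an FPKM-like expression matrix with planted biomarkers
#'
#' Background genes are drawn independently of drug response (lognormal
#' FPKM). Each planted biomarker's log-expression is a linear mix of the
#' standardized log GR50 of its compound (signed by direction) and unit
#' Gaussian noise, so its rank correlation with GR50 grows with
#' \code{effect_size}; with \code{noise_sd = 0} the correlation is exactly
#' +/-1. A configurable fraction of background genes is forced below the
#' expression floor in all lines.
#'
#' @param truth an \code{\link{expression_truth}}
#' @param gr50_table numeric matrix of GR50 values (nM), compounds in rows,
#'   cell lines in columns; must cover every planted compound and have at
#'   least 3 columns
#' @param noise_sd SD of the per-gene noise component for planted genes
#'   (default 1)
#' @param floor FPKM floor used for the unexpressed fraction (default 10)
#' @param seed integer seed
#' @return list with \code{fpkm} (genes x lines matrix) and \code{truth}
#' @export
gen_expression <- function(truth, gr50_table, noise_sd = 1, floor = 10,
                           seed = 1) {
  stopifnot(inherits(truth, "expression_truth"), is.matrix(gr50_table),
            ncol(gr50_table) >= 3, noise_sd >= 0)
  n_lines <- truth$n_lines
  if (ncol(gr50_table) != n_lines) {
    stop("gr50_table must have one column per cell line in the truth")
  }
  pb <- truth$planted_biomarkers
  if (nrow(pb) > 0 && !all(pb$compound %in% rownames(gr50_table))) {
    stop("every planted compound must appear in gr50_table")
  }
  n_genes <- truth$n_genes
  set.seed(child_seed(seed, "expression"))
  genes <- sprintf("G%05d", seq_len(n_genes))
  # background: lognormal FPKM centred near 30 FPKM
  logf <- matrix(stats::rnorm(n_genes * n_lines, mean = 1.5, sd = 0.5),
                 nrow = n_genes,
                 dimnames = list(genes, colnames(gr50_table)))
  if (nrow(pb) > 0) {
    pb$gene <- as.character(pb$gene)
    missing <- setdiff(pb$gene, genes)
    if (length(missing) > 0) {
      # planted names outside the generated universe take over leading
      # background rows so the planted genes are a subset of the universe
      taken <- match(intersect(pb$gene, genes), genes)
      slots <- setdiff(seq_len(n_genes), taken)[seq_along(missing)]
      rownames(logf)[slots] <- missing
      genes <- rownames(logf)
    }
    for (i in seq_len(nrow(pb))) {
      s <- if (pb$direction[i] == "sensitizing") -1 else 1
      zg <- as.numeric(scale(log10(gr50_table[pb$compound[i], ])))
      latent <- s * pb$effect_size[i] * zg + noise_sd * stats::rnorm(n_lines)
      # unit-variance latent keeps planted genes on the same FPKM dynamic
      # range as the background whatever the effect size
      latent <- latent / sqrt(pb$effect_size[i]^2 + noise_sd^2)
      logf[pb$gene[i], ] <- 1.5 + 0.5 * latent
    }
  }
  fpkm <- 10^logf
  n_off <- round(truth$frac_unexpressed * n_genes)
  if (n_off > 0) {
    off <- setdiff(genes, pb$gene)[seq_len(n_off)]
    fpkm[off, ] <- matrix(stats::runif(length(off) * n_lines, 0, floor * 0.5),
                          nrow = length(off))
  }
  list(fpkm = fpkm, truth = truth)
}

#' Generate a random gene-set collection, optionally with a planted set
#'
#' @param gene_universe character vector of gene identifiers
#' @param n_sets number of random sets (0 allowed)
#' @param set_size_range integer pair, inclusive size bounds
#' @param planted_set optional character vector; emitted verbatim (after
#'   deduplication, with a warning on duplicates) as set
#'   \code{"PLANTED_SET"}
#' @param seed integer seed
#' @return named list of character vectors (GMT-structured)
#' @export
gen_gene_sets <- function(gene_universe, n_sets, set_size_range = c(15, 50),
                          planted_set = NULL, seed = 1) {
  if (length(gene_universe) == 0) stop("gene universe is empty")
  stopifnot(n_sets >= 0, length(set_size_range) == 2,
            set_size_range[1] >= 1,
            set_size_range[2] <= length(gene_universe),
            set_size_range[1] <= set_size_range[2])
  set.seed(child_seed(seed, "gene_sets"))
  sets <- list()
  if (n_sets > 0) {
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                    replace = TRUE)
    sets <- lapply(sizes, function(k) sample(gene_universe, k))
    names(sets) <- sprintf("RANDOM_SET_%03d", seq_len(n_sets))
  }
  if (!is.null(planted_set)) {
    if (anyDuplicated(planted_set)) {
      warning("duplicate gene symbols in planted set; deduplicated")
      planted_set <- unique(planted_set)
    }
    sets$PLANTED_SET <- planted_set
  }
  sets
}
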