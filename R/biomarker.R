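#' Preprocess a raw FPKM expression matrix
#'
#' (1) resolves duplicate gene rows by keeping, per gene, the row with the
#' highest standard deviation across samples; (2) quantile-normalizes
#' across samples (ties within a sample receive the mean of the reference
#' quantiles they span); (3) adds 1e-5; (4) log10-transforms.
#'
#' @param mat numeric matrix of FPKM values (>= 0), genes in rows
#'   (rownames), samples in columns
#' @return matrix of normalized log10 expression with unique gene rows
#' @export
preprocess_expression <- function(mat) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (any(mat < 0)) stop("FPKM values must be non-negative")
  .check_finite(mat, "FPKM values")
  if (anyDuplicated(rownames(mat))) {
    sds <- apply(mat, 1, stats::sd)
    ord <- order(rownames(mat), -sds)
    mat <- mat[ord, , drop = FALSE]
    mat <- mat[!duplicated(rownames(mat)), , drop = FALSE]
  }
  qn <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(qn) <- dimnames(mat)
  log10(qn + 1e-5)
}

#' Drop genes unexpressed in every sample
#'
#' Removes genes whose FPKM is below the floor in all samples (a gene
#' above the floor in even one line is kept). Applied on the raw FPKM
#' scale before any transformation.
#'
#' @param mat raw FPKM matrix, genes in rows
#' @param floor FPKM expression floor (default 10)
#' @return row-subset of \code{mat}
#' @export
filter_expressed <- function(mat, floor = 10) {
  keep <- apply(mat, 1, function(x) any(x >= floor))
  mat[keep, , drop = FALSE]
}

# internal: two-sided p for a Spearman rho via the t approximation
.spearman_p <- function(rho, n) {
  t_stat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  p
}

#' Correlate gene expression with drug response
#'
#' Spearman rank correlation (average ranks for ties) of each gene's
#' processed expression with the per-sample drug response (GR50), with
#' two-sided p-values from the t approximation. Negative rho means high
#' expression accompanies low GR50, i.e. sensitivity to the drug. A gene
#' passes the single-panel criterion when \code{|rho| >= rho_min} and
#' \code{p < alpha} simultaneously. Genes with constant expression (rho
#' undefined) are returned with NA and a reason.
#'
#' @param mat normalized log-expression matrix, genes in rows, samples in
#'   columns (column names are cell lines)
#' @param response named numeric vector of GR50 values per cell line;
#'   >= 4 samples must be shared with \code{mat}
#' @param rho_min correlation threshold (default 0.65)
#' @param alpha p-value threshold (default 0.05)
#' @return data.frame: \code{gene, rho, p_value, direction,
#'   passes_single, reason}
#' @export
correlate_gene_drug <- function(mat, response, rho_min = 0.65, alpha = 0.05) {
  shared <- intersect(colnames(mat), names(response))
  if (length(shared) < 4) stop("need >= 4 shared samples")
  m <- mat[, shared, drop = FALSE]
  y <- response[shared]
  if (length(unique(y)) < 2) stop("response vector is constant")
  n <- length(y)
  rho <- suppressWarnings(
    as.numeric(stats::cor(t(m), y, method = "spearman")))
  p <- .spearman_p(rho, n)
  reason <- ifelse(is.na(rho), "constant expression", NA_character_)
  data.frame(
    gene = rownames(m),
    rho = rho, p_value = p,
    direction = ifelse(is.na(rho), NA_character_,
                       ifelse(rho < 0, "sensitizing", "resistance")),
    passes_single = !is.na(rho) & abs(rho) >= rho_min & p < alpha,
    reason = reason, stringsAsFactors = FALSE)
}

#' Leave-one-out robust biomarker selection
#'
#' Repeats the Spearman association once per cell line, each time leaving
#' that line out, and keeps the genes whose correlation exceeds
#' \code{rho_fold} in absolute value (strictly) in every fold with a
#' consistent sign. A fold in which rho is undefined disqualifies the gene
#' (conservative). This guards against associations carried by a single
#' outlier cell line.
#'
#' @param mat normalized log-expression matrix, genes x samples
#' @param response named numeric GR50 vector; >= 5 shared samples
#' @param rho_fold per-fold threshold (default 0.8, strict)
#' @return data.frame of selected genes: \code{gene, rho_full, rho_min,
#'   rho_max, direction} where \code{rho_min}/\code{rho_max} summarize the
#'   fold-wise values
#' @export
loo_robust_biomarkers <- function(mat, response, rho_fold = 0.8) {
  shared <- intersect(colnames(mat), names(response))
  if (length(shared) < 5) stop("need >= 5 shared samples for leave-one-out")
  m <- mat[, shared, drop = FALSE]
  y <- response[shared]
  n <- length(y)
  folds <- matrix(NA_real_, nrow = nrow(m), ncol = n,
                  dimnames = list(rownames(m), shared))
  for (i in seq_len(n)) {
    folds[, i] <- suppressWarnings(
      as.numeric(stats::cor(t(m[, -i, drop = FALSE]), y[-i],
                            method = "spearman")))
  }
  ok <- apply(folds, 1, function(r) {
    !anyNA(r) && all(abs(r) > rho_fold) && (all(r > 0) || all(r < 0))
  })
  rho_full <- suppressWarnings(
    as.numeric(stats::cor(t(m), y, method = "spearman")))
  sel <- which(ok)
  data.frame(
    gene = rownames(m)[sel],
    rho_full = rho_full[sel],
    rho_min = apply(folds[sel, , drop = FALSE], 1, function(r)
      r[which.min(abs(r))]),
    rho_max = apply(folds[sel, , drop = FALSE], 1, function(r)
      r[which.max(abs(r))]),
    direction = ifelse(rho_full[sel] < 0, "sensitizing", "resistance"),
    stringsAsFactors = FALSE, row.names = NULL)
}

# internal: weighted Kolmogorov-Smirnov running-sum enrichment score.
# w_sorted: |score|^weight in ranking order; hits: sorted positions of the
# set in the ranking. Returns the signed extremum and its hit index/side.
.es_stat <- function(w_sorted, hits, n) {
  k <- length(hits)
  nr <- sum(w_sorted[hits])
  if (nr == 0) w_hit <- rep(1 / k, k) else w_hit <- w_sorted[hits] / nr
  miss <- 1 / (n - k)
  cum <- cumsum(w_hit)
  idx <- seq_len(k)
  after <- cum - (hits - idx) * miss          # running sum just after each hit
  before <- c(0, cum[-k]) - (hits - idx) * miss  # just before each hit
  cand <- c(after, before)
  j <- which.max(abs(cand))
  list(es = cand[j],
       hit_index = if (j <= k) j else j - k,
       side = if (j <= k) "after" else "before")
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment on a ranked
#' gene list (weight exponent 1 on the absolute score). The null
#' distribution comes from gene-label permutations — for a fixed ranking
#' it depends only on set size, so permutations are drawn once per
#' distinct size. NES divides each ES by the mean absolute null ES of the
#' matching sign, and FDR follows the standard signed-pool procedure over
#' all sets' null NES values. A set is flagged significant at
#' \code{fdr < 0.001} and \code{|es| > 0.5}.
#'
#' @param scores named numeric ranking scores (e.g. Spearman rho per
#'   gene); at least 2 distinct values
#' @param sets named list of character vectors; sets are intersected with
#'   the ranking, and sets outside \code{[min_size, max_size]} after
#'   intersection are dropped
#' @param n_perm gene-label permutations per set size (default 1000)
#' @param seed integer seed (results are deterministic given the seed)
#' @param min_size,max_size set-size window (defaults 15 and 500)
#' @param weight exponent on \code{|score|} (default 1)
#' @return data.frame: \code{gene_set, size, es, nes, fdr, significant,
#'   n_leading_edge}, with the leading-edge genes in the list column
#'   \code{leading_edge} and skipped sets recorded in the
#'   \code{"skipped"} attribute
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, seed = 1,
                           min_size = 15, max_size = 500, weight = 1) {
  stopifnot(!is.null(names(scores)), length(unique(scores)) >= 2,
            n_perm >= 1)
  ord <- order(scores, decreasing = TRUE)
  ranked <- names(scores)[ord]
  w_sorted <- abs(scores[ord])^weight
  n <- length(ranked)

  skipped <- data.frame(gene_set = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  hits_list <- list()
  for (nm in names(sets)) {
    pos <- sort(match(intersect(sets[[nm]], ranked), ranked))
    if (length(pos) == 0) {
      skipped <- rbind(skipped, data.frame(gene_set = nm,
                                           reason = "no overlap with ranking"))
    } else if (length(pos) < min_size || length(pos) > max_size) {
      skipped <- rbind(skipped, data.frame(gene_set = nm,
                                           reason = "size outside window"))
    } else if (length(pos) >= n) {
      skipped <- rbind(skipped, data.frame(gene_set = nm,
                                           reason = "set covers whole ranking"))
    } else {
      hits_list[[nm]] <- pos
    }
  }
  if (length(hits_list) == 0) {
    out <- data.frame(gene_set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0), fdr = numeric(0),
                      significant = logical(0), n_leading_edge = integer(0))
    out$leading_edge <- list()
    attr(out, "skipped") <- skipped
    return(out)
  }

  obs <- lapply(hits_list, .es_stat, w_sorted = w_sorted, n = n)
  es_obs <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(hits_list, length, integer(1))

  # gene-label permutation null, one draw matrix per distinct set size
  set.seed(child_seed(seed, "gsea"))
  null_by_size <- list()
  for (k in sort(unique(sizes))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(j) {
      .es_stat(w_sorted, sort(sample.int(n, k)), n)$es
    }, numeric(1))
  }

  # per-size sign-matched normalization factors
  norm_es <- function(es, null_es) {
    pos_mean <- mean(null_es[null_es > 0])
    neg_mean <- mean(abs(null_es[null_es < 0]))
    ifelse(es >= 0,
           ifelse(is.finite(pos_mean) & pos_mean > 0, es / pos_mean, NA_real_),
           ifelse(is.finite(neg_mean) & neg_mean > 0, es / neg_mean, NA_real_))
  }
  nes_obs <- vapply(seq_along(es_obs), function(i) {
    norm_es(es_obs[i], null_by_size[[as.character(sizes[i])]])
  }, numeric(1))
  nes_null <- unlist(lapply(unique(sizes), function(k) {
    ne <- null_by_size[[as.character(k)]]
    norm_es(ne, ne)
  }), use.names = FALSE)
  nes_null <- nes_null[is.finite(nes_null)]

  # signed-pool FDR on NES
  fdr_of <- function(nes) {
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      null_tail <- mean(nes_null[nes_null >= 0] >= nes)
      obs_tail <- mean(nes_obs[!is.na(nes_obs) & nes_obs >= 0] >= nes)
    } else {
      null_tail <- mean(nes_null[nes_null < 0] <= nes)
      obs_tail <- mean(nes_obs[!is.na(nes_obs) & nes_obs < 0] <= nes)
    }
    if (!is.finite(null_tail)) null_tail <- 0
    if (!is.finite(obs_tail) || obs_tail == 0) return(NA_real_)
    min(1, null_tail / obs_tail)
  }
  fdr <- vapply(nes_obs, fdr_of, numeric(1))

  leading <- lapply(seq_along(hits_list), function(i) {
    pos <- hits_list[[i]]
    o <- obs[[i]]
    if (o$es >= 0) {
      ranked[pos[seq_len(o$hit_index - (o$side == "before"))]]
    } else {
      j0 <- o$hit_index - (o$side == "before") + 1
      if (j0 > length(pos)) character(0) else ranked[pos[j0:length(pos)]]
    }
  })
  out <- data.frame(gene_set = names(hits_list), size = sizes,
                    es = unname(es_obs), nes = unname(nes_obs),
                    fdr = unname(fdr),
                    significant = !is.na(fdr) & fdr < 0.001 &
                      abs(es_obs) > 0.5,
                    n_leading_edge = vapply(leading, length, integer(1)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- leading
  attr(out, "skipped") <- skipped
  out
}
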