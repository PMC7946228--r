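#' Default run configuration
#'
#' Assembles the configuration consumed by \code{\link{run_pipeline}}:
#' synthesis parameters for the default synthetic scenario, stage toggles
#' and all analysis thresholds (screen AUC cutoff 2 on the 0-4 scale,
#' growth-reduction contrast level 0.05, arrest/regrowth windows of 3
#' percentage points, association thresholds |rho| >= 0.65 with p < 0.05,
#' per-fold threshold 0.8, GSEA FDR < 0.001 with |ES| > 0.5).
#'
#' @param seed integer seed governing every stochastic stage
#' @param out_dir output directory for stage artifacts
#' @param ... overrides for any configuration entry
#' @return a named list (class \code{dsrt_config})
#' @export
run_config <- function(seed = 1, out_dir = tempfile("dsrt_run_"), ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    stages = list(screen = TRUE, growth = TRUE, grfit = TRUE,
                  biomarker = TRUE, concordance = TRUE),
    # synthesis: 13-line panel, 10 compounds of which 6 are planted hits
    n_lines = 13, n_compounds = 10, n_hits = 6,
    n_genes = 600, n_sets = 40,
    noise_cv = 0.05, conf_noise_sd = 1, n_growth_reps = 3,
    # thresholds
    auc_threshold = 2, min_lines = 1,
    alpha = 0.05, arrest_delta = 3, regrowth_delta = 3,
    rho_min = 0.65, rho_fold = 0.8, n_perm = 1000)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "dsrt_config")
}

#' Load a run configuration from a YAML file
#'
#' @param path YAML file with configuration overrides
#' @return a \code{dsrt_config}
#' @export
load_run_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(run_config, over)
}

#' Default synthetic study scenario with known ground truth
#'
#' Builds the latent truths the generators consume: a panel of cell lines
#' and compounds in which the planted hits share one latent potency per
#' cell line across the screen (4PL viability), the GR assay (4PL GR
#' curve) and the growth kinetics (dose-threshold rate suppression), plus
#' planted expression biomarkers (3 per hit compound, alternating
#' direction). Non-hit compounds have a weak, high-EC50 effect.
#'
#' @param cfg a \code{\link{run_config}}
#' @return list of truth collections: \code{screen}, \code{gr},
#'   \code{growth}, \code{expression}, and the dose grids used
#' @export
default_scenario <- function(cfg) {
  lines <- sprintf("L%02d", seq_len(cfg$n_lines))
  compounds <- sprintf("C%02d", seq_len(cfg$n_compounds))
  hits <- compounds[seq_len(cfg$n_hits)]
  doses <- 10^(0:4)  # screen: 1 nM .. 10 uM
  set.seed(child_seed(cfg$seed, "scenario"))
  screen_truths <- list()
  gr_truths <- list()
  growth_truths <- list()
  for (cp in compounds) {
    is_hit <- cp %in% hits
    for (ln in lines) {
      if (is_hit) {
        # shared latent potency drives screen, GR and kinetics alike
        pot <- 10^stats::runif(1, log10(3), log10(80))
        screen_truths[[paste(ln, cp)]] <-
          screen_truth(ln, cp, e_inf = 0, ec50 = pot, hill = 1.5)
        gr_truths[[paste(ln, cp)]] <-
          gr_truth(ln, cp, gr_inf = -0.5, gec50 = pot, hill = 1.5)
        # rate multipliers: full growth below the potency decade, half a
        # decade of slowed growth, arrest above
        red_t <- 10^(ceiling(log10(pot)))
        eff <- stats::setNames(ifelse(doses < red_t, 1,
                                      ifelse(doses < red_t * 10, 0.5, 0)),
                               doses)
        growth_truths[[paste(ln, cp)]] <-
          growth_truth(ln, cp, baseline_rate = 0.035, drug_effect = eff)
      } else {
        screen_truths[[paste(ln, cp)]] <-
          screen_truth(ln, cp, e_inf = 0.85, ec50 = 5e4, hill = 1)
      }
    }
  }
  planted <- do.call(rbind, lapply(seq_along(hits), function(i) {
    data.frame(gene = sprintf("BM_%s_%d", hits[i], 1:3),
               compound = hits[i],
               direction = c("sensitizing", "resistance", "sensitizing"),
               effect_size = 6, stringsAsFactors = FALSE)
  }))
  list(screen = screen_truths, gr = gr_truths, growth = growth_truths,
       expression = expression_truth(planted, n_genes = cfg$n_genes,
                                     n_lines = cfg$n_lines),
       lines = lines, compounds = compounds, hits = hits,
       screen_doses = doses, gr_doses = 10^seq(-1, 5),
       growth_doses = c(0, doses))
}

#' Cross-stage concordance of response summaries
#'
#' Per compound, the Spearman correlation across shared cell lines of each
#' pair among the screen AUC, the fitted GR50 and the growth-arresting
#' concentration (untransformed values; rank correlation makes the scale
#' immaterial). Pairs with fewer than 4 overlapping finite values are
#' omitted with a reason; entries are flagged at p < 0.05.
#'
#' @param auc_mat compound x line AUC matrix
#' @param gr50_mat compound x line GR50 matrix (may be NULL)
#' @param arrest_mat compound x line arresting-concentration matrix (may
#'   be NULL)
#' @return data.frame: \code{compound, comparison, rho, p_value, n,
#'   significant}
#' @export
concordance <- function(auc_mat, gr50_mat = NULL, arrest_mat = NULL) {
  tabs <- list(auc = auc_mat, gr50 = gr50_mat, arrest = arrest_mat)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  if (length(tabs) < 2) stop("need at least two response tables")
  pairs <- utils::combn(names(tabs), 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    a <- tabs[[pr[1]]]; b <- tabs[[pr[2]]]
    for (cp in intersect(rownames(a), rownames(b))) {
      shared <- intersect(colnames(a), colnames(b))
      x <- a[cp, shared]; y <- b[cp, shared]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 4) {
        rows[[length(rows) + 1L]] <- data.frame(
          compound = cp, comparison = paste(pr, collapse = "_vs_"),
          rho = NA_real_, p_value = NA_real_, n = sum(ok),
          significant = NA, stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        compound = cp, comparison = paste(pr, collapse = "_vs_"),
        rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
        significant = ct$p.value < 0.05, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on the default synthetic scenario
#'
#' Executes, in dependency order: data synthesis, screen normalization +
#' QC + AUC scoring + hit selection, growth-kinetics calls (hit compounds
#' only, as the downstream assays follow the screen's selection), GR
#' dose-response fits, biomarker association with leave-one-out
#' cross-validation and pre-ranked GSEA, and cross-stage concordance.
#' Every intermediate artifact is written to \code{cfg$out_dir} and listed
#' in a JSON manifest with parameters, seed and content hashes; rerunning
#' with an identical configuration reproduces identical hashes. A stage
#' failure aborts downstream stages and is recorded in the manifest.
#'
#' @param cfg a \code{\link{run_config}} or path to a YAML configuration
#' @return the manifest, invisibly (list with \code{files}, \code{params},
#'   \code{seed}, \code{status})
#' @export
run_pipeline <- function(cfg = run_config()) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- default_scenario(cfg)
  files <- character(0)
  status <- list()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    files[[name]] <<- path
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(list(value = fun(), error = NULL),
                    error = function(e) list(value = NULL,
                                             error = conditionMessage(e)))
    status[[name]] <<- if (is.null(res$error)) "ok" else
      paste("failed:", res$error)
    res
  }

  # --- screen stage -------------------------------------------------------
  auc_mat <- NULL; hits_df <- NULL
  if (isTRUE(cfg$stages$screen)) {
    st <- run_stage("screen", function() {
      wells <- do.call(rbind, lapply(sc$lines, function(ln) {
        truths <- Filter(function(t) t$cell_line == ln, sc$screen)
        gen_plate(truths, concentrations = sc$screen_doses,
                  noise_cv = cfg$noise_cv, plate_id = paste0("P_", ln),
                  seed = cfg$seed)
      }))
      norm <- normalize_plate(wells)
      prof <- viability_profiles(norm)
      list(wells = wells, qc = plate_qc(wells), prof = prof,
           auc = auc_matrix(prof))
    })
    if (is.null(status$screen) || status$screen == "ok") {
      v <- st$value
      auc_mat <- v$auc
      hits_df <- select_hits(auc_mat, threshold = cfg$auc_threshold,
                             min_lines = cfg$min_lines)
      emit("plates.csv", function(p) write_plate_csv(v$wells, p))
      emit("plate_qc.csv", function(p) utils::write.csv(v$qc, p,
                                                        row.names = FALSE))
      emit("profiles.csv", function(p) utils::write.csv(v$prof, p,
                                                        row.names = FALSE))
      emit("auc_matrix.csv", function(p) utils::write.csv(auc_mat, p))
      emit("hits.tsv", function(p) utils::write.table(hits_df, p, sep = "\t",
                                                      row.names = FALSE,
                                                      quote = FALSE))
    }
  }

  # --- growth stage (hit compounds only) ----------------------------------
  arrest_mat <- NULL
  if (isTRUE(cfg$stages$growth) && !is.null(auc_mat)) {
    st <- run_stage("growth", function() {
      curves <- do.call(rbind, lapply(sc$growth, function(tr) {
        gen_growth_curves(tr, concentrations = sc$growth_doses,
                          n_reps = cfg$n_growth_reps,
                          noise_sd = cfg$conf_noise_sd, seed = cfg$seed)
      }))
      calls <- kinetic_calls(curves, alpha = cfg$alpha,
                             arrest_delta = cfg$arrest_delta,
                             regrowth_delta = cfg$regrowth_delta)
      list(curves = curves, calls = calls)
    })
    if (status$growth == "ok") {
      v <- st$value
      emit("confluence.csv", function(p) write_confluence_csv(v$curves, p))
      emit("kinetic_calls.csv", function(p)
        utils::write.csv(v$calls, p, row.names = FALSE))
      arrest_mat <- matrix(NA_real_, length(sc$hits), length(sc$lines),
                           dimnames = list(sc$hits, sc$lines))
      arrest_mat[cbind(v$calls$compound, v$calls$cell_line)] <-
        v$calls$growth_arresting_conc
    }
  }

  # --- GR fitting stage ---------------------------------------------------
  gr50_mat <- NULL
  if (isTRUE(cfg$stages$grfit)) {
    st <- run_stage("grfit", function() {
      assay <- gen_gr_assay(unname(sc$gr), concentrations = sc$gr_doses,
                            noise_cv = cfg$noise_cv, seed = cfg$seed)
      fits <- fit_gr_table(assay)
      list(assay = assay, fits = fits)
    })
    if (status$grfit == "ok") {
      v <- st$value
      emit("gr_assay.csv", function(p) utils::write.csv(v$assay, p,
                                                        row.names = FALSE))
      emit("gr_fits.csv", function(p) utils::write.csv(v$fits, p,
                                                       row.names = FALSE))
      gr50_mat <- matrix(NA_real_, length(sc$hits), length(sc$lines),
                         dimnames = list(sc$hits, sc$lines))
      gr50_mat[cbind(v$fits$compound, v$fits$cell_line)] <- v$fits$gr50_nM
    }
  }

  # --- biomarker stage ----------------------------------------------------
  if (isTRUE(cfg$stages$biomarker) && !is.null(gr50_mat)) {
    st <- run_stage("biomarker", function() {
      expr <- gen_expression(sc$expression, gr50_mat, seed = cfg$seed)
      kept <- filter_expressed(expr$fpkm)
      proc <- preprocess_expression(kept)
      assoc <- list(); loo <- list(); enr <- list()
      sets <- gen_gene_sets(rownames(expr$fpkm), n_sets = cfg$n_sets,
                            planted_set =
                              sc$expression$planted_biomarkers$gene,
                            seed = cfg$seed)
      for (cp in sc$hits) {
        resp <- gr50_mat[cp, ]
        a <- correlate_gene_drug(proc, resp, rho_min = cfg$rho_min,
                                 alpha = cfg$alpha)
        a$compound <- cp
        assoc[[cp]] <- a
        l <- loo_robust_biomarkers(proc, resp, rho_fold = cfg$rho_fold)
        if (nrow(l) > 0) l$compound <- cp
        loo[[cp]] <- l
        scores <- stats::setNames(a$rho, a$gene)
        scores <- scores[!is.na(scores)]
        e <- gsea_preranked(scores, sets, n_perm = cfg$n_perm,
                            seed = child_seed(cfg$seed, paste0("gsea:", cp)))
        e$leading_edge <- NULL
        if (nrow(e) > 0) e$compound <- cp
        enr[[cp]] <- e
      }
      list(fpkm = expr$fpkm, sets = sets,
           assoc = do.call(rbind, assoc),
           loo = do.call(rbind, loo[vapply(loo, nrow, integer(1)) > 0]),
           enr = do.call(rbind, enr))
    })
    if (status$biomarker == "ok") {
      v <- st$value
      emit("expression.gct", function(p) write_gct(v$fpkm, p))
      emit("gene_sets.gmt", function(p) write_gmt(v$sets, p))
      emit("associations.csv", function(p)
        utils::write.csv(v$assoc, p, row.names = FALSE))
      emit("loo_biomarkers.csv", function(p)
        utils::write.csv(v$loo, p, row.names = FALSE))
      emit("enrichment.csv", function(p)
        utils::write.csv(v$enr, p, row.names = FALSE))
    }
  }

  # --- concordance stage --------------------------------------------------
  if (isTRUE(cfg$stages$concordance) && !is.null(auc_mat) &&
      (!is.null(gr50_mat) || !is.null(arrest_mat))) {
    st <- run_stage("concordance", function() {
      concordance(auc_mat, gr50_mat, arrest_mat)
    })
    if (status$concordance == "ok") {
      emit("concordance.csv", function(p)
        utils::write.csv(st$value, p, row.names = FALSE))
    }
  }

  manifest <- list(
    seed = cfg$seed,
    params = unclass(cfg)[setdiff(names(cfg), c("out_dir"))],
    status = status,
    files = lapply(files, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
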