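#' Latent screen truth for one compound x cell line
#'
#' Describes the true concentration-viability relationship of one compound
#' in one cell line as a four-parameter log-logistic curve on the
#' normalized-viability scale. Used by the plate generator and by
#' closed-form oracles for the screen scoring chain.
#'
#' @param cell_line,compound identifiers
#' @param e_inf viability floor, in \code{[0, e_max]}
#' @param ec50 inflection concentration (nM, > 0)
#' @param hill slope (> 0)
#' @param e_max viability ceiling, in \code{[e_inf, 1]} (default 1)
#' @return an object of class \code{screen_truth}
#' @export
screen_truth <- function(cell_line, compound, e_inf, ec50, hill, e_max = 1) {
  stopifnot(e_inf >= 0, e_inf <= e_max, e_max <= 1, ec50 > 0, hill > 0)
  structure(list(cell_line = as.character(cell_line),
                 compound = as.character(compound),
                 e_inf = e_inf, ec50 = ec50, hill = hill, e_max = e_max),
            class = "screen_truth")
}

#' Latent GR-curve truth for one compound x cell line
#'
#' Same 4PL form as \code{\link{screen_truth}} but on the GR scale, where
#' the lower asymptote may reach -1 (complete cell loss). Consumed by
#' \code{\link{gen_gr_assay}}.
#'
#' @param cell_line,compound identifiers
#' @param gr_inf GR floor, in \code{[-1, 1]}
#' @param gec50 inflection concentration (nM, > 0)
#' @param hill slope (> 0)
#' @return an object of class \code{gr_truth}
#' @export
gr_truth <- function(cell_line, compound, gr_inf, gec50, hill) {
  stopifnot(gr_inf >= -1, gr_inf <= 1, gec50 > 0, hill > 0)
  structure(list(cell_line = as.character(cell_line),
                 compound = as.character(compound),
                 gr_inf = gr_inf, gec50 = gec50, hill = hill),
            class = "gr_truth")
}

#' Latent growth-kinetics truth for one cell line x compound
#'
#' Logistic confluence growth with a dose-dependent multiplicative
#' suppression of the intrinsic rate. \code{drug_effect} maps each tested
#' concentration to a rate multiplier in \code{[0, 1]}; a multiplier of 0
#' is complete growth arrest. \code{reversible} marks conditions whose rate
#' reverts to baseline after drug withdrawal.
#'
#' @param cell_line,compound identifiers
#' @param baseline_rate intrinsic growth rate, doublings per hour (> 0)
#' @param carrying_capacity plateau confluence, percent (<= 100)
#' @param drug_effect named numeric vector: names are concentrations in nM,
#'   values are rate multipliers in \code{[0, 1]}, non-increasing in
#'   concentration
#' @param c0 starting confluence, percent (default 15)
#' @param reversible logical flag (default FALSE)
#' @return an object of class \code{growth_truth}
#' @export
growth_truth <- function(cell_line, compound, baseline_rate,
                         carrying_capacity = 95, drug_effect,
                         c0 = 15, reversible = FALSE) {
  stopifnot(baseline_rate > 0, carrying_capacity <= 100, carrying_capacity > 0,
            c0 > 0, c0 < carrying_capacity)
  conc <- as.numeric(names(drug_effect))
  if (anyNA(conc)) stop("drug_effect must be named by numeric concentrations (nM)")
  ord <- order(conc)
  eff <- drug_effect[ord]
  if (any(eff < 0) || any(eff > 1)) stop("rate multipliers must lie in [0, 1]")
  if (any(diff(unname(eff)) > 1e-12)) {
    stop("rate multipliers must be non-increasing in concentration")
  }
  structure(list(cell_line = as.character(cell_line),
                 compound = as.character(compound),
                 baseline_rate = baseline_rate,
                 carrying_capacity = carrying_capacity,
                 drug_effect = eff, c0 = c0,
                 reversible = isTRUE(reversible)),
            class = "growth_truth")
}

#' Latent expression-biomarker truth
#'
#' Declares which genes are planted as biomarkers of which compound, with
#' what direction and effect size, inside an otherwise response-independent
#' FPKM-like background matrix.
#'
#' @param planted_biomarkers data.frame with columns \code{gene},
#'   \code{compound}, \code{direction} (\code{"sensitizing"} = high
#'   expression with low GR50, rho < 0; \code{"resistance"} = rho > 0) and
#'   \code{effect_size} (> 0; the latent signal-to-noise ratio)
#' @param n_genes total number of genes to generate
#' @param n_lines number of cell lines (default 13)
#' @param frac_unexpressed fraction of genes forced below the FPKM
#'   expression floor in all lines (default 0.1)
#' @return an object of class \code{expression_truth}
#' @export
expression_truth <- function(planted_biomarkers, n_genes, n_lines = 13,
                             frac_unexpressed = 0.1) {
  pb <- as.data.frame(planted_biomarkers)
  needed <- c("gene", "compound", "direction", "effect_size")
  if (nrow(pb) > 0) {
    stopifnot(all(needed %in% names(pb)),
              all(pb$direction %in% c("sensitizing", "resistance")),
              all(pb$effect_size > 0))
  }
  if (nrow(pb) > n_genes) stop("cannot plant more biomarkers than genes")
  stopifnot(n_genes >= 1, n_lines >= 3, frac_unexpressed >= 0,
            frac_unexpressed < 1)
  structure(list(planted_biomarkers = pb, n_genes = as.integer(n_genes),
                 n_lines = as.integer(n_lines),
                 frac_unexpressed = frac_unexpressed),
            class = "expression_truth")
}

#' Expected normalized viability under a screen truth
#'
#' @param truth a \code{\link{screen_truth}}
#' @param conc concentrations (nM)
#' @return expected viability fractions
#' @export
true_viability <- function(truth, conc) {
  stopifnot(inherits(truth, "screen_truth"))
  four_pl(conc, truth$e_inf, truth$ec50, truth$hill, top = truth$e_max)
}

#' Expected GR value under a GR truth
#'
#' @param truth a \code{\link{gr_truth}}
#' @param conc concentrations (nM)
#' @return expected GR values
#' @export
true_gr <- function(truth, conc) {
  stopifnot(inherits(truth, "gr_truth"))
  four_pl(conc, truth$gr_inf, truth$gec50, truth$hill, top = 1)
}
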