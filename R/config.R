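#' Simulation configuration
#'
#' Collects every knob of the population design in one validated list. The
#' defaults describe the full-scale study population: a historical phase of
#' 8000 animals randomly mated for 300 generations plus 15 further
#' generations expanding from 12,000 to 17,000 animals (mutation-drift/LD
#' equilibration), a founder generation G0 of 1500 males and 15,000 females,
#' and four generations G1-G4 of EBV truncation selection with 50%/20%
#' male/female replacement, one progeny per dam and a 50% sex ratio. The
#' trait has h2 = 0.4 (genetic variance 0.4, residual 0.6), 100 QTL with
#' effects either gamma(shape 0.4)-distributed or predefined GV fractions,
#' and 200K evenly spaced markers on 10 chromosomes of 100 cM.
#'
#' `scale` uniformly shrinks locus counts, population sizes and historical
#' generations for desk-scale runs; any explicitly supplied value overrides
#' the scaled default.
#'
#' @param n_chromosomes,chrom_length_cM genome shape.
#' @param n_markers,n_qtl panel and causal locus counts (after segregation
#'   filtering; candidates are oversampled by `marker_oversample` and
#'   `qtl_oversample`).
#' @param marker_maf_min,qtl_maf_min minor-allele-frequency floors applied to
#'   the final historical generation when the panel is drawn.
#' @param mutation_rate recurrent allele-flip rate per locus per gamete per
#'   generation.
#' @param hist_generations,hist_size constant-size historical random-mating
#'   phase.
#' @param expand_generations,expand_size_start,expand_size_end linear
#'   population-growth tail of the historical phase.
#' @param n_males,n_females founder (G0) counts.
#' @param n_select_generations generations of selection after G0 (G1..G4).
#' @param male_replacement,female_replacement fraction of the breeding sires /
#'   dams replaced by top young animals each generation.
#' @param sex_ratio probability an offspring is male.
#' @param h2,sigma2_g,sigma2_e trait variance components (phenotypic variance
#'   1 at the nominal setting).
#' @param qtl_effect_dist `"gamma"` (|effect| ~ gamma(shape `gamma_shape`),
#'   random sign) or `"predefined"` (per-QTL GV fractions ~
#'   U(`min_gv_fraction`, 3 * `min_gv_fraction`), renormalized).
#' @param gamma_shape,min_gv_fraction parameters of the two effect models.
#' @param residual_policy `"rescale_to_realized_h2"` sets the residual
#'   variance from the realized founder TBV variance so h2 is held at `h2`;
#'   `"nominal"` uses `sigma2_e` as given.
#' @param selection `"blup"` (pedigree animal-model BLUP EBVs) or
#'   `"phenotypic"` (own phenotype; faster).
#' @param ld_regime `"high"` targets strong adjacent-marker LD (~0.65-0.70
#'   r2, the dense-chip regime); `"low"` multiplies the historical size by
#'   `low_ld_size_factor` to weaken drift-generated LD to ~0.3.
#' @param low_ld_size_factor historical-size multiplier for `ld_regime =
#'   "low"`.
#' @param genotyped_generations generations whose animals are genotyped.
#' @param scale desk-scale shrink factor in (0, 1].
#' @param seed master seed; all stage seeds derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 10, chrom_length_cM = 100,
                       n_markers = 200000, n_qtl = 100,
                       marker_maf_min = 0.01, qtl_maf_min = 0.05,
                       marker_oversample = 1.6, qtl_oversample = 3,
                       mutation_rate = 1e-4,
                       hist_generations = 300, hist_size = 8000,
                       expand_generations = 15,
                       expand_size_start = 12000, expand_size_end = 17000,
                       n_males = 1500, n_females = 15000,
                       n_select_generations = 4,
                       male_replacement = 0.5, female_replacement = 0.2,
                       sex_ratio = 0.5,
                       h2 = 0.4, sigma2_g = 0.4, sigma2_e = 0.6,
                       qtl_effect_dist = c("gamma", "predefined"),
                       gamma_shape = 0.4, min_gv_fraction = 0.005,
                       residual_policy = c("rescale_to_realized_h2", "nominal"),
                       selection = c("blup", "phenotypic"),
                       ld_regime = c("high", "low"),
                       low_ld_size_factor = 4,
                       genotyped_generations = c(3, 4),
                       scale = 1, seed = 1) {
  qtl_effect_dist <- match.arg(qtl_effect_dist)
  residual_policy <- match.arg(residual_policy)
  selection <- match.arg(selection)
  ld_regime <- match.arg(ld_regime)
  stopifnot(scale > 0, scale <= 1)
  supplied <- names(match.call())[-1]
  shrink <- function(name, value, floor = 1) {
    if (name %in% supplied || scale == 1) value
    else max(floor, round(value * scale))
  }
  cfg <- list(
    n_chromosomes = as.integer(shrink("n_chromosomes", n_chromosomes)),
    chrom_length_cM = chrom_length_cM,
    n_markers = as.integer(shrink("n_markers", n_markers, floor = 10)),
    n_qtl = as.integer(shrink("n_qtl", n_qtl, floor = 2)),
    marker_maf_min = marker_maf_min, qtl_maf_min = qtl_maf_min,
    marker_oversample = marker_oversample, qtl_oversample = qtl_oversample,
    mutation_rate = mutation_rate,
    hist_generations = as.integer(shrink("hist_generations", hist_generations, floor = 2)),
    hist_size = as.integer(shrink("hist_size", hist_size, floor = 10)),
    expand_generations = as.integer(expand_generations),
    expand_size_start = as.integer(shrink("expand_size_start", expand_size_start, floor = 10)),
    expand_size_end = as.integer(shrink("expand_size_end", expand_size_end, floor = 10)),
    n_males = as.integer(shrink("n_males", n_males)),
    n_females = as.integer(shrink("n_females", n_females)),
    n_select_generations = as.integer(n_select_generations),
    male_replacement = male_replacement,
    female_replacement = female_replacement,
    sex_ratio = sex_ratio,
    h2 = h2, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    qtl_effect_dist = qtl_effect_dist,
    gamma_shape = gamma_shape, min_gv_fraction = min_gv_fraction,
    residual_policy = residual_policy,
    selection = selection,
    ld_regime = ld_regime,
    low_ld_size_factor = low_ld_size_factor,
    genotyped_generations = as.integer(genotyped_generations),
    scale = scale, seed = as.integer(seed)
  )
  if (cfg$ld_regime == "low")
    cfg$hist_size <- as.integer(round(cfg$hist_size * cfg$low_ld_size_factor))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chromosomes", "n_markers", "n_qtl", "hist_generations",
              "hist_size", "expand_size_start", "expand_size_end",
              "n_males", "n_females")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop("config field '", nm, "' must be positive")
  if (cfg$n_select_generations < 0) stop("n_select_generations must be >= 0")
  if (cfg$mutation_rate < 0 || cfg$mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)")
  stopifnot(cfg$h2 > 0, cfg$h2 < 1, cfg$sigma2_g > 0, cfg$sigma2_e >= 0,
            cfg$male_replacement > 0, cfg$male_replacement <= 1,
            cfg$female_replacement > 0, cfg$female_replacement <= 1,
            cfg$sex_ratio > 0, cfg$sex_ratio < 1)
  invisible(cfg)
}

#' Desk-scale study configuration
#'
#' The scaled counterpart of the full design used throughout the package's
#' tests and examples: 2 chromosomes of 100 cM carrying a 4000-SNP panel and
#' 40 QTL, a historical phase sized to reach strong adjacent-marker LD at
#' this marker spacing, 250 sires x 2500 dams, and four generations of
#' selection, so G3 supports a 2000-animal training set and G4 a 1000-animal
#' validation set.
#'
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
scaled_sim_config <- function(...) {
  defaults <- list(
    n_chromosomes = 2, chrom_length_cM = 100,
    n_markers = 4000, n_qtl = 40,
    marker_oversample = 9, qtl_oversample = 10,
    hist_generations = 150, hist_size = 45,
    expand_generations = 15,
    expand_size_start = 2000, expand_size_end = 2830,
    n_males = 250, n_females = 2500
  )
  dots <- list(...)
  dots <- dots[!duplicated(names(dots), fromLast = TRUE)]
  do.call(sim_config, modifyList(defaults, dots))
}

#' Read a simulation configuration from a YAML file
#'
#' Field names mirror the arguments of [sim_config()].
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}
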