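#' @title Forward-in-time population simulation
#' @description Internal constructor for haplotype populations.
#' @noRd
new_haplo_pop <- function(haplotypes, pedigree, genome) {
  stopifnot(is.raw(haplotypes), nrow(haplotypes) == nrow(genome$loci),
            ncol(haplotypes) == 2L * nrow(pedigree))
  structure(list(haplotypes = haplotypes, pedigree = pedigree,
                 genome = genome), class = "haplo_pop")
}

#' @export
print.haplo_pop <- function(x, ...) {
  gens <- table(x$pedigree$generation)
  cat(sprintf("<haplo_pop> %d animals, %d loci; generations: %s\n",
              nrow(x$pedigree), nrow(x$genome$loci),
              paste(sprintf("%s(%d)", names(gens), gens), collapse = " ")))
  invisible(x)
}

#' Extract allele dosages from a haplotype population
#'
#' @param pop a `haplo_pop`.
#' @param ids animal ids (default all).
#' @param loci `"markers"`, `"qtl"`, `"all"`, or a vector of locus ids.
#' @return numeric matrix (animals x loci) of 0/1/2 dosages with dimnames.
#' @export
dosages <- function(pop, ids = NULL, loci = "markers") {
  stopifnot(inherits(pop, "haplo_pop"))
  if (is.null(ids)) ids <- pop$pedigree$id
  idx <- if (identical(loci, "markers")) pop$genome$marker_idx
         else if (identical(loci, "qtl")) pop$genome$qtl_idx
         else if (identical(loci, "all")) seq_len(nrow(pop$genome$loci))
         else match(loci, pop$genome$loci$id)
  if (anyNA(idx)) stop("unknown locus ids requested")
  out <- cpp_dosage(pop$haplotypes, as.integer(ids) - 1L,
                    as.integer(idx) - 1L)
  dimnames(out) <- list(as.character(ids), pop$genome$loci$id[idx])
  out
}

#' One meiosis under the Haldane model
#'
#' Generates a recombinant gamete from a pair of parental haplotypes: per
#' chromosome, the crossover count is Poisson(map length in Morgans),
#' crossover positions are uniform (no interference), and the starting
#' parental strand is chosen uniformly.
#'
#' @param parent_haplotypes matrix with one row per locus and two columns
#'   (the parental haplotype pair), 0/1 coded.
#' @param genome a [genome_spec()] covering the same loci, in order.
#' @param mutation_rate per-locus allele-flip probability applied to the
#'   gamete.
#' @return integer vector (one allele per locus).
#' @export
meiosis <- function(parent_haplotypes, genome, mutation_rate = 0) {
  stopifnot(is.matrix(parent_haplotypes), ncol(parent_haplotypes) == 2L,
            nrow(parent_haplotypes) == nrow(genome$loci))
  h <- matrix(as.raw(parent_haplotypes), nrow(parent_haplotypes), 2L)
  m <- genome_cpp_map(genome)
  g <- cpp_gametes(h, 0L, m$pos_M, m$chrom_off, m$chrom_len_M, mutation_rate)
  as.integer(g[, 1L])
}

#' Historical random-mating phase
#'
#' Initializes every candidate locus at allele frequency 0.5 in linkage
#' equilibrium and evolves the population by discrete-generation random
#' mating (distinct random parents per offspring) with recurrent biallelic
#' mutation, first at constant size `hist_size` for `hist_generations`
#' generations, then through a linear expansion to `expand_size_end` over
#' `expand_generations` generations. Drift in the finite population is what
#' builds linkage disequilibrium between nearby loci and spreads allele
#' frequencies away from 0.5. At the end, the marker panel (`n_markers`
#' loci with MAF >= `marker_maf_min`, thinned evenly from the oversampled
#' candidates) and the QTL set (`n_qtl` drawn from candidates with MAF >=
#' `qtl_maf_min`) are fixed, and only those loci are carried forward.
#'
#' @param config a [sim_config()].
#' @param rng_seed integer seed for this stage.
#' @return A `haplo_pop` holding the final historical generation, with the
#'   finalized `genome_spec` attached and the per-locus allele frequencies in
#'   attribute `freq`.
#' @export
run_historical <- function(config, rng_seed = config$seed) {
  validate_sim_config(config)
  set.seed(as.integer(rng_seed))
  n_mark_cand <- as.integer(ceiling(config$n_markers * config$marker_oversample))
  n_qtl_cand <- as.integer(ceiling(config$n_qtl * config$qtl_oversample))
  genome_cand <- place_candidate_loci(config$n_chromosomes,
                                      config$chrom_length_cM,
                                      n_mark_cand, n_qtl_cand)
  map <- genome_cpp_map(genome_cand)
  L <- nrow(genome_cand$loci)
  if (L == 0L) stop("degenerate config: no loci")
  sizes <- c(rep(config$hist_size, config$hist_generations),
             if (config$expand_generations > 0L)
               round(seq(config$expand_size_start, config$expand_size_end,
                         length.out = config$expand_generations)))
  if (any(sizes < 2)) stop("degenerate config: historical size below 2")

  n0 <- sizes[1L]
  haps <- matrix(as.raw(rbinom(L * 2L * n0, 1L, 0.5)), L, 2L * n0)
  n_cur <- n0
  for (g in seq_along(sizes)) {
    n_next <- sizes[min(g + 1L, length(sizes))]
    if (g == length(sizes)) break
    s <- sample.int(n_cur, n_next, replace = TRUE)
    d <- sample.int(n_cur, n_next, replace = TRUE)
    clash <- which(s == d)
    while (length(clash) > 0L) {
      d[clash] <- sample.int(n_cur, length(clash), replace = TRUE)
      clash <- clash[s[clash] == d[clash]]
    }
    haps <- cpp_mate(haps, s - 1L, d - 1L, map$pos_M, map$chrom_off,
                     map$chrom_len_M, config$mutation_rate)
    n_cur <- n_next
  }

  freq <- cpp_allele_freq(haps, seq_len(n_cur) - 1L)
  maf <- pmin(freq, 1 - freq)
  is_marker <- genome_cand$loci$type == "marker"
  mark_ok <- which(is_marker & maf >= config$marker_maf_min)
  qtl_ok <- which(!is_marker & maf >= config$qtl_maf_min)
  if (length(mark_ok) < config$n_markers)
    stop(sprintf(paste0("only %d of %d candidate markers segregate at MAF >= %g;",
                        " increase marker_oversample"),
                 length(mark_ok), n_mark_cand, config$marker_maf_min))
  if (length(qtl_ok) < config$n_qtl)
    stop(sprintf(paste0("only %d of %d candidate QTL segregate at MAF >= %g;",
                        " increase qtl_oversample"),
                 length(qtl_ok), n_qtl_cand, config$qtl_maf_min))
  mark_sel <- mark_ok[unique(round(seq(1, length(mark_ok),
                                       length.out = config$n_markers)))]
  qtl_sel <- sort(sample(qtl_ok, config$n_qtl))
  keep <- sort(c(mark_sel, qtl_sel))
  loci <- genome_cand$loci[keep, , drop = FALSE]
  genome <- genome_spec(config$n_chromosomes, genome_cand$chrom_length_cM,
                        markers = loci[loci$type == "marker", ],
                        qtl = loci[loci$type == "qtl", ])
  ped <- data.frame(id = seq_len(n_cur), sire = 0L, dam = 0L,
                    generation = -1L, sex = 0L, genotyped = FALSE)
  pop <- new_haplo_pop(haps[keep, , drop = FALSE], ped, genome)
  attr(pop, "freq") <- freq[keep]
  pop
}

#' Found generation zero from the historical population
#'
#' Samples `n_males + n_females` animals from the final historical
#' generation (without replacement when enough animals are available,
#' otherwise with replacement), assigns sexes, and tags them as generation
#' 0. Mating of these founders is random; no selection is applied at this
#' step.
#'
#' @param historical `haplo_pop` from [run_historical()].
#' @param n_males,n_females founder counts.
#' @param rng_seed integer seed.
#' @param replace sample with replacement; defaults to TRUE only when the
#'   historical generation is smaller than the founder count.
#' @return A `haplo_pop` of the founders (generation 0).
#' @export
found_population <- function(historical, n_males, n_females,
                             rng_seed = 1L,
                             replace = nrow(historical$pedigree) < n_males + n_females) {
  stopifnot(inherits(historical, "haplo_pop"), n_males >= 1, n_females >= 1)
  set.seed(as.integer(rng_seed))
  n <- n_males + n_females
  n_hist <- nrow(historical$pedigree)
  if (!replace && n_hist < n)
    stop(sprintf("historical generation has %d animals but %d founders requested without replacement",
                 n_hist, n))
  pick <- sample.int(n_hist, n, replace = replace)
  cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  sex <- sample(rep(c(1L, 2L), c(n_males, n_females)))
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L, generation = 0L,
                    sex = sex, genotyped = FALSE)
  new_haplo_pop(historical$haplotypes[, cols, drop = FALSE], ped,
                historical$genome)
}

#' EBV computation and truncation selection of replacements
#'
#' Computes breeding values for all animals (pedigree animal-model BLUP with
#' the known variance ratio, or own phenotype under `selection =
#' "phenotypic"`) and updates the breeding sets: the bottom
#' `male_replacement` fraction of the current sires and `female_replacement`
#' fraction of the dams are culled on EBV and replaced by the top young
#' males/females of the candidate cohort.
#'
#' @param pop `haplo_pop` covering all animals so far.
#' @param phenotypes numeric vector aligned with `pop$pedigree` (NA allowed).
#' @param sires,dams current breeding-set ids.
#' @param candidates ids of the young cohort eligible as replacements.
#' @param config `sim_config` (supplies replacement rates, h2, selection
#'   mode).
#' @return list with the new `sires`, `dams` and the `ebv` vector.
#' @export
ebv_and_select <- function(pop, phenotypes, sires, dams, candidates, config) {
  ped <- pop$pedigree
  stopifnot(length(phenotypes) == nrow(ped))
  if (config$selection == "blup") {
    lambda <- (1 - config$h2) / config$h2
    ebv <- blup_ebv(ped, phenotypes, lambda)$ebv
  } else {
    ebv <- phenotypes
  }
  take_top <- function(ids, k) ids[order(ebv[ids], decreasing = TRUE)][seq_len(k)]
  n_m_new <- round(config$male_replacement * length(sires))
  n_f_new <- round(config$female_replacement * length(dams))
  young_m <- candidates[ped$sex[candidates] == 1L]
  young_f <- candidates[ped$sex[candidates] == 2L]
  if (length(young_m) < n_m_new || length(young_f) < n_f_new)
    stop("not enough young animals of the required sex for replacement")
  sires_kept <- take_top(sires, length(sires) - n_m_new)
  dams_kept <- take_top(dams, length(dams) - n_f_new)
  list(sires = c(sires_kept, take_top(young_m, n_m_new)),
       dams = c(dams_kept, take_top(young_f, n_f_new)),
       ebv = ebv)
}

# mean adjacent-marker r2 (within chromosomes) over a sample of animals
mean_adjacent_r2 <- function(pop, ids, max_animals = 1000L) {
  if (length(ids) > max_animals) ids <- sample(ids, max_animals)
  g <- pop$genome
  geno <- dosages(pop, ids, "markers")
  chrom <- g$loci$chrom[g$marker_idx]
  j <- seq_len(ncol(geno) - 1L)
  same <- chrom[j] == chrom[j + 1L]
  r2 <- vapply(j[same], function(k) {
    a <- geno[, k]; b <- geno[, k + 1L]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)^2
  }, numeric(1))
  mean(r2, na.rm = TRUE)
}

#' Run the full population simulation
#'
#' Orchestrates the study design: historical LD-building phase, founder
#' sampling (G0), QTL-effect assignment on founder frequencies, phenotype
#' generation, and `n_select_generations` generations of EBV truncation
#' selection with random mating among the selected parents, one progeny per
#' dam and a 50% sex ratio. Animals in the genotyped generations (G3 and G4
#' by default) are flagged. The residual variance is fixed once from the
#' founder cohort under the configured policy and reused for all later
#' generations. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An object of class `fst_sim`: list with `pop` (all of G0..G4),
#'   `genome`, `trait` (QTL indices/effects, TBV, phenotypes, variance
#'   components), `ld` (mean adjacent-marker r2 at G0), `config`, and the
#'   per-stage `seeds`.
#' @export
run_simulation <- function(config) {
  validate_sim_config(config)
  ngen <- config$n_select_generations
  stages <- c("historical", "founders", "trait",
              if (ngen > 0L) paste0("gen", seq_len(ngen)))
  seeds <- derive_seeds(config$seed, stages)

  hist_pop <- run_historical(config, seeds[["historical"]])
  pop <- found_population(hist_pop, config$n_males, config$n_females,
                          seeds[["founders"]])
  genome <- pop$genome
  map <- genome_cpp_map(genome)
  rm(hist_pop)

  set.seed(seeds[["trait"]])
  n0 <- nrow(pop$pedigree)
  qtl_freq <- as.numeric(colMeans(dosages(pop, loci = "qtl"))) / 2
  effects <- switch(config$qtl_effect_dist,
    gamma = assign_qtl_effects_gamma(qtl_freq, config$gamma_shape,
                                     config$sigma2_g),
    predefined = assign_qtl_effects_predefined(qtl_freq, config$sigma2_g,
                                               config$min_gv_fraction))
  tbv <- as.numeric(dosages(pop, loci = "qtl") %*% effects)
  y <- simulate_phenotypes(tbv, config$residual_policy, config$h2,
                           config$sigma2_e)
  sigma2_e_used <- attr(y, "sigma2_e")
  phen <- as.numeric(y)
  ld_g0 <- mean_adjacent_r2(pop, pop$pedigree$id)

  ped <- pop$pedigree
  haps <- pop$haplotypes
  sires <- ped$id[ped$sex == 1L]
  dams <- ped$id[ped$sex == 2L]

  for (g in seq_len(ngen)) {
    set.seed(seeds[[paste0("gen", g)]])
    n_off <- length(dams)
    sire_of <- sample(sires, n_off, replace = TRUE)
    off_haps <- cpp_mate(haps, sire_of - 1L, dams - 1L, map$pos_M,
                         map$chrom_off, map$chrom_len_M,
                         config$mutation_rate)
    ids <- nrow(ped) + seq_len(n_off)
    new_ped <- data.frame(
      id = ids, sire = sire_of, dam = dams, generation = g,
      sex = 1L + rbinom(n_off, 1L, 1 - config$sex_ratio),
      genotyped = g %in% config$genotyped_generations)
    haps <- cbind(haps, off_haps)
    ped <- rbind(ped, new_ped)
    qd <- cpp_dosage(haps, ids - 1L, genome$qtl_idx - 1L)
    tbv_new <- as.numeric(qd %*% effects)
    tbv <- c(tbv, tbv_new)
    phen <- c(phen, tbv_new + rnorm(n_off, 0, sqrt(sigma2_e_used)))

    if (g < ngen) {
      pop_now <- new_haplo_pop(haps, ped, genome)
      sel <- ebv_and_select(pop_now, phen, sires, dams, ids, config)
      sires <- sel$sires
      dams <- sel$dams
    }
  }

  pop <- new_haplo_pop(haps, ped, genome)
  trait <- structure(list(
    qtl_idx = genome$qtl_idx,
    qtl_ids = genome$loci$id[genome$qtl_idx],
    qtl_effects = effects,
    qtl_freq_g0 = qtl_freq,
    tbv = tbv, phenotype = phen,
    sigma2_g = config$sigma2_g,
    sigma2_g_realized_g0 = var(tbv[seq_len(n0)]),
    sigma2_e = sigma2_e_used,
    h2 = config$h2,
    residual_policy = config$residual_policy
  ), class = "trait_arch")

  structure(list(pop = pop, genome = genome, trait = trait,
                 ld = list(adjacent_r2_g0 = ld_g0),
                 config = config, seeds = as.list(seeds)),
            class = "fst_sim")
}

#' @export
print.fst_sim <- function(x, ...) {
  cat(sprintf(paste0("<fst_sim> %d animals (%d generations of selection), ",
                     "%d markers, %d QTL\n  mean adjacent-marker r2 at G0: %.3f; ",
                     "sigma2_e used: %.3f\n"),
              nrow(x$pop$pedigree), x$config$n_select_generations,
              length(x$genome$marker_idx), length(x$genome$qtl_idx),
              x$ld$adjacent_r2_g0, x$trait$sigma2_e))
  invisible(x)
}

#' Realized heritability of a cohort
#'
#' `100 * Var(TBV) / Var(phenotype)` over the animals of one generation.
#'
#' @param sim an `fst_sim`.
#' @param generation generation index (0 = founders).
#' @return percentage.
#' @export
realized_h2_pct <- function(sim, generation = 0L) {
  sel <- sim$pop$pedigree$generation == generation
  if (!any(sel)) stop("no animals in that generation")
  100 * var(sim$trait$tbv[sel]) / var(sim$trait$phenotype[sel])
}
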