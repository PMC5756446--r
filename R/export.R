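#' Export a simulation to plain-text files
#'
#' Writes, under `dir`: genotype dosages of the genotyped animals
#' (`genotypes.raw` PLINK-raw and, optionally, `genotypes.vcf`), the marker
#' map (`map.tsv`: chrom, id, cM position), the QTL truth table
#' (`qtl.tsv`: position, effect, GV fraction), the per-animal table
#' (`animals.tsv`: id, generation, sex, TBV, phenotype, genotyped), the
#' pedigree (`pedigree.tsv`) and a JSON run manifest.
#'
#' @param sim an `fst_sim` from [run_simulation()].
#' @param dir output directory (created if needed).
#' @param vcf also write a VCF of the genotyped animals.
#' @return `dir`, invisibly.
#' @export
export_simulation <- function(sim, dir, vcf = FALSE) {
  stopifnot(inherits(sim, "fst_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim$pop$pedigree
  g <- sim$genome

  gids <- ped$id[ped$genotyped]
  if (length(gids) > 0L) {
    geno <- dosages(sim$pop, gids, "markers")
    write_dosage(geno, file.path(dir, "genotypes.raw"), "plink_raw")
    if (vcf) {
      mk <- g$loci[g$marker_idx, ]
      write_dosage(geno, file.path(dir, "genotypes.vcf"), "vcf",
                   map = data.frame(chrom = mk$chrom, id = mk$id,
                                    pos = round(mk$pos_cM * 1e4)))
    }
  }
  mk <- g$loci[g$marker_idx, ]
  data.table::fwrite(data.frame(chrom = mk$chrom, id = mk$id,
                                pos_cM = mk$pos_cM),
                     file.path(dir, "map.tsv"), sep = "\t")
  qt <- g$loci[g$qtl_idx, ]
  data.table::fwrite(data.frame(
    chrom = qt$chrom, id = qt$id, pos_cM = qt$pos_cM,
    effect = sim$trait$qtl_effects,
    gv_fraction = qtl_gv_fractions(sim$trait$qtl_effects,
                                   sim$trait$qtl_freq_g0)),
    file.path(dir, "qtl.tsv"), sep = "\t")
  data.table::fwrite(data.frame(
    id = ped$id, generation = ped$generation, sex = ped$sex,
    tbv = sim$trait$tbv, phenotype = sim$trait$phenotype,
    genotyped = ped$genotyped),
    file.path(dir, "animals.tsv"), sep = "\t")
  data.table::fwrite(ped[, c("id", "sire", "dam", "generation", "sex")],
                     file.path(dir, "pedigree.tsv"), sep = "\t")
  write_manifest(file.path(dir, "manifest.json"),
                 config = unclass(sim$config), seeds = sim$seeds,
                 extra = list(adjacent_r2_g0 = sim$ld$adjacent_r2_g0,
                              sigma2_e_used = sim$trait$sigma2_e))
  invisible(dir)
}

#' Read a two-column phenotype TSV (id, value)
#'
#' @param path TSV with a header; first column animal id, second phenotype.
#' @return named numeric vector.
#' @export
read_phenotypes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  if (ncol(df) < 2L) stop("phenotype file needs columns: id, value")
  stats::setNames(as.numeric(df[[2L]]), as.character(df[[1L]]))
}
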