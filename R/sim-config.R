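#' Configuration for the synthetic staygreen mapping experiment
#'
#' Collects every tunable parameter of the synthetic-data generator: the
#' genome layout, the EMS mutation load, the RIL population design, the
#' senescence phenotype model and the sequencing model. Defaults reproduce
#' the experimental design of the mapping study the package implements: an
#' F4 single-seed-descent population of ~96 lines from a biparental cross,
#' a single dominant causal locus delaying onset of senescence by ~8 days,
#' bulks of 17 lines each, and ~20x sequencing depth per bulk.
#'
#' @param n_chromosomes number of chromosomes in the toy genome.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_ems_snps total EMS-induced SNPs across the genome (G:A or C:T
#'   transitions only); includes the single causal SNP when `> 0`.
#' @param n_varietal_snps SNPs fixed between the mutagenized cultivar and
#'   the reference assembly; carried at dosage 2 by every line.
#' @param causal_chrom,causal_pos location of the causal EMS SNP.
#' @param n_rils number of recombinant inbred lines.
#' @param generation selfing generation (4 = F4); must be >= 2.
#' @param dominance `"dominant"`, `"semi_dominant"` or `"recessive"`:
#'   phenotype of heterozygotes relative to the mutant homozygote.
#' @param onset_delay_days delay of senescence onset in the mutant relative
#'   to wild type, in calendar days (converted to thermal time internally).
#' @param bulk_size_sg,bulk_size_nsg bulk sizes (staygreen / non-staygreen).
#' @param include_heterozygotes if `TRUE`, phenotypically staygreen
#'   heterozygotes are eligible for the staygreen bulk; default restricts
#'   bulks to homozygotes, the selection under which complete enrichment
#'   (delta SNP index = 1) is attainable.
#' @param misclassification_rate probability that a bulk slot is filled by
#'   a line of the opposite phenotypic class.
#' @param depth_mean mean sequencing depth per site per sample.
#' @param depth_model `"poisson"` or `"negative_binomial"`.
#' @param nb_dispersion size parameter of the negative binomial depth model.
#' @param depth_min minimum depth per site per sample; draws below it are
#'   clamped so that every emitted variant site is observed in every sample
#'   (called variant sites have coverage by construction).
#' @param seq_error per-read probability that the observed allele is
#'   flipped.
#' @param cm_per_mb genetic:physical map ratio used to place crossovers.
#' @param t50_wt thermal time (day degC after GS55) at which the wild-type
#'   senescence score reaches 50.
#' @param sen_rate logistic rate of senescence progression per day degC;
#'   identical for mutant and wild type (the mutation delays onset, not
#'   rate).
#' @param t50_noise_sd plot-level Gaussian noise on the senescence midpoint
#'   in day degC.
#' @param obs_interval_days days between visual scorings (protocol: every
#'   2-4 d).
#' @param season_days length of the scoring window after GS55, days.
#' @param qual_range range of simulated VCF site qualities.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_ems_snps = 50, n_rils = 20)
#' cfg$generation
#' @export
sim_config <- function(n_chromosomes = 5,
                       chrom_length_bp = 2e8,
                       n_ems_snps = 500,
                       n_varietal_snps = 200,
                       causal_chrom = 3,
                       causal_pos = 1e8,
                       n_rils = 96,
                       generation = 4,
                       dominance = c("dominant", "semi_dominant", "recessive"),
                       onset_delay_days = 8,
                       bulk_size_sg = 17,
                       bulk_size_nsg = 17,
                       include_heterozygotes = FALSE,
                       misclassification_rate = 0,
                       depth_mean = 20,
                       depth_model = c("poisson", "negative_binomial"),
                       nb_dispersion = 5,
                       depth_min = 1,
                       seq_error = 0.001,
                       cm_per_mb = 1,
                       t50_wt = 600,
                       sen_rate = 0.012,
                       t50_noise_sd = 15,
                       obs_interval_days = 3,
                       season_days = 80,
                       qual_range = c(30, 60)) {
  dominance <- match.arg(dominance)
  depth_model <- match.arg(depth_model)
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.numeric(chrom_length_bp),
    n_ems_snps = as.integer(n_ems_snps),
    n_varietal_snps = as.integer(n_varietal_snps),
    causal_chrom = as.integer(causal_chrom),
    causal_pos = as.numeric(causal_pos),
    n_rils = as.integer(n_rils),
    generation = as.integer(generation),
    dominance = dominance,
    onset_delay_days = as.numeric(onset_delay_days),
    bulk_size_sg = as.integer(bulk_size_sg),
    bulk_size_nsg = as.integer(bulk_size_nsg),
    include_heterozygotes = isTRUE(include_heterozygotes),
    misclassification_rate = as.numeric(misclassification_rate),
    depth_mean = as.numeric(depth_mean),
    depth_model = depth_model,
    nb_dispersion = as.numeric(nb_dispersion),
    depth_min = as.integer(depth_min),
    seq_error = as.numeric(seq_error),
    cm_per_mb = as.numeric(cm_per_mb),
    t50_wt = as.numeric(t50_wt),
    sen_rate = as.numeric(sen_rate),
    t50_noise_sd = as.numeric(t50_noise_sd),
    obs_interval_days = as.numeric(obs_interval_days),
    season_days = as.integer(season_days),
    qual_range = as.numeric(qual_range)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c("n_chromosomes", "chrom_length_bp", "n_ems_snps",
              "n_varietal_snps", "n_rils", "bulk_size_sg", "bulk_size_nsg",
              "season_days", "depth_min")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0)
      stop("sim_config: `", f, "` must be a non-negative count", call. = FALSE)
  }
  probs <- c("misclassification_rate", "seq_error")
  for (f in probs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: `", f, "` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$causal_chrom < 1 || cfg$causal_chrom > cfg$n_chromosomes)
    stop("sim_config: `causal_chrom` outside the genome", call. = FALSE)
  if (cfg$causal_pos < 1 || cfg$causal_pos > cfg$chrom_length_bp)
    stop("sim_config: `causal_pos` must satisfy 1 <= causal_pos <= chrom_length_bp",
         call. = FALSE)
  if (cfg$generation < 2)
    stop("sim_config: `generation` must be >= 2 (F2 or later)", call. = FALSE)
  if (cfg$depth_mean <= 0 || cfg$cm_per_mb <= 0 || cfg$sen_rate <= 0)
    stop("sim_config: depth_mean, cm_per_mb and sen_rate must be positive",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic staygreen mapping experiment\n")
  cat(sprintf("  genome     : %d chromosomes x %.0f Mb, %d EMS + %d varietal SNPs\n",
              x$n_chromosomes, x$chrom_length_bp / 1e6,
              x$n_ems_snps, x$n_varietal_snps))
  cat(sprintf("  causal SNP : chr%d:%.0f (%s, onset delayed %g d)\n",
              x$causal_chrom, x$causal_pos, x$dominance, x$onset_delay_days))
  cat(sprintf("  population : %d F%d RILs by single seed descent\n",
              x$n_rils, x$generation))
  cat(sprintf("  bulks      : SG n=%d, NSG n=%d (misclassification %.3f)\n",
              x$bulk_size_sg, x$bulk_size_nsg, x$misclassification_rate))
  cat(sprintf("  sequencing : %s depth, mean %g, error %g\n",
              x$depth_model, x$depth_mean, x$seq_error))
  invisible(x)
}
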