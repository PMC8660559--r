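#' Simulate the genetic architecture of an EMS mutagenesis experiment
#'
#' Draws SNP positions and alleles for a toy genome. EMS-induced mutations
#' are restricted to the canonical alkylation spectrum, G>A and C>T
#' transitions; varietal SNPs (fixed differences between the mutagenized
#' cultivar and the reference assembly) may be any substitution. Exactly
#' one EMS SNP, placed at `causal_chrom:causal_pos`, is flagged
#' `ems_causal` whenever `n_ems_snps > 0`.
#'
#' @param config a [sim_config()].
#' @return a data.frame with columns `chrom`, `pos`, `ref`, `alt`, `class`
#'   (`ems_causal`, `ems_background` or `varietal`), sorted by chromosome
#'   then position, positions unique within chromosome.
#' @examples
#' set.seed(1)
#' snps <- simulate_genetic_architecture(sim_config(n_ems_snps = 20,
#'                                                  n_varietal_snps = 5))
#' table(snps$class)
#' @export
simulate_genetic_architecture <- function(config) {
  validate_sim_config(config)
  n_total <- config$n_ems_snps + config$n_varietal_snps
  if (n_total == 0) {
    return(data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      class = character(), stringsAsFactors = FALSE))
  }
  if (n_total > config$n_chromosomes * config$chrom_length_bp)
    stop("more SNPs requested than available genome positions", call. = FALSE)

  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  # spread non-causal SNPs uniformly over chromosomes
  n_free <- n_total - (config$n_ems_snps > 0)
  chrom_of <- sample(chroms, n_free, replace = TRUE)
  rows <- vector("list", config$n_chromosomes)
  causal_chrom <- chroms[config$causal_chrom]
  for (i in seq_len(config$n_chromosomes)) {
    n_here <- sum(chrom_of == chroms[i])
    pos <- sample.int(config$chrom_length_bp, n_here, replace = FALSE)
    if (chroms[i] == causal_chrom && config$n_ems_snps > 0) {
      pos <- pos[pos != config$causal_pos]
      pos <- c(pos, config$causal_pos)
    }
    rows[[i]] <- data.frame(chrom = chroms[i], pos = pos,
                            stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, rows)

  # assign classes: the causal SNP first, then background EMS, then varietal
  snps$class <- "unassigned"
  is_causal <- snps$chrom == causal_chrom & snps$pos == config$causal_pos
  if (config$n_ems_snps > 0) snps$class[is_causal] <- "ems_causal"
  free_idx <- which(snps$class == "unassigned")
  free_idx <- sample(free_idx)  # random interleaving of classes
  n_bg <- config$n_ems_snps - (config$n_ems_snps > 0)
  snps$class[free_idx[seq_len(n_bg)]] <- "ems_background"
  if (config$n_varietal_snps > 0)
    snps$class[free_idx[n_bg + seq_len(config$n_varietal_snps)]] <- "varietal"

  bases <- c("A", "C", "G", "T")
  n <- nrow(snps)
  snps$ref <- character(n)
  snps$alt <- character(n)
  ems <- snps$class %in% c("ems_causal", "ems_background")
  ems_ref <- sample(c("G", "C"), sum(ems), replace = TRUE)
  snps$ref[ems] <- ems_ref
  snps$alt[ems] <- ifelse(ems_ref == "G", "A", "T")
  if (any(!ems)) {
    var_ref <- sample(bases, sum(!ems), replace = TRUE)
    var_alt <- vapply(var_ref, function(b) sample(setdiff(bases, b), 1), "")
    snps$ref[!ems] <- var_ref
    snps$alt[!ems] <- var_alt
  }

  snps <- snps[order(match(snps$chrom, chroms), snps$pos), ]
  rownames(snps) <- NULL
  snps[, c("chrom", "pos", "ref", "alt", "class")]
}

# one meiosis over a set of ordered loci on a single chromosome.
# haps: 2 x n_loci matrix of 0/1; cm: locus positions in centimorgans.
# Crossover count is Poisson in map length (no interference), placement
# uniform, so recombination between loci follows Haldane's model at
# generation time; Kosambi is used only at estimation time.
.gamete <- function(haps, cm) {
  n <- length(cm)
  L <- cm[n] - cm[1]
  n_xo <- if (L > 0) stats::rpois(1L, L / 100) else 0L
  start <- sample.int(2L, 1L)
  if (n_xo == 0L) return(haps[start, ])
  breaks <- sort(stats::runif(n_xo, min = cm[1], max = cm[n]))
  seg <- findInterval(cm, breaks)
  pick <- (seg + start) %% 2L + 1L
  haps[cbind(pick, seq_len(n))]
}

#' Simulate an F_g RIL population by single seed descent
#'
#' Each line descends from a fully heterozygous F1 through
#' `generation - 1` rounds of self-fertilization, one offspring kept per
#' generation. Crossovers per meiosis are Poisson in map length with
#' uniform placement (no interference); physical positions are converted
#' to map positions at `cm_per_mb`. At unlinked loci the expected
#' heterozygote fraction at F_g is (1/2)^(g-1).
#'
#' @param truth SNP table from [simulate_genetic_architecture()].
#' @param config a [sim_config()].
#' @return integer matrix (`n_rils` x n SNPs) of mutant-allele dosages
#'   0/1/2, columns named `chrom_pos` in the row order of `truth`;
#'   varietal SNPs carry dosage 2 in every line.
#' @export
simulate_ril_population <- function(truth, config) {
  validate_sim_config(config)
  if (config$generation < 2)
    stop("generation must be >= 2", call. = FALSE)
  n_snp <- nrow(truth)
  ids <- sprintf("RIL%03d", seq_len(config$n_rils))
  geno <- matrix(2L, nrow = config$n_rils, ncol = n_snp,
                 dimnames = list(ids, paste(truth$chrom,
                                            format(truth$pos, scientific = FALSE,
                                                   trim = TRUE), sep = "_")))
  seg <- truth$class != "varietal"   # only EMS loci segregate
  if (!any(seg) || config$n_rils == 0) {
    return(geno)
  }
  seg_chrom <- truth$chrom[seg]
  seg_cm <- truth$pos[seg] * config$cm_per_mb / 1e6
  by_chrom <- split(seq_len(sum(seg)), seg_chrom)
  dosage <- matrix(0L, nrow = config$n_rils, ncol = sum(seg))
  for (loci in by_chrom) {
    cm <- seg_cm[loci]
    o <- order(cm)
    cm_o <- cm[o]
    n_loci <- length(loci)
    for (r in seq_len(config$n_rils)) {
      haps <- rbind(rep(1L, n_loci), rep(0L, n_loci))  # F1: mutant x wt
      for (g in seq_len(config$generation - 1L)) {
        haps <- rbind(.gamete(haps, cm_o), .gamete(haps, cm_o))
      }
      dosage[r, loci[o]] <- haps[1L, ] + haps[2L, ]
    }
  }
  geno[, seg] <- dosage
  geno
}

#' Phenotype class implied by causal dosage and dominance
#'
#' @param dosage integer vector of mutant-allele dosages at the causal SNP.
#' @param dominance dominance model of the mutant allele.
#' @return character vector: `"staygreen"`, `"non_staygreen"` or
#'   `"intermediate"` (heterozygotes under the semi-dominant model).
#' @export
phenotype_class <- function(dosage,
                            dominance = c("dominant", "semi_dominant",
                                          "recessive")) {
  dominance <- match.arg(dominance)
  het <- switch(dominance,
                dominant = "staygreen",
                semi_dominant = "intermediate",
                recessive = "non_staygreen")
  out <- rep("non_staygreen", length(dosage))
  out[dosage == 2L] <- "staygreen"
  out[dosage == 1L] <- het
  out
}

#' Select staygreen and non-staygreen bulks from the simulated truth
#'
#' Default selection mirrors the design under which complete enrichment is
#' attainable: only homozygous lines enter bulks (mutant homozygotes into
#' the staygreen bulk, wild-type homozygotes into the non-staygreen bulk).
#' With `include_heterozygotes = TRUE`, heterozygotes whose phenotype class
#' matches a bulk are also eligible. `misclassification_rate` swaps each
#' selected slot, independently, for a random line of the opposite
#' homozygous class.
#'
#' @param genotypes dosage matrix from [simulate_ril_population()].
#' @param truth SNP table from [simulate_genetic_architecture()].
#' @param config a [sim_config()].
#' @return list with character vectors `sg` and `nsg` of RIL ids.
#' @export
select_sim_bulks <- function(genotypes, truth, config) {
  causal <- which(truth$class == "ems_causal")
  if (length(causal) != 1L)
    stop("truth table must contain exactly one ems_causal SNP", call. = FALSE)
  dos <- genotypes[, causal]
  cls <- phenotype_class(dos, config$dominance)
  sg_pool <- if (config$include_heterozygotes) {
    names(dos)[cls == "staygreen"]
  } else names(dos)[dos == 2L]
  nsg_pool <- if (config$include_heterozygotes) {
    names(dos)[cls == "non_staygreen" & dos != 1L]
  } else names(dos)[dos == 0L]
  if (length(sg_pool) < config$bulk_size_sg ||
      length(nsg_pool) < config$bulk_size_nsg)
    stop(sprintf(
      "not enough eligible RILs for bulks (SG pool %d < %d or NSG pool %d < %d)",
      length(sg_pool), config$bulk_size_sg,
      length(nsg_pool), config$bulk_size_nsg), call. = FALSE)
  sg <- sample(sg_pool, config$bulk_size_sg)
  nsg <- sample(nsg_pool, config$bulk_size_nsg)
  if (config$misclassification_rate > 0) {
    flip_sg <- stats::runif(length(sg)) < config$misclassification_rate
    flip_nsg <- stats::runif(length(nsg)) < config$misclassification_rate
    wrong_sg <- setdiff(nsg_pool, nsg)
    wrong_nsg <- setdiff(sg_pool, sg)
    k_sg <- min(sum(flip_sg), length(wrong_sg))
    k_nsg <- min(sum(flip_nsg), length(wrong_nsg))
    if (k_sg > 0)
      sg[which(flip_sg)[seq_len(k_sg)]] <- sample(wrong_sg, k_sg)
    if (k_nsg > 0)
      nsg[which(flip_nsg)[seq_len(k_nsg)]] <- sample(wrong_nsg, k_nsg)
  }
  list(sg = sg, nsg = nsg)
}

#' Simulate a daily temperature series for the scoring season
#'
#' Daily minima and maxima around a mid-June UK baseline (mean ~16 degC)
#' with a mild warming trend across the season and day-to-day noise.
#'
#' @param config a [sim_config()]; `season_days` sets the length.
#' @param start_date calendar date of GS55 (ear emergence) plus one day.
#' @return data.frame with columns `date`, `tmin`, `tmax`.
#' @export
simulate_temperature_series <- function(config,
                                        start_date = as.Date("2017-06-02")) {
  n <- config$season_days
  day <- seq_len(n)
  base <- 16 + 0.03 * day
  tmin <- base - 5 + stats::rnorm(n, 0, 1.5)
  tmax <- base + 5 + stats::rnorm(n, 0, 1.5)
  tmax <- pmax(tmax, tmin)  # invariant: tmax >= tmin
  data.frame(date = start_date + day - 1L,
             tmin = round(tmin, 1), tmax = round(tmax, 1))
}

#' Simulate plot-level senescence score time courses
#'
#' Each line senesces along a logistic curve
#' `score(t) = 100 / (1 + exp(-k (t - t50)))` in thermal time t (day degC
#' after GS55), snapped to the visual 0-100 scale in steps of 5. The
#' causal mutation shifts `t50` by `onset_delay_days` (converted to
#' thermal time at the series' mean daily temperature) for mutant
#' homozygotes; heterozygotes shift fully, by half, or not at all under
#' the dominant, semi-dominant and recessive models. Plot-level Gaussian
#' noise (`t50_noise_sd`) acts on the midpoint. Scoring occurs every
#' `obs_interval_days` days, as in a 2-4 d visual scoring protocol.
#'
#' @param genotypes dosage matrix from [simulate_ril_population()], or an
#'   integer vector of causal dosages named by line.
#' @param truth SNP table (needed to locate the causal SNP when a matrix
#'   is given); ignored for a dosage vector.
#' @param config a [sim_config()].
#' @param temps temperature series from [simulate_temperature_series()].
#' @return data.frame with columns `plot`, `day` (days after GS55),
#'   `thermal_time` (day degC), `score`.
#' @export
simulate_senescence_timecourse <- function(genotypes, truth, config, temps) {
  if (is.null(temps) || nrow(temps) == 0)
    stop("empty temperature series", call. = FALSE)
  if (is.matrix(genotypes)) {
    causal <- which(truth$class == "ems_causal")
    if (length(causal) != 1L)
      stop("truth table must contain exactly one ems_causal SNP", call. = FALSE)
    dos <- genotypes[, causal]
  } else {
    dos <- genotypes
    if (is.null(names(dos))) names(dos) <- sprintf("RIL%03d", seq_along(dos))
  }
  daily_mean <- pmax(0, (temps$tmin + temps$tmax) / 2)
  tt <- cumsum(daily_mean)                     # thermal time at day 1, 2, ...
  delay_tt <- config$onset_delay_days * mean(daily_mean)
  het_frac <- switch(config$dominance,
                     dominant = 1, semi_dominant = 0.5, recessive = 0)
  shift <- ifelse(dos == 2L, 1, ifelse(dos == 1L, het_frac, 0)) * delay_tt
  t50 <- config$t50_wt + shift + stats::rnorm(length(dos), 0, config$t50_noise_sd)

  obs_days <- seq(0, config$season_days, by = config$obs_interval_days)
  obs_tt <- c(0, tt)[obs_days + 1L]
  out <- do.call(rbind, lapply(seq_along(dos), function(i) {
    raw <- 100 / (1 + exp(-config$sen_rate * (obs_tt - t50[i])))
    score <- pmin(100, pmax(0, 5 * round(raw / 5)))
    data.frame(plot = names(dos)[i], day = obs_days,
               thermal_time = obs_tt, score = score,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate pooled sequencing read counts for bulks and parents
#'
#' The alternate-allele frequency of a bulk at a SNP is the mean
#' mutant-allele dosage of its member lines divided by 2. Total depth DP is
#' drawn per SNP per sample from the configured depth model (clamped at
#' `depth_min`); the alternate-read count DV is Binomial(DP, p) with
#' p = freq (1 - e) + (1 - freq) e for sequencing error e. Records are
#' emitted for both bulks and both parents; the mutant parent carries every
#' EMS SNP at dosage 2, both parents carry every varietal SNP at dosage 2.
#'
#' @param truth SNP table from [simulate_genetic_architecture()].
#' @param genotypes dosage matrix from [simulate_ril_population()].
#' @param bulks list with RIL id vectors `sg` and `nsg`.
#' @param config a [sim_config()].
#' @return data.frame of variant records: `chrom`, `pos`, `ref`, `alt`,
#'   `qual`, and `DP.*` / `DV.*` columns for samples `SG_bulk`,
#'   `NSG_bulk`, `mutant_parent`, `wt_parent`; sample names in
#'   `attr(, "samples")`.
#' @export
simulate_bulk_readcounts <- function(truth, genotypes, bulks, config) {
  if (length(bulks$sg) == 0 || length(bulks$nsg) == 0)
    stop("empty bulk", call. = FALSE)
  missing_ids <- setdiff(c(bulks$sg, bulks$nsg), rownames(genotypes))
  if (length(missing_ids) > 0)
    stop("bulk members absent from genotype matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  n <- nrow(truth)
  freq <- cbind(
    SG_bulk = colMeans(genotypes[bulks$sg, , drop = FALSE]) / 2,
    NSG_bulk = colMeans(genotypes[bulks$nsg, , drop = FALSE]) / 2,
    mutant_parent = rep(1, n),  # all EMS + varietal SNPs at dosage 2
    wt_parent = ifelse(truth$class == "varietal", 1, 0)
  )
  e <- config$seq_error
  rec <- data.frame(chrom = truth$chrom, pos = truth$pos,
                    ref = truth$ref, alt = truth$alt,
                    qual = round(stats::runif(n, config$qual_range[1],
                                              config$qual_range[2]), 1),
                    stringsAsFactors = FALSE)
  for (s in colnames(freq)) {
    dp <- switch(config$depth_model,
                 poisson = stats::rpois(n, config$depth_mean),
                 negative_binomial = stats::rnbinom(
                   n, size = config$nb_dispersion, mu = config$depth_mean))
    dp <- pmax(config$depth_min, dp)
    p <- freq[, s] * (1 - e) + (1 - freq[, s]) * e
    dv <- stats::rbinom(n, dp, p)
    rec[[paste0("DP.", s)]] <- dp
    rec[[paste0("DV.", s)]] <- dv
  }
  attr(rec, "samples") <- colnames(freq)
  rec
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper chaining architecture, RIL descent, bulk selection,
#' senescence phenotyping (optionally over several seasons) and pooled
#' read sampling. All randomness flows from the current RNG state; call
#' `set.seed()` first for reproducibility.
#'
#' @param config a [sim_config()].
#' @param n_years number of simulated scoring seasons.
#' @param phenology simulate senescence time courses? (Disable for speed
#'   when only the sequencing side is needed.)
#' @return object of class `staygreen_sim`: list with `config`, `truth`
#'   (SNP table), `genotypes`, `phenotype_class`, `bulks`, `records`, and
#'   (if requested) `temps` and `timecourses`, each a list per year.
#' @examples
#' set.seed(7)
#' sim <- simulate_experiment(sim_config(n_ems_snps = 60, n_varietal_snps = 20,
#'                                       n_rils = 40, bulk_size_sg = 6,
#'                                       bulk_size_nsg = 6), phenology = FALSE)
#' names(sim)
#' @export
simulate_experiment <- function(config = sim_config(), n_years = 2,
                                phenology = TRUE) {
  validate_sim_config(config)
  truth <- simulate_genetic_architecture(config)
  genotypes <- simulate_ril_population(truth, config)
  causal <- which(truth$class == "ems_causal")
  cls <- phenotype_class(genotypes[, causal], config$dominance)
  names(cls) <- rownames(genotypes)
  bulks <- select_sim_bulks(genotypes, truth, config)
  out <- list(config = config, truth = truth, genotypes = genotypes,
              phenotype_class = cls, bulks = bulks)
  if (phenology) {
    out$temps <- list()
    out$timecourses <- list()
    for (y in seq_len(n_years)) {
      start <- as.Date(sprintf("%d-06-02", 2016L + y))
      temps <- simulate_temperature_series(config, start_date = start)
      out$temps[[as.character(2016L + y)]] <- temps
      out$timecourses[[as.character(2016L + y)]] <-
        simulate_senescence_timecourse(genotypes, truth, config, temps)
    }
  }
  out$records <- simulate_bulk_readcounts(truth, genotypes, bulks, config)
  class(out) <- "staygreen_sim"
  out
}

#' @export
print.staygreen_sim <- function(x, ...) {
  cat("Simulated staygreen mapping experiment\n")
  cat(sprintf("  %d SNPs (%d EMS, %d varietal), %d RILs (F%d)\n",
              nrow(x$truth), sum(x$truth$class != "varietal"),
              sum(x$truth$class == "varietal"),
              nrow(x$genotypes), x$config$generation))
  causal <- x$truth[x$truth$class == "ems_causal", , drop = FALSE]
  if (nrow(causal) == 1)
    cat(sprintf("  causal SNP %s_%d (%s>%s), bulks SG n=%d / NSG n=%d\n",
                causal$chrom, causal$pos, causal$ref, causal$alt,
                length(x$bulks$sg), length(x$bulks$nsg)))
  if (!is.null(x$timecourses))
    cat(sprintf("  phenology: %d season(s) scored\n", length(x$timecourses)))
  invisible(x)
}
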