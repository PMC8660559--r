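test_that("genetic architecture respects the EMS mutation spectrum", {
  set.seed(1)
  cfg <- sim_config(n_ems_snps = 100, n_varietal_snps = 30)
  snps <- simulate_genetic_architecture(cfg)
  ems <- snps[snps$class != "varietal", ]
  expect_equal(nrow(ems), 100)
  expect_true(all(paste(ems$ref, ems$alt) %in% c("G A", "C T")))
  expect_equal(sum(snps$class == "ems_causal"), 1)
  causal <- snps[snps$class == "ems_causal", ]
  expect_equal(causal$chrom, "chr3")
  expect_equal(causal$pos, cfg$causal_pos)
  # positions unique and sorted within chromosome
  for (chr in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == chr]
    expect_false(is.unsorted(p, strictly = TRUE))
  }
})

test_that("architecture edge cases: empty genome, determinism, overflow", {
  cfg0 <- sim_config(n_ems_snps = 0, n_varietal_snps = 0)
  expect_equal(nrow(simulate_genetic_architecture(cfg0)), 0)

  cfg <- sim_config(n_ems_snps = 50, n_varietal_snps = 10)
  set.seed(1); a <- simulate_genetic_architecture(cfg)
  set.seed(1); b <- simulate_genetic_architecture(cfg)
  expect_identical(a, b)

  tiny <- sim_config(n_chromosomes = 1, chrom_length_bp = 10,
                     n_ems_snps = 8, n_varietal_snps = 8,
                     causal_chrom = 1, causal_pos = 5)
  expect_error(simulate_genetic_architecture(tiny), "more SNPs")
})

test_that("heterozygosity decays as (1/2)^(g-1) through selfing", {
  # many short chromosomes approximate unlinked loci; the mean heterozygote
  # fraction is linkage-free in expectation
  truth <- manual_truth(rep(paste0("chr", 1:20), each = 25),
                        rep(seq(1e6, 25e6, length.out = 25), 20),
                        causal_index = 1)
  for (g in c(2, 3, 4, 6)) {
    cfg <- sim_config(n_rils = 200, generation = g, n_chromosomes = 20,
                      chrom_length_bp = 25e6, causal_chrom = 1,
                      causal_pos = 1e6)
    set.seed(100 + g)
    geno <- simulate_ril_population(truth, cfg)
    p <- (1 / 2)^(g - 1)
    band <- 3 * sqrt(p * (1 - p) / (200 * 20))  # one effective locus/chrom
    expect_lt(abs(mean(geno == 1L) - p), band)
  }
})

test_that("F4 heterozygote fraction matches the Mendelian recursion at scale", {
  truth <- manual_truth(rep(paste0("chr", 1:20), each = 25),
                        rep(seq(1e6, 25e6, length.out = 25), 20),
                        causal_index = 1)
  cfg <- sim_config(n_rils = 400, generation = 4, n_chromosomes = 20,
                    chrom_length_bp = 25e6, causal_chrom = 1, causal_pos = 1e6)
  set.seed(11)
  geno <- simulate_ril_population(truth, cfg)
  expect_lt(abs(mean(geno == 1L) - 0.125), 0.01)
  expect_true(all(geno %in% 0:2))
})

test_that("recombination respects the genetic map", {
  # completely linked markers never recombine
  truth2 <- manual_truth("chr1", c(5e6, 5e6), causal_index = 1)
  cfg <- sim_config(n_rils = 100, n_chromosomes = 1, chrom_length_bp = 1e7,
                    causal_chrom = 1, causal_pos = 5e6)
  set.seed(2)
  g2 <- simulate_ril_population(truth2, cfg)
  expect_true(all(g2[, 1] == g2[, 2]))

  # recombinant fraction is monotone non-decreasing in map distance
  pos <- c(1, 5e6, 1e7, 2e7, 4e7, 8e7)
  truth6 <- manual_truth("chr1", pos, causal_index = 1)
  cfg6 <- sim_config(n_rils = 500, n_chromosomes = 1, chrom_length_bp = 1e8,
                     causal_chrom = 1, causal_pos = 1)
  set.seed(3)
  g6 <- simulate_ril_population(truth6, cfg6)
  rf <- vapply(2:6, function(j) {
    hom <- g6[, 1] %in% c(0, 2) & g6[, j] %in% c(0, 2)
    mean(g6[hom, 1] != g6[hom, j])
  }, numeric(1))
  expect_true(all(diff(rf) >= -0.02))  # sampling slack
  expect_lt(rf[1], 0.15)
})

test_that("F2 generation gives ~50% heterozygotes", {
  truth <- manual_truth(rep(paste0("chr", 1:10), each = 10),
                        rep(seq(1e6, 10e6, length.out = 10), 10),
                        causal_index = 1)
  cfg <- sim_config(n_rils = 200, generation = 2, n_chromosomes = 10,
                    chrom_length_bp = 1e7, causal_chrom = 1, causal_pos = 1e6)
  set.seed(4)
  geno <- simulate_ril_population(truth, cfg)
  expect_lt(abs(mean(geno == 1L) - 0.5), 0.05)
  expect_error(simulate_ril_population(truth, sim_config(generation = 1)),
               "generation")
})

test_that("clean homozygous bulks are fixed at the causal SNP", {
  set.seed(5)
  sim <- simulate_experiment(fast_config(seq_error = 0), phenology = FALSE)
  causal <- which(sim$truth$class == "ems_causal")
  expect_true(all(sim$genotypes[sim$bulks$sg, causal] == 2L))
  expect_true(all(sim$genotypes[sim$bulks$nsg, causal] == 0L))
  # and the reads reflect fixation exactly when error-free
  rec <- sim$records[causal, ]
  expect_equal(rec$DV.SG_bulk, rec$DP.SG_bulk)
  expect_equal(rec$DV.NSG_bulk, 0)
})

test_that("bulk read counts follow the pooling model", {
  truth <- manual_truth("chr1", seq(1e6, 200e6, length.out = 200),
                        causal_index = 1)
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e8,
                    causal_chrom = 1, causal_pos = 1e6,
                    seq_error = 0, depth_mean = 200)
  # hand-built genotypes: every RIL heterozygous -> bulk frequency 0.5
  geno <- matrix(1L, nrow = 20, ncol = 200,
                 dimnames = list(sprintf("RIL%03d", 1:20), NULL))
  set.seed(6)
  rec <- simulate_bulk_readcounts(truth, geno,
                                  list(sg = rownames(geno)[1:10],
                                       nsg = rownames(geno)[11:20]), cfg)
  idx <- rec$DV.SG_bulk / rec$DP.SG_bulk
  se <- sqrt(0.25 / 200)
  expect_lt(abs(mean(idx) - 0.5), 3 * se / sqrt(200))

  # fixed-alt bulk: DV = DP at every SNP
  geno2 <- matrix(2L, nrow = 20, ncol = 200, dimnames = dimnames(geno))
  rec2 <- simulate_bulk_readcounts(truth, geno2,
                                   list(sg = rownames(geno)[1:10],
                                        nsg = rownames(geno)[11:20]), cfg)
  expect_equal(rec2$DV.SG_bulk, rec2$DP.SG_bulk)
  expect_error(simulate_bulk_readcounts(truth, geno, list(sg = character(),
                                                          nsg = "RIL001"),
                                        cfg), "empty bulk")
})

test_that("varietal SNPs are fixed in bulks and both parents", {
  set.seed(7)
  sim <- simulate_experiment(fast_config(seq_error = 0), phenology = FALSE)
  v <- sim$records[sim$truth$class == "varietal", ]
  expect_true(all(v$DV.SG_bulk == v$DP.SG_bulk))
  expect_true(all(v$DV.NSG_bulk == v$DP.NSG_bulk))
  expect_true(all(v$DV.mutant_parent == v$DP.mutant_parent))
  expect_true(all(v$DV.wt_parent == v$DP.wt_parent))
  # wild-type parent carries no EMS alleles when error-free
  e <- sim$records[sim$truth$class != "varietal", ]
  expect_true(all(e$DV.wt_parent == 0))
})

test_that("senescence curves respond to dosage and dominance as configured", {
  cfg <- fast_config(t50_noise_sd = 0)
  temps <- within(data.frame(date = as.Date("2017-06-02") + 0:79),
                  { tmin <- 12; tmax <- 20 })
  dos <- c(wt = 0L, het = 1L, hom = 2L)

  tc_dom <- simulate_senescence_timecourse(dos, NULL, cfg, temps)
  expect_identical(tc_dom$score[tc_dom$plot == "het"],
                   tc_dom$score[tc_dom$plot == "hom"])

  cfg_null <- fast_config(t50_noise_sd = 0, onset_delay_days = 0)
  tc_null <- simulate_senescence_timecourse(dos, NULL, cfg_null, temps)
  expect_identical(tc_null$score[tc_null$plot == "wt"],
                   tc_null$score[tc_null$plot == "hom"])

  cfg_semi <- fast_config(t50_noise_sd = 0, dominance = "semi_dominant")
  tc_semi <- simulate_senescence_timecourse(dos, NULL, cfg_semi, temps)
  tt50 <- vapply(split(tc_semi, tc_semi$plot), function(d)
    interpolate_tt_score(d, 50), numeric(1))
  expect_lt(abs(tt50["het"] - (tt50["wt"] + tt50["hom"]) / 2), 20)

  # scores live on the step-5 scale and never decrease
  expect_true(all(tc_dom$score %% 5 == 0))
  for (p in unique(tc_dom$plot))
    expect_false(is.unsorted(tc_dom$score[tc_dom$plot == p]))
  expect_error(simulate_senescence_timecourse(dos, NULL, cfg,
                                              temps[0, ]), "empty temperature")
})
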