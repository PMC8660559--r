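test_that("recombination fractions count recombinant homozygote pairs", {
  g <- cbind(m1 = c("A", "B", "A", "B"), m2 = c("A", "B", "B", "A"))
  expect_equal(estimate_rf(g, "m1", "m2", min_informative = 4), 0.5)
  ident <- cbind(m1 = rep(c("A", "B"), 10), m2 = rep(c("A", "B"), 10))
  expect_equal(estimate_rf(ident, "m1", "m2"), 0)
  # RIL-at-fixation correction: R = 0.2 -> r = 0.125
  g20 <- cbind(m1 = rep("A", 20), m2 = c(rep("B", 4), rep("A", 16)))
  expect_equal(estimate_rf(g20, "m1", "m2", correction = TRUE), 0.125)
  # heterozygotes and missing calls are uninformative
  gh <- cbind(m1 = c("A", "H", NA, "B"), m2 = c("A", "A", "A", "B"))
  expect_warning(r <- estimate_rf(gh, "m1", "m2"), "informative")
  expect_true(is.na(r))
})

test_that("Kosambi distances match the closed form and its limits", {
  expect_equal(kosambi_distance(0), 0)
  expect_equal(kosambi_distance(0.25), 25 * log(3), tolerance = 1e-12)
  expect_equal(kosambi_distance(0.25), 27.465, tolerance = 1e-4)
  expect_equal(kosambi_distance(0.49), 25 * log(99), tolerance = 1e-12)
  expect_equal(kosambi_distance(0.49), 114.88, tolerance = 1e-4)
  grid <- seq(0.01, 0.49, by = 0.01)
  d <- kosambi_distance(grid)
  expect_true(all(diff(d) > 0))          # strictly increasing
  expect_true(all(d >= 100 * grid))      # dominates the naive 100r line
  expect_gt(kosambi_distance(0.4999), 200)  # diverges toward r = 0.5
  expect_error(kosambi_distance(0.5), "0.5")
})

test_that("marker ordering minimizes map length and matches a brute oracle", {
  # simulate 5 markers in known physical order
  pos <- c(10e6, 30e6, 50e6, 70e6, 90e6)
  truth <- manual_truth("chr1", pos, causal_index = 1)
  cfg <- sim_config(n_rils = 300, n_chromosomes = 1, chrom_length_bp = 1e8,
                    causal_chrom = 1, causal_pos = 10e6)
  set.seed(60)
  dos <- simulate_ril_population(truth, cfg)
  calls <- dos; calls[] <- c("A", "H", "B")[dos + 1L]
  shuffle <- sample(ncol(calls))
  info <- data.frame(marker = colnames(calls), chrom = "chr1", bp = pos)
  map <- order_markers(calls[, shuffle], info)
  expect_equal(map$marker, colnames(calls))      # physical order recovered
  expect_false(is.unsorted(map$cM))
  expect_equal(map$cM[1], 0)

  # exhaustive result equals the brute-force permutation oracle (n = 5)
  rf <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j) {
    if (i == j) return(0)
    suppressWarnings(estimate_rf(calls, colnames(calls)[i],
                                 colnames(calls)[j]))
  }))
  rf <- pmin(rf, 0.499)
  perms <- all_perms(5)
  lens <- apply(perms, 1, function(o)
    sum(kosambi_distance(rf[cbind(o[-5], o[-1])])))
  expect_equal(max(map$cM), min(lens), tolerance = 1e-9)
  # map length is invariant under order reversal by construction
  rev_len <- sum(kosambi_distance(rf[cbind(rev(seq_len(5))[-5],
                                           rev(seq_len(5))[-1])]))
  fwd_len <- sum(kosambi_distance(rf[cbind(seq_len(5)[-5], seq_len(5)[-1])]))
  expect_equal(rev_len, fwd_len)

  two <- order_markers(calls[, 1:2], info[1:2, ])
  expect_equal(nrow(two), 2)
})

test_that("Holm adjustment equals brute-force step-down on random vectors", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(61)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    expect_equal(holm_adjust(p), brute_holm(p))
    expect_equal(holm_adjust(p), p.adjust(p, method = "holm"))
    expect_true(all(holm_adjust(p) >= p))
  }
})

test_that("single-marker association peaks at the causal marker", {
  pos <- c(10e6, 40e6, 70e6, 100e6, 130e6)
  truth <- manual_truth("chr1", pos, causal_index = 3)
  cfg <- sim_config(n_rils = 200, n_chromosomes = 1, chrom_length_bp = 2e8,
                    causal_chrom = 1, causal_pos = 70e6)
  set.seed(62)
  dos <- simulate_ril_population(truth, cfg)
  calls <- dos; calls[] <- c("A", "H", "B")[dos + 1L]
  pheno <- dos[, 3] * 60 + rnorm(200, sd = 30)
  res <- single_marker_assoc(calls, pheno)
  expect_equal(attr(res, "peaks")[["metric"]], colnames(calls)[3])
  # association decays away from the causal marker
  expect_lt(res$p_holm[3], res$p_holm[1])
  expect_lt(res$p_holm[3], res$p_holm[5])
  expect_true(all(res$p_holm >= res$p))

  # perfect separation of homozygote classes
  g1 <- cbind(m = rep(c("A", "B"), each = 10))
  y <- c(rnorm(10, 0, 0.01), rnorm(10, 10, 0.01))
  expect_lt(single_marker_assoc(g1, y)$p, 1e-10)
  # constant phenotype: p = 1 by convention
  expect_equal(single_marker_assoc(g1, rep(3, 20))$p, 1)
})

test_that("permuted phenotypes rarely reach Holm-corrected significance", {
  set.seed(63)
  pos <- seq(10e6, 150e6, by = 20e6)   # 8 markers
  truth <- manual_truth("chr1", pos, causal_index = 1)
  cfg <- sim_config(n_rils = 100, n_chromosomes = 1, chrom_length_bp = 2e8,
                    causal_chrom = 1, causal_pos = 10e6)
  dos <- simulate_ril_population(truth, cfg)
  calls <- dos; calls[] <- c("A", "H", "B")[dos + 1L]
  hits <- 0
  for (i in 1:100) {
    pheno <- rnorm(100)                # no marker-trait link
    res <- single_marker_assoc(calls, pheno)
    if (min(res$p_holm) > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("inheritance mode is recovered from phenotype-by-genotype groups", {
  set.seed(64)
  recover <- function(h_shift) {
    modes <- character(100)
    for (s in 1:100) {
      a <- rnorm(12, 0); b <- rnorm(12, 10); h <- rnorm(6, h_shift)
      modes[s] <- classify_inheritance(c(a, h, b),
                                       rep(c("A", "H", "B"), c(12, 6, 12)),
                                       alpha = 0.01)$mode
    }
    modes
  }
  expect_gte(mean(recover(10) == "dominant"), 0.95)
  expect_gt(mean(recover(5) == "semi_dominant"), 0.5)
  expect_gte(mean(recover(0) == "recessive"), 0.95)

  no_h <- classify_inheritance(c(rnorm(5), rnorm(5, 10)),
                               rep(c("A", "B"), each = 5))
  expect_equal(no_h$mode, "ambiguous")
  expect_match(no_h$note, "no heterozygotes")
  flat <- classify_inheritance(rnorm(15), rep(c("A", "H", "B"), each = 5))
  expect_equal(flat$mode, "ambiguous")
  expect_match(flat$note, "no trait signal")
  expect_error(classify_inheritance(1:4, c("A", "A", "B", "B")), "three")
})
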