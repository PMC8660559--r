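#' Recombination fraction between two markers in a RIL population
#'
#' Counts recombinant pairs among lines homozygous at both markers
#' (heterozygous calls are uninformative for phase at advanced selfing
#' generations and are excluded). The raw fraction R can optionally be
#' converted to a single-meiosis recombination fraction with the
#' RIL-at-fixation correction r = R / (2 (1 - R)), capped at 0.499; the
#' correction assumes complete inbreeding and is off by default for
#' finite generations such as F4.
#'
#' @param geno character matrix of calls `A` (wild-type homozygote), `H`
#'   (heterozygote), `B` (mutant homozygote) or `NA`; rows = lines,
#'   columns = markers.
#' @param marker_i,marker_j column names or indices.
#' @param correction apply the RIL-selfing correction?
#' @param min_informative minimum jointly homozygous lines.
#' @return recombination fraction, or `NA` (with a warning) when too few
#'   informative pairs exist.
#' @examples
#' g <- cbind(m1 = c("A", "B", "A", "B"), m2 = c("A", "B", "B", "A"))
#' estimate_rf(g, "m1", "m2", min_informative = 4)  # 0.5
#' @export
estimate_rf <- function(geno, marker_i, marker_j, correction = FALSE,
                        min_informative = 10) {
  gi <- geno[, marker_i]
  gj <- geno[, marker_j]
  inf <- !is.na(gi) & !is.na(gj) & gi %in% c("A", "B") & gj %in% c("A", "B")
  if (sum(inf) < min_informative) {
    warning(sprintf("only %d informative pairs for %s/%s (need %d)",
                    sum(inf), marker_i, marker_j, min_informative),
            call. = FALSE)
    return(NA_real_)
  }
  R <- mean(gi[inf] != gj[inf])
  if (correction) min(R / (2 * (1 - R)), 0.499) else R
}

#' Kosambi map distance
#'
#' Converts a recombination fraction to centimorgans under the Kosambi
#' mapping function, d = 25 ln((1 + 2r) / (1 - 2r)), which partially
#' accounts for crossover interference.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return map distance in cM.
#' @examples
#' kosambi_distance(0.25)  # 25 * log(3) = 27.465
#' @export
kosambi_distance <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

# pairwise rf matrix; stops listing undefined pairs
.rf_matrix <- function(geno, correction = FALSE, min_informative = 10) {
  m <- ncol(geno)
  markers <- colnames(geno)
  rf <- matrix(0, m, m, dimnames = list(markers, markers))
  bad <- character()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r <- suppressWarnings(
        estimate_rf(geno, i, j, correction, min_informative))
      if (is.na(r)) bad <- c(bad, paste(markers[i], markers[j], sep = "/"))
      rf[i, j] <- rf[j, i] <- min(r, 0.499)  # finite Kosambi length
    }
  }
  if (length(bad) > 0)
    stop("undefined recombination fraction for pair(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  rf
}

.map_length <- function(order, rf) {
  sum(kosambi_distance(rf[cbind(order[-length(order)], order[-1])]))
}

# all permutations of 1..n (n small)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Order markers into a genetic map of minimal length
#'
#' Finds the marker order minimizing total Kosambi map length: by
#' exhaustive permutation search up to `max_markers_exact` markers, and by
#' greedy nearest-neighbour construction refined with 2-opt reversals
#' beyond that. The orientation is canonicalized so the first marker has
#' the lowest physical coordinate.
#'
#' @param geno call matrix (see [estimate_rf()]).
#' @param marker_info data.frame with `marker`, `chrom`, `bp` matching the
#'   columns of `geno`; `NULL` derives placeholders from column order.
#' @param max_markers_exact largest marker count for exhaustive search.
#' @param correction,min_informative passed to [estimate_rf()].
#' @return object of class `genetic_map`: data.frame with `marker`,
#'   `chrom`, `bp`, `r_adj` (recombination fraction to the previous
#'   marker) and cumulative `cM`.
#' @export
order_markers <- function(geno, marker_info = NULL, max_markers_exact = 8,
                          correction = FALSE, min_informative = 10) {
  m <- ncol(geno)
  if (m < 2) stop("need at least two markers", call. = FALSE)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("M", seq_len(m))
  if (is.null(marker_info))
    marker_info <- data.frame(marker = colnames(geno), chrom = NA,
                              bp = seq_len(m), stringsAsFactors = FALSE)
  rf <- .rf_matrix(geno, correction, min_informative)

  if (m <= max_markers_exact) {
    perms <- .permutations(m)
    lengths <- apply(perms, 1, .map_length, rf = rf)
    best <- perms[which.min(lengths), ]
  } else {
    # greedy chain from the tightest pair, then 2-opt refinement
    best <- order(rf[1, ])  # seed: proximity to marker 1
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          cand <- best
          cand[i:j] <- rev(cand[i:j])
          if (.map_length(cand, rf) < .map_length(best, rf) - 1e-12) {
            best <- cand
            improved <- TRUE
          }
        }
      }
    }
  }
  bp <- marker_info$bp[match(colnames(geno), marker_info$marker)]
  if (!is.na(bp[best[1]]) && !is.na(bp[best[m]]) && bp[best[1]] > bp[best[m]])
    best <- rev(best)
  r_adj <- c(NA, rf[cbind(best[-m], best[-1])])
  out <- data.frame(
    marker = colnames(geno)[best],
    chrom = marker_info$chrom[match(colnames(geno)[best], marker_info$marker)],
    bp = bp[best],
    r_adj = r_adj,
    cM = cumsum(c(0, kosambi_distance(r_adj[-1]))),
    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("Genetic map: %d markers, %.2f cM\n", nrow(x), max(x$cM)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Holm step-down multiple-testing adjustment
#'
#' Step-down familywise-error correction: p-values sorted ascending are
#' multiplied by (m - i + 1), a running maximum enforced, capped at 1,
#' and returned in the original order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p)
  adj <- pmin(1, cummax(p[o] * (m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Single-marker association between genotype and senescence metrics
#'
#' Per marker and metric, regresses the metric on mutant-allele dosage
#' (A = 0, H = 1, B = 2) and reports the regression F-test p-value,
#' Holm-adjusted across markers within each metric. The peak marker per
#' metric is the one with the smallest adjusted p.
#'
#' @param geno call matrix (see [estimate_rf()]).
#' @param phenotypes numeric vector (one metric) or data.frame of metrics,
#'   rows aligned with `geno`.
#' @return object of class `marker_assoc`: data.frame with `metric`,
#'   `marker`, `p`, `p_holm`, `neg_log10_p` (of the adjusted p),
#'   `direction` (sign of the dosage effect); peak markers per metric in
#'   `attr(, "peaks")`.
#' @export
single_marker_assoc <- function(geno, phenotypes) {
  if (is.numeric(phenotypes)) phenotypes <- data.frame(metric = phenotypes)
  if (is.null(colnames(geno)))
    colnames(geno) <- paste0("M", seq_len(ncol(geno)))
  dosage_of <- c(A = 0, H = 1, B = 2)
  res <- list()
  for (metric in names(phenotypes)) {
    y_all <- phenotypes[[metric]]
    p <- numeric(ncol(geno)); dir <- numeric(ncol(geno))
    for (k in seq_len(ncol(geno))) {
      dos <- unname(dosage_of[geno[, k]])
      ok <- !is.na(dos) & !is.na(y_all)
      y <- y_all[ok]; d <- dos[ok]
      if (length(unique(y)) < 2 || length(unique(d)) < 2) {
        p[k] <- 1; dir[k] <- 0
      } else {
        fit <- stats::lm(y ~ d)
        an <- stats::anova(fit)
        p[k] <- an[["Pr(>F)"]][1]
        dir[k] <- sign(stats::coef(fit)[["d"]])
      }
    }
    res[[metric]] <- data.frame(metric = metric, marker = colnames(geno),
                                p = p, p_holm = holm_adjust(p),
                                direction = dir, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$neg_log10_p <- -log10(pmax(out$p_holm, .Machine$double.xmin))
  rownames(out) <- NULL
  peaks <- vapply(res, function(d) d$marker[which.min(d$p_holm)], "")
  attr(out, "peaks") <- peaks
  class(out) <- c("marker_assoc", "data.frame")
  out
}

#' @export
print.marker_assoc <- function(x, ...) {
  cat("Single-marker association (Holm-adjusted)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  peaks <- attr(x, "peaks")
  cat("peak marker(s):",
      paste(names(peaks), peaks, sep = " -> ", collapse = "; "), "\n")
  invisible(x)
}

#' Classify the mode of inheritance from phenotype-by-genotype groups
#'
#' Compares heterozygotes to both homozygote classes with Welch t-tests.
#' The mutant allele is called dominant when heterozygotes differ from
#' wild-type homozygotes (p < alpha) but resemble mutant homozygotes
#' (p >= alpha); recessive in the reverse case; semi-dominant when they
#' differ from both with a mean strictly between the homozygote means.
#' Without a significant difference between the homozygote classes there
#' is no trait signal and the call is ambiguous.
#'
#' @param phenotype numeric phenotype values (e.g. TT70).
#' @param genotype calls `A` (wild-type hom), `H` (het), `B` (mutant hom).
#' @param alpha significance level.
#' @return list with `mode` (`"dominant"`, `"semi_dominant"`,
#'   `"recessive"` or `"ambiguous"`), the three Welch p-values (`p_AB`,
#'   `p_HA`, `p_HB`), group means, and a `note`.
#' @export
classify_inheritance <- function(phenotype, genotype, alpha = 0.05) {
  gA <- phenotype[genotype == "A" & !is.na(phenotype)]
  gH <- phenotype[genotype == "H" & !is.na(phenotype)]
  gB <- phenotype[genotype == "B" & !is.na(phenotype)]
  if (length(gA) < 3 || length(gB) < 3)
    stop("need at least three lines in each homozygote class", call. = FALSE)
  means <- c(A = mean(gA), H = if (length(gH)) mean(gH) else NA, B = mean(gB))
  if (length(gH) < 2)
    return(list(mode = "ambiguous", p_AB = NA, p_HA = NA, p_HB = NA,
                means = means, note = "no heterozygotes"))
  p_AB <- stats::t.test(gA, gB)$p.value
  if (p_AB >= alpha)
    return(list(mode = "ambiguous", p_AB = p_AB, p_HA = NA, p_HB = NA,
                means = means, note = "no trait signal (homozygotes alike)"))
  p_HA <- stats::t.test(gH, gA)$p.value
  p_HB <- stats::t.test(gH, gB)$p.value
  between <- (means["H"] > min(means["A"], means["B"])) &&
    (means["H"] < max(means["A"], means["B"]))
  mode <- if (p_HA < alpha && p_HB >= alpha) "dominant"
          else if (p_HB < alpha && p_HA >= alpha) "recessive"
          else if (p_HA < alpha && p_HB < alpha && between) "semi_dominant"
          else "ambiguous"
  list(mode = mode, p_AB = p_AB, p_HA = p_HA, p_HB = p_HB, means = means,
       note = "")
}
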