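#' Per-bulk SNP indices and the delta SNP index
#'
#' The SNP index of a bulk at a site is DV/DP, the fraction of reads
#' carrying the alternate allele; the delta SNP index is the staygreen
#' bulk index minus the non-staygreen bulk index. A variant fully linked
#' to the causal mutation is expected at index 1 in the staygreen bulk and
#' 0 in the non-staygreen bulk (delta 1); a varietal variant is fixed in
#' both bulks (delta 0). Records with zero depth in either bulk are
#' skipped and counted.
#'
#' @param records variant record data.frame with per-sample `DP.<sample>`
#'   and `DV.<sample>` columns (see [simulate_bulk_readcounts()] or
#'   [read_variants()]).
#' @param sg_sample,nsg_sample sample names of the staygreen and
#'   non-staygreen bulks.
#' @return data.frame of SNP index records: `chrom`, `pos`, `ref`, `alt`,
#'   `index_sg`, `index_nsg`, `delta`, `dp_sg`, `dp_nsg`, and logical
#'   flags `ems_transition`, `varietal` (set by [remove_varietal()]),
#'   `enriched` (set by [filter_enriched()]). The number of skipped
#'   records is in `attr(, "n_skipped")`.
#' @examples
#' rec <- data.frame(chrom = "chr1", pos = 100, ref = "G", alt = "A",
#'                   DP.sg = 20, DV.sg = 20, DP.nsg = 15, DV.nsg = 0)
#' compute_indices(rec, "sg", "nsg")$delta  # 1
#' @export
compute_indices <- function(records, sg_sample = "SG_bulk",
                            nsg_sample = "NSG_bulk") {
  for (s in c(sg_sample, nsg_sample)) {
    if (!all(paste0(c("DP.", "DV."), s) %in% names(records)))
      stop("unknown sample name: ", s, call. = FALSE)
  }
  dp_sg <- records[[paste0("DP.", sg_sample)]]
  dv_sg <- records[[paste0("DV.", sg_sample)]]
  dp_nsg <- records[[paste0("DP.", nsg_sample)]]
  dv_nsg <- records[[paste0("DV.", nsg_sample)]]
  keep <- dp_sg > 0 & dp_nsg > 0
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message(n_skipped, " record(s) skipped for zero depth in a bulk")
  out <- data.frame(
    chrom = records$chrom[keep], pos = records$pos[keep],
    ref = records$ref[keep], alt = records$alt[keep],
    index_sg = dv_sg[keep] / dp_sg[keep],
    index_nsg = dv_nsg[keep] / dp_nsg[keep],
    dp_sg = dp_sg[keep], dp_nsg = dp_nsg[keep],
    stringsAsFactors = FALSE)
  out$delta <- out$index_sg - out$index_nsg
  out$ems_transition <- vapply(seq_len(nrow(out)), function(i)
    is_ems_transition(out$ref[i], out$alt[i]), logical(1))
  out$varietal <- rep(FALSE, nrow(out))
  out$enriched <- rep(FALSE, nrow(out))
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Is a substitution an EMS-characteristic transition?
#'
#' EMS alkylates guanine, so induced mutations are overwhelmingly G>A (and
#' the complementary C>T) transitions. Only those two directed
#' substitutions qualify; A>G and T>C, though transitions, are not the EMS
#' signature, and transversions never qualify.
#'
#' @param ref,alt single-base reference and alternate alleles.
#' @return `TRUE` iff (ref, alt) is (G, A) or (C, T).
#' @examples
#' is_ems_transition("G", "A")  # TRUE
#' is_ems_transition("A", "G")  # FALSE
#' @export
is_ems_transition <- function(ref, alt) {
  if (nchar(ref) != 1L || nchar(alt) != 1L)
    stop("multi-base alleles are not supported: ", ref, ">", alt,
         call. = FALSE)
  (ref == "G" && alt == "A") || (ref == "C" && alt == "T")
}

#' Remove varietal variants fixed in both bulks
#'
#' Variants at SNP index ~1 in both bulks are fixed differences between
#' the mutagenized cultivar and the reference assembly -- they segregate
#' in neither bulk and carry no mapping information. The default
#' threshold 0.9 tolerates sequencing error; pass
#' `varietal_threshold = 1` for the exact rule.
#'
#' @param index_records output of [compute_indices()].
#' @param varietal_threshold both-bulk index threshold, in (0.5, 1].
#' @return list with `kept` and `removed` data.frames; removed records
#'   carry `varietal = TRUE`.
#' @export
remove_varietal <- function(index_records, varietal_threshold = 0.9) {
  if (varietal_threshold <= 0.5 || varietal_threshold > 1)
    stop("`varietal_threshold` must lie in (0.5, 1]", call. = FALSE)
  is_var <- index_records$index_sg >= varietal_threshold &
    index_records$index_nsg >= varietal_threshold
  removed <- index_records[is_var, , drop = FALSE]
  removed$varietal <- rep(TRUE, nrow(removed))
  list(kept = index_records[!is_var, , drop = FALSE], removed = removed)
}

#' Filter for variants enriched in the staygreen bulk
#'
#' Keeps variants near-fixed in the staygreen bulk and near-absent in the
#' non-staygreen bulk, with adequate depth in both bulks, optionally
#' restricted to EMS-characteristic transitions. Two named presets ship:
#' `"methods"` (index > 0.9 / < 0.1, DP > 3, both strict) and the stricter
#' `"results"` default (index >= 0.95 / <= 0.05, DP >= 5, inclusive).
#' Free thresholds (`sg_min`, `nsg_max`, `min_dp`, inclusive) override the
#' preset.
#'
#' @param index_records output of [compute_indices()] (after
#'   [remove_varietal()]).
#' @param preset `"results"` or `"methods"`.
#' @param sg_min,nsg_max,min_dp free thresholds (inclusive); `NULL` uses
#'   the preset.
#' @param transitions_only restrict to EMS transitions?
#' @return the enriched subset, with `enriched = TRUE`.
#' @export
filter_enriched <- function(index_records, preset = c("results", "methods"),
                            sg_min = NULL, nsg_max = NULL, min_dp = NULL,
                            transitions_only = TRUE) {
  custom <- !is.null(sg_min) || !is.null(nsg_max) || !is.null(min_dp)
  if (custom) {
    sg_min <- if (is.null(sg_min)) 0.95 else sg_min
    nsg_max <- if (is.null(nsg_max)) 0.05 else nsg_max
    min_dp <- if (is.null(min_dp)) 5 else min_dp
    if (sg_min < nsg_max)
      stop("contradictory bounds: sg_min < nsg_max", call. = FALSE)
    ok <- index_records$index_sg >= sg_min &
      index_records$index_nsg <= nsg_max &
      index_records$dp_sg >= min_dp & index_records$dp_nsg >= min_dp
  } else {
    preset <- match.arg(preset)
    ok <- switch(preset,
      methods = index_records$index_sg > 0.9 &
        index_records$index_nsg < 0.1 &
        index_records$dp_sg > 3 & index_records$dp_nsg > 3,
      results = index_records$index_sg >= 0.95 &
        index_records$index_nsg <= 0.05 &
        index_records$dp_sg >= 5 & index_records$dp_nsg >= 5)
  }
  if (isTRUE(transitions_only)) ok <- ok & index_records$ems_transition
  out <- index_records[ok, , drop = FALSE]
  out$enriched <- rep(TRUE, nrow(out))
  out
}

#' Detect candidate regions of completely enriched variants
#'
#' Scans each chromosome of a position-sorted, filtered SNP list for
#' maximal runs of consecutive variants with delta SNP index at or above
#' `delta_exact` (default 1, complete enrichment). Any intervening listed
#' variant below the threshold breaks a run, unless `max_gap_snps` allows
#' that many below-threshold variants inside a run. Regions are ranked by
#' member count, then physical span.
#'
#' @param index_records filtered SNP index records (the list within which
#'   contiguity is judged).
#' @param delta_exact delta threshold defining region membership.
#' @param max_gap_snps below-threshold variants tolerated inside a run.
#' @return data.frame of class `candidate_regions`: `chrom`, `start`,
#'   `end` (bp of first/last member), `span_bp`, `n_members`, and a
#'   list-column `members` of member positions; empty for empty input.
#' @export
detect_candidate_regions <- function(index_records, delta_exact = 1,
                                     max_gap_snps = 0) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), span_bp = numeric(),
                      n_members = integer(), stringsAsFactors = FALSE)
  empty$members <- list()
  class(empty) <- c("candidate_regions", "data.frame")
  if (nrow(index_records) == 0) return(empty)
  regions <- list()
  tol <- 1e-9
  for (chr in unique(index_records$chrom)) {
    d <- index_records[index_records$chrom == chr, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    qual <- d$delta >= delta_exact - tol
    i <- 1L
    while (i <= nrow(d)) {
      if (!qual[i]) { i <- i + 1L; next }
      members <- i
      gap <- 0L
      j <- i + 1L
      while (j <= nrow(d)) {
        if (qual[j]) {
          members <- c(members, j)
          gap <- 0L
        } else {
          gap <- gap + 1L
          if (gap > max_gap_snps) break
        }
        j <- j + 1L
      }
      regions[[length(regions) + 1L]] <- list(
        chrom = chr, pos = d$pos[members])
      i <- members[length(members)] + 1L
    }
  }
  if (length(regions) == 0) return(empty)
  out <- data.frame(
    chrom = vapply(regions, `[[`, "", "chrom"),
    start = vapply(regions, function(r) min(r$pos), numeric(1)),
    end = vapply(regions, function(r) max(r$pos), numeric(1)),
    stringsAsFactors = FALSE)
  out$span_bp <- out$end - out$start
  out$n_members <- vapply(regions, function(r) length(r$pos), integer(1))
  out$members <- lapply(regions, `[[`, "pos")
  out <- out[order(-out$n_members, -out$span_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' @export
print.candidate_regions <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("No candidate regions\n")
    return(invisible(x))
  }
  cat(sprintf("%d candidate region(s):\n", nrow(x)))
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %s:%.0f-%.0f  (%.2f Mb, %d SNPs)\n", x$chrom[i],
                x$start[i], x$end[i], x$span_bp[i] / 1e6, x$n_members[i]))
  invisible(x)
}

#' Genome-wide delta SNP index table for plotting
#'
#' Applies varietal removal, restricts to EMS transitions, and emits
#' `(chrom, pos, delta)` sorted by chromosome and position -- the table
#' behind a genome-wide delta SNP index scatter.
#'
#' @param index_records output of [compute_indices()].
#' @param varietal_threshold passed to [remove_varietal()].
#' @return data.frame with `chrom`, `pos`, `delta`.
#' @export
genome_delta_table <- function(index_records, varietal_threshold = 0.9) {
  kept <- remove_varietal(index_records, varietal_threshold)$kept
  kept <- kept[kept$ems_transition, c("chrom", "pos", "delta"), drop = FALSE]
  kept <- kept[order(kept$chrom, kept$pos), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Run a full bulk segregant scan
#'
#' Chains [compute_indices()], [remove_varietal()], [filter_enriched()]
#' and [detect_candidate_regions()] into one call, returning a classed
#' object with print, summary and plot methods.
#'
#' @param records variant records (see [compute_indices()]).
#' @param sg_sample,nsg_sample bulk sample names.
#' @param preset enrichment preset (see [filter_enriched()]).
#' @param varietal_threshold both-bulk index threshold for varietal
#'   removal.
#' @param delta_exact region-membership delta threshold.
#' @param transitions_only restrict enrichment to EMS transitions?
#' @return object of class `bsa_scan`: list with `indices` (post
#'   varietal removal), `varietal` (removed records), `enriched`,
#'   `regions`, `delta_table` and `params`.
#' @export
bsa_scan <- function(records, sg_sample = "SG_bulk", nsg_sample = "NSG_bulk",
                     preset = "results", varietal_threshold = 0.9,
                     delta_exact = 1, transitions_only = TRUE) {
  idx <- compute_indices(records, sg_sample, nsg_sample)
  split <- remove_varietal(idx, varietal_threshold)
  enriched <- filter_enriched(split$kept, preset = preset,
                              transitions_only = transitions_only)
  regions <- detect_candidate_regions(enriched, delta_exact = delta_exact)
  out <- list(indices = split$kept, varietal = split$removed,
              enriched = enriched, regions = regions,
              delta_table = genome_delta_table(idx, varietal_threshold),
              params = list(preset = preset,
                            varietal_threshold = varietal_threshold,
                            delta_exact = delta_exact,
                            transitions_only = transitions_only,
                            sg_sample = sg_sample, nsg_sample = nsg_sample),
              n_skipped = attr(idx, "n_skipped"))
  class(out) <- "bsa_scan"
  out
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulk segregant scan\n")
  cat(sprintf("  %d variants indexed (%d varietal removed, %d skipped)\n",
              nrow(x$indices) + nrow(x$varietal), nrow(x$varietal),
              x$n_skipped))
  cat(sprintf("  %d enriched under preset '%s'\n", nrow(x$enriched),
              x$params$preset))
  print(x$regions)
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  top <- if (nrow(object$regions) > 0) object$regions[1, ] else NULL
  structure(list(n_indexed = nrow(object$indices) + nrow(object$varietal),
                 n_varietal = nrow(object$varietal),
                 n_enriched = nrow(object$enriched),
                 n_regions = nrow(object$regions),
                 top_region = top,
                 params = object$params),
            class = "summary.bsa_scan")
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  cat(sprintf(
    "BSA scan: %d variants, %d varietal, %d enriched ('%s'), %d region(s)\n",
    x$n_indexed, x$n_varietal, x$n_enriched, x$params$preset, x$n_regions))
  if (!is.null(x$top_region))
    cat(sprintf("  top region %s:%.0f-%.0f (%d SNPs)\n",
                x$top_region$chrom, x$top_region$start, x$top_region$end,
                x$top_region$n_members))
  invisible(x)
}

#' @export
#' @importFrom graphics abline axis plot points
plot.bsa_scan <- function(x, ...) {
  d <- x$delta_table
  if (nrow(d) == 0) stop("nothing to plot", call. = FALSE)
  chroms <- unique(d$chrom)
  offs <- c(0, cumsum(vapply(chroms, function(c) max(d$pos[d$chrom == c]),
                             numeric(1))))
  names(offs) <- c(chroms, "end")
  xpos <- d$pos + offs[d$chrom]
  cols <- rep_len(c("grey30", "grey60"), length(chroms))
  plot(xpos, d$delta, pch = 16, cex = 0.5,
       col = cols[match(d$chrom, chroms)],
       xlab = "genome position", ylab = expression(Delta * " SNP index"),
       ylim = c(-1, 1), xaxt = "n", ...)
  mids <- offs[seq_along(chroms)] +
    vapply(chroms, function(c) max(d$pos[d$chrom == c]), numeric(1)) / 2
  axis(1, at = mids, labels = chroms)
  abline(h = c(0, 1), lty = 3)
  invisible(x)
}
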