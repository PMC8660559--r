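#' Read variant records from a multi-sample VCF
#'
#' Reads a VCF (via vcfR), applies the record-level QC used throughout:
#' sites with QUAL strictly above `min_qual` are retained, sites with any
#' missing genotype (`./.`) are dropped when `drop_missing`, and
#' multi-allelic sites are skipped. Per-sample total depth DP and
#' alternate-read depth DV are taken from the FORMAT fields; when DV is
#' absent, the allele-depth field AD is used as a fallback with
#' DV = AD[alt] and DP = sum(AD). All drop counts are recorded and
#' reconcile with the input site count.
#'
#' @param path path to a VCF file.
#' @param min_qual QUAL retention threshold (strict).
#' @param drop_missing drop sites with any missing genotype?
#' @return data.frame of variant records (`chrom`, `pos`, `ref`, `alt`,
#'   `qual`, `DP.<sample>`, `DV.<sample>`); sample names in
#'   `attr(, "samples")`, QC counts in `attr(, "counts")`.
#' @export
read_variants <- function(path, min_qual = 20, drop_missing = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(vcf)
  if (is.null(dim(fixm))) fixm <- t(fixm)  # single-site VCF yields a vector
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  multi <- grepl(",", fix$ALT)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_gt <- apply(gt, 1, function(g) any(is.na(g) | g == "./." | g == "."))
  low_qual <- is.na(qual) | qual <= min_qual

  # precedence for counting: qual, then missing, then multi-allelic
  drop_qual <- low_qual
  drop_missing_site <- !drop_qual & drop_missing & missing_gt
  drop_multi <- !drop_qual & !drop_missing_site & multi
  keep <- !(drop_qual | drop_missing_site | drop_multi)

  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  have_dv <- "DV" %in% fmt
  have_ad <- "AD" %in% fmt
  if (!have_dv && !have_ad) {
    bad <- paste0(fix$CHROM[1], ":", fix$POS[1])
    stop("VCF lacks both DV and AD FORMAT fields (first site ", bad, ")",
         call. = FALSE)
  }
  if (have_dv) {
    dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    dv <- vcfR::extract.gt(vcf, element = "DV", as.numeric = TRUE)
  } else {
    ad <- vcfR::extract.gt(vcf, element = "AD")
    split_ad <- function(x) {
      parts <- strsplit(x, ",")
      ref_d <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
      alt_d <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
      cbind(ref_d + alt_d, alt_d)
    }
    dp <- dv <- matrix(NA_real_, nrow(ad), ncol(ad), dimnames = dimnames(ad))
    for (s in colnames(ad)) {
      both <- split_ad(ad[, s])
      dp[, s] <- both[, 1]
      dv[, s] <- both[, 2]
    }
  }

  out <- data.frame(chrom = fix$CHROM[keep],
                    pos = as.numeric(fix$POS[keep]),
                    ref = fix$REF[keep], alt = fix$ALT[keep],
                    qual = qual[keep], stringsAsFactors = FALSE)
  for (s in samples) {
    out[[paste0("DP.", s)]] <- as.numeric(dp[keep, s])
    out[[paste0("DV.", s)]] <- as.numeric(dv[keep, s])
  }
  rownames(out) <- NULL
  counts <- c(input = n_in, kept = sum(keep),
              dropped_qual = sum(drop_qual),
              dropped_missing = sum(drop_missing_site),
              dropped_multiallelic = sum(drop_multi))
  message(sprintf(
    "read_variants: %d sites in, %d kept (%d low QUAL, %d missing GT, %d multi-allelic)",
    counts["input"], counts["kept"], counts["dropped_qual"],
    counts["dropped_missing"], counts["dropped_multiallelic"]))
  attr(out, "samples") <- samples
  attr(out, "counts") <- counts
  out
}

#' Write variant records as a VCF 4.2 file
#'
#' Emits a plain-text multi-sample VCF with FORMAT fields GT, DP and DV,
#' one sample column per bulk/parent. Genotypes are derived from the read
#' counts (0/0 when DV = 0, 1/1 when DV = DP, 0/1 otherwise).
#'
#' @param records variant records (see [simulate_bulk_readcounts()]).
#' @param path output path.
#' @param samples sample names; default from `attr(records, "samples")`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, samples = attr(records, "samples")) {
  if (is.null(samples))
    stop("sample names missing; pass `samples`", call. = FALSE)
  contigs <- unique(records$chrom)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=staygreenBSA",
    paste0("##contig=<ID=", contigs, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##FORMAT=<ID=DV,Number=1,Type=Integer,Description="Number of reads with the alternate allele">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_of <- function(dp, dv) ifelse(dv == 0, "0/0",
                            ifelse(dv == dp, "1/1", "0/1"))
  cols <- lapply(samples, function(s) {
    dp <- records[[paste0("DP.", s)]]
    dv <- records[[paste0("DV.", s)]]
    paste(gt_of(dp, dv), dp, dv, sep = ":")
  })
  body <- do.call(paste, c(list(records$chrom,
                                format(records$pos, scientific = FALSE,
                                       trim = TRUE), ".",
                                records$ref, records$alt,
                                format(records$qual, trim = TRUE), ".", ".",
                                "GT:DP:DV"),
                           cols, sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read senescence phenotype tables
#'
#' Reads the three CSV tables of a field season -- visual senescence
#' scores (`plot`, `date`, `score`, optional `tissue`), GS55 dates
#' (`plot`, `date`) and daily temperatures (`date`, `tmin`, `tmax`) --
#' validates them, and converts scoring dates to thermal time from each
#' plot's GS55. Scores off the step-5 alphabet are kept with a warning;
#' plots without a GS55 date are excluded with a message.
#'
#' @param scores_csv,gs55_csv,temps_csv file paths.
#' @return list with `timecourses` (data.frame `plot`, `tissue`, `date`,
#'   `thermal_time`, `score`), `gs55` and `temps`.
#' @export
read_phenotypes <- function(scores_csv, gs55_csv, temps_csv) {
  scores <- utils::read.csv(scores_csv, stringsAsFactors = FALSE)
  gs55 <- utils::read.csv(gs55_csv, stringsAsFactors = FALSE)
  temps <- utils::read.csv(temps_csv, stringsAsFactors = FALSE)
  need <- function(d, cols, what) {
    miss <- setdiff(cols, names(d))
    if (length(miss) > 0)
      stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  need(scores, c("plot", "date", "score"), "score table")
  need(gs55, c("plot", "date"), "GS55 table")
  need(temps, c("date", "tmin", "tmax"), "temperature table")
  parse_date <- function(x, what) {
    d <- as.Date(x, format = "%Y-%m-%d")
    if (anyNA(d))
      stop(what, ": unparseable date at row ",
           paste(which(is.na(d)), collapse = ", "), call. = FALSE)
    d
  }
  scores$date <- parse_date(scores$date, "score table")
  gs55$date <- parse_date(gs55$date, "GS55 table")
  temps$date <- parse_date(temps$date, "temperature table")
  if (!is.numeric(scores$score) || anyNA(scores$score))
    stop("score table: non-numeric or missing scores", call. = FALSE)
  off_scale <- scores$score %% 5 != 0 | scores$score < 0 | scores$score > 100
  if (any(off_scale))
    warning(sum(off_scale), " score(s) off the 0-100 step-5 scale (kept)",
            call. = FALSE)
  if (!"tissue" %in% names(scores)) scores$tissue <- "leaf"

  no_gs55 <- setdiff(unique(scores$plot), gs55$plot)
  if (length(no_gs55) > 0) {
    message("excluding plot(s) without GS55 date: ",
            paste(no_gs55, collapse = ", "))
    scores <- scores[!scores$plot %in% no_gs55, , drop = FALSE]
  }
  t0 <- gs55$date[match(scores$plot, gs55$plot)]
  scores$thermal_time <- mapply(function(t0_i, t_i)
    compute_thermal_time(temps, t0_i, t_i), t0, scores$date)
  out <- scores[order(scores$plot, scores$date),
                c("plot", "tissue", "date", "thermal_time", "score")]
  rownames(out) <- NULL
  list(timecourses = out, gs55 = gs55, temps = temps)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/mRNA/exon/CDS features (1-based inclusive, via
#' rtracklayer) and assembles one [gene_model()] per gene from its first
#' mRNA. CDS lengths not divisible by 3 raise an error naming the gene.
#'
#' @param path GFF3 file path.
#' @param flank_bp upstream/downstream window for the models.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path, flank_bp = 5000) {
  gff <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gff)
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  models <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    mr <- mrnas[vapply(mrnas$Parent, function(p) gid %in% p, logical(1)), ,
                drop = FALSE]
    if (nrow(mr) == 0)
      stop("gene ", gid, " has no mRNA feature", call. = FALSE)
    mid <- mr$ID[1]
    kids <- df[vapply(df$Parent, function(p) mid %in% p, logical(1)), ,
               drop = FALSE]
    exons <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cds <- kids[kids$type == "CDS", c("start", "end"), drop = FALSE]
    if (nrow(exons) == 0 || nrow(cds) == 0)
      stop("gene ", gid, " lacks exon or CDS features", call. = FALSE)
    models[[gid]] <- gene_model(
      gene_id = gid, chrom = as.character(genes$seqnames[i]),
      strand = as.character(genes$strand[i]),
      exons = as.matrix(exons), cds = as.matrix(cds), flank_bp = flank_bp)
  }
  models
}

#' Write a simulated dataset to disk
#'
#' Emits the files an analysis run consumes: a multi-sample VCF of bulks
#' and parents, per-season senescence score / GS55 / temperature CSVs,
#' ground-truth tables (SNP classes, genotype dosages, bulk membership),
#' and a JSON manifest listing every written file and the seed.
#'
#' @param sim a `staygreen_sim` from [simulate_experiment()].
#' @param out_dir output directory (created if needed).
#' @param seed seed to record in the manifest (informational).
#' @return the manifest as a list (paths relative to `out_dir`),
#'   invisibly; also written as `manifest.json`.
#' @export
emit_dataset <- function(sim, out_dir, seed = NA) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  if (!ok || file.access(out_dir, mode = 2) != 0)
    stop("cannot write to directory: ", out_dir, call. = FALSE)
  files <- character()
  w <- function(fun, obj, name) {
    path <- file.path(out_dir, name)
    fun(obj, path)
    files <<- c(files, name)
  }
  write_csv <- function(obj, path) utils::write.csv(obj, path,
                                                    row.names = FALSE)
  w(write_vcf, sim$records, "bulks.vcf")
  w(write_csv, sim$truth, "truth_snps.csv")
  geno_df <- data.frame(ril = rownames(sim$genotypes), sim$genotypes,
                        check.names = FALSE, stringsAsFactors = FALSE)
  w(write_csv, geno_df, "truth_genotypes.csv")
  bulk_df <- data.frame(ril = c(sim$bulks$sg, sim$bulks$nsg),
                        bulk = rep(c("sg", "nsg"),
                                   c(length(sim$bulks$sg),
                                     length(sim$bulks$nsg))),
                        stringsAsFactors = FALSE)
  w(write_csv, bulk_df, "bulk_membership.csv")
  if (!is.null(sim$timecourses)) {
    for (year in names(sim$timecourses)) {
      tc <- sim$timecourses[[year]]
      temps <- sim$temps[[year]]
      gs55_date <- temps$date[1] - 1
      scores <- data.frame(plot = tc$plot, date = gs55_date + tc$day,
                           score = tc$score, tissue = "leaf",
                           stringsAsFactors = FALSE)
      w(write_csv, scores, sprintf("scores_%s.csv", year))
      w(write_csv, data.frame(plot = unique(tc$plot), date = gs55_date),
        sprintf("gs55_%s.csv", year))
      w(write_csv, temps, sprintf("temperatures_%s.csv", year))
    }
  }
  manifest <- list(seed = seed, files = files,
                   n_snps = nrow(sim$truth), n_rils = nrow(sim$genotypes))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$files <- c(manifest$files, "manifest.json")
  invisible(manifest)
}
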