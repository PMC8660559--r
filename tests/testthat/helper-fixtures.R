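# Published candidate SNP tables shipped as plain-text fixtures
load_candidate_table <- function(which = c("6A", "6D")) {
  which <- match.arg(which)
  file <- switch(which,
                 "6A" = "candidate_snps_1189a_6A.csv",
                 "6D" = "candidate_snps_2316b_6D.csv")
  path <- system.file("extdata", file, package = "staygreenBSA")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# minimal SNP truth table for controlled population simulations
manual_truth <- function(chrom, pos, causal_index = NA) {
  cls <- rep("ems_background", length(pos))
  if (!is.na(causal_index)) cls[causal_index] <- "ems_causal"
  data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A",
             class = cls, stringsAsFactors = FALSE)
}

# small config shortcut for fast simulations
fast_config <- function(...) {
  sim_config(n_chromosomes = 3, chrom_length_bp = 5e7, n_ems_snps = 60,
             n_varietal_snps = 20, causal_chrom = 2, causal_pos = 2.5e7,
             n_rils = 48, bulk_size_sg = 8, bulk_size_nsg = 8, ...)
}

# write a small hand-rolled VCF; rows are preformatted body lines
write_test_vcf <- function(body, path, samples = c("SG", "NSG"),
                           format_defs = c("GT", "DP", "DV")) {
  defs <- c(
    GT = '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    DP = '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    DV = '##FORMAT=<ID=DV,Number=1,Type=Integer,Description="Alt depth">',
    AD = '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">')
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
           unname(defs[format_defs]),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

# toy reference + single-gene model for consequence calling.
# codon_seq becomes the CDS (on the given strand), placed at CDS_start.
toy_gene <- function(codon_seq, strand = "+", cds_start = 11,
                     chrom = "chrTest") {
  n <- nchar(codon_seq)
  genomic_cds <- if (strand == "-") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(codon_seq)))
  } else codon_seq
  seq <- paste0(strrep("A", cds_start - 1), genomic_cds, strrep("A", 10))
  model <- gene_model("toy", chrom, strand,
                      exons = cbind(cds_start, cds_start + n - 1),
                      cds = cbind(cds_start, cds_start + n - 1))
  ref <- stats::setNames(list(seq), chrom)
  list(model = model, ref = ref, seq = seq,
       cds_range = c(cds_start, cds_start + n - 1))
}

# brute-force Holm step-down straight from the definition
brute_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- min(1, (m - i + 1) * p[o[i]])
    running <- max(running, val)
    adj[o[i]] <- running
  }
  adj
}

# brute-force maximal-run region finder (max_gap_snps = 0 only)
brute_regions <- function(records, delta_exact = 1) {
  out <- list()
  for (chr in unique(records$chrom)) {
    d <- records[records$chrom == chr, ]
    d <- d[order(d$pos), ]
    qual <- d$delta >= delta_exact - 1e-9
    r <- rle(qual)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      members <- d$pos[starts[k]:ends[k]]
      out[[length(out) + 1]] <- data.frame(
        chrom = chr, start = min(members), end = max(members),
        n_members = length(members), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

# all permutations of seq_len(n), one per row (test-side oracle)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, sub + (sub >= k))))
}
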