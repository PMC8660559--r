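#' Construct a gene model
#'
#' A minimal transcript-level gene model for variant consequence calling:
#' exon and CDS intervals (1-based, inclusive, genomic coordinates) on one
#' strand, with a flanking window for upstream/downstream calls.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds two-column matrices (start, end) of 1-based inclusive
#'   intervals; CDS must lie within exons and its total length must be a
#'   multiple of 3.
#' @param flank_bp upstream/downstream window, bp.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds, flank_bp = 5000) {
  exons <- matrix(as.numeric(exons), ncol = 2)
  cds <- matrix(as.numeric(cds), ncol = 2)
  check_intervals <- function(iv, what) {
    if (any(iv[, 2] < iv[, 1]))
      stop(gene_id, ": malformed ", what, " interval", call. = FALSE)
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop(gene_id, ": overlapping ", what, " intervals", call. = FALSE)
    iv
  }
  exons <- check_intervals(exons, "exon")
  cds <- check_intervals(cds, "CDS")
  in_exon <- function(a, b) any(exons[, 1] <= a & exons[, 2] >= b)
  if (!all(mapply(in_exon, cds[, 1], cds[, 2])))
    stop(gene_id, ": CDS not contained in exons", call. = FALSE)
  cds_len <- sum(cds[, 2] - cds[, 1] + 1)
  if (cds_len %% 3 != 0)
    stop(gene_id, ": CDS length ", cds_len, " not divisible by 3",
         call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop(gene_id, ": strand must be '+' or '-'", call. = FALSE)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, flank_bp = flank_bp),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("Gene model %s (%s%s): %d exon(s), CDS %d bp\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              sum(x$cds[, 2] - x$cds[, 1] + 1)))
  invisible(x)
}

.in_intervals <- function(pos, iv) {
  any(iv[, 1] <= pos & iv[, 2] >= pos)
}

# distance to the nearest exon-intron junction; NA for single-exon genes
.junction_distance <- function(pos, model) {
  if (nrow(model$exons) < 2) return(NA_real_)
  ends <- model$exons[-nrow(model$exons), 2]    # junction at exon end
  starts <- model$exons[-1, 1]                  # junction at next exon start
  min(abs(pos - ends), abs(pos - starts))
}

# location of a position relative to ONE model; class + splice flag
.locate_in_model <- function(pos, model) {
  span <- range(model$exons)
  splice <- FALSE
  if (pos >= span[1] && pos <= span[2]) {
    jd <- .junction_distance(pos, model)
    splice <- !is.na(jd) && jd <= 3
    if (.in_intervals(pos, model$cds)) return(list(class = "coding",
                                                   splice = splice))
    if (.in_intervals(pos, model$exons)) {
      cds_span <- range(model$cds)
      before_cds <- pos < cds_span[1]
      utr <- if (model$strand == "+") {
        if (before_cds) "5utr" else "3utr"
      } else {
        if (before_cds) "3utr" else "5utr"
      }
      return(list(class = utr, splice = splice))
    }
    return(list(class = "intronic", splice = splice))
  }
  upstream_side <- if (model$strand == "+") pos < span[1] else pos > span[2]
  dist <- min(abs(pos - span))
  if (dist <= model$flank_bp)
    return(list(class = if (upstream_side) "upstream" else "downstream",
                splice = FALSE))
  list(class = "intergenic", splice = FALSE)
}

#' Classify the genomic location of a variant
#'
#' Assigns one primary location class per variant against a set of gene
#' models, by precedence coding (CDS) > UTR > intron > upstream /
#' downstream > intergenic across all models on the chromosome. Variants
#' within 3 bp of an exon-intron junction additionally carry a
#' splice-region flag.
#'
#' @param variant list or one-row data.frame with `chrom` and `pos`.
#' @param models list of [gene_model()] objects.
#' @return list with `class` (`"coding"`, `"5utr"`, `"3utr"`,
#'   `"intronic"`, `"upstream"`, `"downstream"` or `"intergenic"`),
#'   `splice_region` (logical) and `gene_id` (`NA` for intergenic).
#' @export
classify_location <- function(variant, models) {
  pos <- as.numeric(variant$pos)
  chrom <- as.character(variant$chrom)
  precedence <- c(coding = 1, "5utr" = 2, "3utr" = 2, intronic = 3,
                  upstream = 4, downstream = 4, intergenic = 5)
  best <- list(class = "intergenic", splice = FALSE, gene_id = NA_character_)
  best_rank <- precedence["intergenic"]
  for (m in models) {
    if (m$chrom != chrom) next
    loc <- .locate_in_model(pos, m)
    rank <- precedence[loc$class]
    if (rank < best_rank) {
      best <- list(class = loc$class, splice = loc$splice,
                   gene_id = m$gene_id)
      best_rank <- rank
    }
  }
  list(class = unname(best$class), splice_region = best$splice,
       gene_id = best$gene_id)
}

# CDS genomic positions in translation order (5' -> 3' of the transcript)
.cds_positions <- function(model) {
  pos <- unlist(lapply(seq_len(nrow(model$cds)),
                       function(i) seq(model$cds[i, 1], model$cds[i, 2])))
  if (model$strand == "-") rev(pos) else pos
}

.complement <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Coding consequence of a SNP inside a CDS
#'
#' Builds the affected codon from strand-aware CDS coordinates, applies
#' the substitution (complemented on the minus strand), translates with
#' the standard genetic code, and reports the consequence class with the
#' amino-acid change in `XnY` notation (`n` = residue number from the CDS
#' start).
#'
#' @param variant list or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (genomic, plus-strand alleles).
#' @param model a [gene_model()]; the variant must fall in its CDS.
#' @param ref_seq reference sequence: a named character vector / list of
#'   chromosome sequences, or a `Biostrings::DNAStringSet` named by
#'   chromosome.
#' @return list with `class` (`"synonymous"`, `"missense"`,
#'   `"stop_gained"` or `"stop_lost"`), `aa_change` (`""` for
#'   synonymous), `aa_pos`, `codon_ref`, `codon_alt`.
#' @export
coding_consequence <- function(variant, model, ref_seq) {
  pos <- as.numeric(variant$pos)
  ref <- as.character(variant$ref)
  alt <- as.character(variant$alt)
  if (!.in_intervals(pos, model$cds))
    stop("variant ", pos, " is not inside the CDS of ", model$gene_id,
         call. = FALSE)
  chrom_seq <- if (methods::is(ref_seq, "DNAStringSet")) {
    as.character(ref_seq[[model$chrom]])
  } else as.character(ref_seq[[model$chrom]])
  genomic_base <- toupper(substr(chrom_seq, pos, pos))
  if (genomic_base != toupper(ref))
    stop(sprintf("reference mismatch at %s:%.0f (sequence %s, variant ref %s)",
                 model$chrom, pos, genomic_base, ref), call. = FALSE)

  cds_pos <- .cds_positions(model)
  idx <- match(pos, cds_pos)
  aa_pos <- (idx - 1) %/% 3 + 1
  codon_idx <- cds_pos[(aa_pos - 1) * 3 + 1:3]
  fetch <- function(p) {
    b <- toupper(substr(chrom_seq, p, p))
    if (model$strand == "-") .complement(b) else b
  }
  codon_ref <- vapply(codon_idx, fetch, "")
  codon_alt <- codon_ref
  within <- match(pos, codon_idx)
  codon_alt[within] <- if (model$strand == "-") .complement(toupper(alt))
                       else toupper(alt)
  code <- Biostrings::GENETIC_CODE
  aa_ref <- code[[paste(codon_ref, collapse = "")]]
  aa_alt <- code[[paste(codon_alt, collapse = "")]]
  cls <- if (aa_ref == aa_alt) "synonymous"
         else if (aa_alt == "*") "stop_gained"
         else if (aa_ref == "*") "stop_lost"
         else "missense"
  aa_change <- if (cls == "synonymous") "" else paste0(aa_ref, aa_pos, aa_alt)
  list(class = cls, aa_change = aa_change, aa_pos = aa_pos,
       codon_ref = paste(codon_ref, collapse = ""),
       codon_alt = paste(codon_alt, collapse = ""))
}

#' Annotate variants against gene models
#'
#' Combines [classify_location()] and [coding_consequence()] over a table
#' of variants, producing a candidate-table-style annotation (position,
#' substitution, delta SNP index when present, effect, amino-acid change,
#' gene).
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `delta` and `sift`.
#' @param models list of [gene_model()] objects.
#' @param ref_seq reference sequence (see [coding_consequence()]);
#'   required whenever a variant falls in a CDS.
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `delta`,
#'   `effect`, `splice_region`, `aa_change`, `sift`, `gene`.
#' @export
annotate_variants <- function(variants, models, ref_seq = NULL) {
  n <- nrow(variants)
  effect <- character(n); aa <- character(n)
  gene <- character(n); splice <- logical(n)
  for (i in seq_len(n)) {
    v <- variants[i, , drop = FALSE]
    loc <- classify_location(v, models)
    splice[i] <- loc$splice_region
    gene[i] <- loc$gene_id
    if (loc$class == "coding") {
      if (is.null(ref_seq))
        stop("coding variant at ", v$chrom, ":", v$pos,
             " but no reference sequence supplied", call. = FALSE)
      model <- models[[which(vapply(models, function(m)
        identical(m$gene_id, loc$gene_id), logical(1)))[1]]]
      cc <- coding_consequence(v, model, ref_seq)
      effect[i] <- cc$class
      aa[i] <- cc$aa_change
    } else {
      effect[i] <- loc$class
      aa[i] <- ""
    }
  }
  data.frame(chrom = variants$chrom, pos = variants$pos,
             ref = variants$ref, alt = variants$alt,
             delta = if ("delta" %in% names(variants)) variants$delta else NA,
             effect = effect, splice_region = splice, aa_change = aa,
             sift = if ("sift" %in% names(variants)) variants$sift
                    else NA_real_,
             gene = gene, stringsAsFactors = FALSE)
}

#' Filter missense variants by deleteriousness score
#'
#' Keeps missense variants whose supplied pathogenicity score (SIFT-style:
#' 0 = deleterious, 1 = tolerated) is at most `sift_max`. Non-missense
#' records and missense records without a score are excluded; scores are
#' consumed from an input column, never computed.
#'
#' @param consequences data.frame with columns `effect` (matched
#'   case-insensitively against "missense") and `sift`.
#' @param sift_max maximum score retained.
#' @return the deleterious missense subset.
#' @export
filter_deleterious <- function(consequences, sift_max) {
  is_missense <- grepl("missense", tolower(consequences$effect))
  keep <- is_missense & !is.na(consequences$sift) &
    consequences$sift <= sift_max
  out <- consequences[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
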