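#' @include AllClasses.R AllGenerics.R cohort-io.R
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Build a five-group feature schema
#'
#' Fixes the feature layout: the sorted mutation-profile genes, the two
#' mutation rates, the six pyrimidine mutation spectra, the 96 trinucleotide
#' mutation signatures, and the sorted copy-number genes (prefixed `cnv:`).
#' Gene symbols are upper-cased; duplicates after case normalization are an
#' error.
#'
#' @param mutGenes genes for the mutation-profile block.
#' @param cnvGenes genes for the copy-number block.
#' @param territoryMb sequenced territory (megabases) used by the per-Mb
#'   mutation rate; default 38, a typical exome footprint.
#' @return a [FeatureSchema-class] of dimension
#'   `length(mutGenes) + 2 + 6 + 96 + length(cnvGenes)`.
#' @examples
#' sch <- buildSchema(paste0("G", 1:10), paste0("C", 1:5))
#' nFeatures(sch)  # 10 + 2 + 6 + 96 + 5 = 119
#' @export
buildSchema <- function(mutGenes, cnvGenes, territoryMb = 38) {
  mutGenes <- toupper(mutGenes)
  cnvGenes <- toupper(cnvGenes)
  if (anyDuplicated(mutGenes))
    stop("duplicate mutation-profile gene(s): ",
         paste(unique(mutGenes[duplicated(mutGenes)]), collapse = ", "))
  if (anyDuplicated(cnvGenes))
    stop("duplicate copy-number gene(s): ",
         paste(unique(cnvGenes[duplicated(cnvGenes)]), collapse = ", "))
  new("FeatureSchema", mutGenes = sort(mutGenes), cnvGenes = sort(cnvGenes),
      territoryMb = territoryMb)
}

#' Normalize a substitution to pyrimidine-strand spectrum and signature names
#'
#' Single-base substitutions are referenced to the pyrimidine strand: when the
#' reference base is a purine (A/G), ref and alt are complemented and the
#' flanks are swapped and complemented (the 5' flank of the pyrimidine-strand
#' representation is the complement of the original 3' flank, and vice versa).
#' The signature key is absent (NA) when either flank is unknown ("N").
#'
#' All arguments are vectorized.
#'
#' @param ref,alt reference and alternate bases (A/C/G/T, `ref != alt`).
#' @param context5,context3 5' and 3' flanking bases (A/C/G/T/N).
#' @return list with character vectors `spectrum` (e.g. `"C>T"`) and
#'   `signature` (e.g. `"GCA.C>T"`, NA when a flank is N).
#' @examples
#' normalizeToPyrimidine("G", "A", "T", "C")  # "C>T", "GCA.C>T"
#' @export
normalizeToPyrimidine <- function(ref, alt, context5 = "N", context3 = "N") {
  n <- max(length(ref), length(alt), length(context5), length(context3))
  ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
  c5 <- rep_len(toupper(context5), n); c3 <- rep_len(toupper(context3), n)
  if (any(!ref %in% .BASES) || any(!alt %in% .BASES))
    stop("ref and alt must be single bases in {A,C,G,T}")
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(!c5 %in% c(.BASES, "N")) || any(!c3 %in% c(.BASES, "N")))
    stop("contexts must be single bases in {A,C,G,T,N}")
  purine <- ref %in% c("A", "G")
  nref <- ifelse(purine, .COMPLEMENT[ref], ref)
  nalt <- ifelse(purine, .COMPLEMENT[alt], alt)
  n5 <- ifelse(purine, .COMPLEMENT[c3], c5)
  n3 <- ifelse(purine, .COMPLEMENT[c5], c3)
  spectrum <- paste0(nref, ">", nalt)
  signature <- ifelse(n5 == "N" | n3 == "N", NA_character_,
                      paste0(n5, nref, n3, ".", spectrum))
  list(spectrum = unname(spectrum), signature = unname(signature))
}

## Resolve the sample universe for per-block featurizers.
.resolveSamples <- function(variants, samples) {
  if (is.null(samples)) unique(variants@records$sample_id) else
    as.character(samples)
}

#' Gene-level mutation profile
#'
#' Counts protein-altering SNVs and indels per (sample, gene) over the
#' schema's mutation-profile genes. Variants in genes absent from the schema
#' are dropped, with a message reporting the dropped count.
#'
#' @param variants a [VariantTable-class] (already filtered to
#'   protein-altering records).
#' @param schema a [FeatureSchema-class].
#' @param samples sample universe (row order); default the variant table's
#'   samples.
#' @return integer matrix, samples x mutation-profile genes.
#' @export
mutationProfile <- function(variants, schema, samples = NULL) {
  samples <- .resolveSamples(variants, samples)
  genes <- schema@mutGenes
  df <- variants@records
  df$gene <- toupper(df$gene)
  keep <- df$gene %in% genes & df$sample_id %in% samples
  dropped <- sum(df$sample_id %in% samples & !df$gene %in% genes)
  if (dropped > 0)
    message(dropped, " variant(s) in genes outside the schema were dropped ",
            "from the mutation profile")
  M <- matrix(0L, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  if (any(keep)) {
    tab <- table(factor(df$sample_id[keep], levels = samples),
                 factor(df$gene[keep], levels = genes))
    M[] <- as.integer(tab)
  }
  M
}

#' Per-sample mutation rates
#'
#' Two rates per sample: the total filtered SNV+indel count per megabase of
#' sequenced territory, and the fraction of schema genes carrying at least
#' one variant.
#'
#' @inheritParams mutationProfile
#' @return numeric matrix, samples x 2, columns `snv_indel_per_mb` and
#'   `mutated_gene_fraction`.
#' @export
mutationRates <- function(variants, schema, samples = NULL) {
  samples <- .resolveSamples(variants, samples)
  df <- variants@records[variants@records$sample_id %in% samples, ,
                         drop = FALSE]
  df$gene <- toupper(df$gene)
  total <- table(factor(df$sample_id, levels = samples))
  ing <- df[df$gene %in% schema@mutGenes, , drop = FALSE]
  nGenes <- vapply(split(ing$gene, factor(ing$sample_id, levels = samples)),
                   function(g) length(unique(g)), integer(1))
  M <- cbind(as.numeric(total) / schema@territoryMb,
             nGenes / length(schema@mutGenes))
  dimnames(M) <- list(samples, .RATE_NAMES)
  M
}

## SNV records eligible for spectrum counting (ACGT ref/alt only).
.eligibleSnvs <- function(df) {
  df[df$variant_type == "SNP" & df$ref %in% .BASES & df$alt %in% .BASES, ,
     drop = FALSE]
}

#' Per-sample mutation spectra
#'
#' The proportion of each sample's SNVs falling in the six pyrimidine
#' substitution classes (purine-referenced SNVs are reverse-complemented).
#' Indels are ignored; a sample with no eligible SNVs gets an all-zero row.
#'
#' @inheritParams mutationProfile
#' @return numeric matrix, samples x 6, rows summing to 1 (or all zero).
#' @export
mutationSpectra <- function(variants, samples = NULL) {
  samples <- .resolveSamples(variants, samples)
  df <- .eligibleSnvs(variants@records)
  df <- df[df$sample_id %in% samples, , drop = FALSE]
  M <- matrix(0, nrow = length(samples), ncol = length(.SPECTRUM_NAMES),
              dimnames = list(samples, .SPECTRUM_NAMES))
  if (nrow(df) > 0) {
    spec <- normalizeToPyrimidine(df$ref, df$alt)$spectrum
    tab <- table(factor(df$sample_id, levels = samples),
                 factor(spec, levels = .SPECTRUM_NAMES))
    counts <- matrix(as.numeric(tab), nrow = length(samples))
    tot <- rowSums(counts)
    M[] <- counts / ifelse(tot == 0, 1, tot)
  }
  M
}

#' Per-sample 96-context mutation signatures
#'
#' The proportion of each sample's SNVs in the 96 trinucleotide substitution
#' contexts ({A,C,G,T} x 6 spectra x {A,C,G,T}), pyrimidine-referenced.
#' Flanking bases are taken from the variant records' `context5`/`context3`
#' columns; when absent and a `genome` is supplied they are looked up with
#' [fetchContext()]. SNVs with an "N" flank are excluded from numerator and
#' denominator; a sample with no eligible SNVs gets an all-zero row.
#'
#' @inheritParams mutationProfile
#' @param genome optional sequence source for [fetchContext()].
#' @return numeric matrix, samples x 96, rows summing to 1 (or all zero).
#' @export
mutationSignatures <- function(variants, genome = NULL, samples = NULL) {
  samples <- .resolveSamples(variants, samples)
  df <- .eligibleSnvs(variants@records)
  df <- df[df$sample_id %in% samples, , drop = FALSE]
  M <- matrix(0, nrow = length(samples), ncol = length(.SIGNATURE_NAMES),
              dimnames = list(samples, .SIGNATURE_NAMES))
  if (nrow(df) == 0) return(M)
  need <- is.na(df$context5) | is.na(df$context3)
  if (any(need)) {
    if (is.null(genome)) {
      i <- which(need)[1]
      stop(sprintf(paste0("variant %s %s:%d %s>%s has no trinucleotide ",
                          "context and no genome was supplied"),
                   df$sample_id[i], df$chrom[i], df$pos[i], df$ref[i],
                   df$alt[i]))
    }
    for (i in which(need)) {
      cx <- fetchContext(genome, df$chrom[i], df$pos[i])
      df$context5[i] <- cx[1]; df$context3[i] <- cx[2]
    }
  }
  sig <- normalizeToPyrimidine(df$ref, df$alt, df$context5,
                               df$context3)$signature
  ok <- !is.na(sig)
  if (any(ok)) {
    tab <- table(factor(df$sample_id[ok], levels = samples),
                 factor(sig[ok], levels = .SIGNATURE_NAMES))
    counts <- matrix(as.numeric(tab), nrow = length(samples))
    tot <- rowSums(counts)
    M[] <- counts / ifelse(tot == 0, 1, tot)
  }
  M
}

#' Gene-level copy-number features
#'
#' Accepts either a gene-level samples-by-genes log2 copy-ratio matrix (values
#' passed through; schema genes absent from the matrix filled with 0) or a
#' SEG-style segment table plus a gene-interval model, in which case each
#' gene's value is the length-weighted mean log2 ratio of its overlapping
#' segments (1-based inclusive overlap; 0 when nothing overlaps). Samples
#' missing from the source are zero-filled with a warning (log2 ratio 0 =
#' copy-neutral) or raise an error when `onMissingSample = "error"`.
#'
#' @param source either a numeric matrix with sample rows and gene columns,
#'   or `list(segments = <data.frame from readSegmentTable>,
#'   genes = <data.frame from readGeneIntervals>)`.
#' @param schema a [FeatureSchema-class].
#' @param samples sample universe (row order); default the source's samples.
#' @param onMissingSample "zero" (default) or "error".
#' @return numeric matrix, samples x cnv genes (unprefixed column names).
#' @importFrom GenomicRanges GRanges findOverlaps pintersect
#' @importFrom IRanges IRanges width
#' @importFrom S4Vectors queryHits subjectHits
#' @export
scnaFeatures <- function(source, schema, samples = NULL,
                         onMissingSample = c("zero", "error")) {
  onMissingSample <- match.arg(onMissingSample)
  genes <- schema@cnvGenes
  if (is.matrix(source) || is.data.frame(source)) {
    src <- as.matrix(source)
    colnames(src) <- toupper(colnames(src))
    if (is.null(samples)) samples <- rownames(src)
    M <- matrix(0, nrow = length(samples), ncol = length(genes),
                dimnames = list(samples, genes))
    missSamp <- setdiff(samples, rownames(src))
    if (length(missSamp) > 0) {
      if (onMissingSample == "error")
        stop("sample(s) absent from copy-number source: ",
             paste(missSamp, collapse = ", "))
      warning(length(missSamp),
              " sample(s) absent from the copy-number matrix were zero-filled")
    }
    shared <- intersect(samples, rownames(src))
    hit <- intersect(genes, colnames(src))
    M[shared, hit] <- src[shared, hit]
    return(M)
  }
  if (!is.list(source) || !all(c("segments", "genes") %in% names(source)))
    stop("source must be a gene-level matrix or list(segments=, genes=)")
  seg <- source$segments
  gi <- source$genes
  gi$gene <- toupper(gi$gene)
  gi <- gi[gi$gene %in% genes, , drop = FALSE]
  if (is.null(samples)) samples <- unique(seg$sample_id)
  M <- matrix(0, nrow = length(samples), ncol = length(genes),
              dimnames = list(samples, genes))
  missSamp <- setdiff(samples, unique(seg$sample_id))
  if (length(missSamp) > 0) {
    if (onMissingSample == "error")
      stop("sample(s) absent from segment table: ",
           paste(missSamp, collapse = ", "))
    warning(length(missSamp),
            " sample(s) absent from the segment table were zero-filled")
  }
  if (nrow(gi) == 0 || nrow(seg) == 0) return(M)
  gr <- GenomicRanges::GRanges(gi$chrom, IRanges::IRanges(gi$start, gi$end))
  for (s in intersect(samples, unique(seg$sample_id))) {
    ss <- seg[seg$sample_id == s, , drop = FALSE]
    sr <- GenomicRanges::GRanges(ss$chrom, IRanges::IRanges(ss$start, ss$end))
    ov <- GenomicRanges::findOverlaps(gr, sr)
    if (length(ov) == 0) next
    w <- IRanges::width(GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                                  sr[S4Vectors::subjectHits(ov)]))
    val <- ss$log2_ratio[S4Vectors::subjectHits(ov)]
    num <- tapply(w * val, gi$gene[S4Vectors::queryHits(ov)], sum)
    den <- tapply(w, gi$gene[S4Vectors::queryHits(ov)], sum)
    M[s, names(num)] <- as.numeric(num / den)
  }
  M
}

#' Assemble the full five-group feature matrix
#'
#' Builds one row per labeled sample with the blocks concatenated in schema
#' order [profile | rates | spectra | signatures | scna]. A labeled sample
#' must appear in the variant table or the copy-number source; a sample with
#' variants but no copy-number data gets a zero scna block (with a warning),
#' and vice versa.
#'
#' @param variants a [VariantTable-class].
#' @param scnaSource copy-number source, as in [scnaFeatures()].
#' @param labels named factor of sample labels (defines the row universe and
#'   order).
#' @param schema a [FeatureSchema-class].
#' @param genome optional sequence source for signature context lookup.
#' @return a [FeatureMatrix-class].
#' @export
assembleMatrix <- function(variants, scnaSource, labels, schema,
                           genome = NULL) {
  samples <- names(labels)
  scnaSamples <- if (is.matrix(scnaSource) || is.data.frame(scnaSource))
    rownames(scnaSource) else unique(scnaSource$segments$sample_id)
  orphan <- setdiff(samples, union(sampleIds(variants), scnaSamples))
  if (length(orphan) > 0)
    stop("labeled sample(s) absent from both variant and copy-number ",
         "sources: ", paste(orphan, collapse = ", "))
  vals <- cbind(mutationProfile(variants, schema, samples),
                mutationRates(variants, schema, samples),
                mutationSpectra(variants, samples),
                mutationSignatures(variants, genome, samples),
                scnaFeatures(scnaSource, schema, samples))
  colnames(vals) <- featureNames(schema)
  .newFeatureMatrix(vals, schema, labels)
}
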