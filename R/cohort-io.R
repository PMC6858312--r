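#' @include AllClasses.R AllGenerics.R
NULL

## Header aliases accepted for MAF-style variant tables.
.MAF_ALIASES <- list(
  sample_id     = c("sample_id", "sample", "Tumor_Sample_Barcode"),
  gene          = c("gene", "Hugo_Symbol", "gene_symbol"),
  chrom         = c("chrom", "chr", "Chromosome"),
  pos           = c("pos", "position", "Start_Position", "Start_position"),
  ref           = c("ref", "ref_allele", "Reference_Allele"),
  alt           = c("alt", "alt_allele", "Tumor_Seq_Allele2"),
  variant_type  = c("variant_type", "Variant_Type"),
  variant_class = c("variant_class", "Variant_Classification"),
  context5      = c("context5", "ref_context5"),
  context3      = c("context3", "ref_context3")
)

.resolveAlias <- function(header, aliases) {
  hit <- intersect(aliases, header)
  if (length(hit) == 0) NA_character_ else hit[1]
}

#' Default protein-altering variant classifications
#'
#' MAF `Variant_Classification` values counted as protein-altering and hence
#' retained by [readVariantTable()]. The set is a documented choice (missense,
#' nonsense, nonstop, splice-site, frameshift and in-frame indels, and
#' translation-start-site changes) and is fully configurable via the
#' `keepClasses` argument of the reader.
#'
#' @return character vector of classification strings.
#' @export
proteinAlteringClasses <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Splice_Site", "Frame_Shift_Del", "Frame_Shift_Ins",
    "In_Frame_Del", "In_Frame_Ins", "Translation_Start_Site")
}

#' Read a MAF-style somatic variant table
#'
#' Reads a tab-delimited variant file (standard MAF column names are accepted
#' as aliases for the canonical lower-case names), keeps only records whose
#' `variant_class` is in `keepClasses`, and returns them in input order with
#' coordinates unchanged (1-based inclusive). Optional `context5`/`context3`
#' columns carrying the flanking reference bases are preserved. Chromosome
#' names are used verbatim.
#'
#' @param path path to a tab-delimited file with a header.
#' @param keepClasses variant classifications to retain; default
#'   [proteinAlteringClasses()].
#' @return a [VariantTable-class].
#' @examples
#' maf <- tempfile(fileext = ".tsv")
#' writeLines(c(paste("sample", "gene", "chrom", "pos", "ref", "alt",
#'                    "variant_type", "variant_class", sep = "\t"),
#'              "S1\tTP53\tchr17\t7578406\tC\tT\tSNP\tMissense_Mutation"), maf)
#' readVariantTable(maf)
#' @export
readVariantTable <- function(path, keepClasses = proteinAlteringClasses()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          check.names = FALSE, comment.char = "#")
  header <- colnames(df)
  cols <- vapply(.MAF_ALIASES, .resolveAlias, character(1), header = header)
  required <- setdiff(names(.MAF_ALIASES), c("context5", "context3"))
  missing <- required[is.na(cols[required])]
  if (length(missing) > 0)
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  rec <- data.frame(sample_id = df[[cols["sample_id"]]],
                    gene = df[[cols["gene"]]],
                    chrom = df[[cols["chrom"]]],
                    pos_raw = df[[cols["pos"]]],
                    ref = toupper(df[[cols["ref"]]]),
                    alt = toupper(df[[cols["alt"]]]),
                    variant_type = df[[cols["variant_type"]]],
                    variant_class = df[[cols["variant_class"]]],
                    stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(rec$pos_raw))
  bad <- which(is.na(pos) & nzchar(rec$pos_raw))
  bad <- union(bad, which(is.na(rec$pos_raw)))
  if (length(bad) > 0)
    stop(sprintf("unparseable position at data line %d ('%s')",
                 bad[1], rec$pos_raw[bad[1]]))
  rec$pos <- pos
  rec$pos_raw <- NULL
  for (cx in c("context5", "context3")) {
    rec[[cx]] <- if (!is.na(cols[cx])) {
      v <- toupper(df[[cols[cx]]])
      ifelse(nzchar(v), v, NA_character_)
    } else rep(NA_character_, nrow(rec))
  }
  rec <- rec[rec$variant_class %in% keepClasses, , drop = FALSE]
  rownames(rec) <- NULL
  new("VariantTable", records = rec[, .VARIANT_COLUMNS, drop = FALSE])
}

#' Write a VariantTable as a MAF-style file
#'
#' Writes records with canonical MAF column names plus `context5`/`context3`.
#' `readVariantTable(writeVariantTable(x))` is the identity on the records.
#'
#' @param variants a [VariantTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  stopifnot(is(variants, "VariantTable"))
  df <- variants@records
  out <- data.frame(Tumor_Sample_Barcode = df$sample_id,
                    Hugo_Symbol = df$gene,
                    Chromosome = df$chrom,
                    Start_Position = df$pos,
                    Reference_Allele = df$ref,
                    Tumor_Seq_Allele2 = df$alt,
                    Variant_Type = df$variant_type,
                    Variant_Classification = df$variant_class,
                    context5 = ifelse(is.na(df$context5), "", df$context5),
                    context3 = ifelse(is.na(df$context3), "", df$context3),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-format copy-number segment table
#'
#' One record per row: sample, chromosome, 1-based inclusive start/end and the
#' segment mean log2 copy ratio, taken as-is.
#'
#' @param path path to a tab-delimited SEG file with header columns
#'   sample/ID, chrom/Chromosome, start/Start, end/End and
#'   seg.mean/Segment_Mean/log2.
#' @return data.frame with columns sample_id, chrom, start, end, log2_ratio.
#' @export
readSegmentTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  header <- colnames(df)
  aliases <- list(sample_id = c("sample", "sample_id", "ID", "Sample"),
                  chrom = c("chrom", "chr", "Chromosome"),
                  start = c("start", "Start", "loc.start"),
                  end = c("end", "End", "loc.end"),
                  log2_ratio = c("seg.mean", "log2", "Segment_Mean",
                                 "log2_ratio"))
  cols <- vapply(aliases, .resolveAlias, character(1), header = header)
  if (anyNA(cols))
    stop("segment table is missing required column(s): ",
         paste(names(cols)[is.na(cols)], collapse = ", "))
  out <- data.frame(sample_id = as.character(df[[cols["sample_id"]]]),
                    chrom = as.character(df[[cols["chrom"]]]),
                    start = as.integer(df[[cols["start"]]]),
                    end = as.integer(df[[cols["end"]]]),
                    log2_ratio = as.numeric(df[[cols["log2_ratio"]]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start > out$end)
  if (length(bad) > 0)
    stop(sprintf("segment start > end at data line %d", bad[1]))
  out
}

#' Read a BED-like gene-interval file
#'
#' BED input is 0-based half-open and is converted to the package's internal
#' 1-based inclusive convention (start + 1, end unchanged). Duplicate gene
#' symbols on the same chromosome are merged to their spanning interval with a
#' warning.
#'
#' @param path path to a whitespace- or tab-delimited headerless file with
#'   columns chrom, start, end, gene.
#' @return data.frame with columns gene, chrom, start, end (1-based
#'   inclusive), one row per gene.
#' @export
readGeneIntervals <- function(path) {
  df <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "",
                      col.names = c("chrom", "start", "end", "gene"),
                      colClasses = c("character", "integer", "integer",
                                     "character"),
                      comment.char = "#"),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), gene = character(0)))
      stop("malformed gene-interval file: ", conditionMessage(e))
    })
  if (nrow(df) == 0)
    return(data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  if (anyNA(df$start) || anyNA(df$end))
    stop(sprintf("malformed interval at line %d",
                 which(is.na(df$start) | is.na(df$end))[1]))
  df$start <- df$start + 1L  # BED 0-based half-open -> 1-based inclusive
  if (anyDuplicated(df$gene)) {
    dup <- unique(df$gene[duplicated(df$gene)])
    warning(sprintf("%d duplicate gene symbol(s) merged to spanning intervals: %s",
                    length(dup), paste(utils::head(dup, 5), collapse = ", ")))
    merged <- lapply(split(df, df$gene), function(g) {
      if (length(unique(g$chrom)) > 1)
        stop("gene ", g$gene[1], " maps to multiple chromosomes")
      data.frame(gene = g$gene[1], chrom = g$chrom[1],
                 start = min(g$start), end = max(g$end))
    })
    out <- do.call(rbind, merged)
  } else {
    out <- data.frame(gene = df$gene, chrom = df$chrom,
                      start = df$start, end = df$end)
  }
  out <- out[order(match(out$gene, df$gene)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Look up the flanking bases of a genomic position
#'
#' Returns the uppercased reference bases immediately 5' and 3' of a 1-based
#' position. A flank that falls off the contig boundary is returned as "N"
#' (callers drop such variants from signature counting).
#'
#' @param genome a named [Biostrings::DNAStringSet] (e.g. from
#'   [Biostrings::readDNAStringSet()]) or a named character vector of contig
#'   sequences.
#' @param chrom contig name; unknown contigs are an error.
#' @param pos 1-based position; must lie on the contig.
#' @return character vector `c(context5, context3)`.
#' @importFrom Biostrings readDNAStringSet
#' @export
fetchContext <- function(genome, chrom, pos) {
  seqs <- if (is.character(genome)) genome else
    as.character(genome)  # DNAStringSet -> named character
  if (!chrom %in% names(seqs))
    stop("unknown contig: ", chrom)
  s <- toupper(seqs[[chrom]])
  len <- nchar(s)
  if (pos < 1 || pos > len)
    stop(sprintf("position %d outside contig %s (length %d)", pos, chrom, len))
  c5 <- if (pos - 1 >= 1) substr(s, pos - 1, pos - 1) else "N"
  c3 <- if (pos + 1 <= len) substr(s, pos + 1, pos + 1) else "N"
  c(c5, c3)
}

#' Read and write sample-label tables
#'
#' A label table is two-column tab-delimited text (sample identifier, cancer
#' type) with a header. Duplicate sample identifiers are an error. The result
#' is a named factor; the level order is the order of first appearance.
#'
#' @param path file path.
#' @return `readLabelTable`: a named factor mapping sample_id to label.
#' @export
readLabelTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) stop("label table needs two columns (sample, label)")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample_id in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  labs <- df[[2]]
  stats::setNames(factor(labs, levels = unique(labs)), ids)
}

#' @rdname readLabelTable
#' @param labels named factor or character vector of labels.
#' @return `writeLabelTable`: `path`, invisibly.
#' @export
writeLabelTable <- function(labels, path) {
  utils::write.table(data.frame(sample = names(labels),
                                label = as.character(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read a feature matrix as delimited text
#'
#' The canonical on-disk form is a TSV with a `sample` column followed by one
#' column per schema feature; the sequenced territory is stored in a
#' `#territory_mb=` comment line so the schema can be rebuilt on read.
#' Writing then reading is the identity on schema order, sample order and
#' values (to well below 1e-9).
#'
#' @param fm a [FeatureMatrix-class].
#' @param path file path.
#' @return `writeFeatureMatrix`: `path`, invisibly; `readFeatureMatrix`: a
#'   [FeatureMatrix-class] (unlabeled unless `labels` is given).
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  vals <- featureValues(fm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#territory_mb=%.10g", fm@schema@territoryMb), con)
  out <- data.frame(sample = rownames(vals), vals, check.names = FALSE)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @param labels optional named factor of sample labels to attach.
#' @export
readFeatureMatrix <- function(path, labels = NULL) {
  first <- readLines(path, n = 1)
  territory <- if (grepl("^#territory_mb=", first))
    as.numeric(sub("^#territory_mb=", "", first)) else 38
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#")
  if (colnames(df)[1] != "sample")
    stop("feature-matrix file must start with a 'sample' column")
  feats <- colnames(df)[-1]
  fixed <- c(.RATE_NAMES, .SPECTRUM_NAMES, .SIGNATURE_NAMES)
  if (!all(fixed %in% feats))
    stop("feature-matrix header does not contain the fixed rate/spectrum/",
         "signature columns; not a schema-conformant matrix")
  cnv <- sub("^cnv:", "", feats[startsWith(feats, "cnv:")])
  mut <- setdiff(feats[!startsWith(feats, "cnv:")], fixed)
  schema <- new("FeatureSchema", mutGenes = mut, cnvGenes = cnv,
                territoryMb = territory)
  want <- featureNames(schema)
  if (!identical(feats, want))
    stop("feature-matrix columns are not in schema order")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$sample
  .newFeatureMatrix(vals, schema, labels)
}

## Build a FeatureMatrix from a samples-by-features matrix.
.newFeatureMatrix <- function(vals, schema, labels = NULL) {
  cd <- if (is.null(labels)) {
    S4Vectors::DataFrame(row.names = rownames(vals))
  } else {
    S4Vectors::DataFrame(label = as.character(labels[rownames(vals)]),
                         row.names = rownames(vals))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(vals)),
    rowData = S4Vectors::DataFrame(group = featureGroups(schema)),
    colData = cd)
  new("FeatureMatrix", se, schema = schema)
}
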