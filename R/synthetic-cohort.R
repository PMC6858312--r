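#' @include AllClasses.R feature-construction.R
NULL

#' Default synthetic-cohort configurations
#'
#' Two fully specified, seeded study designs: `tiny` (3 types x 30 samples,
#' 200 mutation genes, 100 copy-number genes) for unit tests, and `desk`
#' (6 types x 200 samples, 2,000 mutation genes, 1,000 copy-number genes) for
#' desk-scale evaluation runs. Any field can be overridden afterwards.
#'
#' @param scale "tiny" or "desk".
#' @return a `SimulationConfig` list; see [simulateCohort()] for the fields.
#' @examples
#' cfg <- defaultSimulationConfig("tiny")
#' cfg$nTypes * cfg$samplesPerType  # 90 samples
#' @export
defaultSimulationConfig <- function(scale = c("tiny", "desk")) {
  scale <- match.arg(scale)
  base <- list(
    driversPerType = 3L,
    driverMutationProb = 0.5,
    backgroundMutationRate = 30,
    burdenLognormalSigma = 0.5,
    signatureDirichletAlpha = 5,
    hotContextsPerType = 8L,
    hotContextMass = 0.6,
    hotContextSpectrum = NA_character_,
    indelFraction = 0.1,
    cnaLog2ShiftMean = 0.4,
    cnaLog2ShiftSd = 0.2,
    cnaNoiseSd = 0.1,
    territoryMb = 38,
    seed = 42L)
  dims <- switch(scale,
    tiny = list(nTypes = 3L, samplesPerType = 30L, nMutGenes = 200L,
                nCnvGenes = 100L, cnaGenesPerType = 10L),
    desk = list(nTypes = 6L, samplesPerType = 200L, nMutGenes = 2000L,
                nCnvGenes = 1000L, cnaGenesPerType = 30L, seed = 7L))
  cfg <- utils::modifyList(base, dims)
  structure(cfg, class = "SimulationConfig")
}

.validateConfig <- function(cfg) {
  counts <- c("nTypes", "nMutGenes", "nCnvGenes", "driversPerType",
              "cnaGenesPerType", "hotContextsPerType")
  for (f in counts)
    if (is.null(cfg[[f]]) || any(cfg[[f]] < 1))
      stop("config field ", f, " must be >= 1")
  spp <- cfg$samplesPerType
  if (!(length(spp) == 1 || length(spp) == cfg$nTypes) || any(spp < 1))
    stop("samplesPerType must be a single count or one count per type")
  for (f in c("driverMutationProb", "hotContextMass", "indelFraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config field ", f, " must be a probability in [0,1]")
  if (cfg$driversPerType > cfg$nMutGenes)
    stop("driversPerType cannot exceed nMutGenes")
  if (cfg$cnaGenesPerType > cfg$nCnvGenes)
    stop("cnaGenesPerType cannot exceed nCnvGenes")
  pool <- length(.hotContextPool(cfg))
  if (cfg$nTypes * cfg$hotContextsPerType > pool)
    stop("nTypes * hotContextsPerType cannot exceed the ", pool,
         " available contexts")
  invisible(cfg)
}

## Contexts eligible as type-specific "hot" contexts. Confining them to one
## spectrum class (hotContextSpectrum) plants signal in the signature block
## while leaving the 6-class spectrum marginals uninformative.
.hotContextPool <- function(cfg) {
  sp <- cfg$hotContextSpectrum
  if (is.null(sp) || is.na(sp)) return(.SIGNATURE_NAMES)
  if (!sp %in% .SPECTRUM_NAMES)
    stop("hotContextSpectrum must be one of ",
         paste(.SPECTRUM_NAMES, collapse = ", "))
  grep(paste0("\\.", sp, "$"), .SIGNATURE_NAMES, value = TRUE)
}

## Decode a 96-context signature key into (context5, ref, context3, alt).
.decodeSignature <- function(keys) {
  data.frame(context5 = substr(keys, 1, 1), ref = substr(keys, 2, 2),
             context3 = substr(keys, 3, 3), alt = substr(keys, 7, 7),
             stringsAsFactors = FALSE)
}

#' Simulate a labeled multi-class cohort with planted, recoverable signal
#'
#' Emulates the statistical structure the pipeline exploits: cancer types
#' leave type-specific footprints in the mutation data. Per type the
#' generator plants (i) driver genes that absorb `driverMutationProb` of each
#' SNV's gene-assignment probability, (ii) a 96-context signature vector that
#' puts `hotContextMass` on `hotContextsPerType` type-specific "hot"
#' trinucleotide contexts (disjoint across types; confined to one
#' substitution class when `hotContextSpectrum` is set, which keeps the
#' 6-class spectrum marginals uninformative) over a shared Dirichlet
#' background, and (iii) `cnaGenesPerType` copy-number genes shifted by
#' N(`cnaLog2ShiftMean`, `cnaLog2ShiftSd`) over N(0, `cnaNoiseSd`) noise.
#'
#' Per sample, the SNV count is lognormal
#' (`log(backgroundMutationRate)`, `burdenLognormalSigma`); each SNV draws a
#' context category from the type's signature vector and carries its flanking
#' bases on the record (half the SNVs are emitted in their purine-strand
#' representation to exercise pyrimidine normalization); roughly
#' `indelFraction` of the SNV count is added as context-free indels in random
#' genes. The same config and seed reproduce the output exactly.
#'
#' @param config a `SimulationConfig`, e.g. from [defaultSimulationConfig()].
#' @return list with elements `variants` ([VariantTable-class]), `cnv`
#'   (samples x genes log2-ratio matrix), `labels` (named factor) and `truth`
#'   (a `SimulationTruth` list: per-type `driverGenes`, `signatureVectors`
#'   (96 x types, columns sum to 1), `hotContexts`, `cnaGenes`, and
#'   `informativeFeatures`, the union of all planted feature names).
#' @importFrom withr with_seed
#' @importFrom stats rnorm rlnorm rgamma
#' @export
simulateCohort <- function(config = defaultSimulationConfig("tiny")) {
  cfg <- .validateConfig(config)
  withr::with_seed(cfg$seed, .simulateCohortImpl(cfg))
}

.simulateCohortImpl <- function(cfg) {
  types <- paste0("type", seq_len(cfg$nTypes))
  mutGenes <- sprintf("MG%04d", seq_len(cfg$nMutGenes))
  cnvGenes <- sprintf("CG%04d", seq_len(cfg$nCnvGenes))
  spp <- rep_len(cfg$samplesPerType, cfg$nTypes)

  ## --- planted truth ---
  drivers <- lapply(seq_len(cfg$nTypes), function(i)
    sample(mutGenes, cfg$driversPerType))
  hotPool <- sample(.hotContextPool(cfg),
                    cfg$nTypes * cfg$hotContextsPerType)
  hot <- split(hotPool, rep(seq_len(cfg$nTypes),
                            each = cfg$hotContextsPerType))
  bg <- rgamma(length(.SIGNATURE_NAMES), shape = cfg$signatureDirichletAlpha)
  bg <- bg / sum(bg)  # shared Dirichlet background across types
  sigVec <- vapply(seq_len(cfg$nTypes), function(i) {
    v <- (1 - cfg$hotContextMass) * bg
    idx <- match(hot[[i]], .SIGNATURE_NAMES)
    v[idx] <- v[idx] + cfg$hotContextMass / length(idx)
    v / sum(v)
  }, numeric(length(.SIGNATURE_NAMES)))
  dimnames(sigVec) <- list(.SIGNATURE_NAMES, types)
  cnaSets <- lapply(seq_len(cfg$nTypes), function(i)
    sample(cnvGenes, cfg$cnaGenesPerType))
  names(drivers) <- names(hot) <- names(cnaSets) <- types

  ## --- samples and labels ---
  ids <- unlist(lapply(seq_len(cfg$nTypes), function(i)
    sprintf("%s_S%03d", types[i], seq_len(spp[i]))))
  labels <- stats::setNames(
    factor(rep(types, spp), levels = types), ids)

  ## --- variants ---
  indelClasses <- c(INS = "Frame_Shift_Ins", DEL = "Frame_Shift_Del")
  snvClasses <- c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site")
  perSample <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    ty <- as.character(labels[j])
    nSnv <- max(1L, round(rlnorm(1, log(cfg$backgroundMutationRate),
                                 cfg$burdenLognormalSigma)))
    isDriver <- stats::runif(nSnv) < cfg$driverMutationProb
    dset <- drivers[[ty]]
    gene <- ifelse(isDriver,
                   dset[sample.int(length(dset), nSnv, replace = TRUE)],
                   mutGenes[sample.int(length(mutGenes), nSnv,
                                       replace = TRUE)])
    ctxIdx <- sample.int(96L, nSnv, replace = TRUE, prob = sigVec[, ty])
    dec <- .decodeSignature(.SIGNATURE_NAMES[ctxIdx])
    ## emit about half the SNVs in purine-strand representation
    flip <- stats::runif(nSnv) < 0.5
    ref <- ifelse(flip, .COMPLEMENT[dec$ref], dec$ref)
    alt <- ifelse(flip, .COMPLEMENT[dec$alt], dec$alt)
    c5 <- ifelse(flip, .COMPLEMENT[dec$context3], dec$context5)
    c3 <- ifelse(flip, .COMPLEMENT[dec$context5], dec$context3)
    snv <- data.frame(
      sample_id = ids[j], gene = gene,
      chrom = paste0("chr", sample.int(22L, nSnv, replace = TRUE)),
      pos = sample.int(100000000L, nSnv, replace = TRUE),
      ref = unname(ref), alt = unname(alt),
      variant_type = "SNP",
      variant_class = sample(snvClasses, nSnv, replace = TRUE,
                             prob = c(0.7, 0.15, 0.15)),
      context5 = unname(c5), context3 = unname(c3),
      stringsAsFactors = FALSE)
    nIndel <- round(cfg$indelFraction * nSnv)
    if (nIndel > 0) {
      itype <- sample(c("INS", "DEL"), nIndel, replace = TRUE)
      indel <- data.frame(
        sample_id = ids[j],
        gene = sample(mutGenes, nIndel, replace = TRUE),
        chrom = paste0("chr", sample.int(22L, nIndel, replace = TRUE)),
        pos = sample.int(100000000L, nIndel, replace = TRUE),
        ref = ifelse(itype == "DEL", "A", "-"),
        alt = ifelse(itype == "DEL", "-", "A"),
        variant_type = itype,
        variant_class = unname(indelClasses[itype]),
        context5 = NA_character_, context3 = NA_character_,
        stringsAsFactors = FALSE)
      snv <- rbind(snv, indel)
    }
    perSample[[j]] <- snv
  }
  variants <- new("VariantTable",
                  records = do.call(rbind, perSample))

  ## --- copy-number matrix ---
  cnv <- matrix(rnorm(length(ids) * cfg$nCnvGenes, 0, cfg$cnaNoiseSd),
                nrow = length(ids), ncol = cfg$nCnvGenes,
                dimnames = list(ids, cnvGenes))
  for (ty in types) {
    rows <- which(labels == ty)
    cols <- match(cnaSets[[ty]], cnvGenes)
    cnv[rows, cols] <- cnv[rows, cols] +
      rnorm(length(rows) * length(cols), cfg$cnaLog2ShiftMean,
            cfg$cnaLog2ShiftSd)
  }

  truth <- structure(list(
    driverGenes = drivers,
    signatureVectors = sigVec,
    hotContexts = hot,
    cnaGenes = cnaSets,
    informativeFeatures = unique(c(unlist(drivers), unlist(hot),
                                   paste0("cnv:", unlist(cnaSets))))),
    class = "SimulationTruth")

  list(variants = variants, cnv = cnv, labels = labels, truth = truth,
       config = cfg, mutGenes = mutGenes, cnvGenes = cnvGenes)
}

#' Write a simulated cohort to a directory
#'
#' Writes `maf.tsv`, `cnv_matrix.tsv`, `labels.tsv` and `truth.json` so the
#' cohort can be consumed through the file-based readers or the command-line
#' interface.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeVariantTable(cohort$variants, file.path(dir, "maf.tsv"))
  cnv <- data.frame(sample = rownames(cohort$cnv), cohort$cnv,
                    check.names = FALSE)
  utils::write.table(cnv, file.path(dir, "cnv_matrix.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLabelTable(cohort$labels, file.path(dir, "labels.tsv"))
  truth <- cohort$truth
  truth$signatureVectors <- as.data.frame(truth$signatureVectors)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Featurize a simulated cohort
#'
#' Convenience wrapper: builds the schema over the simulated gene universes
#' and assembles the five-group feature matrix.
#'
#' @param cohort result of [simulateCohort()].
#' @return a [FeatureMatrix-class].
#' @export
cohortFeatureMatrix <- function(cohort) {
  schema <- buildSchema(cohort$mutGenes, cohort$cnvGenes,
                        territoryMb = cohort$config$territoryMb)
  suppressWarnings(assembleMatrix(cohort$variants, cohort$cnv,
                                  cohort$labels, schema))
}
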