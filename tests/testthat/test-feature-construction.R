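## In-code variant-table constructor for hand-built cases.
vt <- function(sample, gene, ref, alt, type = "SNP",
               class = "Missense_Mutation", c5 = NA_character_,
               c3 = NA_character_, chrom = "chr1", pos = NULL) {
  n <- max(length(sample), length(gene), length(ref), length(alt))
  if (is.null(pos)) pos <- seq_len(n) + 100L
  new("VariantTable", records = data.frame(
    sample_id = rep_len(sample, n), gene = rep_len(gene, n),
    chrom = rep_len(chrom, n), pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n), alt = rep_len(alt, n),
    variant_type = rep_len(type, n), variant_class = rep_len(class, n),
    context5 = rep_len(c5, n), context3 = rep_len(c3, n),
    stringsAsFactors = FALSE))
}

test_that("schema dimension identity holds and duplicates are rejected", {
  sch <- buildSchema(paste0("G", 1:10), paste0("C", 1:5))
  expect_equal(nFeatures(sch), 119L)  # 10 + 2 + 6 + 96 + 5
  expect_equal(sum(featureGroups(sch) == "signatures"), 96L)
  expect_equal(length(featureNames(sch)), nFeatures(sch))
  expect_false(anyDuplicated(featureNames(sch)) > 0)
  expect_error(buildSchema(c("TP53", "tp53"), "C1"), "duplicate")
  ## dimension identity on random gene-list sizes
  for (gm in c(1, 7, 40)) for (gc in c(1, 13)) {
    s <- buildSchema(paste0("M", seq_len(gm)), paste0("K", seq_len(gc)))
    expect_equal(nFeatures(s), gm + 2 + 6 + 96 + gc)
  }
})

test_that("pyrimidine normalization complements purine-strand calls", {
  expect_equal(normalizeToPyrimidine("C", "T", "A", "A"),
               list(spectrum = "C>T", signature = "ACA.C>T"))
  ## purine ref: complement alleles, swap-and-complement flanks (TGC -> GCA)
  expect_equal(normalizeToPyrimidine("G", "A", "T", "C"),
               list(spectrum = "C>T", signature = "GCA.C>T"))
  ## N flank suppresses the signature but not the spectrum
  r <- normalizeToPyrimidine("T", "G", "N", "A")
  expect_equal(r$spectrum, "T>G")
  expect_true(is.na(r$signature))
  expect_error(normalizeToPyrimidine("A", "A", "C", "C"), "differ")
  expect_error(normalizeToPyrimidine("X", "A"), "base")
})

test_that("mutation profile counts per gene and drops off-schema genes", {
  sch <- buildSchema(c("GENE1", "GENE2", "GENE3"), "C1")
  v <- vt("S1", c("GENE1", "GENE1", "GENE2", "WEIRD"),
          c("C", "C", "C", "C"), c("T", "T", "T", "T"),
          type = c("SNP", "SNP", "DEL", "SNP"))
  expect_message(P <- mutationProfile(v, sch), "dropped")
  expect_equal(as.integer(P["S1", ]), c(2L, 1L, 0L))
  ## sample with no variants gets an all-zero row
  P2 <- mutationProfile(v, sch, samples = c("S1", "S2"))
  expect_equal(sum(P2["S2", ]), 0L)
})

test_that("mutation rates use territory and schema gene fraction", {
  sch <- buildSchema(paste0("G", 1:20), "C1", territoryMb = 38)
  v <- vt("S1", paste0("G", rep(1:5, length.out = 76)), "C", "T")
  R <- mutationRates(v, sch)
  expect_equal(unname(R["S1", "snv_indel_per_mb"]), 2.0)  # 76 / 38
  expect_equal(unname(R["S1", "mutated_gene_fraction"]), 0.25)  # 5 / 20
  v0 <- vt("S1", "G1", "C", "T")
  v0@records <- v0@records[0, ]
  R0 <- mutationRates(v0, sch, samples = "S1")
  expect_equal(unname(R0["S1", ]), c(0, 0), ignore_attr = TRUE)
})

test_that("spectra are SNV-only pyrimidine proportions", {
  v <- vt("S1", "G1", c("C", "C", "G"), c("T", "T", "A"))
  S <- mutationSpectra(v)
  expect_equal(unname(S["S1", ]), c(0, 0, 1, 0, 0, 0))  # G>A complements to C>T
  v2 <- vt("S1", "G1", "T", "G")
  expect_equal(unname(mutationSpectra(v2)["S1", "T>G"]), 1.0)
  ## indels only -> all-zero row
  v3 <- vt("S1", "G1", "-", "A", type = "INS")
  expect_equal(sum(mutationSpectra(v3)), 0)
})

test_that("signatures count trinucleotide contexts and respect N exclusion", {
  v <- vt("S1", "G1", c("C", "C"), c("T", "T"), c5 = "A", c3 = "A")
  G <- mutationSignatures(v)
  expect_equal(unname(G["S1", "ACA.C>T"]), 1.0)
  expect_equal(sum(G["S1", ]), 1.0)
  ## purine-strand record lands on the reverse-complement key
  v2 <- vt("S1", "G1", "G", "A", c5 = "T", c3 = "C")
  expect_equal(unname(mutationSignatures(v2)["S1", "GCA.C>T"]), 1.0)
  ## N context excluded from numerator and denominator
  v3 <- vt("S1", "G1", "C", "T", c5 = "N", c3 = "A")
  expect_equal(sum(mutationSignatures(v3)["S1", ]), 0)
  ## missing context with no genome names the record
  v4 <- vt("S1", "G1", "C", "T")
  expect_error(mutationSignatures(v4), "no trinucleotide context")
  ## genome lookup fills contexts: pos 3 of c1 = ACGTA -> flanks C,T
  v5 <- vt("S1", "G1", "G", "A", chrom = "c1", pos = 3)
  expect_equal(unname(mutationSignatures(v5, genome = toyGenome())["S1", "ACG.C>T"]),
               1.0)  # CGT revcomps to ACG
})

test_that("strand invariance: reverse-complement representation changes nothing", {
  co <- tinyCohort()
  rec <- variantRecords(co$variants)
  snp <- rec$variant_type == "SNP"
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  flipped <- rec
  flipped$ref[snp] <- comp[rec$ref[snp]]
  flipped$alt[snp] <- comp[rec$alt[snp]]
  flipped$context5[snp] <- comp[rec$context3[snp]]
  flipped$context3[snp] <- comp[rec$context5[snp]]
  vflip <- new("VariantTable", records = flipped)
  expect_equal(mutationSpectra(vflip), mutationSpectra(co$variants))
  expect_equal(mutationSignatures(vflip), mutationSignatures(co$variants))
})

test_that("signature proportions marginalize to spectrum proportions", {
  co <- tinyCohort()
  ## all simulated SNVs carry contexts, so the eligible sets coincide
  S <- mutationSpectra(co$variants)
  G <- mutationSignatures(co$variants)
  for (sp in colnames(S)) {
    cols <- grep(paste0("\\.", sp, "$"), colnames(G))
    expect_length(cols, 16L)
    expect_lt(max(abs(rowSums(G[, cols]) - S[, sp])), 1e-9)
  }
})

test_that("copy-number featurization handles both source forms", {
  sch <- buildSchema("G1", c("GENEA", "GENEB"))
  ## matrix passthrough with zero-fill for missing genes/samples
  m <- matrix(c(0.5, -0.2), nrow = 1,
              dimnames = list("S1", c("GENEA", "OTHER")))
  expect_warning(V <- scnaFeatures(m, sch, samples = c("S1", "S2")),
                 "zero-filled")
  expect_equal(unname(V["S1", ]), c(0.5, 0))
  expect_equal(unname(V["S2", ]), c(0, 0))
  expect_error(scnaFeatures(m, sch, samples = c("S1", "S2"),
                            onMissingSample = "error"), "absent")

  ## segment form: length-weighted mean over 1-based inclusive overlap
  genes <- data.frame(gene = c("GENEA", "GENEB"), chrom = "chr1",
                      start = c(101L, 501L), end = c(200L, 600L))
  segs <- data.frame(sample_id = "S1", chrom = "chr1",
                     start = c(101L, 161L), end = c(160L, 200L),
                     log2_ratio = c(0.5, -0.5))
  V2 <- scnaFeatures(list(segments = segs, genes = genes), sch)
  expect_equal(unname(V2["S1", "GENEA"]), 0.5 * 0.6 + (-0.5) * 0.4)
  expect_equal(unname(V2["S1", "GENEB"]), 0)  # no overlapping segment
})

test_that("assembled matrix concatenates blocks in schema order", {
  fm <- tinyFeatureMatrix()
  expect_equal(dim(featureValues(fm)), c(90L, 404L))
  groups <- featureGroups(fm)
  expect_equal(as.character(unique(groups)),
               c("profile", "rates", "spectra", "signatures", "scna"))
  vals <- featureValues(fm)
  prof <- vals[, groups == "profile"]
  expect_true(all(prof >= 0 & prof == round(prof)))
  for (g in c("spectra", "signatures")) {
    rs <- rowSums(vals[, groups == g])
    expect_true(all(abs(rs - 1) < 1e-9 | rs == 0))
  }
  ## profile column sums equal total filtered per-gene counts
  rec <- variantRecords(tinyCohort()$variants)
  counts <- table(factor(rec$gene, levels = colnames(prof)))
  expect_equal(unname(colSums(prof)), as.numeric(counts))
  ## a labeled sample missing everywhere is an error
  labs <- c(sampleLabels(fm),
            stats::setNames(factor("type1", levels(sampleLabels(fm))),
                            "GHOST"))
  expect_error(assembleMatrix(tinyCohort()$variants, tinyCohort()$cnv,
                              labs, featureSchema(fm)), "GHOST")
})
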