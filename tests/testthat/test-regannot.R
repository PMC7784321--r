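# one toy genome used across the annotation tests:
#   geneA  + strand, single exon 2001-2090, fully coding (30 codons)
#   geneB  - strand, exon 5001-5200, CDS 5021-5110
#   geneC  + strand, exons 8001-8100 / 8201-8300, CDS spans both
toy_genome <- local({
  withr::with_seed(101, {
    seq <- sample(c("A", "C", "G", "T"), 12000, replace = TRUE)
  })
  seq[2001:2006] <- c("A", "T", "G", "C", "T", "T")  # ATG CTT ...
  fa <- tempfile(fileext = ".fa")
  dna <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(dna) <- "chrT"
  Biostrings::writeXStringSet(dna, fa)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t2001\t2090\t.\t+\t.\tID=geneA;Name=GENEA",
    "chrT\ttoy\tmRNA\t2001\t2090\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chrT\ttoy\texon\t2001\t2090\t.\t+\t.\tID=geneA.e1;Parent=geneA.t1",
    "chrT\ttoy\tCDS\t2001\t2090\t.\t+\t0\tID=geneA.c1;Parent=geneA.t1",
    "chrT\ttoy\tgene\t5001\t5200\t.\t-\t.\tID=geneB;Name=GENEB",
    "chrT\ttoy\tmRNA\t5001\t5200\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chrT\ttoy\texon\t5001\t5200\t.\t-\t.\tID=geneB.e1;Parent=geneB.t1",
    "chrT\ttoy\tCDS\t5021\t5110\t.\t-\t0\tID=geneB.c1;Parent=geneB.t1",
    "chrT\ttoy\tgene\t8001\t8300\t.\t+\t.\tID=geneC;Name=GENEC",
    "chrT\ttoy\tmRNA\t8001\t8300\t.\t+\t.\tID=geneC.t1;Parent=geneC",
    "chrT\ttoy\texon\t8001\t8100\t.\t+\t.\tID=geneC.e1;Parent=geneC.t1",
    "chrT\ttoy\texon\t8201\t8300\t.\t+\t.\tID=geneC.e2;Parent=geneC.t1",
    "chrT\ttoy\tCDS\t8001\t8100\t.\t+\t0\tID=geneC.c1;Parent=geneC.t1",
    "chrT\ttoy\tCDS\t8201\t8298\t.\t+\t2\tID=geneC.c2;Parent=geneC.t1"
  ), gff)
  list(fa = fa, gff = gff, seq = seq)
})

base_at <- function(i) toy_genome$seq[i]
other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
snp_at <- function(pos, alt = NULL) {
  ref <- base_at(pos)
  tibble::tibble(chrom = "chrT", pos = pos, ref = ref,
                 alt = alt %||% other_base(ref))
}

test_that("gene models load with strand-aware TSS and structural validation", {
  m <- read_gene_models(toy_genome$gff)
  expect_equal(nrow(m), 3L)
  expect_equal(m$tss[m$gene_id == "geneA"], 2001L)
  expect_equal(m$tss[m$gene_id == "geneB"], 5200L)  # minus strand
  expect_true(all(m$cds_complete))

  orphan <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chrT\ttoy\texon\t100\t200\t.\t+\t.\tID=x;Parent=nope"),
             orphan)
  expect_error(read_gene_models(orphan), "without parent")

  outside <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t100\t400\t.\t+\t.\tID=g",
    "chrT\ttoy\tmRNA\t100\t400\t.\t+\t.\tID=g.t;Parent=g",
    "chrT\ttoy\texon\t100\t200\t.\t+\t.\tID=g.e;Parent=g.t",
    "chrT\ttoy\tCDS\t150\t260\t.\t+\t0\tID=g.c;Parent=g.t"
  ), outside)
  expect_error(read_gene_models(outside), "CDS outside exons")

  short_cds <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttoy\tgene\t100\t400\t.\t+\t.\tID=g",
    "chrT\ttoy\tmRNA\t100\t400\t.\t+\t.\tID=g.t;Parent=g",
    "chrT\ttoy\texon\t100\t400\t.\t+\t.\tID=g.e;Parent=g.t",
    "chrT\ttoy\tCDS\t150\t159\t.\t+\t0\tID=g.c;Parent=g.t"
  ), short_cds)
  expect_warning(ms <- read_gene_models(short_cds), "not divisible by 3")
  expect_false(ms$cds_complete)
})

test_that("every CDS change of the 30-codon gene is synonymous or missense, matching translation", {
  models <- read_gene_models(toy_genome$gff)
  cds_seq <- paste(toy_genome$seq[2001:2090], collapse = "")
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds_seq), no.init.codon = TRUE
  ))
  n_checked <- 0
  for (pos in 2001:2090) {
    for (alt in other_base(base_at(pos))[1]) {
      alts <- setdiff(c("A", "C", "G", "T"), base_at(pos))
      for (alt in alts) {
        res <- classify_consequence(snp_at(pos, alt), models,
                                    toy_genome$fa)
        coding <- res$consequence[res$gene_id == "geneA"]
        expect_length(coding, 1L)
        expect_true(coding %in% c("synonymous", "missense"))
        mut <- cds_seq
        substr(mut, pos - 2000L, pos - 2000L) <- alt
        aa_alt <- suppressWarnings(as.character(Biostrings::translate(
          Biostrings::DNAString(mut), no.init.codon = TRUE
        )))
        expect_equal(coding == "synonymous", aa_ref == aa_alt)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 270L)  # 90 positions x 3 alternates, no gaps
})

test_that("specific codon, strand, UTR, splice and upstream calls are correct", {
  models <- read_gene_models(toy_genome$gff)
  cls <- function(pos, alt = NULL) {
    classify_consequence(snp_at(pos, alt), models, toy_genome$fa)$consequence
  }
  # ATG -> ACG (Met -> Thr)
  expect_equal(cls(2002, "C"), "missense")
  # CTT -> CTC (Leu -> Leu)
  expect_equal(cls(2006, "C"), "synonymous")

  # 200 bp beyond the minus-strand gene's end coordinate -> upstream
  expect_true("upstream" %in% cls(5400))
  # beyond the configured upstream window -> not upstream
  expect_false("upstream" %in% cls(5200 + 5001))

  # minus-strand UTRs: exonic above the CDS span is 5', below is 3'
  expect_true("utr5" %in% cls(5150))
  expect_true("utr3" %in% cls(5010))

  # minus-strand coding call agrees with reverse-complement translation
  # (the SNP also sits in geneC's upstream window, so filter by gene)
  res5050 <- classify_consequence(snp_at(5050), models, toy_genome$fa)
  expect_true(all(res5050$consequence[res5050$gene_id == "geneB"] %in%
                    c("synonymous", "missense")))

  # 2 bp into the intron of geneC -> splice_region; deep intron -> intronic
  expect_true("splice_region" %in% cls(8102))
  expect_true("intronic" %in% cls(8150))
  expect_false("splice_region" %in% cls(8150))
  # last exonic base of an internal boundary carries splice + coding labels
  labs <- cls(8100)
  expect_true("splice_region" %in% labs)
  expect_true(any(c("synonymous", "missense") %in% labs))

  expect_equal(cls(11500), "intergenic")

  bad <- snp_at(2002); bad$ref <- other_base(bad$ref)
  expect_error(classify_consequence(bad, models, toy_genome$fa),
               "REF mismatch at chrT:2002")
})

test_that("allele-frequency reporting flags fixed and near-fixed variants", {
  hap <- matrix(1L, nrow = 168, ncol = 3)
  hap[, 2] <- 0L
  hap[1, 3] <- 0L                 # 167/168 = 0.994
  p <- mk_panel(hap, pops = rep("CHCU", 84))
  rep_ <- allele_frequency_report(
    p, tibble::tibble(chrom = "chr1", pos = c(1000L, 2000L, 3000L, 9999L))
  )
  expect_equal(rep_$fixed, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(round(rep_$freq_alt[3], 3), 0.994)
  expect_true(rep_$near_fixed[3])
  expect_true(is.na(rep_$freq_alt[4]))
})

test_that("gene-interval intersection uses 1-bp overlap and is monotone", {
  models <- read_gene_models(toy_genome$gff)
  iv <- function(s, e) tibble::tibble(chrom = "chrT", start = s, end = e)
  expect_equal(genes_in_intervals(models, iv(1900L, 2200L))$gene_id, "geneA")
  expect_equal(genes_in_intervals(models, iv(2090L, 2500L))$gene_id, "geneA")
  expect_equal(nrow(genes_in_intervals(models, iv(2091L, 2500L))), 0L)
  expect_equal(nrow(genes_in_intervals(models, iv(0L, 0L)[0, ])), 0L)

  n_small <- nrow(genes_in_intervals(models, iv(1900L, 2200L)))
  n_big <- nrow(genes_in_intervals(models, iv(1900L, 9000L)))
  expect_gte(n_big, n_small)
})
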