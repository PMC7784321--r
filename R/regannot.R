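#' Read gene models from a GFF3 file
#'
#' Parses gene / mRNA / exon / CDS features into a transcript-level table.
#' Features whose `Parent` does not resolve are rejected with their
#' location; CDS segments must lie within their transcript's exons; a CDS
#' whose length is not divisible by 3 is flagged incomplete.
#'
#' @param gff3_path Path to a GFF3 file.
#' @return A `gene_models` tibble, one row per transcript, with columns
#'   `gene_id`, `gene_name`, `tx_id`, `chrom`, `strand`, `gene_start`,
#'   `gene_end`, `tss`, list-columns `exons` and `cds` (tibbles of
#'   `start`, `end`), `cds_len`, `cds_complete`.
#' @export
read_gene_models <- function(gff3_path) {
  g <- as.data.frame(rtracklayer::readGFF(gff3_path))
  g$Parent <- vapply(g$Parent, function(p) {
    if (length(p)) as.character(p)[1] else NA_character_
  }, character(1))
  genes <- g[g$type == "gene", ]
  txs <- g[g$type == "mRNA", ]
  exons <- g[g$type == "exon", ]
  cdss <- g[g$type == "CDS", ]

  bad_tx <- !(txs$Parent %in% genes$ID)
  if (any(bad_tx)) {
    i <- which(bad_tx)[1]
    abort(sprintf("mRNA without parent gene at %s:%d-%d",
                  txs$seqid[i], txs$start[i], txs$end[i]))
  }
  for (feat in list(exons, cdss)) {
    bad <- !(feat$Parent %in% txs$ID)
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("%s without parent mRNA at %s:%d-%d",
                    feat$type[i], feat$seqid[i], feat$start[i], feat$end[i]))
    }
  }

  out <- purrr::map_dfr(seq_len(nrow(txs)), function(i) {
    tx <- txs[i, ]
    ex <- exons[exons$Parent == tx$ID, c("start", "end")]
    ex <- as_tibble(ex[order(ex$start), ])
    cd <- cdss[cdss$Parent == tx$ID, c("start", "end")]
    cd <- as_tibble(cd[order(cd$start), ])
    if (nrow(cd) > 0) {
      inside <- vapply(seq_len(nrow(cd)), function(k) {
        any(ex$start <= cd$start[k] & ex$end >= cd$end[k])
      }, logical(1))
      if (!all(inside)) {
        k <- which(!inside)[1]
        abort(sprintf("CDS outside exons at %s:%d-%d",
                      tx$seqid, cd$start[k], cd$end[k]))
      }
    }
    gene <- genes[genes$ID == tx$Parent, ]
    cds_len <- if (nrow(cd)) sum(cd$end - cd$start + 1L) else 0L
    strand <- as.character(tx$strand)
    tibble(
      gene_id = gene$ID,
      gene_name = if (!is.null(gene$Name) && !is.na(gene$Name)) gene$Name
                  else gene$ID,
      tx_id = tx$ID, chrom = as.character(tx$seqid), strand = strand,
      gene_start = as.integer(min(ex$start)),
      gene_end = as.integer(max(ex$end)),
      tss = if (strand == "-") as.integer(max(ex$end))
            else as.integer(min(ex$start)),
      exons = list(ex), cds = list(cd),
      cds_len = cds_len,
      cds_complete = cds_len > 0L && cds_len %% 3L == 0L
    )
  })
  if (any(out$cds_len > 0 & !out$cds_complete)) {
    warn(sprintf("%d transcript(s) with CDS length not divisible by 3",
                 sum(out$cds_len > 0 & !out$cds_complete)))
  }
  structure(out, class = c("gene_models", class(out)))
}

load_reference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

ref_base <- function(reference, chrom, at) {
  as.character(Biostrings::subseq(reference[[chrom]], at, at))
}

# coding-orientation CDS coordinate of a genomic position (NA outside CDS)
cds_coord <- function(cd, strand, pos) {
  hit <- which(cd$start <= pos & cd$end >= pos)
  if (!length(hit)) return(NA_integer_)
  before <- if (hit > 1) sum(cd$end[seq_len(hit - 1)] -
                               cd$start[seq_len(hit - 1)] + 1L) else 0L
  plus_coord <- before + (pos - cd$start[hit] + 1L)
  if (strand == "-") {
    sum(cd$end - cd$start + 1L) - plus_coord + 1L
  } else {
    plus_coord
  }
}

cds_sequence <- function(reference, chrom, cd, strand) {
  parts <- vapply(seq_len(nrow(cd)), function(k) {
    as.character(Biostrings::subseq(reference[[chrom]], cd$start[k],
                                    cd$end[k]))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

classify_coding <- function(reference, chrom, cd, strand, pos, alt) {
  cpos <- cds_coord(cd, strand, pos)
  cds_seq <- cds_sequence(reference, chrom, cd, strand)
  codon_i <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L + 1L
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  if (nchar(codon) < 3L) return(NA_character_)  # incomplete terminal codon
  alt_c <- if (strand == "-") complement_base(alt) else alt
  codon_alt <- codon
  substr(codon_alt, within, within) <- alt_c
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "missense"
}

classify_one_tx <- function(snp, tx, reference, upstream_bp, splice_exonic,
                            splice_intronic) {
  pos <- snp$pos
  labels <- character()
  ex <- tx$exons[[1]]
  cd <- tx$cds[[1]]
  n_ex <- nrow(ex)

  if (pos < tx$gene_start || pos > tx$gene_end) {
    upstream <- if (tx$strand == "-") {
      pos > tx$gene_end && pos - tx$gene_end <= upstream_bp
    } else {
      pos < tx$gene_start && tx$gene_start - pos <= upstream_bp
    }
    return(if (upstream) "upstream" else character())
  }

  exon_hit <- which(ex$start <= pos & ex$end >= pos)
  if (length(exon_hit)) {
    i <- exon_hit[1]
    near_left <- i > 1L && pos - ex$start[i] < splice_exonic
    near_right <- i < n_ex && ex$end[i] - pos < splice_exonic
    if (near_left || near_right) labels <- c(labels, "splice_region")
    if (nrow(cd) && any(cd$start <= pos & cd$end >= pos)) {
      lab <- classify_coding(reference, tx$chrom, cd, tx$strand, pos,
                             snp$alt)
      if (!is.na(lab)) labels <- c(labels, lab)
    } else if (nrow(cd)) {
      five <- if (tx$strand == "-") pos > max(cd$end) else pos < min(cd$start)
      labels <- c(labels, if (five) "utr5" else "utr3")
    }
  } else {
    prev_end <- max(ex$end[ex$end < pos])
    next_start <- min(ex$start[ex$start > pos])
    dist <- min(pos - prev_end, next_start - pos)
    labels <- c(labels,
                if (dist <= splice_intronic) "splice_region" else "intronic")
  }
  labels
}

#' Classify the gene-model consequence of candidate SNPs
#'
#' Labels each SNP against every transcript it touches with one or more of
#' `upstream`, `utr5`, `utr3`, `splice_region`, `synonymous`, `missense`,
#' `intronic`; SNPs touching no transcript (nor an upstream region) are
#' `intergenic`.  Coding status uses the standard genetic code on the
#' CDS-projected codon, strand-aware; a change creating a stop codon is
#' reported as missense.  Splice regions are the first/last
#' `splice_exonic` bases of internal exons and the first/last
#' `splice_intronic` bases of introns.
#'
#' @param snps Tibble with columns `chrom`, `pos`, `ref`, `alt`.
#' @param models A `gene_models` table from [read_gene_models()].
#' @param reference A named `DNAStringSet` or FASTA path; each SNP's `ref`
#'   must match the reference base at its position (error otherwise).
#' @param upstream_bp Upstream-region length in bp (default 5000).
#' @param splice_exonic,splice_intronic Splice-region widths (defaults 2
#'   and 8).
#' @return A tibble with one row per SNP x transcript x label:
#'   `chrom`, `pos`, `ref`, `alt`, `gene_id`, `gene_name`, `tx_id`,
#'   `consequence` (gene columns NA for intergenic SNPs).
#' @export
classify_consequence <- function(snps, models, reference,
                                 upstream_bp = 5000, splice_exonic = 2,
                                 splice_intronic = 8) {
  reference <- load_reference(reference)
  purrr::map_dfr(seq_len(nrow(snps)), function(si) {
    snp <- snps[si, ]
    got <- ref_base(reference, snp$chrom, snp$pos)
    if (got != snp$ref) {
      abort(sprintf("REF mismatch at %s:%d (VCF %s, FASTA %s)",
                    snp$chrom, snp$pos, snp$ref, got))
    }
    rows <- purrr::map_dfr(
      which(models$chrom == snp$chrom),
      function(ti) {
        tx <- models[ti, ]
        labs <- classify_one_tx(snp, tx, reference, upstream_bp,
                                splice_exonic, splice_intronic)
        if (!length(labs)) return(NULL)
        tibble(chrom = snp$chrom, pos = snp$pos, ref = snp$ref,
               alt = snp$alt, gene_id = tx$gene_id,
               gene_name = tx$gene_name, tx_id = tx$tx_id,
               consequence = labs)
      }
    )
    if (nrow(rows) == 0) {
      rows <- tibble(chrom = snp$chrom, pos = snp$pos, ref = snp$ref,
                     alt = snp$alt, gene_id = NA_character_,
                     gene_name = NA_character_, tx_id = NA_character_,
                     consequence = "intergenic")
    }
    rows
  })
}

#' Per-population allele frequencies and fixation flags for candidate SNPs
#'
#' @param panel A [haplotype_panel()].
#' @param snps Tibble with columns `chrom`, `pos` (SNPs absent from the
#'   panel yield NA rows).
#' @param pops Population labels (default: all in the panel).
#' @param near_fixed_min Frequency at or above which a non-fixed SNP is
#'   flagged near-fixed (default 0.99).
#' @return A tibble with columns `chrom`, `pos`, `population`, `n_hap`,
#'   `freq_alt`, `fixed`, `near_fixed`.
#' @export
allele_frequency_report <- function(panel, snps, pops = NULL,
                                    near_fixed_min = 0.99) {
  pops <- pops %||% unique(unname(panel$populations))
  key_panel <- paste(panel$chrom, panel$positions)
  idx <- match(paste(snps$chrom, snps$pos), key_panel)
  purrr::map_dfr(pops, function(pp) {
    f <- site_freq(panel, pp)
    n <- site_n(panel, pp)
    fa <- ifelse(is.na(idx), NA_real_, f[idx])
    tibble(
      chrom = snps$chrom, pos = snps$pos, population = pp,
      n_hap = ifelse(is.na(idx), NA_integer_, n[idx]),
      freq_alt = fa,
      fixed = !is.na(fa) & fa == 1,
      near_fixed = !is.na(fa) & fa >= near_fixed_min & fa < 1
    )
  }) %>% arrange(chrom, pos, population)
}

#' Genes overlapping candidate intervals
#'
#' A gene is listed (once) when its genomic span overlaps any interval by
#' at least 1 bp.
#'
#' @param models A `gene_models` table.
#' @param intervals Tibble with `chrom`, `start`, `end` (1-based
#'   inclusive), e.g. from [merge_intervals()].
#' @return A tibble with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`.
#' @export
genes_in_intervals <- function(models, intervals) {
  genes <- models %>%
    group_by(gene_id, gene_name, chrom) %>%
    summarise(start = min(gene_start), end = max(gene_end),
              .groups = "drop")
  if (nrow(intervals) == 0) return(genes[0, ])
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    any(intervals$chrom == genes$chrom[i] &
          intervals$start <= genes$end[i] &
          intervals$end >= genes$start[i])
  }, logical(1))
  genes[hit, ]
}
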