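#' Read a phased VCF into a haplotype panel
#'
#' Ingests a VCF 4.x file with phased `GT` fields ('|' separator) and
#' returns a [haplotype_panel()].  Only biallelic SNP records are kept;
#' multiallelic and indel records are skipped with a reported count.  '.'
#' alleles become missing entries.  Sample order is preserved.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param pop_map Sample-to-population map: a path to a two-column TSV
#'   (`sample_id`, `population`), a data frame with those columns, or a
#'   named character vector (names = sample ids).
#' @param region Optional `"chrom"` or `"chrom:start-end"` string limiting
#'   the returned sites.
#'
#' @return A [haplotype_panel()].
#' @export
read_phased_vcf <- function(path, pop_map, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- v@gt
  samples <- colnames(gt_raw)[-1]

  keep <- !is.na(fix$ALT) & !is.na(fix$REF) &
    !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("skipped %d multiallelic/indel record(s)", n_skipped))
  }
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]

  pops <- resolve_pop_map(pop_map, samples)

  n_site <- nrow(fix)
  if (n_site == 0L) {
    return(haplotype_panel(
      chrom = character(), positions = integer(), ref = character(),
      alt = character(),
      hap = matrix(integer(), nrow = 2L * length(samples), ncol = 0L),
      sample_ids = samples, populations = pops
    ))
  }

  # first FORMAT field is GT by VCF convention; take the part before ':'
  gt <- sub(":.*$", "", gt_raw[, -1, drop = FALSE])
  slash <- which(matrix(grepl("/", gt, fixed = TRUE), nrow = nrow(gt)),
                 arr.ind = TRUE)
  if (nrow(slash) > 0) {
    i <- slash[1, 1]; j <- slash[1, 2]
    abort(sprintf(
      "unphased genotype '%s' at %s:%s for sample %s",
      gt[i, j], fix$CHROM[i], fix$POS[i], samples[j]
    ))
  }
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  a2[nchar(gt) < 3L] <- "."          # haploid-style or bare '.' records
  to_int <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[a == "0"] <- 0L
    out[a == "1"] <- 1L
    out
  }
  # haplotypes x sites, rows interleaved as sample1.1, sample1.2, sample2.1 ...
  hap <- matrix(NA_integer_, nrow = 2L * length(samples), ncol = n_site)
  hap[seq(1L, nrow(hap), by = 2L), ] <- t(matrix(to_int(a1), nrow = n_site))
  hap[seq(2L, nrow(hap), by = 2L), ] <- t(matrix(to_int(a2), nrow = n_site))

  panel <- haplotype_panel(
    chrom = fix$CHROM, positions = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, hap = hap,
    sample_ids = samples, populations = pops
  )
  if (!is.null(region)) panel <- subset_region(panel, region)
  panel
}

resolve_pop_map <- function(pop_map, samples) {
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map)) {
    pop_map <- read.table(pop_map, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  }
  if (is.data.frame(pop_map)) {
    pop_map <- setNames(as.character(pop_map[[2]]), pop_map[[1]])
  }
  missing <- setdiff(samples, names(pop_map))
  if (length(missing)) {
    abort(sprintf("samples missing from population map: %s",
                  paste(missing, collapse = ", ")))
  }
  unname(pop_map[samples])
}

subset_region <- function(panel, region) {
  m <- regmatches(region, regexec("^([^:]+)(?::(\\d+)-(\\d+))?$", region))[[1]]
  if (!length(m)) abort(sprintf("cannot parse region '%s'", region))
  keep <- panel$chrom == m[2]
  if (m[3] != "") {
    keep <- keep & panel$positions >= as.integer(m[3]) &
      panel$positions <= as.integer(m[4])
  }
  subset_sites(panel, keep)
}

#' Write a haplotype panel as a phased VCF
#'
#' Emits plain-text VCF 4.2 with phased `GT` fields; missing entries are
#' written as '.'.  `read_phased_vcf(write_phased_vcf(p), map)` reproduces
#' `p` exactly.
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tropiscan",
    sprintf("##contig=<ID=%s>", unique(panel$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  if (n_sites(panel) > 0L) {
    al <- matrix(as.character(panel$hap), nrow = nrow(panel$hap))
    al[is.na(al)] <- "."
    odd <- al[seq(1L, nrow(al), by = 2L), , drop = FALSE]
    even <- al[seq(2L, nrow(al), by = 2L), , drop = FALSE]
    gt <- matrix(paste(odd, even, sep = "|"), nrow = nrow(odd))
    lines <- paste(
      panel$chrom, panel$positions, ".", panel$ref, panel$alt, ".", "PASS",
      ".", "GT", apply(gt, 2L, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a sample-to-population map
#'
#' @param panel A [haplotype_panel()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pop_map <- function(panel, path) {
  write.table(
    data.frame(sample_id = panel$sample_ids,
               population = unname(panel$populations)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
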