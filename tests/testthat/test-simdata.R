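test_that("Balding-Nichols frequencies centre on the ancestral value and shrink as F -> 0", {
  f <- simulate_frequencies_bn(20000, fst_target = 0.2,
                               pops = c("a", "b"), seed = 2)
  p <- attr(f, "ancestral")
  expect_lt(abs(mean(f[, "a"] - p)), 0.01)
  expect_true(all(f >= 0 & f <= 1))

  f0 <- simulate_frequencies_bn(5000, fst_target = 1e-13, pops = "a",
                                seed = 3)
  expect_lt(max(abs(f0[, "a"] - attr(f0, "ancestral"))), 1e-6)

  expect_error(simulate_frequencies_bn(10, 0, seed = 1), "strictly inside")
  expect_error(simulate_frequencies_bn(10, 1, seed = 1), "strictly inside")
  expect_error(sim_config(), "seed")
})

test_that("panel simulation is a pure function of the configuration and seed", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 4e5), seed = 10)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$hap, b$hap)
  expect_identical(a$positions, b$positions)
  c2 <- simulate_panel(sim_config(chrom_lengths = c(chr1 = 4e5), seed = 11))
  expect_false(identical(a$hap, c2$hap))
})

test_that("degenerate copying limits behave as designed", {
  # two founders and no switching: every haplotype equals a founder
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e5),
                    pop_sizes = c(focal = 10), n_founder_haps = 2,
                    ld_block_bp = 1e9, seed = 12)
  p <- simulate_panel(cfg)
  strs <- apply(p$hap, 1, paste, collapse = "")
  expect_lte(length(unique(strs)), 2L)

  # tiny blocks decorrelate sites: the above-cutoff extent of the EHHS
  # curve collapses to a few markers (sites are ~1 kb apart), while long
  # blocks sustain haplotype sharing over a much wider span
  curve_extent <- function(ld) {
    cfg <- sim_config(chrom_lengths = c(chr1 = 5e5),
                      pop_sizes = c(focal = 12), ld_block_bp = ld,
                      seed = 13)
    p <- simulate_panel(cfg)
    cores <- round(seq(50, n_sites(p) - 50, length.out = 20))
    median(vapply(cores, function(co) {
      cv <- ehhs_curve(p, co)
      if (!nrow(cv)) return(0)
      max(abs(cv$pos - attr(cv, "core_pos")))
    }, numeric(1)))
  }
  ext_short <- curve_extent(500)
  expect_lt(ext_short, 10000)
  expect_gt(curve_extent(50000), 2 * ext_short)
})

test_that("EHHS half-decay distance tracks the configured LD block length", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), pop_sizes = c(focal = 12),
                    ld_block_bp = 20000, seed = 14)
  p <- simulate_panel(cfg)
  cores <- round(seq(200, n_sites(p) - 200, length.out = 30))
  half <- vapply(cores, function(co) {
    cv <- ehhs_curve(p, co)
    d <- cv[cv$value < 0.5, ]
    if (!nrow(d)) return(NA_real_)
    min(abs(d$pos - attr(cv, "core_pos")))
  }, numeric(1))
  expect_lt(median(half, na.rm = TRUE), 2 * 20000)
  expect_gt(median(half, na.rm = TRUE), 0.05 * 20000)
})

test_that("sweep implanting produces the designed degenerate and truth behaviour", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 3e5),
                    pop_sizes = c(focal = 8, founder = 8), seed = 15)
  p <- simulate_panel(cfg)

  p0 <- implant_sweep(p, pop = "focal", chrom = "chr1", locus = 1.5e5,
                      beta = 0, tract_bp = 1e5, seed = 1)
  expect_identical(p0$hap, p$hap)

  p1 <- implant_sweep(p, pop = "focal", chrom = "chr1", locus = 1.5e5,
                      beta = 1, tract_bp = 1e9, seed = 1)
  rows <- tropiscan:::hap_rows_of(
    p1, p1$sample_ids[p1$populations == "focal"]
  )
  strs <- apply(p1$hap[rows, ], 1, paste, collapse = "")
  expect_equal(length(unique(strs)), 1L)
  # other population untouched
  other <- setdiff(seq_len(nrow(p$hap)), rows)
  expect_identical(p1$hap[other, ], p$hap[other, ])
  expect_equal(nrow(attr(p1, "sweeps")), 1L)

  expect_message(
    implant_sweep(p, pop = "focal", chrom = "chr1", locus = 2.9e5,
                  beta = 0.5, tract_bp = 1e5, seed = 2),
    "clipped"
  )
})

test_that("introgression hits its genome fraction and the truth dosage matches the tracts", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6, chr2 = 2e6),
                    pop_sizes = c(focal = 12, donor = 10),
                    introgression = list(donor = "donor",
                                         recipient = "focal",
                                         genome_fraction = 0.06,
                                         mean_tract_bp = 1.5e5),
                    seed = 16)
  st <- simulate_study(cfg)
  realized <- mean(st$truth$dosage$dosage) / 2
  expect_lt(abs(realized - 0.06), 0.015)
  expect_true(all(st$truth$dosage$dosage %in% 0:2))

  # dosage recomputed from the tract list matches exactly
  recomputed <- st$truth$dosage %>% dplyr::mutate(expected = 0L)
  for (k in seq_len(nrow(st$truth$tracts))) {
    tr <- st$truth$tracts[k, ]
    hit <- recomputed$sample_id == tr$sample_id &
      recomputed$chrom == tr$chrom &
      recomputed$pos >= tr$start & recomputed$pos <= tr$end
    recomputed$expected[hit] <- recomputed$expected[hit] + 1L
  }
  expect_identical(recomputed$expected, as.integer(recomputed$dosage))

  # zero fraction -> zero dosage everywhere
  cfg0 <- cfg
  cfg0$introgression$genome_fraction <- 0
  st0 <- simulate_study(cfg0)
  expect_true(all(st0$truth$dosage$dosage == 0))
})

test_that("diversity ordering is donor > introgressed hybrid > taurine", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 2e6),
                    introgression = list(donor = "donor",
                                         recipient = "focal",
                                         genome_fraction = 0.06,
                                         mean_tract_bp = 1.5e5),
                    seed = 17)
  st <- simulate_study(cfg)
  g <- make_window_grid(cfg$chrom_lengths)
  th <- function(pp) {
    mean(watterson_theta_windows(panel_pop(st$panel, pp), g)$theta_w)
  }
  expect_gt(th("donor"), th("focal"))
  expect_gt(th("focal"), th("founder"))
})

test_that("the fixture bundle is deterministic, self-consistent and loads everywhere", {
  cfg <- sim_config(
    chrom_lengths = c(chr1 = 3e5, chr2 = 2e5),
    pop_sizes = c(focal = 6, founder = 6, donor = 4),
    sweeps = tibble::tibble(pop = "focal", chrom = "chr1", locus = 1.5e5,
                            beta = 0.9, tract_bp = 8e4),
    introgression = list(donor = "donor", recipient = "focal",
                         genome_fraction = 0.06, mean_tract_bp = 5e4),
    seed = 18
  )
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  p1 <- emit_fixture_bundle(cfg, d1)
  p2 <- emit_fixture_bundle(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     info = nm)
  }

  panel <- read_phased_vcf(p1[["vcf"]], p1[["pops"]])
  expect_equal(n_samples(panel), 16L)
  expect_gt(n_sites(panel), 100L)

  dos <- read_dosage_table(p1[["dosage"]], p1[["dosage_sites"]])
  expect_true(all(dos$dosage >= 0 & dos$dosage <= 2))
  expect_equal(sort(unique(dos$sample_id)),
               sort(panel$sample_ids[panel$populations == "focal"]))

  models <- read_gene_models(p1[["gff"]])
  expect_gte(nrow(models), 1L)
  pwms <- read_pwms_jaspar(p1[["pwm"]])
  expect_gte(length(pwms), 2L)

  # VCF REF alleles are planted in the FASTA
  fa <- Biostrings::readDNAStringSet(p1[["fasta"]])
  names(fa) <- sub("\\s.*$", "", names(fa))
  for (j in sample(seq_len(n_sites(panel)), 25)) {
    expect_equal(
      as.character(Biostrings::subseq(fa[[panel$chrom[j]]],
                                      panel$positions[j],
                                      panel$positions[j])),
      panel$ref[j]
    )
  }

  # gene models straddle the sweep locus and lie inside the FASTA bounds
  expect_true(any(models$gene_start <= 1.5e5 & models$gene_end >= 1.5e5 &
                    models$chrom == "chr1"))
  expect_true(all(models$gene_end <= Biostrings::width(fa)[
    match(models$chrom, names(fa))]))
})
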