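#' Configuration for the synthetic study generator
#'
#' The defaults emulate the study design the package targets: a derived
#' (focal) population and its founder population differentiated at
#' F_ST ~ 0.05, a second control population of the same stock, and a
#' distant donor population (pairwise F_ST ~ 0.25 with the taurine-like
#' populations, about twice their diversity) contributing a few percent of
#' the focal genome through introgression tracts.  Haplotypes are built by
#' a founder block-copying model so extended haplotype homozygosity decays
#' on the scale of `ld_block_bp`.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param site_density Expected SNPs per bp (default 1/1000).
#' @param pop_sizes Named vector of diploid sample sizes.
#' @param fst_taurine Pairwise F_ST target among the taurine-like
#'   populations (default 0.05).
#' @param fst_donor Pairwise F_ST target between taurine-like populations
#'   and the donor (default 0.25).
#' @param private_weights Named per-population weight of
#'   population-private polymorphic sites, relative to a weight of 1 for
#'   sites shared through the common ancestor.  The defaults (small for
#'   the taurine-like populations, near parity with shared sites for the
#'   donor) reproduce the qualitative diversity contrast of a distant,
#'   more diverse donor: donor Watterson theta about twice the taurine
#'   level, and donor-exclusive SNP counts rivalling shared ones.
#' @param ld_block_bp Mean founder-copying block length (bp); sets the EHH
#'   decay scale.
#' @param n_founder_haps Founder haplotypes per population.
#' @param sweeps Tibble of sweep specs (`pop`, `chrom`, `locus`, `beta`,
#'   `tract_bp`, optional `mode`); default none.
#' @param introgression NULL or a list with `donor`, `recipient`,
#'   `genome_fraction`, `mean_tract_bp`, optional `het_concentration`.
#' @param seed Integer seed (mandatory; every generator is a pure function
#'   of the configuration and this seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 3e6, chr2 = 3e6),
                       site_density = 1 / 1000,
                       pop_sizes = c(focal = 12, founder = 15,
                                     control = 15, donor = 10),
                       fst_taurine = 0.05,
                       fst_donor = 0.25,
                       private_weights = c(focal = 0.02, founder = 0.02,
                                           control = 0.02, donor = 1),
                       ld_block_bp = 20000,
                       n_founder_haps = 24,
                       sweeps = NULL,
                       introgression = NULL,
                       seed) {
  if (missing(seed)) abort("sim_config() requires a seed")
  stopifnot(all(chrom_lengths >= 1), site_density > 0,
            all(pop_sizes >= 1), fst_taurine > 0, fst_taurine < 1,
            fst_donor > 0, fst_donor < 1, ld_block_bp > 0,
            n_founder_haps >= 2)
  if (!is.null(introgression)) {
    stopifnot(introgression$genome_fraction >= 0,
              introgression$genome_fraction < 1,
              introgression$mean_tract_bp > 0)
  }
  structure(
    list(chrom_lengths = chrom_lengths, site_density = site_density,
         pop_sizes = pop_sizes, fst_taurine = fst_taurine,
         fst_donor = fst_donor, private_weights = private_weights,
         ld_block_bp = ld_block_bp,
         n_founder_haps = n_founder_haps, sweeps = sweeps,
         introgression = introgression, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Balding-Nichols draw: population frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
bn_draw <- function(p_anc, fst) {
  if (fst < 1e-12) return(p_anc)
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  rbeta(length(p_anc), a, b)
}

#' Balding-Nichols per-population allele frequencies
#'
#' Ancestral frequencies are drawn uniformly on
#' `[ancestral_range[1], ancestral_range[2]]`; each population's frequency
#' is Beta-distributed around the ancestral one with variance
#' `F p (1 - p)`, so the expected pairwise Hudson F_ST between two
#' populations simulated at per-population divergence `F` is `F` itself.
#'
#' @param n_sites Number of sites.
#' @param fst_target Per-population divergence F (scalar, or vector named
#'   by population).
#' @param pops Population names (default from `fst_target` names or
#'   `pop1..popK`).
#' @param ancestral_range Range of the uniform ancestral frequency
#'   distribution (default `c(0.05, 0.95)`).
#' @param seed Integer seed.
#' @return A sites x populations matrix of allele frequencies with the
#'   ancestral frequencies in `attr(, "ancestral")`.
#' @export
simulate_frequencies_bn <- function(n_sites, fst_target, pops = NULL,
                                    ancestral_range = c(0.05, 0.95),
                                    seed) {
  if (any(fst_target <= 0) || any(fst_target >= 1)) {
    abort("fst_target must be strictly inside (0, 1)")
  }
  pops <- pops %||% names(fst_target) %||%
    paste0("pop", seq_along(fst_target))
  if (length(fst_target) == 1L && length(pops) > 1L) {
    fst_target <- rep(fst_target, length(pops))
  }
  withr::with_seed(seed, {
    p <- runif(n_sites, ancestral_range[1], ancestral_range[2])
    freq <- vapply(seq_along(pops), function(j) bn_draw(p, fst_target[j]),
                   numeric(n_sites))
  })
  colnames(freq) <- pops
  attr(freq, "ancestral") <- p
  freq
}

# one haplotype by block-copying from K founder haplotypes: exponential
# segment lengths (mean ld_block_bp), an independently drawn founder per
# segment
copy_haplotype <- function(founders, positions, chrom, chrom_lengths,
                           ld_block_bp) {
  K <- nrow(founders)
  out <- integer(ncol(founders))
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    len <- chrom_lengths[[cc]]
    n_seg <- max(1L, stats::qpois(1 - 1e-9, len / ld_block_bp))
    breaks <- cumsum(rexp(n_seg, 1 / ld_block_bp))
    while (breaks[length(breaks)] <= len) {
      breaks <- c(breaks, breaks[length(breaks)] +
                    cumsum(rexp(8L, 1 / ld_block_bp)))
    }
    src <- sample.int(K, length(breaks) + 1L, replace = TRUE)
    seg <- findInterval(positions[idx], breaks) + 1L
    out[idx] <- founders[cbind(src[seg], idx)]
  }
  out
}

#' Simulate a multi-population phased haplotype panel
#'
#' Sites are placed at the configured density; shared sites receive
#' Balding-Nichols frequencies around a common ancestral frequency
#' (per-population divergence chosen so pairwise F_ST targets are met);
#' population-private sites (their number set by `private_weights`) are
#' polymorphic in one population only.  For each population,
#' `n_founder_haps` founder haplotypes are drawn from the frequencies and
#' the sample haplotypes copy founders in blocks of mean length
#' `ld_block_bp`, which produces realistic EHH decay.  Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A combined [haplotype_panel()] (all populations; use
#'   [panel_pop()] to split), with the site classes and frequencies in
#'   `attr(, "sim_info")`.
#' @export
simulate_panel <- function(config) {
  pops <- names(config$pop_sizes)
  # Per-population Balding-Nichols divergence from the shared ancestor:
  # pairwise F_ST ~ (F_a + F_b) / 2, so taurine-like pops take fst_taurine
  # and the donor 2 * fst_donor - fst_taurine.  The per-population flips
  # that realize the frequency targets on the shared founder pool add
  # about 0.55/K of drift at small F (and scale the realized divergence by
  # ~1.28 at donor-level F); both empirical constants of this generator
  # are compensated here so realized pairwise F_ST lands on the targets.
  drift <- 0.55 / config$n_founder_haps
  f_pop <- setNames(
    rep(max(0.004, config$fst_taurine - drift), length(pops)), pops
  )
  if ("donor" %in% pops) {
    f_pop["donor"] <- min(
      0.95, max(0.004, (2 * config$fst_donor - config$fst_taurine) / 1.28)
    )
  }
  pw <- config$private_weights[pops]
  pw[is.na(pw)] <- 0.02

  withr::with_seed(config$seed, {
    chrom <- character(); positions <- integer()
    for (cc in names(config$chrom_lengths)) {
      n <- max(2L, round(config$chrom_lengths[[cc]] * config$site_density))
      positions <- c(positions,
                     sort(sample.int(config$chrom_lengths[[cc]], n)))
      chrom <- c(chrom, rep(cc, n))
    }
    n_sites <- length(positions)
    ref <- sample(BASES, n_sites, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))

    # site ownership: shared vs private-to-one-population
    w <- c(shared = 1, setNames(pw, pops))
    class_of <- sample(names(w), n_sites, replace = TRUE, prob = w / sum(w))

    p_anc <- runif(n_sites, 0.05, 0.95)
    freq <- vapply(pops, function(pp) {
      f <- bn_draw(p_anc, f_pop[pp])
      private_here <- class_of == pp
      f[class_of != "shared"] <- 0
      f[private_here] <- runif(sum(private_here), 0.05, 0.5)
      f
    }, numeric(n_sites))

    # One shared ancestral founder pool; each population's founder pool is
    # the shared pool with site-wise coherent allele flips that move the
    # marginal frequencies to that population's targets.  Closely related
    # populations therefore share most haplotype block structure (as real
    # sister populations do), which the label-permutation null relies on.
    K <- config$n_founder_haps
    shared <- matrix(rbinom(K * n_sites, 1L, rep(p_anc, each = K)),
                     nrow = K)
    hap_blocks <- lapply(pops, function(pp) {
      tgt <- freq[, pp]
      up <- pmax(0, (tgt - p_anc) / (1 - p_anc))
      down <- pmax(0, (p_anc - tgt) / pmax(p_anc, 1e-12))
      u <- matrix(runif(K * n_sites), nrow = K)
      founders <- shared
      flip_up <- founders == 0L & u < matrix(up, K, n_sites, byrow = TRUE)
      flip_dn <- founders == 1L & u < matrix(down, K, n_sites, byrow = TRUE)
      founders[flip_up] <- 1L
      founders[flip_dn] <- 0L
      n_hap <- 2L * config$pop_sizes[[pp]]
      t(vapply(seq_len(n_hap), function(h) {
        copy_haplotype(founders, positions, chrom, config$chrom_lengths,
                       config$ld_block_bp)
      }, integer(n_sites)))
    })
  })

  hap <- do.call(rbind, hap_blocks)
  sample_ids <- unlist(lapply(pops, function(pp) {
    paste0(pp, seq_len(config$pop_sizes[[pp]]))
  }))
  panel <- haplotype_panel(
    chrom = chrom, positions = positions, ref = ref, alt = alt, hap = hap,
    sample_ids = sample_ids,
    populations = rep(pops, times = config$pop_sizes)
  )
  attr(panel, "sim_info") <- list(site_class = class_of, freq = freq,
                                  f_pop = f_pop)
  panel
}

#' Implant a selective sweep into one population
#'
#' A fraction `beta` of the population's haplotypes have the interval
#' `locus +/- tract_bp / 2` overwritten with the sequence of one favored
#' haplotype (hard sweep) or of one of `n_source` favored haplotypes (soft
#' sweep), creating the extended-homozygosity signature of recent positive
#' selection without simulating selection dynamics.
#'
#' @param panel A [haplotype_panel()] (combined or single-population).
#' @param pop Population to sweep (NULL = all samples).
#' @param chrom,locus Sweep position.
#' @param beta Final favored-haplotype frequency, in (0, 1].
#' @param tract_bp Sweep tract length (clipped to the chromosome with a
#'   message if needed).
#' @param seed Integer seed.
#' @param mode `"hard"` (default) or `"soft"`.
#' @param n_source Number of favored source haplotypes for soft sweeps.
#' @return The modified panel; implanted sweeps accumulate in
#'   `attr(, "sweeps")`.
#' @export
implant_sweep <- function(panel, pop = NULL, chrom, locus, beta, tract_bp,
                          seed, mode = c("hard", "soft"), n_source = 2L) {
  mode <- match.arg(mode)
  stopifnot(beta >= 0, beta <= 1)
  prior <- attr(panel, "sweeps")
  sim_info <- attr(panel, "sim_info")
  if (beta == 0) return(panel)
  rows <- hap_rows_of(panel,
                      if (is.null(pop)) NULL else
                        panel$sample_ids[panel$populations == pop])
  start <- max(1, round(locus - tract_bp / 2))
  end <- round(locus + tract_bp / 2)
  max_pos <- max(panel$positions[panel$chrom == chrom])
  if (end > max_pos || start < min(panel$positions[panel$chrom == chrom])) {
    inform(sprintf("sweep tract at %s:%d clipped to the chromosome",
                   chrom, locus))
  }
  sites <- which(panel$chrom == chrom & panel$positions >= start &
                   panel$positions <= end)
  hap <- panel$hap
  withr::with_seed(seed, {
    sources <- sample(rows, if (mode == "hard") 1L else n_source)
    carriers <- sample(rows, round(beta * length(rows)))
    for (h in carriers) {
      src <- if (length(sources) == 1L) sources else sample(sources, 1L)
      hap[h, sites] <- hap[src, sites]
    }
  })
  out <- haplotype_panel(panel$chrom, panel$positions, panel$ref, panel$alt,
                         hap, panel$sample_ids, unname(panel$populations))
  attr(out, "sweeps") <- bind_rows(
    prior,
    tibble(pop = pop %||% NA_character_, chrom = chrom, locus = locus,
           start = start, end = min(end, max_pos), beta = beta, mode = mode)
  )
  attr(out, "sim_info") <- sim_info
  out
}

#' Implant donor introgression tracts into a recipient population
#'
#' Each recipient haplotype receives non-overlapping tracts with
#' exponentially distributed lengths (mean `mean_tract_bp`) copied from
#' random donor haplotypes until its donor-genome fraction reaches an
#' individual-specific target drawn from a Beta distribution with mean
#' `genome_fraction` (heterogeneity across individuals, as local-ancestry
#' maps of recently admixed populations show); the final tract is trimmed
#' so the realized fraction matches the target.  The exact truth dosage is
#' recorded.
#'
#' @param panel A combined [haplotype_panel()] holding both populations.
#' @param donor,recipient Population labels.
#' @param genome_fraction Target donor fraction of the recipient genome.
#' @param mean_tract_bp Mean tract length (bp).
#' @param chrom_lengths Named chromosome lengths (bp).
#' @param seed Integer seed.
#' @param het_concentration Beta concentration of the per-individual
#'   targets (default 12; larger = more homogeneous).
#' @param focus_intervals Optional tibble (`chrom`, `start`, `end`); with
#'   probability `focus_frac` a tract is started inside a random focus
#'   interval instead of uniformly, concentrating donor ancestry there
#'   (e.g. in sweep regions).
#' @param focus_frac Probability of focused tract placement (default 0).
#' @return A list with `panel` (modified), `tracts` (tibble `sample_id`,
#'   `hap`, `chrom`, `start`, `end`) and `dosage` (a `dosage_table` of the
#'   exact per-SNP donor dosage of every recipient individual).
#' @export
implant_introgression <- function(panel, donor = "donor",
                                  recipient = "focal", genome_fraction,
                                  mean_tract_bp, chrom_lengths, seed,
                                  het_concentration = 12,
                                  focus_intervals = NULL, focus_frac = 0) {
  stopifnot(genome_fraction >= 0, genome_fraction < 1)
  rec_samples <- panel$sample_ids[panel$populations == recipient]
  don_rows <- hap_rows_of(panel,
                          panel$sample_ids[panel$populations == donor])
  rec_rows <- hap_rows_of(panel, rec_samples)
  genome_len <- sum(chrom_lengths)
  hap <- panel$hap
  anc <- matrix(FALSE, nrow = length(rec_rows), ncol = n_sites(panel))
  tract_rows <- list()

  if (genome_fraction > 0) {
    withr::with_seed(seed, {
      targets <- rbeta(length(rec_rows),
                       genome_fraction * het_concentration,
                       (1 - genome_fraction) * het_concentration)
      # keep the heterogeneity but pin the population-mean donor fraction
      # to the configured genome_fraction
      targets <- pmin(0.95, targets * genome_fraction / mean(targets))
      for (k in seq_along(rec_rows)) {
        covered <- 0
        placed <- tibble(chrom = character(), start = numeric(),
                         end = numeric())
        for (att in seq_len(2000L)) {
          if (covered >= targets[k] * genome_len) break
          if (!is.null(focus_intervals) && nrow(focus_intervals) &&
              runif(1) < focus_frac) {
            fi <- focus_intervals[sample.int(nrow(focus_intervals), 1L), ]
            cc <- fi$chrom
            start <- ceiling(runif(1, fi$start - 1, fi$end))
          } else {
            cc <- sample(names(chrom_lengths), 1L,
                         prob = chrom_lengths / genome_len)
            start <- ceiling(runif(1, 0, chrom_lengths[[cc]]))
          }
          len <- ceiling(rexp(1, 1 / mean_tract_bp))
          remaining <- targets[k] * genome_len - covered
          len <- min(len, remaining, chrom_lengths[[cc]] - start + 1)
          end <- start + len - 1
          if (len < 1) break
          if (any(placed$chrom == cc & placed$start <= end &
                    placed$end >= start)) next
          placed <- bind_rows(placed,
                              tibble(chrom = cc, start = start, end = end))
          covered <- covered + len
          sites <- which(panel$chrom == cc & panel$positions >= start &
                           panel$positions <= end)
          if (length(sites)) {
            src <- sample(don_rows, 1L)
            hap[rec_rows[k], sites] <- hap[src, sites]
            anc[k, sites] <- TRUE
          }
        }
        if (nrow(placed)) {
          tract_rows[[k]] <- placed %>%
            mutate(sample_id = rec_samples[ceiling(k / 2)],
                   hap = (k - 1L) %% 2L + 1L)
        }
      }
    })
  }

  tracts <- if (length(tract_rows)) {
    bind_rows(tract_rows) %>%
      mutate(start = as.integer(start), end = as.integer(end)) %>%
      select(sample_id, hap, chrom, start, end) %>%
      arrange(sample_id, hap, chrom, start)
  } else {
    tibble(sample_id = character(), hap = integer(), chrom = character(),
           start = integer(), end = integer())
  }
  dosage_m <- t(anc[seq(1, nrow(anc), 2), , drop = FALSE] +
                  anc[seq(2, nrow(anc), 2), , drop = FALSE])
  out_panel <- haplotype_panel(panel$chrom, panel$positions, panel$ref,
                               panel$alt, hap, panel$sample_ids,
                               unname(panel$populations))
  attr(out_panel, "sweeps") <- attr(panel, "sweeps")
  list(
    panel = out_panel,
    tracts = tracts,
    dosage = as_dosage_table(dosage_m, panel$chrom, panel$positions,
                             rec_samples)
  )
}

#' Simulate a full synthetic study with ground truth
#'
#' Runs [simulate_panel()], implants the configured sweeps and
#' introgression, and returns the panel together with the exact truth.
#'
#' @param config A [sim_config()].
#' @return A list with `panel` and `truth` (list: `sweeps`, `tracts`,
#'   `dosage`).
#' @export
simulate_study <- function(config) {
  panel <- simulate_panel(config)
  if (!is.null(config$sweeps) && nrow(config$sweeps)) {
    for (i in seq_len(nrow(config$sweeps))) {
      sw <- config$sweeps[i, ]
      panel <- implant_sweep(
        panel, pop = sw$pop, chrom = sw$chrom, locus = sw$locus,
        beta = sw$beta, tract_bp = sw$tract_bp,
        seed = config$seed + 1000L + i,
        mode = if ("mode" %in% names(sw)) sw$mode else "hard"
      )
    }
  }
  tracts <- NULL; dosage <- NULL
  if (!is.null(config$introgression)) {
    ig <- config$introgression
    res <- implant_introgression(
      panel, donor = ig$donor %||% "donor",
      recipient = ig$recipient %||% "focal",
      genome_fraction = ig$genome_fraction,
      mean_tract_bp = ig$mean_tract_bp,
      chrom_lengths = config$chrom_lengths,
      seed = config$seed + 5000L,
      het_concentration = ig$het_concentration %||% 12,
      focus_intervals = ig$focus_intervals,
      focus_frac = ig$focus_frac %||% 0
    )
    panel <- res$panel
    tracts <- res$tracts
    dosage <- res$dosage
  }
  list(panel = panel,
       truth = list(sweeps = attr(panel, "sweeps"), tracts = tracts,
                    dosage = dosage))
}

#' Neutral panel with known Watterson theta
#'
#' Generates an unlinked panel whose expected segregating-site count is
#' `theta * L * a(n)` with allele counts drawn from the neutral frequency
#' spectrum (`P(i) proportional to 1/i`); used as an independent check of
#' the windowed theta estimator.
#'
#' @param theta Per-bp Watterson theta.
#' @param chrom_length Chromosome length (bp).
#' @param n_hap Number of haplotypes (must be even).
#' @param seed Integer seed.
#' @param chrom Chromosome label.
#' @return A single-population [haplotype_panel()].
#' @export
simulate_neutral_panel <- function(theta, chrom_length, n_hap, seed,
                                   chrom = "chr1") {
  stopifnot(n_hap %% 2 == 0, n_hap >= 4)
  withr::with_seed(seed, {
    s <- rpois(1, theta * chrom_length * sum(1 / seq_len(n_hap - 1)))
    s <- min(s, chrom_length)
    positions <- sort(sample.int(chrom_length, s))
    counts <- sample(seq_len(n_hap - 1), s, replace = TRUE,
                     prob = 1 / seq_len(n_hap - 1))
    hap <- matrix(0L, nrow = n_hap, ncol = s)
    for (j in seq_len(s)) hap[sample.int(n_hap, counts[j]), j] <- 1L
    ref <- sample(BASES, s, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                  character(1))
  })
  haplotype_panel(rep(chrom, s), positions, ref, alt, hap,
                  sample_ids = paste0("s", seq_len(n_hap / 2)),
                  populations = rep("pop1", n_hap / 2))
}

#' Write a self-consistent fixture bundle to disk
#'
#' Simulates a study from `config` and writes: the combined phased VCF,
#' the sample-population TSV, the truth dosage matrix with its site-info
#' sidecar, BED files of the truth introgression tracts and sweep tracts,
#' a toy reference FASTA carrying the panel's REF alleles, a toy GFF3 with
#' genes straddling the sweep loci, and a small JASPAR pfm motif set.  The
#' bundle is byte-identical when regenerated from the same configuration
#' and seed.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(config)
  panel <- study$panel
  paths <- c(
    vcf = file.path(outdir, "panel.vcf"),
    pops = file.path(outdir, "pops.tsv"),
    dosage = file.path(outdir, "truth_dosage.txt"),
    dosage_sites = file.path(outdir, "truth_dosage_sites.tsv"),
    tracts = file.path(outdir, "truth_tracts.bed"),
    sweeps = file.path(outdir, "truth_sweeps.bed"),
    fasta = file.path(outdir, "reference.fa"),
    gff = file.path(outdir, "genes.gff3"),
    pwm = file.path(outdir, "motifs.pfm")
  )
  write_phased_vcf(panel, paths["vcf"])
  write_pop_map(panel, paths["pops"])
  if (!is.null(study$truth$dosage)) {
    write_dosage_table(study$truth$dosage, paths["dosage"],
                       paths["dosage_sites"])
    write_bed(study$truth$tracts, paths["tracts"])
  } else {
    rec <- panel$sample_ids[panel$populations ==
                              (config$introgression$recipient %||% "focal")]
    zero <- matrix(0, nrow = n_sites(panel), ncol = length(rec))
    write_dosage_table(
      as_dosage_table(zero, panel$chrom, panel$positions, rec),
      paths["dosage"], paths["dosage_sites"]
    )
    write_bed(tibble(chrom = character(), start = integer(),
                     end = integer()), paths["tracts"])
  }
  sweeps <- study$truth$sweeps %||%
    tibble(chrom = character(), start = integer(), end = integer())
  write_bed(sweeps, paths["sweeps"])

  # toy reference: random bases, REF allele planted at every site
  withr::with_seed(config$seed + 9000L, {
    seqs <- lapply(names(config$chrom_lengths), function(cc) {
      s <- sample(BASES, config$chrom_lengths[[cc]], replace = TRUE)
      idx <- which(panel$chrom == cc)
      s[panel$positions[idx]] <- panel$ref[idx]
      paste(s, collapse = "")
    })
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- names(config$chrom_lengths)
  Biostrings::writeXStringSet(dna, paths["fasta"])

  write_toy_gff3(config, sweeps, paths["gff"])
  write_toy_pfm(paths["pwm"])
  invisible(paths)
}

# genes straddling each sweep locus (or at fixed places when no sweeps),
# single-exon fully coding models so consequences are well defined
write_toy_gff3 <- function(config, sweeps, path) {
  loci <- if (nrow(sweeps)) {
    sweeps %>% select(chrom, locus) %>% distinct()
  } else {
    tibble(chrom = names(config$chrom_lengths)[1],
           locus = round(config$chrom_lengths[[1]] / 2))
  }
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(loci))) {
    cc <- loci$chrom[i]
    center <- loci$locus[i]
    len <- 3L * 400L  # 400 codons
    start <- max(1L, as.integer(center - len / 2))
    end <- start + len - 1L
    gid <- sprintf("gene%02d", i)
    strand <- if (i %% 2 == 0) "-" else "+"
    lines <- c(
      lines,
      sprintf("%s\ttropiscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=TOY%02d",
              cc, start, end, strand, gid, i),
      sprintf("%s\ttropiscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              cc, start, end, strand, gid, gid),
      sprintf("%s\ttropiscan\texon\t%d\t%d\t.\t%s\t.\tID=%s.e1;Parent=%s.t1",
              cc, start, end, strand, gid, gid),
      sprintf("%s\ttropiscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c1;Parent=%s.t1",
              cc, start, end, strand, gid, gid)
    )
  }
  writeLines(lines, path)
}

write_toy_pfm <- function(path) {
  writeLines(c(
    ">TOY1 consensusACGT",
    "A [ 8 0 0 0 ]",
    "C [ 0 8 0 0 ]",
    "G [ 0 0 8 0 ]",
    "T [ 0 0 0 8 ]",
    ">TOY2 tataLike",
    "A [ 1 9 9 1 ]",
    "C [ 1 0 0 1 ]",
    "G [ 1 0 0 1 ]",
    "T [ 7 1 1 7 ]"
  ), path)
}
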