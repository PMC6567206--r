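test_that("parental genomes are deterministic under a seed and fully divergent", {
  cfg <- small_config()
  p1 <- make_parental_genomes(cfg, seed = 5)
  p2 <- make_parental_genomes(cfg, seed = 5)
  expect_identical(p1$map$markers, p2$map$markers)

  mk <- p1$map$markers
  expect_true(all(mk$ref != mk$alt))
  expect_true(all(tapply(mk$pos, mk$chrom, function(p) all(diff(p) > 0))))
  expect_true(all(mk$pos <= p1$map$chrom_lengths[mk$chrom]))
  # marker count apportioned close to the requested total
  expect_equal(nrow(mk), cfg$n_markers, tolerance = 0.01)

  # zero density on a chromosome leaves a valid, empty marker list
  expect_warning(
    p0 <- make_parental_genomes(
      sim_config(chrom_lengths = c(chrA = 50e6, chrB = 1e4),
                 n_markers = 100)),
    "zero markers")
  expect_false("chrB" %in% p0$map$markers$chrom)
})

test_that("meiosis crossover counts follow the genetic length (Poisson)", {
  # one 40 Mb chromosome at 2.5 cM/Mb = 100 cM -> mean 1 crossover
  cfg <- sim_config(chrom_lengths = c(chrA = 40e6), n_markers = 10)
  p <- make_parental_genomes(cfg, seed = 6)
  f1 <- list(hap1 = p$donor$hap1, hap2 = p$recurrent$hap1)
  set.seed(60)
  n_co <- replicate(10000, {
    g <- meiosis(f1, p$map)
    # with pure opposite-origin chromatids every crossover is a breakpoint
    length(g$chrA$bp) - 1L
  })
  expect_equal(mean(n_co), 1.0, tolerance = 3 / 100)  # 3 SE, SE = 1/sqrt(1e4)

  # genetic length 0: gamete equals a parental haplotype
  cfg0 <- sim_config(chrom_lengths = c(chrA = 40e6), cm_per_mb = 0,
                     n_markers = 10)
  p0 <- make_parental_genomes(cfg0, seed = 7)
  g0 <- meiosis(list(hap1 = p0$donor$hap1, hap2 = p0$recurrent$hap1), p0$map)
  expect_true(identical(g0, p0$donor$hap1) || identical(g0, p0$recurrent$hap1))

  # homozygous diploid: gamete identical regardless of crossovers
  gh <- meiosis(p$donor, p$map)
  expect_equal(gh$chrA$origin, "D")
})

test_that("the F1 is heterozygous everywhere and recovers exactly half", {
  p <- make_parental_genomes(small_config(), seed = 8)
  f1 <- run_scheme(scheme_spec(n_backcross = 0, n_self = 0,
                               target_chrom = "chr01", target_pos = 1e6,
                               select_target = FALSE), p, seed = 9)
  expect_equal(true_recovery(f1, p$map), 0.5)
  sites <- genotype_markers(f1, p$map, noise_model(preset = "none"))
  expect_true(all(sites$progeny_gt == "0/1"))
  expect_equal(true_recovery(p$recurrent, p$map), 1.0)
})

test_that("foreground selection fixes the donor allele at the target", {
  p <- make_parental_genomes(small_config(), seed = 10)
  for (s in c(11, 12)) {
    ind <- run_scheme(scheme_spec(target_chrom = "chr01", target_pos = 20e6),
                      p, seed = s)
    sites <- genotype_markers(ind, p$map, noise_model(preset = "none"))
    at_target <- which.min(abs(sites$pos - 20e6) +
                             ifelse(sites$chrom == "chr01", 0, 1e9))
    # nearest marker to the target is donor-carrying (hom barring an
    # improbable double recombination within the marker spacing)
    expect_true(sites$progeny_gt[at_target] %in% c("1/1", "0/1"))
    o1 <- ind$hap1$chr01; o2 <- ind$hap2$chr01
    at <- function(h) h$origin[findInterval(20e6 - 1e-9, c(0, h$bp))]
    expect_equal(at(o1), "D")
    expect_equal(at(o2), "D")
  }
  # unsatisfiable selection fails explicitly
  pr <- list(map = p$map, donor = p$recurrent, recurrent = p$recurrent)
  expect_error(run_scheme(scheme_spec(target_chrom = "chr01",
                                      target_pos = 20e6,
                                      max_attempts = 5), pr, seed = 13),
               "unsatisfiable")
})

test_that("seeded simulation emits byte-identical VCFs", {
  run_once <- function() {
    p <- make_parental_genomes(small_config(500), seed = 14)
    ind <- run_scheme(scheme_spec(target_chrom = "chr01", target_pos = 2e7),
                      p, seed = 15)
    sites <- genotype_markers(ind, p$map,
                              noise_model(missing_rate = 0.05), seed = 16)
    f <- tempfile(fileext = ".vcf")
    emit_vcf(sites, f, p$map$chrom_lengths, source_info = "seed=14/15/16")
    readLines(f)
  }
  expect_identical(run_once(), run_once())
})

test_that("noiseless emit -> read -> classify reproduces the truth exactly", {
  p <- make_parental_genomes(small_config(3000), seed = 17)
  ind <- run_scheme(scheme_spec(target_chrom = "chr01", target_pos = 2e7),
                    p, seed = 18)
  sites <- genotype_markers(ind, p$map, noise_model(preset = "none"))
  f <- tempfile(fileext = ".vcf")
  emit_vcf(sites, f, p$map$chrom_lengths)
  back <- read_multisample_variants(
    f, c(donor = "donor", recurrent = "recurrent", progeny = "progeny"))
  expect_equal(nrow(back), nrow(sites))
  for (col in names(sites))
    expect_equal(back[[col]], sites[[col]], info = col)

  flt <- apply_site_filters(back)
  expect_equal(flt$n_passing, flt$n_input)  # nothing to remove
  cls <- classify_sites(select_informative_sites(flt$sites))
  expect_false(any(cls$class == "NON_PARENTAL"))  # Mendelian at zero noise
  est <- recovery_rate(sum(cls$class == "RECURRENT_HOM"),
                       sum(cls$class == "HET"),
                       sum(cls$class == "DONOR_HOM"))
  expect_equal(est, true_recovery(ind, p$map), tolerance = 1e-12)
})

test_that("injected noise is removed by the matching filters", {
  p <- make_parental_genomes(small_config(10000), seed = 19)
  # a BC1F1 carries het segments on roughly half the genome, so the
  # balance-skew path is always exercised
  ind <- run_scheme(scheme_spec(n_backcross = 1, n_self = 0,
                                target_chrom = "chr01", target_pos = 2e7),
                    p, seed = 20)

  # missing calls: removal count ~ Binomial(n, 0.1)
  sites <- genotype_markers(ind, p$map,
                            noise_model(missing_rate = 0.1), seed = 21)
  flt <- apply_site_filters(sites)
  n <- nrow(sites)
  expected <- 0.1 * n
  se <- sqrt(n * 0.1 * 0.9)
  got <- flt$tally$removed[flt$tally$filter == "missing"]
  expect_lt(abs(got - expected), 3 * se)

  # forced 30% allele balance at every het site: exactly those removed by
  # the balance filter
  sites2 <- genotype_markers(ind, p$map,
                             noise_model(ab_skew_rate = 1), seed = 22)
  log2 <- attr(sites2, "noise_log")
  skewed <- log2$row[log2$event == "ab_skew"]
  expect_gt(length(skewed), 0L)
  flt2 <- apply_site_filters(sites2)
  expect_equal(flt2$tally$removed[flt2$tally$filter == "progeny_af"],
               length(skewed))
  key <- paste(sites2$chrom[skewed], sites2$pos[skewed])
  expect_false(any(key %in% paste(flt2$sites$chrom, flt2$sites$pos)))
})

test_that("heterozygosity halves with each selfing generation", {
  p <- make_parental_genomes(small_config(1500), seed = 23)
  noiseless <- noise_model(preset = "none")
  set.seed(24)
  het_frac <- function(n_self, reps = 120) {
    mean(replicate(reps, {
      ind <- run_scheme(scheme_spec(n_backcross = 1, n_self = n_self,
                                    target_chrom = "chr01",
                                    target_pos = 2e7,
                                    select_target = FALSE), p)
      sites <- genotype_markers(ind, p$map, noiseless)
      mean(sites$progeny_gt == "0/1")
    }))
  }
  h0 <- het_frac(0)   # BC1F1: expected 1/2
  h1 <- het_frac(1)   # BC1F2: expected 1/4
  h2 <- het_frac(2)   # BC1F3: expected 1/8
  # individual het fractions vary widely; 120 reps give SE ~ 0.02
  expect_equal(h0, 0.5, tolerance = 0.08)
  expect_equal(h1, 0.25, tolerance = 0.06)
  expect_equal(h2, 0.125, tolerance = 0.05)
})

test_that("foreground selection depresses recovery near the target locus", {
  cfg <- sim_config(n_markers = 6000)
  sel <- simulate_recovery_study(60, cfg, scheme_spec(), seed = 25)
  no_sel <- simulate_recovery_study(60, cfg, scheme_spec(select_target = FALSE),
                                    seed = 26)
  # linkage drag: selected individuals recover significantly less genome
  expect_lt(mean(sel$estimated), mean(no_sel$estimated))
  expect_lt(mean(sel$estimated), 0.93)
  expect_gt(mean(sel$estimated), 0.8)
})
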