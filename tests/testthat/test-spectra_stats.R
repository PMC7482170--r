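# Spectra, length bins, per-bp / per-Gy rates, fold changes, zygosity
# ratio and the strain summary.

test_that("strand-collapsed substitution classes and transition flags", {
  expect_equal(classify_sbs("A", "G"), "A/T>G/C")
  expect_equal(classify_sbs("T", "C"), "A/T>G/C")  # strand collapse
  expect_equal(classify_sbs("G", "T"), "G/C>T/A")
  expect_equal(classify_sbs("C", "G"), "G/C>C/G")
  expect_true(sbs_is_transition("A/T>G/C"))
  expect_true(sbs_is_transition("G/C>A/T"))
  expect_false(sbs_is_transition("A/T>T/A"))
  expect_error(classify_sbs("A", "A"), "unequal")
  expect_error(classify_sbs("A", "N"), "unequal single bases")
})

test_that("indel length bins", {
  expect_equal(as.character(indel_length_bin(c(1, 2, 10, 11, 15, 30, 31,
                                               100, 101, 250))),
               c("1", "2-10", "2-10", "11-30", "11-30", "11-30",
                 "31-100", "31-100", ">100", ">100"))
  expect_error(indel_length_bin(0), ">= 1")
})

test_that("per-bp rate and per-Gy scaling closed forms", {
  L <- 119146348
  r1 <- per_bp_rate(10, L)
  expect_equal(r1$mean * 1e8, 8.39, tolerance = 1e-3)
  expect_equal(r1$se, 0)
  expect_equal(r1$n, 1L)

  r3 <- per_bp_rate(c(10, 12, 14), L)
  expect_equal(r3$mean, 12 / L)
  expect_equal(r3$se, (2 / sqrt(3)) / L)

  r0 <- per_bp_rate(c(0, 0, 0), L)
  expect_equal(r0$mean, 0)
  expect_equal(r0$se, 0)

  expect_equal(per_gy(30.27e-8, 1000) * 1e10, 3.027, tolerance = 1e-12)
  expect_equal(per_gy(10.71e-8, 100) * 1e10, 10.71, tolerance = 1e-12)
  expect_equal(per_gy(5, 1), 5)
  expect_error(per_gy(1, 0), "positive")
  expect_error(per_bp_rate(numeric(0)), "at least one plant")
})

test_that("fold change and degenerate control", {
  expect_equal(fold_change(c(4, 6), 2), 2.5)
  expect_equal(fold_change(3, 3), 1)
  expect_true(is.na(fold_change(c(1, 2), 0)))
})

test_that("zygosity ratio and exact binomial test", {
  r <- zygosity_ratio(rep(c("homozygous", "heterozygous"), c(10, 20)))
  expect_equal(r$ratio, 0.5)
  expect_equal(r$p_value, 1, tolerance = 0.15)  # consistent with 1/3
  expect_equal(r$p_value,
               binom.test(10, 30, p = 1 / 3)$p.value)

  r0 <- zygosity_ratio(rep("heterozygous", 20))
  expect_equal(r0$ratio, 0)
  expect_lt(r0$p_value, 0.01)

  r1 <- zygosity_ratio(rep(c("homozygous", "heterozygous"), c(15, 15)))
  expect_equal(r1$ratio, 1)

  rnohet <- zygosity_ratio(rep("homozygous", 5))
  expect_true(is.na(rnohet$ratio))
  expect_equal(rnohet$n_hom, 5L)
})

test_that("welch_t matches the textbook formula", {
  x <- c(3.1, 4.2, 5.3, 2.9, 4.8)
  y <- c(6.0, 7.1, 5.9, 8.2)
  got <- welch_t(x, y)
  sx2 <- var(x) / length(x); sy2 <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(sx2 + sy2)
  df <- (sx2 + sy2)^2 /
    (sx2^2 / (length(x) - 1) + sy2^2 / (length(y) - 1))
  expect_equal(got$statistic, tstat, tolerance = 1e-12)
  expect_equal(got$df, df, tolerance = 1e-12)
  expect_equal(got$p.value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("strain summary is additive and consistent across scales", {
  events <- data.frame(
    sample_id = rep(c("p1", "p2", "p3"), times = c(5, 3, 4)),
    category = c("SBS", "SBS", "Del1", "DelGE2", "Complex",
                 "SBS", "Ins1", "SV",
                 "SBS", "DelGE2", "InsGE2", "SBS"),
    zygosity = "heterozygous", stringsAsFactors = FALSE)
  s <- summarize_strain(events, dose_gy = 100, n_plants = 3,
                        genome_length_bp = 1e6, strain = "test")
  tot <- s[s$type == "Total", ]
  types <- s[s$type != "Total", ]
  expect_equal(sum(types$count_mean), tot$count_mean)
  expect_equal(sum(types$rate_per_bp_e8), tot$rate_per_bp_e8)
  expect_equal(sum(types$fraction), 1)
  # per-Gy = per-bp / dose on matching scales (1e-10 vs 1e-8 is x100)
  expect_equal(s$rate_per_bp_per_gy_e10,
               s$rate_per_bp_e8 * 100 / 100)
  # single plant with one event of each type
  ev7 <- data.frame(sample_id = "p1",
                    category = c("SBS", "Del1", "Ins1", "DelGE2",
                                 "InsGE2", "Complex", "SV"),
                    zygosity = "heterozygous")
  s7 <- summarize_strain(ev7, dose_gy = 100, n_plants = 1,
                         genome_length_bp = 1e6, strain = "t")
  expect_equal(s7$fraction[s7$type != "Total"], rep(1 / 7, 7))
  # zero-event plants enter the denominator
  szero <- summarize_strain(ev7, dose_gy = 100, n_plants = 2,
                            genome_length_bp = 1e6, strain = "t")
  expect_equal(szero$count_mean[szero$type == "Total"], 3.5)
})

test_that("per-Gy scaling commutes with averaging across plants", {
  set.seed(3)
  counts <- rpois(8, 20)
  L <- 1e6; dose <- 250
  r <- per_bp_rate(counts, L)
  expect_equal(per_gy(r$mean, dose), mean(per_gy(counts / L, dose)))
})

test_that("sbs_spectrum excludes complex members by default", {
  calls <- rbind(
    call_row(pos = 10, ref_allele = "A", alt_allele = "G",
             variant_class = "substitution"),
    call_row(pos = 100, ref_allele = "C", alt_allele = "T",
             variant_class = "substitution"),
    call_row(pos = 104, ref_allele = "G", alt_allele = "T",
             variant_class = "substitution"))
  calls$zygosity <- "heterozygous"
  ev <- build_events(calls)
  sp <- sbs_spectrum(ev$members, ev$events)
  expect_equal(sum(sp), 1L)  # only the isolated SBS
  expect_equal(unname(sp["A/T>G/C"]), 1L)
  sp_all <- sbs_spectrum(ev$members, ev$events, include_complex = TRUE)
  expect_equal(sum(sp_all), 3L)
})
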