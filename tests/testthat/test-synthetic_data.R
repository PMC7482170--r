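# Synthetic-data generators: determinism, distributional targets,
# M2 segregation, call emission and filter interplay.

test_that("generate_reference is seed-deterministic with target GC", {
  r1 <- generate_reference(100000, 0.36, seed = 1)
  r2 <- generate_reference(100000, 0.36, seed = 1)
  expect_identical(r1$sequences, r2$sequences)
  r3 <- generate_reference(100000, 0.36, seed = 2)
  expect_false(identical(r1$sequences, r3$sequences))

  gc <- function(ref) {
    s <- ref$sequences[[1]]
    tab <- table(strsplit(s, "")[[1]])
    sum(tab[c("G", "C")]) / nchar(s)
  }
  expect_equal(gc(r1), 0.36, tolerance = 0.02 / 0.36)

  at_only <- generate_reference(5000, 0, seed = 3)
  expect_false(grepl("[GC]", at_only$sequences[[1]]))
})

test_that("spike_mutations honors the profile category mix and is reproducible", {
  ref <- generate_reference(4e5, seed = 5)
  prof <- wt_profile(n_plants = 4)
  # SBS-only profile
  prof$rates[] <- 0
  prof$rates["SBS"] <- 10
  t1 <- spike_mutations(ref, prof, seed = 9)
  t2 <- spike_mutations(ref, prof, seed = 9)
  expect_identical(t1$events, t2$events)
  expect_true(all(t1$events$category == "SBS"))
  expect_equal(mean(table(factor(t1$events$sample_id,
                                 levels = unique(t1$events$sample_id)))),
               10, tolerance = 0.35)
  # events are placed far apart: no two events of one sample within 10 bp
  bys <- split(t1$events, t1$events$sample_id)
  for (e in bys) {
    e <- e[order(e$chrom, e$start), ]
    same <- e$chrom[-1] == e$chrom[-nrow(e)]
    gaps <- e$start[-1] - e$end[-nrow(e)] - 1
    expect_true(all(gaps[same] > 10))
  }
})

test_that("deletion placement matches the target microhomology distribution", {
  ref <- generate_reference(6e5, seed = 13)
  prof <- ku70_profile(n_plants = 1)
  prof$rates[] <- 0
  prof$rates["DelGE2"] <- 500
  truth <- spike_mutations(ref, prof, seed = 17, min_event_gap = 20)
  mh <- truth$events$mh_length
  expect_gte(length(mh), 450)
  realized <- table(factor(as.character(bin_microhomology(mh)),
                           levels = names(prof$mh_weights)))
  # chi-square against the profile target, excluding zero-weight bins
  w <- prof$mh_weights[prof$mh_weights > 0]
  ct <- realized[names(w)]
  p <- suppressWarnings(chisq.test(ct, p = w / sum(w))$p.value)
  expect_gt(p, 0.01)
  # the modal bin is the profile's modal bin (3-4 for the mutant profile)
  expect_equal(names(which.max(realized)), "3-4")
  # realized microhomology agrees with the scoring module
  for (i in sample(nrow(truth$events), 25)) {
    e <- truth$events[i, ]
    expect_equal(compute_microhomology(ref, e$chrom, e$start, e$end),
                 e$mh_length)
  }
})

test_that("M2 segregation: carriers ~3/4, hom:het ratio ~0.5", {
  st <- simulate_m2(10000, seed = 21)
  expect_identical(st, simulate_m2(10000, seed = 21))
  tab <- table(st)
  carrier <- 1 - tab[["absent"]] / 10000
  expect_equal(carrier, 0.75, tolerance = 3 * sqrt(0.75 * 0.25 / 10000) /
                 0.75)
  p_hom <- tab[["homozygous"]] / (tab[["homozygous"]] +
                                    tab[["heterozygous"]])
  se <- sqrt((1 / 3) * (2 / 3) / (tab[["homozygous"]] +
                                    tab[["heterozygous"]]))
  expect_lt(abs(p_hom - 1 / 3), 3 * se)
  expect_true(simulate_m2(1, seed = 2) %in%
                c("homozygous", "heterozygous", "absent"))
})

test_that("emitted allele frequencies concentrate near truth at high depth", {
  ref <- generate_reference(3e5, seed = 33)
  prof <- wt_profile(n_plants = 3)
  prof$rates[] <- 0
  prof$rates["SBS"] <- 80
  truth <- spike_mutations(ref, prof, seed = 35)
  calls <- emit_candidate_calls(truth, ref, depth = 1000, seed = 37)
  zyg <- truth$events$zygosity[match(
    paste(calls$sample_id, calls$chrom, calls$pos),
    paste(truth$events$sample_id, truth$events$chrom,
          truth$events$start))]
  het <- calls$allele_frequency[zyg == "heterozygous"]
  expect_gte(mean(het >= 0.45 & het <= 0.55), 0.99)
  hom <- calls$allele_frequency[zyg == "homozygous"]
  expect_true(all(hom == 1))
})

test_that("artifact sites and noise are removed by the filters; exact mode recovers truth", {
  ref <- generate_reference(3e5, seed = 41)
  prof <- ku70_profile(n_plants = 5)
  prof$rates[] <- 0
  prof$rates[c("SBS", "Del1", "DelGE2")] <- c(10, 3, 5)
  truth <- spike_mutations(ref, prof, seed = 43)
  calls <- emit_candidate_calls(truth, ref, af_mode = "exact",
                                error_rate = 4, n_artifact_sites = 3,
                                seed = 45)
  calls <- normalize_calls(calls, ref)
  res <- filter_calls(calls)
  # every injected artifact site (shared by > 2 samples) is excluded
  expect_gte(sum(res$excluded$reason == "shared_site"), 3L)
  # noise is in the low-AF partition
  expect_equal(unname(res$counts["excluded_low_af"]),
               sum(calls$allele_frequency <= 0.25))
  # with no noise at all, calls equal truth exactly after filtering
  clean <- emit_candidate_calls(truth, ref, af_mode = "exact", seed = 47)
  clean <- normalize_calls(clean, ref)
  res2 <- filter_calls(clean)
  expect_equal(nrow(res2$retained), nrow(truth$members))
  truth_calls <- truth$members[, names(clean)[1:9]]
  truth_calls$allele_frequency <- 0.5  # placeholder: truth carries no AF
  norm_truth <- normalize_calls(truth_calls, ref)
  got <- res2$retained[order(res2$retained$sample_id,
                             res2$retained$pos), ]
  want <- norm_truth[order(norm_truth$sample_id, norm_truth$pos), ]
  expect_equal(got$pos, want$pos)
  expect_equal(got$ref_allele, want$ref_allele)
  expect_equal(got$alt_allele, want$alt_allele)
})

test_that("emitted files round-trip through the readers and carry the seed", {
  ref <- generate_reference(2e5, seed = 51)
  prof <- lig4_profile(n_plants = 2)
  prof$rates[] <- 0
  prof$rates[c("SBS", "DelGE2", "InsGE2", "SV")] <- c(6, 6, 3, 2)
  prof$del_len_weights[] <- c(0.3, 0.3, 0.3, 0.1)  # force long indels too
  truth <- spike_mutations(ref, prof, seed = 53)
  dir <- withr::local_tempdir()
  emitted <- emit_candidate_calls(truth, ref, af_mode = "exact",
                                  seed = 55, dir = dir)
  vcfs <- list.files(dir, pattern = "\\.vcf$", full.names = TRUE)
  svs <- list.files(dir, pattern = "\\.sv\\.tsv$", full.names = TRUE)
  expect_equal(length(vcfs), 2L)
  expect_equal(length(svs), 2L)
  expect_true(any(grepl("radmut_seed=55", readLines(vcfs[1]))))
  back <- NULL
  for (f in vcfs) back <- rbind(back, read_candidate_calls(f, "vcf"))
  for (f in svs) back <- rbind(back, read_candidate_calls(f, "sv_tsv"))
  back <- normalize_calls(back, ref)
  norm <- normalize_calls(emitted, ref)
  key <- function(x) sort(paste(x$sample_id, x$chrom, x$pos, x$end,
                                x$ref_allele, x$alt_allele,
                                x$variant_class))
  expect_equal(key(back), key(norm))
  expect_true(file.exists(file.path(dir, "truth_events.tsv")))
  expect_true(file.exists(file.path(dir, "metadata.tsv")))
})

test_that("simulated survival matches closed-form expectations", {
  obs <- simulate_survival(200, 1, doses = c(0, 200), n_plants = 500,
                           n_reps = 20, seed = 61)
  fr <- survival_fractions(obs)
  expect_equal(fr$mean_fraction[fr$dose_gy == 0], 1)
  expect_equal(fr$mean_fraction[fr$dose_gy == 200], exp(-1),
               tolerance = 0.05)
  # round trip through the fitter
  obs2 <- simulate_survival(200, 3, doses = seq(0, 600, 50),
                            n_plants = 200, n_reps = 3, seed = 63)
  fr2 <- survival_fractions(obs2)
  fit <- fit_single_hit_multitarget(fr2$dose_gy, fr2$mean_fraction)
  expect_equal(fit$d0_gy, 200, tolerance = 0.1)
  expect_equal(fit$dq_gy, 200 * log(3), tolerance = 0.1)
})
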