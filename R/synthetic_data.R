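# Synthetic-data generators: reference genomes, ground-truth mutation sets
# per strain profile, candidate-call emission with read-support allele
# frequencies, M2 segregation of induced heterozygous mutations, and
# dose-survival tables. Everything is deterministic under a fixed seed.

#' Strain profile for the mutation generator
#'
#' A profile holds the per-plant event rates for the seven categories and
#' the distributional structure of each: substitution spectrum weights,
#' indel length mixtures, the target microhomology-bin distribution for
#' deletions >= 2 bp, and the composition mixture for complex events.
#'
#' @param name Strain label.
#' @param dose_gy Dose applied to the strain (Gy).
#' @param n_plants Default cohort size.
#' @param rates Named numeric vector of mean events per plant for the seven
#'   categories `SBS, Del1, Ins1, DelGE2, InsGE2, Complex, SV`.
#' @param sbs_weights Weights over the six strand-collapsed substitution
#'   classes (sums to 1).
#' @param del_len_weights,ins_len_weights Weights over the length bins
#'   `2-10, 11-30, 31-100, >100` for Del/Ins >= 2 bp (sum to 1).
#' @param mh_weights Target weights over the microhomology bins
#'   `0, 1, 2, 3-4, 5-9, >=10` for deletions >= 2 bp (sums to 1).
#' @param complex_sbs_only Probability that a complex event consists of
#'   substitutions only (otherwise it contains short indels).
#' @param survival_d0,survival_n Single-hit multitarget parameters of the
#'   strain's dose-survival behaviour.
#' @param survival_doses Default dose series of the survival assay (Gy).
#' @return An object of class `strain_profile`.
#' @export
strain_profile <- function(name, dose_gy, n_plants, rates,
                           sbs_weights, del_len_weights, ins_len_weights,
                           mh_weights, complex_sbs_only,
                           survival_d0, survival_n, survival_doses) {
  stopifnot(all(EVENT_CATEGORIES %in% names(rates)), all(rates >= 0),
            length(sbs_weights) == 6L,
            abs(sum(sbs_weights) - 1) < 1e-8,
            length(del_len_weights) == 4L,
            abs(sum(del_len_weights) - 1) < 1e-8,
            length(ins_len_weights) == 4L,
            abs(sum(ins_len_weights) - 1) < 1e-8,
            length(mh_weights) == 6L,
            abs(sum(mh_weights) - 1) < 1e-8,
            complex_sbs_only >= 0, complex_sbs_only <= 1,
            survival_d0 > 0, survival_n >= 1)
  structure(list(name = name, dose_gy = dose_gy, n_plants = n_plants,
                 rates = rates[EVENT_CATEGORIES],
                 sbs_weights = setNames(sbs_weights, SBS_CLASSES),
                 del_len_weights = setNames(del_len_weights,
                                            INDEL_BINS[-1L]),
                 ins_len_weights = setNames(ins_len_weights,
                                            INDEL_BINS[-1L]),
                 mh_weights = setNames(mh_weights, MH_BINS),
                 complex_sbs_only = complex_sbs_only,
                 survival_d0 = survival_d0, survival_n = survival_n,
                 survival_doses = survival_doses),
            class = "strain_profile")
}

#' Built-in strain profiles
#'
#' Default profiles emulating a gamma-irradiation experiment on wild-type
#' and NHEJ-deficient (Ku70 and Lig4 knockout) Arabidopsis. Event rates per
#' plant equal the published per-type rates (see [strain_rate_table()]);
#' the mutants show the shifted indel length distribution (11-30 bp modal
#' deletions), the 3-4 bp microhomology peak with a low no-microhomology
#' fraction, and indel-containing complex events, while the control peaks
#' at 2 bp microhomology with mostly substitution-only complex events.
#' Survival parameters are calibrated so the profiles' quasi-threshold
#' doses sit near the reported shoulder doses.
#'
#' @param n_plants Optional cohort-size override.
#' @return A `strain_profile`.
#' @export
wt_profile <- function(n_plants = 10L) {
  tab <- strain_rate_table()
  r <- setNames(tab$rate_e8[tab$strain == "WT"][1:7], EVENT_CATEGORIES)
  strain_profile("WT", dose_gy = 1000, n_plants = n_plants, rates = r,
                 sbs_weights = c(0.24, 0.24, 0.20, 0.11, 0.11, 0.10),
                 del_len_weights = c(0.60, 0.25, 0.10, 0.05),
                 ins_len_weights = c(0.70, 0.20, 0.08, 0.02),
                 mh_weights = c(0.24, 0.22, 0.30, 0.18, 0.06, 0),
                 complex_sbs_only = 0.87,
                 survival_d0 = 800, survival_n = 13,
                 survival_doses = c(0, 250, 500, 1000, 1500, 2000, 2500,
                                    3000))
}

#' @rdname wt_profile
#' @export
ku70_profile <- function(n_plants = 10L) {
  tab <- strain_rate_table()
  r <- setNames(tab$rate_e8[tab$strain == "AtKu70"][1:7],
                EVENT_CATEGORIES)
  strain_profile("AtKu70", dose_gy = 100, n_plants = n_plants, rates = r,
                 sbs_weights = c(0.24, 0.24, 0.20, 0.11, 0.11, 0.10),
                 del_len_weights = c(0.25, 0.50, 0.20, 0.05),
                 ins_len_weights = c(0.50, 0.35, 0.12, 0.03),
                 mh_weights = c(0.12, 0.14, 0.26, 0.38, 0.10, 0),
                 complex_sbs_only = 0.15,
                 survival_d0 = 105, survival_n = 6.3,
                 survival_doses = seq(0, 350, by = 50))
}

#' @rdname wt_profile
#' @export
lig4_profile <- function(n_plants = 9L) {
  tab <- strain_rate_table()
  r <- setNames(tab$rate_e8[tab$strain == "AtLig4"][1:7],
                EVENT_CATEGORIES)
  strain_profile("AtLig4", dose_gy = 100, n_plants = n_plants, rates = r,
                 sbs_weights = c(0.24, 0.24, 0.20, 0.11, 0.11, 0.10),
                 del_len_weights = c(0.25, 0.50, 0.20, 0.05),
                 ins_len_weights = c(0.50, 0.35, 0.12, 0.03),
                 mh_weights = c(0.04, 0.14, 0.28, 0.42, 0.12, 0),
                 complex_sbs_only = 0.15,
                 survival_d0 = 115, survival_n = 6.9,
                 survival_doses = seq(0, 350, by = 50))
}

#' Generate a random reference genome
#'
#' @param length_bp Total length in bp (single chromosome `chr1`), or a
#'   named vector of per-chromosome lengths.
#' @param gc_fraction Target GC content (default 0.36, Arabidopsis-like).
#' @param seed Optional RNG seed (reproducible output for a fixed seed).
#' @return A [reference_genome()].
#' @export
generate_reference <- function(length_bp = 1e6, gc_fraction = 0.36,
                               seed = NULL) {
  stopifnot(all(length_bp >= 1000), gc_fraction >= 0, gc_fraction <= 1)
  if (is.null(names(length_bp)))
    names(length_bp) <- paste0("chr", seq_along(length_bp))
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  with_seed(seed, {
    seqs <- vapply(length_bp, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      "")
    reference_genome(seqs)
  })
}

#' Spike ground-truth mutations into a reference
#'
#' Per plant, per-category event counts are drawn Poisson around the
#' profile rates. Substitution classes and indel lengths follow the profile
#' weights; deletions >= 2 bp are placed by rejection sampling (up to
#' `max_place_tries` candidate placements) so their realized microhomology
#' bin matches a draw from the profile's target distribution, and are
#' skipped (with a count in `attr(, "skipped")`) when no placement is
#' found. Complex events are built as 2-3 variants separated by 2-8
#' matching bases. Zygosity is drawn per event as homozygous with
#' probability 1/3 and heterozygous with 2/3 — the Mendelian expectation
#' among mutations detected in one sampled M2 plant (see [simulate_m2()]).
#' Events of all samples are kept at least `min_event_gap` reference bases
#' apart so no two events fall within the merge window.
#'
#' @param ref A [reference_genome()].
#' @param profile A [strain_profile()].
#' @param n_plants Number of plants (default from the profile).
#' @param seed Optional RNG seed.
#' @param min_event_gap Minimum reference gap between distinct events (bp).
#' @param max_place_tries Placement attempts per deletion before skipping.
#' @return Object of class `ground_truth`: list with `events` (one row per
#'   true event: `event_id`, `sample_id`, `chrom`, `start`, `end`,
#'   `category`, `zygosity`, `length`, `mh_length`) and `members` (one row
#'   per variant with `event_id`, in candidate-call layout). The seed and
#'   profile are stored as attributes.
#' @export
spike_mutations <- function(ref, profile, n_plants = profile$n_plants,
                            seed = NULL, min_event_gap = 100L,
                            max_place_tries = 1000L) {
  stopifnot(inherits(profile, "strain_profile"))
  with_seed(seed, {
    gen <- new.env(parent = emptyenv())
    gen$occupied <- lapply(ref$sequences, function(s)
      logical(nchar(s)))  # marks event spans
    gen$members <- list(); gen$events <- list()
    gen$eid <- 0L; gen$skipped <- 0L
    for (pl in seq_len(n_plants)) {
      sample_id <- sprintf("%s_p%02d", profile$name, pl)
      counts <- rpois(length(profile$rates), profile$rates)
      names(counts) <- names(profile$rates)
      for (cat in EVENT_CATEGORIES) {
        for (k in seq_len(counts[[cat]])) {
          spike_one_event(gen, ref, profile, sample_id, cat,
                          min_event_gap, max_place_tries)
        }
      }
    }
    events <- do.call(rbind, gen$events)
    members <- do.call(rbind, gen$members)
    if (is.null(events)) {
      events <- data.frame(event_id = integer(), sample_id = character(),
                           chrom = character(), start = integer(),
                           end = integer(), category = character(),
                           zygosity = character(), length = integer(),
                           mh_length = integer(), stringsAsFactors = FALSE)
      members <- cbind(candidate_calls(), event_id = integer())
    }
    structure(list(events = events, members = members),
              class = "ground_truth", seed = seed,
              profile = profile$name, skipped = gen$skipped)
  })
}

# --- internal generator machinery ------------------------------------------

# Reserve [start, end] if it is >= gap away from every reserved span and
# free of N; returns TRUE on success.
reserve_span <- function(gen, ref, chrom, start, end, gap) {
  occ <- gen$occupied[[chrom]]
  len <- length(occ)
  lo <- max(1L, start - gap); hi <- min(len, end + gap)
  if (start < 2L || end > len - 1L) return(FALSE)
  if (any(occ[lo:hi])) return(FALSE)
  if (grepl("N", substr(ref$sequences[[chrom]], lo, hi), fixed = TRUE))
    return(FALSE)
  gen$occupied[[chrom]][start:end] <- TRUE
  TRUE
}

random_chrom <- function(ref) {
  lens <- nchar(ref$sequences)
  sample_one(names(ref$sequences), prob = lens / sum(lens))
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw an indel length given profile bin weights over 2-10/11-30/31-100/>100.
draw_indel_length <- function(weights) {
  bin <- sample_one(names(weights), prob = weights)
  switch(bin,
         "2-10" = sample_one(2:10),
         "11-30" = sample_one(11:30),
         "31-100" = sample_one(31:100),
         ">100" = sample_one(101:300))
}

# alt base for a target strand-collapsed class given the ref base
sbs_alt_for <- function(ref_base, class) {
  pairs <- list("A/T>G/C" = c(A = "G", T = "C"),
                "G/C>A/T" = c(G = "A", C = "T"),
                "A/T>T/A" = c(A = "T", T = "A"),
                "A/T>C/G" = c(A = "C", T = "G"),
                "G/C>T/A" = c(G = "T", C = "A"),
                "G/C>C/G" = c(G = "C", C = "G"))
  unname(pairs[[class]][ref_base])
}

spike_one_event <- function(gen, ref, profile, sample_id, cat, gap,
                            max_tries) {
  zyg <- if (runif(1) < 1 / 3) "homozygous" else "heterozygous"
  mk_member <- function(chrom, pos, end, ra, aa, cls)
    data.frame(sample_id = sample_id, chrom = chrom, pos = pos, end = end,
               ref_allele = ra, alt_allele = aa, variant_class = cls,
               allele_frequency = NA_real_, source = "truth",
               stringsAsFactors = FALSE)
  # draw the event's distributional targets once, then retry placements,
  # so realized spectra match the profile weights rather than the genome's
  # base composition or the natural microhomology distribution
  sbs_class <- if (cat == "SBS")
    sample_one(SBS_CLASSES, prob = profile$sbs_weights)
  del_len <- if (cat == "DelGE2")
    draw_indel_length(profile$del_len_weights)
  target_bin <- if (cat == "DelGE2")
    sample_one(MH_BINS, prob = profile$mh_weights)
  place <- NULL
  for (try_i in seq_len(max_tries)) {
    chrom <- random_chrom(ref)
    clen <- chrom_length(ref, chrom)
    cand <- switch(cat,
      SBS = {
        src <- if (sbs_class %in% c("A/T>G/C", "A/T>T/A", "A/T>C/G"))
          c("A", "T") else c("G", "C")
        pos <- sample_one(10:(clen - 10L))
        rb <- ref_segment(ref, chrom, pos)
        if (!rb %in% src) NULL
        else list(members = mk_member(chrom, pos, pos, rb,
                                      sbs_alt_for(rb, sbs_class),
                                      "substitution"),
                  start = pos, end = pos, mh = NA_integer_)
      },
      Del1 = {
        pos <- sample_one(10:(clen - 10L))
        list(members = mk_member(chrom, pos, pos,
                                 ref_segment(ref, chrom, pos), "",
                                 "deletion"),
             start = pos, end = pos, mh = NA_integer_)
      },
      Ins1 = {
        pos <- sample_one(10:(clen - 10L))
        list(members = mk_member(chrom, pos, pos, "", random_seq(1L),
                                 "insertion"),
             start = pos, end = pos, mh = NA_integer_)
      },
      DelGE2 = {
        pos <- sample_one(10:(clen - del_len - 10L))
        mh <- compute_microhomology(ref, chrom, pos, pos + del_len - 1L)
        if (is.na(mh) ||
            as.character(bin_microhomology(mh)) != target_bin) NULL
        else list(members = mk_member(chrom, pos, pos + del_len - 1L,
                                      ref_segment(ref, chrom, pos,
                                                  pos + del_len - 1L),
                                      "", "deletion"),
                  start = pos, end = pos + del_len - 1L, mh = mh)
      },
      InsGE2 = {
        len <- draw_indel_length(profile$ins_len_weights)
        pos <- sample_one(10:(clen - 10L))
        list(members = mk_member(chrom, pos, pos, "", random_seq(len),
                                 "insertion"),
             start = pos, end = pos, mh = NA_integer_)
      },
      Complex = build_complex(ref, chrom, clen, profile, mk_member),
      SV = {
        len <- sample_one(200:2000)
        pos <- sample_one(10:(clen - len - 10L))
        list(members = mk_member(chrom, pos, pos + len - 1L, "", "",
                                 "inversion"),
             start = pos, end = pos + len - 1L, mh = NA_integer_)
      })
    if (is.null(cand)) next
    if (reserve_span(gen, ref, chrom, cand$start, cand$end, gap)) {
      place <- cand; place$chrom <- chrom
      break
    }
  }
  if (is.null(place)) {
    gen$skipped <- gen$skipped + 1L
    return(invisible(NULL))
  }
  gen$eid <- gen$eid + 1L
  members <- place$members
  members$event_id <- gen$eid
  gen$members[[length(gen$members) + 1L]] <- members
  gen$events[[length(gen$events) + 1L]] <- data.frame(
    event_id = gen$eid, sample_id = sample_id, chrom = place$chrom,
    start = place$start, end = place$end, category = cat, zygosity = zyg,
    length = switch(cat,
                    SBS = 1L, Del1 = 1L, Ins1 = 1L,
                    DelGE2 = place$end - place$start + 1L,
                    InsGE2 = nchar(members$alt_allele[1L]),
                    Complex = place$end - place$start + 1L,
                    SV = place$end - place$start + 1L),
    mh_length = place$mh, stringsAsFactors = FALSE)
  invisible(NULL)
}

# A complex event: 2-3 small variants separated by 2-8 matching reference
# bases (so they merge into one event but remain distinct change blocks).
build_complex <- function(ref, chrom, clen, profile, mk_member) {
  sbs_only <- runif(1) < profile$complex_sbs_only
  n_var <- sample_one(2:3)
  kinds <- if (sbs_only) rep("substitution", n_var)
           else {
             k <- sample(c("substitution", "deletion", "insertion"), n_var,
                         replace = TRUE)
             if (!any(k %in% c("deletion", "insertion")))
               k[sample.int(n_var, 1L)] <- "deletion"
             k
           }
  pos0 <- sample_one(20:(clen - 100L))
  cursor <- pos0
  members <- NULL
  for (kind in kinds) {
    m <- switch(kind,
      substitution = {
        rb <- ref_segment(ref, chrom, cursor)
        alt <- sample_one(setdiff(c("A", "C", "G", "T"), rb))
        out <- mk_member(chrom, cursor, cursor, rb, alt, "substitution")
        cursor <- cursor + 1L
        out
      },
      deletion = {
        len <- sample_one(2:5)
        out <- mk_member(chrom, cursor, cursor + len - 1L,
                         ref_segment(ref, chrom, cursor,
                                     cursor + len - 1L),
                         "", "deletion")
        cursor <- cursor + len
        out
      },
      insertion = {
        out <- mk_member(chrom, cursor, cursor, "",
                         random_seq(sample_one(2:4)), "insertion")
        cursor <- cursor + 1L
        out
      })
    members <- rbind(members, m)
    cursor <- cursor + sample_one(2:8)  # matching spacer
  }
  list(members = members, start = min(members$pos),
       end = max(members$end), mh = NA_integer_)
}

#' Simulate M2 zygosity of M1-induced heterozygous mutations
#'
#' Each induced heterozygous mutation of the irradiated (M1) generation is
#' observed in one sampled selfed-progeny (M2) plant as homozygous with
#' probability 1/4, heterozygous with 1/2 and absent with 1/4 (Mendelian
#' 1:2:1 segregation), so the expected homozygous:heterozygous ratio among
#' detected mutations is 0.5.
#'
#' @param n_m1_mutations Number of independent induced mutations (>= 1).
#' @param seed Optional RNG seed.
#' @return Character vector of states (`homozygous`, `heterozygous`,
#'   `absent`), one per mutation.
#' @export
simulate_m2 <- function(n_m1_mutations, seed = NULL) {
  stopifnot(n_m1_mutations >= 1)
  with_seed(seed,
    sample(c("homozygous", "heterozygous", "absent"), n_m1_mutations,
           replace = TRUE, prob = c(0.25, 0.5, 0.25)))
}

#' Emit candidate calls from a ground truth
#'
#' Converts true variants to per-sample candidate calls with read-support
#' allele frequencies, optionally adding low-frequency noise calls and
#' multi-sample artifact sites (which the downstream filters must remove),
#' and optionally writing per-sample VCF / sv_tsv files plus the truth
#' table.
#'
#' With `af_mode = "sampled"`, the allele frequency of each variant is
#' `rbinom(1, depth_i, p) / depth_i` with `p = 0.5` (heterozygous) or `1`
#' (homozygous) and per-site depth `depth_i ~ max(1, Poisson(depth))`.
#' With `af_mode = "exact"` (noise-free), the allele frequency is exactly
#' `p`.
#'
#' @param truth A `ground_truth` from [spike_mutations()] (or a compatible
#'   list of `events`/`members`).
#' @param ref The [reference_genome()] the truth was spiked into.
#' @param depth Mean sequencing depth (Poisson per site).
#' @param af_mode `"sampled"` or `"exact"`, see above.
#' @param error_rate Expected number of low-frequency (AF <= 0.25) noise
#'   calls per sample (Poisson).
#' @param n_artifact_sites Number of artifact sites injected, each into
#'   more than two samples with intermediate allele frequencies.
#' @param seed Optional RNG seed.
#' @param dir Optional output directory; when given, writes
#'   `<sample>.vcf`, `<sample>.sv.tsv`, `truth_events.tsv`,
#'   `truth_members.tsv` and `metadata.tsv` (including the seed).
#' @param sv_tsv_min_len Indels at least this long are emitted through the
#'   sv_tsv dialect instead of the VCF (emulating a dedicated long-indel
#'   caller); inversions/translocations always use sv_tsv.
#' @return The candidate-call `data.frame` over all samples (invisibly when
#'   `dir` is given).
#' @export
emit_candidate_calls <- function(truth, ref, depth = 50,
                                 af_mode = c("sampled", "exact"),
                                 error_rate = 0, n_artifact_sites = 0,
                                 seed = NULL, dir = NULL,
                                 sv_tsv_min_len = 31L) {
  af_mode <- match.arg(af_mode)
  stopifnot(depth >= 1)
  members <- truth$members
  events <- truth$events
  with_seed(seed, {
    calls <- members[, call_columns]
    zyg <- events$zygosity[match(members$event_id, events$event_id)]
    p <- ifelse(zyg == "homozygous", 1, 0.5)
    if (af_mode == "exact") {
      calls$allele_frequency <- p
    } else {
      dp <- pmax(1L, rpois(nrow(calls), depth))
      calls$allele_frequency <- rbinom(nrow(calls), dp, p) / dp
    }
    long_indel <- calls$variant_class %in% c("deletion", "insertion") &
      pmax(nchar(calls$ref_allele), nchar(calls$alt_allele)) >=
        sv_tsv_min_len
    is_sv <- calls$variant_class %in% c("inversion", "translocation")
    calls$source <- ifelse(is_sv, "breakdancer_like",
                           ifelse(long_indel, "pindel_like", "gatk_like"))
    samples <- unique(members$sample_id)
    # low-AF sequencing noise
    noise <- NULL
    if (error_rate > 0) {
      for (s in samples) {
        for (k in seq_len(rpois(1, error_rate))) {
          chrom <- random_chrom(ref)
          pos <- sample_one(10:(chrom_length(ref, chrom) - 10L))
          rb <- ref_segment(ref, chrom, pos)
          if (rb == "N") next
          noise <- rbind(noise, candidate_calls(
            s, chrom, pos, pos, rb,
            sample_one(setdiff(c("A", "C", "G", "T"), rb)),
            "substitution", runif(1, 0.02, 0.25), "gatk_like"))
        }
      }
    }
    # artifact sites shared across more than two samples
    artifacts <- NULL
    if (n_artifact_sites > 0) {
      stopifnot(length(samples) >= 3L)
      for (k in seq_len(n_artifact_sites)) {
        chrom <- random_chrom(ref)
        pos <- sample_one(10:(chrom_length(ref, chrom) - 10L))
        rb <- ref_segment(ref, chrom, pos)
        if (rb == "N") next
        alt <- sample_one(setdiff(c("A", "C", "G", "T"), rb))
        carriers <- sample(samples,
                           sample_one(3:min(5L, length(samples))))
        artifacts <- rbind(artifacts, candidate_calls(
          carriers, chrom, pos, pos, rb, alt, "substitution",
          runif(length(carriers), 0.3, 0.7), "gatk_like"))
      }
    }
    all_calls <- rbind(calls, noise, artifacts)
    all_calls <- all_calls[order(all_calls$sample_id, all_calls$chrom,
                                 all_calls$pos), , drop = FALSE]
    rownames(all_calls) <- NULL
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      meta <- c(radmut_seed = if (is.null(seed)) "NA" else
                  as.character(seed),
                depth = as.character(depth), af_mode = af_mode,
                error_rate = as.character(error_rate),
                n_artifact_sites = as.character(n_artifact_sites))
      for (s in samples) {
        sc <- all_calls[all_calls$sample_id == s, , drop = FALSE]
        via_sv <- sc$variant_class %in% c("inversion", "translocation") |
          (sc$variant_class %in% c("deletion", "insertion") &
             pmax(nchar(sc$ref_allele), nchar(sc$alt_allele)) >=
               sv_tsv_min_len)
        write_candidate_vcf(sc[!via_sv, , drop = FALSE], ref,
                            file.path(dir, paste0(s, ".vcf")),
                            meta = meta)
        write_sv_tsv(sc[via_sv, , drop = FALSE],
                     file.path(dir, paste0(s, ".sv.tsv")))
      }
      write_tsv(events, file.path(dir, "truth_events.tsv"))
      write_tsv(members, file.path(dir, "truth_members.tsv"))
      write_tsv(data.frame(key = names(meta), value = unname(meta)),
                file.path(dir, "metadata.tsv"))
      return(invisible(all_calls))
    }
    all_calls
  })
}

#' Simulate a dose-survival assay
#'
#' Survivor counts are drawn binomially from the single-hit multitarget
#' survival probability at each dose.
#'
#' @param d0_gy,n_extrapolation Model parameters (see [shmt_survival()]).
#' @param doses Dose series in Gray.
#' @param n_plants Plants sown per replicate (default 30).
#' @param n_reps Replicates per dose (default 3).
#' @param seed Optional RNG seed.
#' @return `data.frame` with `dose_gy`, `replicate`, `n_sown`,
#'   `n_survived`.
#' @export
simulate_survival <- function(d0_gy, n_extrapolation, doses,
                              n_plants = 30L, n_reps = 3L, seed = NULL) {
  stopifnot(d0_gy > 0, n_extrapolation >= 1, n_plants >= 1, n_reps >= 1)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_reps), dose_gy = doses)
    s <- shmt_survival(grid$dose_gy, d0_gy, n_extrapolation)
    data.frame(dose_gy = grid$dose_gy, replicate = grid$replicate,
               n_sown = n_plants,
               n_survived = rbinom(nrow(grid), n_plants, s))
  })
}
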