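# Allele-frequency, cross-sample and zygosity filtering of candidate calls.
#
# Rules (configurable via filter_config()):
#   * calls with AF <= 0.25 are excluded;
#   * sites detected in more than 2 distinct samples are excluded as
#     shared artifacts (all calls at the site);
#   * a retained call is heterozygous if 0.25 < AF < 0.80 and homozygous if
#     AF >= 0.80, in both cases requiring AF < 0.05 in every other sample;
#     otherwise it is rejected (other-sample signal).

#' Filtering thresholds
#'
#' @param af_exclusion_max Calls with allele frequency at or below this are
#'   excluded (default 0.25).
#' @param het_hom_boundary Allele frequency at or above this is homozygous;
#'   between `af_exclusion_max` (exclusive) and this (exclusive) is
#'   heterozygous (default 0.80).
#' @param other_sample_max Maximum allele frequency tolerated at the same
#'   site in any other sample (default 0.05, exclusive bound).
#' @param shared_site_max_samples Sites present in more than this many
#'   distinct samples are excluded as shared artifacts (default 2).
#' @return A named list of thresholds.
#' @export
filter_config <- function(af_exclusion_max = 0.25,
                          het_hom_boundary = 0.80,
                          other_sample_max = 0.05,
                          shared_site_max_samples = 2L) {
  stopifnot(af_exclusion_max >= 0, af_exclusion_max < het_hom_boundary,
            het_hom_boundary <= 1, other_sample_max >= 0,
            other_sample_max <= 1, shared_site_max_samples >= 1)
  list(af_exclusion_max = af_exclusion_max,
       het_hom_boundary = het_hom_boundary,
       other_sample_max = other_sample_max,
       shared_site_max_samples = as.integer(shared_site_max_samples))
}

# Site identity after normalization: class-aware so SV breakpoint pairs are
# compared as such.
site_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$end, calls$ref_allele,
        calls$alt_allele, calls$variant_class, sep = "\r")
}

#' Exclude low-allele-frequency calls
#'
#' Retains calls with allele frequency strictly greater than `af_max`;
#' the boundary value itself is excluded. Order is preserved.
#'
#' @param calls Candidate-call `data.frame`.
#' @param af_max Exclusion threshold (default 0.25).
#' @return The retained rows.
#' @export
exclude_low_af <- function(calls, af_max = 0.25) {
  validate_calls(calls)
  calls[calls$allele_frequency > af_max, , drop = FALSE]
}

#' Exclude sites shared across too many samples
#'
#' A site (chromosome, position, alleles, class — after normalization) that
#' occurs in more than `max_samples` distinct samples is treated as a
#' systematic false positive and all its calls are removed.
#'
#' @param calls Candidate-call `data.frame` across all samples.
#' @param max_samples Largest tolerated number of distinct samples per site
#'   (default 2).
#' @return The retained rows.
#' @export
exclude_shared_sites <- function(calls, max_samples = 2L) {
  validate_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  key <- site_key(calls)
  nsamp <- tapply(calls$sample_id, key,
                  function(s) length(unique(s)))
  calls[nsamp[key] <= max_samples, , drop = FALSE]
}

# Maximum AF observed at each call's site in *other* samples of `all_calls`
# (0 when the site is absent elsewhere).
other_sample_max_af <- function(calls, all_calls = calls) {
  if (nrow(calls) == 0L) return(numeric(0))
  key_all <- site_key(all_calls)
  key <- site_key(calls)
  vapply(seq_len(nrow(calls)), function(i) {
    at <- key_all == key[i] & all_calls$sample_id != calls$sample_id[i]
    if (any(at)) max(all_calls$allele_frequency[at]) else 0
  }, 0)
}

#' Assign zygosity to retained calls
#'
#' Labels each call heterozygous (`af_exclusion_max < AF <
#' het_hom_boundary`) or homozygous (`AF >= het_hom_boundary`) provided the
#' allele frequency at the same site is below `other_sample_max` in every
#' other sample; calls failing that condition are rejected.
#'
#' @param calls Candidate-call rows that already passed [exclude_low_af()].
#' @param other_af Either a numeric vector giving, per call, the maximum
#'   allele frequency of the same site in other samples, or `NULL` to
#'   compute it from `all_calls`.
#' @param all_calls Full (pre-filter) call set used to look up other-sample
#'   allele frequencies when `other_af` is `NULL`.
#' @param config [filter_config()] thresholds.
#' @return A list with `accepted` (calls plus a `zygosity` column) and
#'   `rejected` (calls plus a `reason` column).
#' @export
assign_zygosity <- function(calls, other_af = NULL, all_calls = calls,
                            config = filter_config()) {
  validate_calls(calls)
  if (is.null(other_af)) other_af <- other_sample_max_af(calls, all_calls)
  stopifnot(length(other_af) == nrow(calls))
  af <- calls$allele_frequency
  ok_other <- other_af < config$other_sample_max
  zyg <- ifelse(af >= config$het_hom_boundary, "homozygous",
                ifelse(af > config$af_exclusion_max, "heterozygous",
                       NA_character_))
  accept <- ok_other & !is.na(zyg)
  accepted <- calls[accept, , drop = FALSE]
  accepted$zygosity <- zyg[accept]
  rejected <- calls[!accept, , drop = FALSE]
  rejected$reason <- ifelse(!ok_other[!accept], "other_sample_signal",
                            "low_af")
  list(accepted = accepted, rejected = rejected)
}

#' Filter candidate calls
#'
#' Applies, in order: cross-sample shared-site exclusion, low-allele-
#' frequency exclusion, and zygosity assignment (which rejects calls with
#' allele-frequency signal at the same site in other samples). Other-sample
#' allele frequencies are looked up in the *unfiltered* call set so that
#' low-frequency signal elsewhere still disqualifies a call. Every input
#' call ends in exactly one of the five partitions reported in `counts`.
#'
#' @param calls Candidate-call `data.frame` across all samples, normalized
#'   (see [normalize_calls()]) so that site identity is well defined.
#' @param config [filter_config()] thresholds.
#' @return A list with elements `retained` (calls plus `zygosity`),
#'   `excluded` (calls plus `reason`: `shared_site`, `low_af` or
#'   `other_sample_signal`) and `counts` (named integer vector:
#'   `input`, `excluded_shared`, `excluded_low_af`,
#'   `rejected_other_sample_signal`, `retained_heterozygous`,
#'   `retained_homozygous`).
#' @export
filter_calls <- function(calls, config = filter_config()) {
  validate_calls(calls)
  n_in <- nrow(calls)
  kept_shared <- exclude_shared_sites(calls, config$shared_site_max_samples)
  shared <- calls[!rownames(calls) %in% rownames(kept_shared), ,
                  drop = FALSE]
  kept_af <- exclude_low_af(kept_shared, config$af_exclusion_max)
  low <- kept_shared[!rownames(kept_shared) %in% rownames(kept_af), ,
                     drop = FALSE]
  zg <- assign_zygosity(kept_af,
                        other_af = other_sample_max_af(kept_af, calls),
                        config = config)
  excluded <- rbind(
    if (nrow(shared)) cbind(shared, reason = "shared_site"),
    if (nrow(low)) cbind(low, reason = "low_af"),
    zg$rejected)
  if (is.null(excluded))
    excluded <- cbind(calls[0, , drop = FALSE], reason = character(0))
  counts <- c(input = n_in,
              excluded_shared = nrow(shared),
              excluded_low_af = nrow(low),
              rejected_other_sample_signal = nrow(zg$rejected),
              retained_heterozygous =
                sum(zg$accepted$zygosity == "heterozygous"),
              retained_homozygous =
                sum(zg$accepted$zygosity == "homozygous"))
  list(retained = zg$accepted, excluded = excluded, counts = counts)
}
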