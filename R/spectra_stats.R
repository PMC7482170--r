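# Mutation spectra, length distributions, per-bp and per-Gy rates, fold
# changes and zygosity ratios.

SBS_CLASSES <- c("A/T>G/C", "G/C>A/T", "A/T>T/A", "A/T>C/G", "G/C>T/A",
                 "G/C>C/G")
INDEL_BINS <- c("1", "2-10", "11-30", "31-100", ">100")

#' Genome length used as the default per-bp denominator
#'
#' Length in bp of the non-redundant reference assembly (golden path of
#' chromosomes 1-5) of Arabidopsis thaliana used as the mutation-rate
#' denominator.
#' @export
ARABIDOPSIS_GOLDEN_PATH_BP <- 119146348L

#' Strand-collapsed substitution class
#'
#' Collapses the twelve possible single-base changes onto six classes by
#' pairing each change with its reverse complement (e.g. `A>G` and `T>C`
#' are both `A/T>G/C`).
#'
#' @param ref_base,alt_base Single bases (vectors allowed), unequal,
#'   in `A, C, G, T`.
#' @return Character vector of classes, one of
#'   `r paste(SBS_CLASSES, collapse = ", ")`.
#' @export
#' @examples
#' classify_sbs("A", "G")   # "A/T>G/C"
#' classify_sbs("T", "C")   # "A/T>G/C" (strand collapse)
classify_sbs <- function(ref_base, alt_base) {
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  ok <- ref_base %in% c("A", "C", "G", "T") &
    alt_base %in% c("A", "C", "G", "T") & ref_base != alt_base
  if (!all(ok)) stop("ref and alt must be unequal single bases in ACGT")
  map <- c("A>G" = "A/T>G/C", "T>C" = "A/T>G/C",
           "G>A" = "G/C>A/T", "C>T" = "G/C>A/T",
           "A>T" = "A/T>T/A", "T>A" = "A/T>T/A",
           "A>C" = "A/T>C/G", "T>G" = "A/T>C/G",
           "G>T" = "G/C>T/A", "C>A" = "G/C>T/A",
           "G>C" = "G/C>C/G", "C>G" = "G/C>C/G")
  unname(map[paste0(ref_base, ">", alt_base)])
}

#' Is a substitution class a transition?
#'
#' @param class Classes from [classify_sbs()].
#' @return Logical vector: `TRUE` for `A/T>G/C` and `G/C>A/T`.
#' @export
sbs_is_transition <- function(class) {
  class %in% c("A/T>G/C", "G/C>A/T")
}

#' Substitution spectrum of classified events
#'
#' Tallies simple SBS events over the six strand-collapsed classes.
#' Members of complex events are excluded by default (they are counted as
#' one complex event, not as substitutions).
#'
#' @param members Event members (calls with `event_id`).
#' @param events Classified events.
#' @param include_complex Also count substitution members of complex events
#'   (default `FALSE`).
#' @return Named integer vector of counts over the six classes.
#' @export
sbs_spectrum <- function(members, events, include_complex = FALSE) {
  keep_cat <- if (include_complex) c("SBS", "Complex") else "SBS"
  ids <- events$event_id[events$category %in% keep_cat]
  m <- members[members$event_id %in% ids &
                 members$variant_class == "substitution" &
                 nchar(members$ref_allele) == 1L, , drop = FALSE]
  cls <- if (nrow(m)) classify_sbs(m$ref_allele, m$alt_allele)
         else character(0)
  counts <- table(factor(cls, levels = SBS_CLASSES))
  setNames(as.integer(counts), SBS_CLASSES)
}

#' Length bin of an insertion/deletion event
#'
#' @param length Integer vector of indel lengths (>= 1).
#' @return Factor with levels `r paste(INDEL_BINS, collapse = ", ")`.
#' @export
indel_length_bin <- function(length) {
  if (any(length < 1L)) stop("indel length must be >= 1")
  cut(length, breaks = c(0.5, 1.5, 10.5, 30.5, 100.5, Inf),
      labels = INDEL_BINS)
}

#' Indel length distribution of classified events
#'
#' @param events Classified events; only the four indel categories are
#'   used (complex and SV events raise no error, they are simply ignored).
#' @return A `data.frame` with `kind` (deletion/insertion), `bin` and
#'   `count`.
#' @export
indel_length_table <- function(events) {
  del <- events[events$category %in% c("Del1", "DelGE2"), , drop = FALSE]
  ins <- events[events$category %in% c("Ins1", "InsGE2"), , drop = FALSE]
  tab <- function(e, kind) {
    counts <- table(indel_length_bin(e$length))
    data.frame(kind = kind, bin = names(counts),
               count = as.integer(counts), stringsAsFactors = FALSE)
  }
  rbind(tab(del, "deletion"), tab(ins, "insertion"))
}

#' Per-base-pair mutation rate across plants
#'
#' @param counts Integer vector of per-plant event counts (one element per
#'   plant; zero-event plants must be included as zeros).
#' @param genome_length_bp Denominator in bp (default the Arabidopsis
#'   golden-path length, `r ARABIDOPSIS_GOLDEN_PATH_BP` bp).
#' @return List with `mean` and `se` (per bp), and `n` (number of plants;
#'   `se` is 0 when `n == 1`).
#' @export
per_bp_rate <- function(counts, genome_length_bp = ARABIDOPSIS_GOLDEN_PATH_BP) {
  n <- length(counts)
  if (n < 1L) stop("at least one plant is required")
  if (genome_length_bp <= 0) stop("genome_length_bp must be positive")
  rates <- counts / genome_length_bp
  list(mean = mean(rates), se = se_mean(rates), n = n)
}

#' Per-Gray scaling of a rate
#'
#' Exact division by dose; standard errors scale identically.
#'
#' @param rate Numeric rate(s) (any consistent scale).
#' @param dose_gy Dose in Gray, > 0.
#' @return `rate / dose_gy`.
#' @export
per_gy <- function(rate, dose_gy) {
  if (!is.numeric(dose_gy) || length(dose_gy) != 1L || dose_gy <= 0)
    stop("dose_gy must be a single positive number")
  rate / dose_gy
}

#' Fold change of mutant per-Gy rates over the control
#'
#' @param mutant_rates Per-Gy rates of the mutant strains (averaged).
#' @param wt_rate Per-Gy rate of the control strain.
#' @return `mean(mutant_rates) / wt_rate`; `NA` when the control rate is 0
#'   (undefined).
#' @export
fold_change <- function(mutant_rates, wt_rate) {
  if (length(wt_rate) != 1L) stop("wt_rate must be a single rate")
  if (is.na(wt_rate) || wt_rate == 0) return(NA_real_)
  mean(mutant_rates) / wt_rate
}

#' Homozygous:heterozygous ratio with exact binomial test
#'
#' Under Mendelian segregation of induced heterozygous mutations, a sampled
#' selfed-generation (M2) plant carries a detected mutation as homozygous
#' with probability 1/3 and heterozygous with probability 2/3, so the
#' expected ratio is 0.5. The test is a two-sided exact binomial test of the
#' homozygous count against expected fraction 1/3 of detected events.
#'
#' @param events Classified events with a `zygosity` column (or any
#'   `data.frame`/vector coercible to zygosity labels).
#' @return List with `n_hom`, `n_het`, `ratio` (`NA` when no heterozygous
#'   events) and `p_value`.
#' @export
zygosity_ratio <- function(events) {
  zyg <- if (is.data.frame(events)) events$zygosity else events
  zyg <- zyg[!is.na(zyg)]
  n_hom <- sum(zyg == "homozygous")
  n_het <- sum(zyg == "heterozygous")
  n <- n_hom + n_het
  list(n_hom = n_hom, n_het = n_het,
       ratio = if (n_het > 0) n_hom / n_het else NA_real_,
       p_value = if (n > 0) binom.test(n_hom, n, p = 1 / 3)$p.value
                 else NA_real_)
}

#' Per-strain mutation-rate summary
#'
#' Tabulates per-plant event counts for the seven categories and derives
#' per-bp (reported on the 1e-8 scale) and per-Gy (1e-10 scale) rates with
#' standard errors across plants, plus each type's fraction of the total.
#'
#' @param events Classified events of one strain.
#' @param dose_gy Dose applied to the strain, in Gray.
#' @param n_plants Number of plants analyzed (>= number of distinct
#'   samples in `events`; plants without any event count as zeros).
#' @param genome_length_bp Rate denominator in bp.
#' @param strain Strain label.
#' @param samples Optional character vector of all sample ids (to identify
#'   zero-event plants by name).
#' @return A `data.frame` with one row per category plus a `Total` row:
#'   `strain`, `dose_gy`, `n_plants`, `type`, `count_mean`, `count_se`,
#'   `rate_per_bp_e8`, `rate_se_e8`, `rate_per_bp_per_gy_e10`,
#'   `rate_se_e10`, `fraction`.
#' @export
summarize_strain <- function(events, dose_gy, n_plants,
                             genome_length_bp = ARABIDOPSIS_GOLDEN_PATH_BP,
                             strain = "strain", samples = NULL) {
  if (is.null(samples)) samples <- unique(events$sample_id)
  samples <- unique(c(samples, events$sample_id))
  if (length(samples) < n_plants)
    samples <- c(samples,
                 sprintf("%s_zero%02d", strain,
                         seq_len(n_plants - length(samples))))
  if (length(samples) > n_plants)
    stop("more distinct samples than n_plants")
  counts <- table(factor(events$sample_id, levels = samples),
                  factor(events$category, levels = EVENT_CATEGORIES))
  counts <- matrix(as.integer(counts), nrow = length(samples),
                   dimnames = list(samples, EVENT_CATEGORIES))
  per_plant_total <- rowSums(counts)
  row_for <- function(type, cnt) {
    r <- per_bp_rate(cnt, genome_length_bp)
    data.frame(strain = strain, dose_gy = dose_gy, n_plants = n_plants,
               type = type,
               count_mean = mean(cnt), count_se = se_mean(cnt),
               rate_per_bp_e8 = r$mean * 1e8,
               rate_se_e8 = r$se * 1e8,
               rate_per_bp_per_gy_e10 = per_gy(r$mean, dose_gy) * 1e10,
               rate_se_e10 = per_gy(r$se, dose_gy) * 1e10,
               fraction = if (sum(per_plant_total) > 0)
                 sum(cnt) / sum(per_plant_total) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(EVENT_CATEGORIES, function(tp) row_for(tp, counts[, tp])),
    list(row_for("Total", per_plant_total))))
  out$fraction[out$type == "Total"] <- 1
  rownames(out) <- NULL
  out
}

#' Published per-type mutation rates used as reference conditions
#'
#' The per-type mutation rates (mean and standard error, on the 1e-8 per-bp
#' scale) reported for gamma-irradiated Arabidopsis: the NHEJ-deficient
#' AtKu70 and AtLig4 knockouts at 100 Gy and the wild-type control at
#' 1000 Gy. Numerically these values also equal the mean number of observed
#' mutation events per plant, and the package's synthetic strain profiles
#' use them as per-plant event rates. `ND` (not detected) entries are 0.
#'
#' @return A `data.frame` with `strain`, `dose_gy`, `n_plants`, `type`,
#'   `rate_e8` and `se_e8`; types are the seven event categories plus
#'   `Total` (the printed total, which may differ from the column sum by
#'   component rounding).
#' @export
strain_rate_table <- function() {
  types <- c(EVENT_CATEGORIES, "Total")
  mk <- function(strain, dose, n, rates, ses)
    data.frame(strain = strain, dose_gy = dose, n_plants = n,
               type = types, rate_e8 = rates, se_e8 = ses,
               stringsAsFactors = FALSE)
  rbind(
    mk("AtKu70", 100, 10,
       c(4.02, 0.34, 0.17, 4.27, 0.50, 1.42, 0.00, 10.71),
       c(0.46, 0.14, 0.11, 0.55, 0.19, 0.25, 0.00, 0.61)),
    mk("AtLig4", 100, 9,
       c(5.21, 0.19, 0.00, 4.84, 0.19, 1.12, 0.09, 11.62),
       c(0.95, 0.12, 0.00, 0.91, 0.12, 0.28, 0.09, 1.97)),
    mk("WT", 1000, 10,
       c(30.27, 6.98, 1.67, 6.28, 0.56, 3.21, 0.14, 49.10),
       c(3.36, 1.20, 0.89, 0.74, 0.28, 0.40, 0.14, 4.36)))
}
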