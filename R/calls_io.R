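# Candidate-call I/O: VCF subset and the sv_tsv dialect used for
# structural-variant caller output. All coordinate-convention conversion
# (VCF anchor base <-> internal minimal representation) lives here.
#
# Internal representation (1-based inclusive):
#   substitution: pos..end substituted, nchar(ref_allele) == nchar(alt_allele)
#   deletion:     pos..end deleted, alt_allele == ""
#   insertion:    alt_allele inserted *after* base `pos`, ref_allele == "",
#                 end == pos (zero-length reference span)
#   inversion/translocation: breakpoints pos (start) and end; alleles empty

CALL_CLASSES <- c("substitution", "deletion", "insertion",
                  "inversion", "translocation")

call_columns <- c("sample_id", "chrom", "pos", "end", "ref_allele",
                  "alt_allele", "variant_class", "allele_frequency",
                  "source")

#' Construct a candidate-call table
#'
#' One row per caller-reported variant in one sample. See
#' [read_candidate_calls()] for the coordinate conventions.
#'
#' @param sample_id,chrom Character vectors.
#' @param pos,end Integer 1-based inclusive coordinates. For insertions,
#'   `pos` is the base immediately left of the insertion point and
#'   `end == pos`.
#' @param ref_allele,alt_allele Character; `""` where not applicable.
#' @param variant_class One of `r paste(CALL_CLASSES, collapse = ", ")`.
#' @param allele_frequency Fraction of mutant-supporting reads, in `[0, 1]`.
#' @param source Caller tag.
#' @return A `data.frame` with the columns above.
#' @export
candidate_calls <- function(sample_id = character(), chrom = character(),
                            pos = integer(), end = integer(),
                            ref_allele = character(),
                            alt_allele = character(),
                            variant_class = character(),
                            allele_frequency = numeric(),
                            source = character()) {
  df <- data.frame(sample_id = as.character(sample_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos), end = as.integer(end),
                   ref_allele = as.character(ref_allele),
                   alt_allele = as.character(alt_allele),
                   variant_class = as.character(variant_class),
                   allele_frequency = as.numeric(allele_frequency),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_calls(df)
  df
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls), all(call_columns %in% names(calls)))
  if (nrow(calls) == 0L) return(invisible(calls))
  bad <- !calls$variant_class %in% CALL_CLASSES
  if (any(bad))
    stop("unknown variant class: ",
         paste(unique(calls$variant_class[bad]), collapse = ", "))
  af <- calls$allele_frequency
  if (any(is.na(af)) || any(af < 0) || any(af > 1))
    stop("allele_frequency must be in [0, 1] and non-missing")
  sub <- calls$variant_class == "substitution"
  if (any(nchar(calls$ref_allele[sub]) != nchar(calls$alt_allele[sub])))
    stop("substitutions must have equal-length ref and alt alleles")
  invisible(calls)
}

# Reference span actually occupied by the variant (insertions occupy the
# zero-length interval [pos + 1, pos] between two bases).
span_start <- function(calls) {
  ifelse(calls$variant_class == "insertion", calls$pos + 1L, calls$pos)
}
span_end <- function(calls) calls$end

#' Read candidate variant calls
#'
#' Reads one sample's candidate calls from either a VCF subset
#' (substitutions, insertions, deletions; allele frequency in an INFO or
#' per-sample FORMAT field) or the `sv_tsv` dialect emulating
#' structural-variant caller output (columns `sample_id, chrom, start, end,
#' type, inserted_seq, af` with `type` one of `DEL, INS, INV, TRA`).
#'
#' VCF anchor-base alleles are converted to the internal minimal
#' representation: shared flanking bases are trimmed, multi-base
#' substitutions are split into per-base substitution calls (the downstream
#' merge rule then treats adjacent substituted bases as one complex event),
#' and length-changing replacements are decomposed into a deletion plus an
#' insertion at the same junction.
#'
#' @param path Input file.
#' @param dialect `"vcf"` or `"sv_tsv"`.
#' @param af_field Name of the VCF INFO (or FORMAT, as fallback) field
#'   carrying the allele frequency. Default `"AF"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension for VCF input (sv_tsv carries its own `sample_id` column).
#' @param source Caller tag stored on every call; defaults to the dialect.
#' @return A candidate-call `data.frame` (see [candidate_calls()]).
#' @export
read_candidate_calls <- function(path, dialect = c("vcf", "sv_tsv"),
                                 af_field = "AF", sample_id = NULL,
                                 source = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "vcf") {
    read_calls_vcf(path, af_field = af_field, sample_id = sample_id,
                   source = source %||% "vcf")
  } else {
    read_calls_sv_tsv(path, source = source %||% "sv_tsv")
  }
}

read_calls_vcf <- function(path, af_field, sample_id, source) {
  if (is.null(sample_id))
    sample_id <- sub("\\.vcf$", "", basename(tools::file_path_sans_ext(
      basename(path), compression = TRUE)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) return(candidate_calls())
  af <- suppressWarnings(vcfR::extract.info(v, element = af_field,
                                            as.numeric = TRUE))
  if (all(is.na(af)) && ncol(v@gt) >= 2L) {
    gt <- suppressWarnings(vcfR::extract.gt(v, element = af_field,
                                            as.numeric = TRUE))
    if (!is.null(gt)) af <- as.numeric(gt[, 1L])
  }
  miss <- which(is.na(af))
  if (length(miss))
    stop("missing ", af_field, " for VCF record ",
         fix[miss[1L], "CHROM"], ":", fix[miss[1L], "POS"], " in ", path)
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alt <- fix[i, "ALT"]
    if (is.na(alt) || grepl("[<,\\[\\]]", alt))
      stop("unsupported ALT allele '", alt, "' at record ",
           fix[i, "CHROM"], ":", fix[i, "POS"], " in ", path)
    out[[i]] <- vcf_to_minimal(chrom = fix[i, "CHROM"],
                               pos = as.integer(fix[i, "POS"]),
                               ref = toupper(fix[i, "REF"]),
                               alt = toupper(alt),
                               sample_id = sample_id, af = af[i],
                               source = source)
  }
  do.call(rbind, out)
}

# Convert one VCF (POS, REF, ALT) record to >= 1 minimal internal calls.
vcf_to_minimal <- function(chrom, pos, ref, alt, sample_id, af, source) {
  if (!nzchar(ref) || !nzchar(alt))
    stop("empty REF or ALT at ", chrom, ":", pos)
  # trim shared suffix, then shared prefix (keeps the left anchor);
  # never trim both alleles to length 0
  while (nchar(ref) >= 1L && nchar(alt) >= 1L &&
         !(nchar(ref) == 1L && nchar(alt) == 1L) &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 0L && la == 0L)
    stop("REF equals ALT at ", chrom, ":", pos)
  mk <- function(p, e, r, a, cls)
    candidate_calls(sample_id, chrom, p, e, r, a, cls, af, source)
  if (lr == la) {
    # equal-length replacement: emit one call per differing base
    rb <- strsplit(ref, "")[[1L]]; ab <- strsplit(alt, "")[[1L]]
    idx <- which(rb != ab)
    return(do.call(rbind, lapply(idx, function(k)
      mk(pos + k - 1L, pos + k - 1L, rb[k], ab[k], "substitution"))))
  }
  if (la == 0L) return(mk(pos, pos + lr - 1L, ref, "", "deletion"))
  if (lr == 0L) return(mk(pos - 1L, pos - 1L, "", alt, "insertion"))
  # length-changing replacement: deletion plus insertion at the junction
  rbind(mk(pos, pos + lr - 1L, ref, "", "deletion"),
        mk(pos - 1L, pos - 1L, "", alt, "insertion"))
}

read_calls_sv_tsv <- function(path, source) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("sample_id", "chrom", "start", "end", "type", "inserted_seq",
            "af")
  if (!all(need %in% names(df)))
    stop("sv_tsv file ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (nrow(df) == 0L) return(candidate_calls())
  type <- toupper(df$type)
  bad <- !type %in% c("DEL", "INS", "INV", "TRA")
  if (any(bad))
    stop("unknown variant class in sv_tsv: ",
         paste(unique(df$type[bad]), collapse = ", "))
  cls <- c(DEL = "deletion", INS = "insertion", INV = "inversion",
           TRA = "translocation")[type]
  start <- as.integer(df$start); end <- as.integer(df$end)
  ins <- cls == "insertion"
  end[ins] <- start[ins]            # insertion after `start`
  candidate_calls(sample_id = df$sample_id, chrom = df$chrom,
                  pos = start, end = end,
                  ref_allele = "",
                  alt_allele = ifelse(ins, toupper(df$inserted_seq), ""),
                  variant_class = unname(cls),
                  allele_frequency = as.numeric(df$af),
                  source = source)
}

#' Write candidate calls to file
#'
#' `write_candidate_vcf()` writes substitution/insertion/deletion calls of
#' one sample as a minimal sites-only VCF 4.2 (anchor-base convention,
#' allele frequency in `INFO/AF`). `write_sv_tsv()` writes
#' inversion/translocation (and optionally long indel) calls in the sv_tsv
#' dialect.
#'
#' @param calls Candidate-call `data.frame` of one sample.
#' @param ref A [reference_genome()] (needed for VCF anchor bases).
#' @param path Output path.
#' @param meta Optional named character vector written as extra
#'   `##key=value` header lines (e.g. generator seed).
#' @return `path`, invisibly.
#' @export
write_candidate_vcf <- function(calls, ref, path, meta = NULL) {
  validate_calls(calls)
  small <- calls[calls$variant_class %in%
                   c("substitution", "deletion", "insertion"), ,
                 drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(meta)) paste0("##", names(meta), "=", meta),
           paste0("##contig=<ID=", names(ref$sequences), ",length=",
                  nchar(ref$sequences), ">"),
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(small)) {
    small <- small[order(small$chrom, small$pos), , drop = FALSE]
    rows <- vapply(seq_len(nrow(small)), function(i) {
      x <- small[i, ]
      rec <- minimal_to_vcf(x, ref)
      paste(x$chrom, rec$pos, ".", rec$ref, rec$alt, ".", "PASS",
            sprintf("AF=%.6g", x$allele_frequency), sep = "\t")
    }, "")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Internal minimal representation -> VCF anchor-base record.
minimal_to_vcf <- function(x, ref) {
  switch(x$variant_class,
    substitution = list(pos = x$pos, ref = x$ref_allele,
                        alt = x$alt_allele),
    deletion = {
      if (x$pos > 1L) {
        anchor <- ref_segment(ref, x$chrom, x$pos - 1L)
        list(pos = x$pos - 1L,
             ref = paste0(anchor, ref_segment(ref, x$chrom, x$pos, x$end)),
             alt = anchor)
      } else {  # deletion at chromosome start: right-anchor
        anchor <- ref_segment(ref, x$chrom, x$end + 1L)
        list(pos = 1L,
             ref = paste0(ref_segment(ref, x$chrom, x$pos, x$end), anchor),
             alt = anchor)
      }
    },
    insertion = {
      if (x$pos >= 1L) {
        anchor <- ref_segment(ref, x$chrom, x$pos)
        list(pos = x$pos, ref = anchor,
             alt = paste0(anchor, x$alt_allele))
      } else {  # insertion before base 1: right-anchor
        anchor <- ref_segment(ref, x$chrom, 1L)
        list(pos = 1L, ref = anchor,
             alt = paste0(x$alt_allele, anchor))
      }
    },
    stop("cannot encode variant class '", x$variant_class, "' in VCF"))
}

#' @rdname write_candidate_vcf
#' @export
write_sv_tsv <- function(calls, path) {
  validate_calls(calls)
  keep <- calls[calls$variant_class %in%
                  c("deletion", "insertion", "inversion", "translocation"), ,
                drop = FALSE]
  type <- c(deletion = "DEL", insertion = "INS", inversion = "INV",
            translocation = "TRA")[keep$variant_class]
  df <- data.frame(sample_id = keep$sample_id, chrom = keep$chrom,
                   start = keep$pos, end = keep$end, type = unname(type),
                   inserted_seq = keep$alt_allele,
                   af = keep$allele_frequency, stringsAsFactors = FALSE)
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  write_tsv(df, path)
}
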