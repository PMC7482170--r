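# Variant normalization, merging of nearby variants into mutation events,
# and the seven-way event classification:
#   SBS, Del1 (-1), Ins1 (+1), DelGE2 (Del >= 2 bp), InsGE2 (Ins >= 2 bp),
#   Complex (>= 2 variants separated by fewer than 10 intervening reference
#   bases, counted as one event), SV (inversions, translocations).

EVENT_CATEGORIES <- c("SBS", "Del1", "Ins1", "DelGE2", "InsGE2",
                      "Complex", "SV")

#' Normalize candidate calls against the reference
#'
#' Fills in deleted sequences for coordinate-only deletion calls (sv_tsv
#' dialect), verifies reference alleles, rejects variants overlapping `N`
#' bases, and left-aligns insertions and deletions to their leftmost
#' equivalent placement (the placement producing the same derived sequence
#' with the smallest start coordinate). Substitutions and SV breakpoints are
#' bounds/consistency-checked only.
#'
#' @param calls Candidate-call `data.frame`.
#' @param ref A [reference_genome()].
#' @return The calls with minimal, left-aligned coordinates and alleles.
#'   Row order is preserved.
#' @export
normalize_calls <- function(calls, ref) {
  validate_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  for (i in seq_len(nrow(calls))) {
    x <- calls[i, ]
    cls <- x$variant_class
    if (cls %in% c("inversion", "translocation")) {
      ref_segment(ref, x$chrom, x$pos, x$end)  # bounds check
      next
    }
    if (cls == "substitution") {
      seg <- ref_segment(ref, x$chrom, x$pos, x$end)
      if (seg != x$ref_allele)
        stop("reference mismatch at ", x$chrom, ":", x$pos,
             ": call has '", x$ref_allele, "', genome has '", seg, "'")
      if (grepl("N", seg, fixed = TRUE) ||
          grepl("N", x$alt_allele, fixed = TRUE))
        stop("variant overlapping N at ", x$chrom, ":", x$pos)
      next
    }
    if (cls == "deletion") {
      seg <- ref_segment(ref, x$chrom, x$pos, x$end)
      if (x$ref_allele == "") {
        calls$ref_allele[i] <- x$ref_allele <- seg
      } else if (seg != x$ref_allele) {
        stop("reference mismatch at ", x$chrom, ":", x$pos,
             ": deletion call has '", x$ref_allele, "', genome has '",
             seg, "'")
      }
      if (grepl("N", seg, fixed = TRUE))
        stop("variant overlapping N at ", x$chrom, ":", x$pos)
      sq <- ref$sequences[[x$chrom]]
      p <- x$pos; e <- x$end; del <- x$ref_allele
      while (p > 1L && substr(sq, p - 1L, p - 1L) ==
             substr(del, nchar(del), nchar(del))) {
        del <- paste0(substr(sq, p - 1L, p - 1L),
                      substr(del, 1L, nchar(del) - 1L))
        p <- p - 1L; e <- e - 1L
      }
      calls$pos[i] <- p; calls$end[i] <- e; calls$ref_allele[i] <- del
      next
    }
    if (cls == "insertion") {
      if (x$alt_allele == "" )
        stop("insertion without inserted sequence at ", x$chrom, ":",
             x$pos)
      if (grepl("N", x$alt_allele, fixed = TRUE))
        stop("variant overlapping N at ", x$chrom, ":", x$pos)
      if (x$pos > 0L) ref_segment(ref, x$chrom, x$pos)  # bounds check
      sq <- ref$sequences[[x$chrom]]
      p <- x$pos; ins <- x$alt_allele
      while (p >= 1L && substr(sq, p, p) ==
             substr(ins, nchar(ins), nchar(ins))) {
        ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                      substr(ins, 1L, nchar(ins) - 1L))
        p <- p - 1L
      }
      calls$pos[i] <- p; calls$end[i] <- p; calls$alt_allele[i] <- ins
      next
    }
  }
  calls
}

#' Merge nearby variants of one sample into mutation events
#'
#' Two small variants are linked when fewer than `window_bp` reference bases
#' lie between their spans (an insertion occupies the zero-length interval
#' between its two flanking bases); events are the connected components of
#' this linkage. Inversions and translocations are never merged with small
#' variants and always form singleton events.
#'
#' @param calls Filtered, normalized calls (any number of samples; merging
#'   is per sample and chromosome).
#' @param window_bp Merge window: variants separated by fewer than this many
#'   intervening reference bases belong to one event (default 10).
#' @return The calls, sorted by (sample, chromosome, span start), with an
#'   integer `event_id` column.
#' @export
merge_into_events <- function(calls, window_bp = 10L) {
  validate_calls(calls)
  calls <- calls[order(calls$sample_id, calls$chrom, span_start(calls),
                       span_end(calls)), , drop = FALSE]
  n <- nrow(calls)
  calls$event_id <- integer(n)
  if (n == 0L) return(calls)
  id <- 0L
  cur_end <- NULL; cur_key <- NULL; cur_sv <- FALSE
  st <- span_start(calls); en <- span_end(calls)
  is_sv <- calls$variant_class %in% c("inversion", "translocation")
  for (i in seq_len(n)) {
    key <- paste(calls$sample_id[i], calls$chrom[i], sep = "\r")
    new_event <- is.null(cur_key) || key != cur_key || is_sv[i] ||
      cur_sv || (st[i] - cur_end - 1L) >= window_bp
    if (new_event) {
      id <- id + 1L
      cur_end <- en[i]
    } else {
      cur_end <- max(cur_end, en[i])
    }
    calls$event_id[i] <- id
    cur_key <- key; cur_sv <- is_sv[i]
  }
  calls
}

#' Classify merged events
#'
#' @param calls Output of [merge_into_events()] (must carry `event_id`;
#'   a `zygosity` column, if present, is aggregated per event).
#' @return A `data.frame` with one row per event: `event_id`, `sample_id`,
#'   `chrom`, `start`, `end`, `category`, `length`, `n_members`,
#'   `zygosity`, `zygosity_mixed` and a semicolon-separated `members`
#'   description. `length` is the variant length for single-member events
#'   (1 for SBS), the span length for complex events and SVs.
#' @export
classify_events <- function(calls) {
  stopifnot("event_id" %in% names(calls))
  if (nrow(calls) > 0L && !"zygosity" %in% names(calls))
    calls$zygosity <- NA_character_
  if (nrow(calls) == 0L)
    return(data.frame(event_id = integer(), sample_id = character(),
                      chrom = character(), start = integer(),
                      end = integer(), category = character(),
                      length = integer(), n_members = integer(),
                      zygosity = character(), zygosity_mixed = logical(),
                      members = character(), stringsAsFactors = FALSE))
  ids <- unique(calls$event_id)
  rows <- lapply(ids, function(eid) {
    m <- calls[calls$event_id == eid, , drop = FALSE]
    m <- m[order(span_start(m), span_end(m)), , drop = FALSE]
    start <- min(m$pos); end <- max(m$end, m$pos)
    cat <- classify_members(m)
    len <- switch(cat,
                  SBS = 1L, Del1 = 1L, Ins1 = 1L,
                  DelGE2 = nchar(m$ref_allele[1L]),
                  InsGE2 = nchar(m$alt_allele[1L]),
                  Complex = end - start + 1L,
                  SV = end - start + 1L)
    zg <- m$zygosity[!is.na(m$zygosity)]
    if (length(zg) == 0L) {
      zyg <- NA_character_; mixed <- FALSE
    } else {
      tab <- sort(table(zg), decreasing = TRUE)
      mixed <- length(tab) > 1L
      zyg <- if (mixed && tab[1L] == tab[2L]) "heterozygous"
             else names(tab)[1L]
    }
    data.frame(event_id = eid, sample_id = m$sample_id[1L],
               chrom = m$chrom[1L], start = start, end = end,
               category = cat, length = len, n_members = nrow(m),
               zygosity = zyg, zygosity_mixed = mixed,
               members = paste(member_label(m), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

classify_members <- function(m) {
  if (nrow(m) == 0L) stop("event without members")
  if (any(m$variant_class %in% c("inversion", "translocation"))) {
    if (nrow(m) > 1L)
      stop("SV calls cannot share an event with other variants")
    return("SV")
  }
  if (nrow(m) >= 2L) return("Complex")
  switch(m$variant_class,
         substitution = if (nchar(m$ref_allele) == 1L) "SBS" else "Complex",
         deletion = if (nchar(m$ref_allele) == 1L) "Del1" else "DelGE2",
         insertion = if (nchar(m$alt_allele) == 1L) "Ins1" else "InsGE2",
         stop("unknown variant class: ", m$variant_class))
}

member_label <- function(m) {
  vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    switch(x$variant_class,
           substitution = paste0(x$pos, ":", x$ref_allele, ">",
                                 x$alt_allele),
           deletion = paste0(x$pos, ":del:", x$ref_allele),
           insertion = paste0(x$pos, ":ins:", x$alt_allele),
           inversion = paste0(x$pos, "-", x$end, ":inv"),
           translocation = paste0(x$pos, "-", x$end, ":tra"))
  }, "")
}

#' Build classified mutation events from filtered calls
#'
#' Convenience wrapper: [normalize_calls()] (optional), then
#' [merge_into_events()] and [classify_events()].
#'
#' @param calls Filtered calls (with `zygosity` if available).
#' @param ref A [reference_genome()], or `NULL` to skip re-normalization.
#' @param window_bp Merge window, see [merge_into_events()].
#' @return A list with `events` (see [classify_events()]) and `members`
#'   (the calls with `event_id`).
#' @export
build_events <- function(calls, ref = NULL, window_bp = 10L) {
  if (!is.null(ref)) calls <- normalize_calls(calls, ref)
  members <- merge_into_events(calls, window_bp = window_bp)
  list(events = classify_events(members), members = members)
}

#' Apply variants to a reference segment
#'
#' Derives the mutant sequence of `[seg_start, seg_end]` on `chrom` after
#' applying the given member variants (which must lie within the segment
#' and not overlap).
#'
#' @param ref A [reference_genome()].
#' @param chrom Chromosome name.
#' @param seg_start,seg_end 1-based inclusive segment bounds.
#' @param members Candidate-call rows (substitution/deletion/insertion).
#' @return The derived (mutant) sequence as a single string.
#' @export
apply_variants <- function(ref, chrom, seg_start, seg_end, members) {
  m <- members[order(span_start(members), span_end(members)), ,
               drop = FALSE]
  out <- character(0)
  cursor <- seg_start
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (x$variant_class == "insertion") {
      if (x$pos >= cursor)
        out <- c(out, ref_segment(ref, chrom, cursor, x$pos))
      out <- c(out, x$alt_allele)
      cursor <- x$pos + 1L
    } else {
      if (x$pos > cursor)
        out <- c(out, ref_segment(ref, chrom, cursor, x$pos - 1L))
      if (x$variant_class == "substitution") out <- c(out, x$alt_allele)
      cursor <- x$end + 1L
    }
  }
  if (cursor <= seg_end)
    out <- c(out, ref_segment(ref, chrom, cursor, seg_end))
  paste(out, collapse = "")
}

#' Describe the composition of a complex event
#'
#' Aligns the mutant segment of a complex event to the reference over the
#' event span and reports change blocks. Runs of two or more
#' reference-matching bases delimit blocks; a single matching base between
#' two changes is absorbed into one block.
#'
#' @param members Member calls of one complex event (normalized).
#' @param ref A [reference_genome()].
#' @param spacer_min_match Minimum run of reference-matching bases that
#'   separates two blocks (default 2).
#' @return A `data.frame` of change blocks in positional order: `kind`
#'   (`substitution_run`, `deletion`, `insertion` or `mixed`), `start`,
#'   `end` (zero-length span for pure insertions: `end == start - 1`),
#'   `ref_seq`, `alt_seq`.
#' @export
describe_complex <- function(members, ref, spacer_min_match = 2L) {
  stopifnot(nrow(members) >= 1L)
  if (any(members$variant_class %in% c("inversion", "translocation")))
    stop("complex-event composition is undefined for SV members")
  m <- members[order(span_start(members), span_end(members)), ,
               drop = FALSE]
  chrom <- m$chrom[1L]
  st <- span_start(m); en <- span_end(m)
  # group members separated by fewer than spacer_min_match matching bases
  grp <- integer(nrow(m)); g <- 1L; grp[1L] <- 1L
  if (nrow(m) > 1L) {
    run_end <- en[1L]
    for (i in 2L:nrow(m)) {
      gap <- st[i] - run_end - 1L
      if (gap >= spacer_min_match) g <- g + 1L
      grp[i] <- g
      run_end <- max(run_end, en[i])
    }
  }
  blocks <- lapply(split(seq_len(nrow(m)), grp), function(idx) {
    mm <- m[idx, , drop = FALSE]
    bs <- min(span_start(mm)); be <- max(span_end(mm))
    kinds <- unique(mm$variant_class)
    kind <- if (all(kinds == "substitution")) "substitution_run"
            else if (nrow(mm) == 1L) kinds
            else "mixed"
    data.frame(kind = kind, start = bs, end = be,
               ref_seq = ref_segment(ref, chrom, bs, be),
               alt_seq = apply_variants(ref, chrom, bs, be, mm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
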