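# Normalization, merging, classification and complex-event composition.

test_that("indels are left-aligned to the placement oracle", {
  ref <- reference_genome(c(chr1 = "GGCAAATGGG"))
  # reported deletion of the 3rd A in the CAAAT run
  del <- call_row(pos = 6, end = 6, ref_allele = "A",
                  variant_class = "deletion")
  norm <- normalize_calls(del, ref)
  ora <- ora_leftmost_del(ref$sequences[["chr1"]], 6, 6)
  expect_equal(norm$pos, ora$start)
  expect_equal(norm$ref_allele, ora$deleted)
  expect_equal(norm$pos, 4L)  # first A of the run

  # substitution is unchanged
  sub <- call_row(pos = 3, ref_allele = "C", alt_allele = "T",
                  variant_class = "substitution")
  expect_equal(normalize_calls(sub, ref), sub)

  # insertion "AT" in an AT repeat left-aligns to the run start
  ref2 <- reference_genome(c(chr1 = "GATATC"))
  ins <- call_row(pos = 3, end = 3, alt_allele = "AT",
                  variant_class = "insertion")
  norm2 <- normalize_calls(ins, ref2)
  ora2 <- ora_leftmost_ins(ref2$sequences[["chr1"]], 3, "AT")
  expect_equal(norm2$pos, ora2$pos)
  expect_equal(norm2$alt_allele, ora2$inserted)
})

test_that("left alignment matches the placement oracle on random indels", {
  set.seed(5)
  # low-complexity alphabet to provoke repeats and shifts
  sq <- paste(sample(c("A", "T", "AT", "TA", "G"), 600,
                     replace = TRUE), collapse = "")
  ref <- reference_genome(c(chr1 = sq))
  L <- nchar(sq)
  for (i in 1:120) {
    if (runif(1) < 0.5) {
      len <- sample(1:6, 1)
      pos <- sample(10:(L - len - 10), 1)
      call <- call_row(pos = pos, end = pos + len - 1,
                       ref_allele = substr(sq, pos, pos + len - 1),
                       variant_class = "deletion")
      norm <- normalize_calls(call, ref)
      ora <- ora_leftmost_del(sq, pos, pos + len - 1)
      expect_equal(norm$pos, ora$start)
      expect_equal(norm$ref_allele, ora$deleted)
    } else {
      ins <- paste(sample(c("A", "T", "G"), sample(1:5, 1),
                          replace = TRUE), collapse = "")
      pos <- sample(10:(L - 10), 1)
      call <- call_row(pos = pos, end = pos, alt_allele = ins,
                       variant_class = "insertion")
      norm <- normalize_calls(call, ref)
      ora <- ora_leftmost_ins(sq, pos, ins)
      expect_equal(norm$pos, ora$pos)
      expect_equal(norm$alt_allele, ora$inserted)
    }
  }
})

test_that("normalization rejects reference mismatches", {
  ref <- reference_genome(c(chr1 = "ACGTACGT"))
  bad <- call_row(pos = 2, ref_allele = "A", alt_allele = "T",
                  variant_class = "substitution")
  expect_error(normalize_calls(bad, ref), "mismatch")
})

test_that("merge window: fewer than 10 intervening bases links variants", {
  sbs <- function(pos, sample = "s1")
    call_row(sample_id = sample, pos = pos, ref_allele = "C",
             alt_allele = "T", variant_class = "substitution")
  # 4 intervening bases -> one event
  m <- merge_into_events(rbind(sbs(100), sbs(105)))
  expect_equal(length(unique(m$event_id)), 1L)
  # exactly 10 intervening bases -> two events
  m <- merge_into_events(rbind(sbs(100), sbs(111)))
  expect_equal(length(unique(m$event_id)), 2L)
  # 9 intervening bases -> still one event
  m <- merge_into_events(rbind(sbs(100), sbs(110)))
  expect_equal(length(unique(m$event_id)), 1L)
  # transitive closure across three variants
  m <- merge_into_events(rbind(sbs(100), sbs(108), sbs(116)))
  expect_equal(length(unique(m$event_id)), 1L)
  expect_equal(sum(m$event_id == m$event_id[1]), 3L)
  # different samples never merge
  m <- merge_into_events(rbind(sbs(100, "a"), sbs(105, "b")))
  expect_equal(length(unique(m$event_id)), 2L)
})

test_that("merging matches the brute-force component oracle and is order-independent", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    pos <- sort(sample(1:300, n))
    kind <- sample(c("substitution", "deletion", "insertion"), n,
                   replace = TRUE)
    len <- ifelse(kind == "deletion", sample(1:8, n, replace = TRUE), 1L)
    calls <- candidate_calls(
      sample_id = "s1", chrom = "chr1", pos = pos,
      end = ifelse(kind == "insertion", pos, pos + len - 1L),
      ref_allele = ifelse(kind == "deletion",
                          strrep("A", len),
                          ifelse(kind == "substitution", "A", "")),
      alt_allele = ifelse(kind == "insertion", "GG",
                          ifelse(kind == "substitution", "G", "")),
      variant_class = kind, allele_frequency = 0.5, source = "t")
    merged <- merge_into_events(calls)
    st <- ifelse(merged$variant_class == "insertion", merged$pos + 1L,
                 merged$pos)
    comp <- ora_merge_components(st, merged$end, 10)
    # same partition (labels may differ)
    expect_equal(length(unique(merged$event_id)), length(unique(comp)))
    expect_true(all(tapply(comp, merged$event_id,
                           function(x) length(unique(x))) == 1L))
    # order independence
    shuf <- merge_into_events(calls[sample.int(nrow(calls)), ])
    expect_equal(shuf[order(shuf$pos), "event_id"] |> factor() |>
                   as.integer(),
                 merged[order(merged$pos), "event_id"] |> factor() |>
                   as.integer())
  }
})

test_that("events are classified into the seven categories", {
  cls <- function(calls) {
    calls$zygosity <- "heterozygous"
    classify_events(merge_into_events(calls))$category
  }
  expect_equal(cls(call_row(pos = 10, ref_allele = "A", alt_allele = "G",
                            variant_class = "substitution")), "SBS")
  expect_equal(cls(call_row(pos = 10, end = 10, ref_allele = "A",
                            variant_class = "deletion")), "Del1")
  expect_equal(cls(call_row(pos = 10, end = 24,
                            ref_allele = strrep("A", 15),
                            variant_class = "deletion")), "DelGE2")
  expect_equal(cls(call_row(pos = 10, alt_allele = "T",
                            variant_class = "insertion")), "Ins1")
  expect_equal(cls(call_row(pos = 10, alt_allele = "TTT",
                            variant_class = "insertion")), "InsGE2")
  expect_equal(cls(call_row(pos = 10, end = 400,
                            variant_class = "inversion")), "SV")
  # SBS + 3-bp deletion 5 bp apart -> one complex event
  expect_equal(cls(rbind(
    call_row(pos = 10, ref_allele = "A", alt_allele = "G",
             variant_class = "substitution"),
    call_row(pos = 16, end = 18, ref_allele = "AAA",
             variant_class = "deletion"))), "Complex")
  # two SBSs within the window are complex, not two SBS events
  expect_equal(cls(rbind(
    call_row(pos = 10, ref_allele = "A", alt_allele = "G",
             variant_class = "substitution"),
    call_row(pos = 13, ref_allele = "C", alt_allele = "T",
             variant_class = "substitution"))), "Complex")
  # SV within 10 bp of an SBS stays separate
  got <- cls(rbind(
    call_row(pos = 10, ref_allele = "A", alt_allele = "G",
             variant_class = "substitution"),
    call_row(pos = 13, end = 300, variant_class = "inversion")))
  expect_setequal(got, c("SBS", "SV"))
})

test_that("mixed-zygosity clusters keep majority zygosity and are flagged", {
  calls <- rbind(
    call_row(pos = 10, ref_allele = "A", alt_allele = "G",
             variant_class = "substitution"),
    call_row(pos = 13, ref_allele = "C", alt_allele = "T",
             variant_class = "substitution"),
    call_row(pos = 16, ref_allele = "C", alt_allele = "T",
             variant_class = "substitution"))
  calls$zygosity <- c("homozygous", "heterozygous", "heterozygous")
  ev <- classify_events(merge_into_events(calls))
  expect_equal(ev$zygosity, "heterozygous")
  expect_true(ev$zygosity_mixed)
})

test_that("complex composition blocks follow the two-matching-base spacer rule", {
  sq <- "AACCGGTTAACCGGTTAACC"
  ref <- reference_genome(c(chr1 = sq))
  sbs <- function(pos) {
    rb <- substr(sq, pos, pos)
    call_row(pos = pos, ref_allele = rb,
             alt_allele = setdiff(c("A", "C", "G", "T"), rb)[1],
             variant_class = "substitution")
  }
  # two SBSs separated by 2 matching bases -> two substitution blocks
  b <- describe_complex(rbind(sbs(5), sbs(8)), ref)
  expect_equal(nrow(b), 2L)
  expect_equal(b$kind, rep("substitution_run", 2))
  # two SBSs separated by 1 matching base -> one 3-bp run block
  b <- describe_complex(rbind(sbs(5), sbs(7)), ref)
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 5L)
  expect_equal(b$end, 7L)
  expect_equal(nchar(b$ref_seq), 3L)
  # single member -> one block identical to the variant
  b <- describe_complex(sbs(5), ref)
  expect_equal(nrow(b), 1L)
  expect_equal(b$ref_seq, substr(sq, 5, 5))
  # mixed block kinds
  b <- describe_complex(rbind(
    sbs(3),
    call_row(pos = 8, end = 9, ref_allele = substr(sq, 8, 9),
             variant_class = "deletion")), ref)
  expect_equal(b$kind, c("substitution_run", "deletion"))
})

test_that("block composition round-trips against direct member application", {
  set.seed(31)
  ref <- ora_random_ref(500)
  sq <- ref$sequences[["chr1"]]
  for (rep in 1:25) {
    base <- sample(50:400, 1)
    n <- sample(2:3, 1)
    cursor <- base
    members <- NULL
    for (k in seq_len(n)) {
      kind <- sample(c("substitution", "deletion", "insertion"), 1)
      m <- switch(kind,
        substitution = {
          rb <- substr(sq, cursor, cursor)
          out <- call_row(pos = cursor, ref_allele = rb,
                          alt_allele = setdiff(c("A","C","G","T"), rb)[1],
                          variant_class = "substitution")
          cursor <- cursor + 1; out
        },
        deletion = {
          len <- sample(2:4, 1)
          out <- call_row(pos = cursor, end = cursor + len - 1,
                          ref_allele = substr(sq, cursor,
                                              cursor + len - 1),
                          variant_class = "deletion")
          cursor <- cursor + len; out
        },
        insertion = {
          out <- call_row(pos = cursor, end = cursor,
                          alt_allele = paste(
                            sample(c("A","C","G","T"), 3, TRUE),
                            collapse = ""),
                          variant_class = "insertion")
          cursor <- cursor + 1; out
        })
      members <- rbind(members, m)
      cursor <- cursor + sample(1:8, 1)
    }
    span <- c(min(members$pos), max(members$end))
    blocks <- describe_complex(members, ref)
    # reconstruct the mutant span from blocks and compare to direct
    mutant <- ""
    cursor <- span[1]
    for (i in seq_len(nrow(blocks))) {
      if (blocks$start[i] > cursor)
        mutant <- paste0(mutant,
                         substr(sq, cursor, blocks$start[i] - 1))
      mutant <- paste0(mutant, blocks$alt_seq[i])
      cursor <- max(blocks$end[i], blocks$start[i] - 1) + 1
    }
    if (cursor <= span[2])
      mutant <- paste0(mutant, substr(sq, cursor, span[2]))
    expect_equal(mutant,
                 apply_variants(ref, "chr1", span[1], span[2], members))
  }
})
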