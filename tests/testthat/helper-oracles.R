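# Independent brute-force oracles used to verify the package's algorithms.

# Derived sequence after deleting [s, e] (1-based inclusive) from a string.
ora_delete <- function(sq, s, e) {
  paste0(substr(sq, 1, s - 1), substr(sq, e + 1, nchar(sq)))
}

# Derived sequence after inserting `ins` after position p (p = 0 allowed).
ora_insert <- function(sq, p, ins) {
  paste0(substr(sq, 1, p), ins, substr(sq, p + 1, nchar(sq)))
}

# Brute-force microhomology: number of distinct equal-length placements of
# the deletion yielding the identical derived sequence, minus one.
ora_mh <- function(sq, s, e) {
  d <- e - s + 1
  target <- ora_delete(sq, s, e)
  n <- 0L
  for (s2 in 1:(nchar(sq) - d + 1)) {
    if (ora_delete(sq, s2, s2 + d - 1) == target) n <- n + 1L
  }
  n - 1L
}

# Brute-force leftmost placement of a deletion: smallest start among all
# placements with the same derived sequence.
ora_leftmost_del <- function(sq, s, e) {
  d <- e - s + 1
  target <- ora_delete(sq, s, e)
  for (s2 in 1:(nchar(sq) - d + 1)) {
    if (ora_delete(sq, s2, s2 + d - 1) == target)
      return(list(start = s2,
                  deleted = substr(sq, s2, s2 + d - 1)))
  }
  stop("unreachable")
}

# Brute-force leftmost placement of an insertion (after position p).
ora_leftmost_ins <- function(sq, p, ins) {
  target <- ora_insert(sq, p, ins)
  k <- nchar(ins)
  for (p2 in 0:nchar(sq)) {
    cand <- substr(target, p2 + 1, p2 + k)
    if (ora_insert(sq, p2, cand) == target)
      return(list(pos = p2, inserted = cand))
  }
  stop("unreachable")
}

# Brute-force connected components of the "< window intervening reference
# bases" linkage over variant spans (transitive closure by flood fill).
ora_merge_components <- function(starts, ends, window) {
  n <- length(starts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    gap <- max(starts[i], starts[j]) - min(ends[i], ends[j]) - 1
    adj[i, j] <- gap < window
  }
  comp <- rep(NA_integer_, n); cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Random test reference on {A,C,G,T}.
ora_random_ref <- function(len, seed = NULL, name = "chr1") {
  if (!is.null(seed)) set.seed(seed)
  reference_genome(setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), name))
}

# One-row candidate-call constructors for terse tests.
call_row <- function(sample_id = "s1", chrom = "chr1", pos, end = pos,
                     ref_allele = "", alt_allele = "",
                     variant_class, af = 0.5, source = "test") {
  candidate_calls(sample_id, chrom, pos, end, ref_allele, alt_allele,
                  variant_class, af, source)
}
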