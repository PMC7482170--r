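#' Reference genome container
#'
#' A light container for named chromosome sequences. Coordinates throughout
#' the package are 1-based and inclusive. Sequences are folded to upper case
#' and restricted to the alphabet `A, C, G, T, N`.
#'
#' @param sequences Named character vector of chromosome sequences.
#' @return An object of class `reference_genome`: a list with elements
#'   `sequences` (named uppercase character vector) and `total_length`
#'   (sum of sequence lengths in bp).
#' @export
#' @examples
#' ref <- reference_genome(c(chr1 = "acgtACGT"))
#' ref$total_length
reference_genome <- function(sequences) {
  if (!is.character(sequences) || length(sequences) == 0L)
    stop("`sequences` must be a non-empty named character vector")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named by chromosome")
  if (anyDuplicated(names(sequences)))
    stop("duplicated chromosome names")
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("sequence(s) ", paste(names(sequences)[bad], collapse = ", "),
         " contain characters outside {A,C,G,T,N}")
  structure(list(sequences = sequences,
                 total_length = sum(nchar(sequences))),
            class = "reference_genome")
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("reference_genome:", length(x$sequences), "sequence(s),",
      format(x$total_length, big.mark = ","), "bp total\n")
  for (nm in names(x$sequences))
    cat(" ", nm, ":", format(nchar(x$sequences[[nm]]), big.mark = ","),
        "bp\n")
  invisible(x)
}

# 1-based inclusive segment lookup with bounds checking.
ref_segment <- function(ref, chrom, start, end = start) {
  seqs <- ref$sequences
  if (!chrom %in% names(seqs))
    stop("chromosome '", chrom, "' not in reference")
  len <- nchar(seqs[[chrom]])
  if (start < 1L || end > len || end < start - 1L)
    stop("segment [", start, ", ", end, "] out of bounds for ", chrom,
         " (length ", len, ")")
  if (end < start) return("")   # zero-length span (insertion point)
  substr(seqs[[chrom]], start, end)
}

chrom_length <- function(ref, chrom) {
  if (!chrom %in% names(ref$sequences))
    stop("chromosome '", chrom, "' not in reference")
  nchar(ref$sequences[[chrom]])
}

#' Read a reference genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A [reference_genome()] object. Lower-case bases are folded to
#'   upper case; record names are the first whitespace-delimited word of the
#'   header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    stop("FASTA format error in ", path, ": file is empty (line 1)")
  if (!startsWith(first, ">"))
    stop("FASTA format error in ", path,
         ": line 1 does not start with '>'")
  # Biostrings downgrades invalid letters to a warning; treat as an error
  set <- withCallingHandlers(
    tryCatch(Biostrings::readDNAStringSet(path),
             error = function(e)
               stop("FASTA format error in ", path, ": ",
                    conditionMessage(e), call. = FALSE)),
    warning = function(w)
      stop("FASTA format error in ", path, ": ", conditionMessage(w),
           call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA format error in ", path, ": no records")
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  reference_genome(seqs)
}

#' Write a reference genome to FASTA
#'
#' @param ref A [reference_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ref, path) {
  set <- Biostrings::DNAStringSet(ref$sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
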