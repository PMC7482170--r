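# Event-table TSV output: one row per classified mutation event, with the
# apparent microhomology filled in for simple Del >= 2 bp events.

event_table_columns <- c("sample_id", "chrom", "start", "end", "category",
                         "zygosity", "length", "n_members", "members",
                         "mh_length")

#' Write the classified event table
#'
#' One tab-separated row per event, ordered deterministically by
#' (sample, chromosome, start). The `mh_length` column is populated for
#' simple Del >= 2 bp events when a reference is supplied and left empty
#' otherwise.
#'
#' @param events Classified events (see [classify_events()]).
#' @param path Output path.
#' @param ref Optional [reference_genome()] used to score deletion-junction
#'   microhomology.
#' @return The written `data.frame`, invisibly.
#' @export
write_event_table <- function(events, path, ref = NULL) {
  df <- events[order(events$sample_id, events$chrom, events$start), ,
               drop = FALSE]
  df$mh_length <- rep(NA_integer_, nrow(df))
  if (!is.null(ref) && nrow(df)) {
    idx <- which(df$category == "DelGE2")
    for (i in idx)
      df$mh_length[i] <- compute_microhomology(ref, df$chrom[i],
                                               df$start[i], df$end[i])
  }
  df <- df[, event_table_columns, drop = FALSE]
  rownames(df) <- NULL
  write_tsv(df, path)
  invisible(df)
}

#' Read a written event table
#'
#' @param path Path written by [write_event_table()].
#' @return The event `data.frame`.
#' @export
read_event_table <- function(path) {
  df <- read_tsv(path, colClasses = c(
    sample_id = "character", chrom = "character", start = "integer",
    end = "integer", category = "character", zygosity = "character",
    length = "integer", n_members = "integer", members = "character",
    mh_length = "integer"))
  if (!all(event_table_columns %in% names(df)))
    stop("not an event table: ", path)
  df
}
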