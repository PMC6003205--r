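#' Construct a set of sequence records
#'
#' The basic container passed between pipeline stages: a data frame with one
#' row per sequence, columns `id` and `seq`, and (for reads) a `qual` list
#' column of per-base Phred scores.
#'
#' @param id Character vector of non-empty, unique identifiers.
#' @param seq Character vector of sequences over `{A,C,G,T,N}`; stored
#'   uppercased.
#' @param qual Optional list of integer vectors of per-base Phred scores,
#'   one per sequence and of matching length.
#' @return A data frame of class `seq_records`.
#' @export
seq_records <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq))
    stop("`id` and `seq` must have the same length")
  if (any(!nzchar(id)) || anyNA(id))
    stop("sequence ids must be non-empty")
  df <- data.frame(id = id, seq = seq, stringsAsFactors = FALSE)
  if (!is.null(qual)) {
    qual <- lapply(qual, as.integer)
    if (length(qual) != length(seq))
      stop("`qual` must have one entry per sequence")
    bad <- which(vapply(qual, length, 1L) != nchar(seq))
    if (length(bad))
      stop("quality length differs from sequence length for record ", bad[1])
    if (any(unlist(qual, use.names = FALSE) < 0L))
      stop("Phred scores must be >= 0")
    df$qual <- I(qual)
  }
  class(df) <- c("seq_records", class(df))
  df
}

#' @export
print.seq_records <- function(x, ...) {
  cat(sprintf("<seq_records> %d sequence(s), total %s bp%s\n",
              nrow(x), format(sum(nchar(x$seq)), big.mark = ","),
              if (!is.null(x$qual)) ", with qualities" else ""))
  invisible(x)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file. An empty file yields an empty record set.
#' @return A [seq_records] data frame; sequences are uppercased and input
#'   order is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(seq_records(character(), character()))
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop("FASTA parse error in ", path, ": ",
                                         conditionMessage(e)))
  if (any(!nzchar(names(x))))
    stop("FASTA parse error in ", path, ": empty header")
  if (any(Biostrings::width(x) == 0))
    stop("FASTA parse error in ", path, ": empty sequence under header '",
         names(x)[Biostrings::width(x) == 0][1], "'")
  # keep only the first whitespace-delimited token of each header
  seq_records(sub("\\s.*$", "", names(x)), as.character(x))
}

#' Write sequence records as FASTA
#'
#' @param records A [seq_records] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return A [seq_records] data frame carrying a `qual` list column.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) return(seq_records(character(), character(), list()))
  # Biostrings warns that FASTQ metadata columns are dropped; nothing of
  # ours lives there
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- as(Biostrings::quality(x), "IntegerList")
  seq_records(sub("\\s.*$", "", names(x)), as.character(x), as.list(qual))
}

#' Write sequence records as FASTQ (Phred+33)
#'
#' @param records A [seq_records] data frame with a `qual` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  if (is.null(records$qual)) stop("records carry no qualities")
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$id
  qstr <- vapply(records$qual,
                 function(v) rawToChar(as.raw(pmin(as.integer(v), 93L) + 33L)),
                 character(1))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qstr))
  invisible(path)
}

#' Quality-filter sequencing reads
#'
#' Removes reads whose fraction of bases below the Phred threshold exceeds
#' `max_low_fraction`, and reads containing any ambiguous base `N`. The
#' default rule drops reads with more than 10\% of bases under Q30.
#'
#' @param reads A [seq_records] data frame with qualities.
#' @param q_threshold Phred score below which a base counts as low quality.
#' @param max_low_fraction Maximum tolerated fraction of low-quality bases.
#' @return The surviving reads, original order preserved.
#' @export
filter_reads <- function(reads, q_threshold = 30, max_low_fraction = 0.10) {
  if (is.null(reads$qual)) stop("reads carry no qualities")
  if (nrow(reads) == 0) return(reads)
  low_frac <- vapply(reads$qual,
                     function(v) mean(v < q_threshold), numeric(1))
  has_n <- grepl("N", reads$seq, fixed = TRUE)
  reads[low_frac <= max_low_fraction & !has_n, , drop = FALSE]
}

#' Assembly summary statistics
#'
#' N50 is the largest length L such that sequences of length >= L together
#' cover at least half of the total assembly length (descending-length
#' cumulative sum). GC fraction is computed over non-N bases.
#'
#' @param records A [seq_records] data frame with at least one sequence.
#' @return An object of class `assembly_stats` with fields `n_sequences`,
#'   `total_length`, `n50`, `max_length`, `mean_length`, `gc_fraction`.
#' @export
assembly_stats <- function(records) {
  if (nrow(records) == 0) stop("assembly_stats() needs at least one sequence")
  len <- nchar(records$seq)
  total <- sum(len)
  sl <- sort(len, decreasing = TRUE)
  n50 <- sl[which(cumsum(sl) >= total / 2)[1]]
  comp <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(records$seq))[, c("A", "C", "G", "T"),
                                           drop = FALSE])
  structure(list(n_sequences = nrow(records),
                 total_length = total,
                 n50 = n50,
                 max_length = max(len),
                 mean_length = total / nrow(records),
                 gc_fraction = unname((comp["C"] + comp["G"]) / sum(comp))),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly summary\n")
  cat(sprintf("  sequences    %s\n", format(x$n_sequences, big.mark = ",")))
  cat(sprintf("  total length %s bp (%s)\n",
              format(x$total_length, big.mark = ","),
              format_genome_size(x$total_length)))
  cat(sprintf("  N50          %s bp\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  max length   %s bp\n", format(x$max_length, big.mark = ",")))
  cat(sprintf("  mean length  %.1f bp\n", x$mean_length))
  cat(sprintf("  GC           %.1f%%\n", 100 * x$gc_fraction))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(n_sequences = x$n_sequences, total_length = x$total_length,
             n50 = x$n50, max_length = x$max_length,
             mean_length = x$mean_length, gc_fraction = x$gc_fraction)
}

#' Write assembly statistics as TSV
#'
#' @param stats An `assembly_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(stats, path) {
  utils::write.table(as.data.frame(stats), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# reverse complement of plain character sequences
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Format a base-pair count in decimal units
#'
#' Reports Gb/Mb/kb as powers of ten with one decimal place.
#'
#' @param bp Number of base pairs.
#' @return A character scalar such as `"2.9 Gb"`.
#' @export
format_genome_size <- function(bp) {
  if (bp >= 1e9) sprintf("%.1f Gb", bp / 1e9)
  else if (bp >= 1e6) sprintf("%.1f Mb", bp / 1e6)
  else if (bp >= 1e3) sprintf("%.1f kb", bp / 1e3)
  else sprintf("%d bp", round(bp))
}
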