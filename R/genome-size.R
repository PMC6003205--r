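#' Canonical k-mer multiplicity histogram
#'
#' Counts k-mers in canonical form (the lexicographically smaller of a k-mer
#' and its reverse complement) across a set of reads and tabulates how many
#' distinct canonical k-mers occur at each multiplicity. Windows containing
#' `N` are skipped.
#'
#' @param reads A [seq_records] data frame.
#' @param k K-mer size >= 3 (default 17; odd sizes avoid reverse-complement
#'   palindromes).
#' @return An object of class `kmer_histogram`: list with `k`,
#'   `multiplicity` (sorted integer vector), `count` (distinct canonical
#'   k-mers at each multiplicity) and `total_occurrences`.
#' @export
kmer_histogram <- function(reads, k = 17) {
  k <- as.integer(k)
  if (k < 3) stop("k must be >= 3")
  pieces <- unlist(strsplit(reads$seq, "N+"), use.names = FALSE)
  pieces <- pieces[nchar(pieces) >= k]
  if (length(pieces) == 0) {
    warning("no read window of length >= k; empty histogram")
    return(structure(list(k = k, multiplicity = integer(),
                          count = integer(), total_occurrences = 0),
                     class = "kmer_histogram"))
  }
  kmers <- unlist(lapply(pieces, function(p) {
    n <- nchar(p)
    substring(p, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  rc <- revcomp(kmers)
  # locale-proof lexicographic comparison: map bases to digits
  a <- chartr("ACGT", "0123", kmers)
  b <- chartr("ACGT", "0123", rc)
  canon <- ifelse(a <= b, kmers, rc)
  mult <- table(canon)
  hist <- table(as.integer(mult))
  structure(list(k = k,
                 multiplicity = as.integer(names(hist)),
                 count = as.integer(hist),
                 total_occurrences = length(kmers)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("<kmer_histogram> k=%d, %s k-mer occurrences, %s distinct\n",
              x$k, format(x$total_occurrences, big.mark = ","),
              format(sum(x$count), big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.kmer_histogram <- function(x, ...) {
  data.frame(multiplicity = x$multiplicity, count = x$count)
}

#' Write a k-mer histogram as two-column TSV
#'
#' @param hist A `kmer_histogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_histogram <- function(hist, path) {
  utils::write.table(as.data.frame(hist), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rebuild a `kmer_histogram` from multiplicity/count pairs
#'
#' @param multiplicity Integer vector of multiplicities (>= 1).
#' @param count Number of distinct canonical k-mers at each multiplicity.
#' @param k The k-mer size the histogram was built with.
#' @return A `kmer_histogram`.
#' @export
kmer_histogram_from_counts <- function(multiplicity, count, k = 17) {
  o <- order(multiplicity)
  multiplicity <- as.integer(multiplicity[o])
  count <- as.integer(count[o])
  if (any(multiplicity < 1)) stop("multiplicities must be >= 1")
  structure(list(k = as.integer(k), multiplicity = multiplicity,
                 count = count,
                 total_occurrences = sum(as.numeric(multiplicity) * count)),
            class = "kmer_histogram")
}

#' Estimate genome size from a k-mer histogram
#'
#' The homozygous-peak method: genome size = (total k-mer occurrences above
#' the error cutoff) / peak depth, where the peak depth is the multiplicity
#' with the most distinct k-mers above the cutoff. By default the cutoff is
#' placed at the first local minimum of the histogram, separating the
#' low-multiplicity sequencing-error noise from the coverage peak.
#'
#' @param hist A `kmer_histogram`.
#' @param error_cutoff Multiplicity at or below which k-mers are treated as
#'   sequencing-error noise; `NULL` (default) picks the first local minimum.
#' @return A list of class `genome_size_estimate` with `peak_depth`,
#'   `size_bp` and `error_cutoff`.
#' @export
estimate_genome_size <- function(hist, error_cutoff = NULL) {
  if (length(hist$multiplicity) == 0) stop("empty k-mer histogram")
  m_max <- max(hist$multiplicity)
  dense <- numeric(m_max)
  dense[hist$multiplicity] <- hist$count
  if (is.null(error_cutoff)) {
    error_cutoff <- 0L
    if (m_max >= 2) {
      rising <- which(dense[-m_max] < dense[-1])
      if (length(rising)) error_cutoff <- rising[1]
    }
  }
  error_cutoff <- as.integer(error_cutoff)
  sel <- hist$multiplicity > error_cutoff
  if (!any(sel)) stop("no multiplicity above the error cutoff")
  m <- hist$multiplicity[sel]
  cnt <- hist$count[sel]
  peak <- m[which.max(cnt)]
  size <- round(sum(as.numeric(m) * cnt) / peak)
  structure(list(peak_depth = peak, size_bp = size,
                 error_cutoff = error_cutoff),
            class = "genome_size_estimate")
}

#' @export
print.genome_size_estimate <- function(x, ...) {
  cat(sprintf(
    "Genome size estimate: %s (%s bp); peak depth %d, error cutoff %d\n",
    format_genome_size(x$size_bp), format(x$size_bp, big.mark = ","),
    x$peak_depth, x$error_cutoff))
  invisible(x)
}

#' Convert a 2C DNA content to base pairs
#'
#' Uses the standard flow-cytometry conversion 1 pg = 0.978e9 bp:
#' genome size (bp) = 0.978e9 x 2C-value (pg).
#'
#' @param two_c_pg 2C DNA amount in picograms (> 0).
#' @return Genome size in base pairs.
#' @export
c_value_to_bp <- function(two_c_pg) {
  if (any(two_c_pg <= 0)) stop("2C-value must be positive")
  0.978e9 * two_c_pg
}

#' Percentage of retained primer pairs
#'
#' @param n_retained Number of pairs surviving a filter.
#' @param n_total Number of pairs entering the filter.
#' @return `100 * n_retained / n_total`.
#' @export
retained_percent <- function(n_retained, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  100 * n_retained / n_total
}

#' Mean spacing between mapped marker sites
#'
#' @param total_bp Genome span in bp.
#' @param n_sites Number of mapped sites.
#' @return Average distance between neighbouring sites, in bp.
#' @export
mean_marker_spacing_bp <- function(total_bp, n_sites) {
  if (n_sites <= 0) stop("n_sites must be positive")
  total_bp / n_sites
}

#' Average sequence length per SSR locus
#'
#' @param total_bp Total sequence length surveyed, in bp.
#' @param n_loci Number of SSR loci detected.
#' @return bp of sequence per locus (one SSR "every X bp").
#' @export
ssr_density_bp <- function(total_bp, n_loci) {
  if (n_loci <= 0) stop("n_loci must be positive")
  total_bp / n_loci
}
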