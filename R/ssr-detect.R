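# smallest period of a motif; motif is primitive iff smallest_period == nchar
smallest_period <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 &&
        motif == strrep(substr(motif, 1, d), u / d)) return(d)
  }
  u
}

all_rotations <- function(motif) {
  u <- nchar(motif)
  doubled <- paste0(motif, motif)
  vapply(seq_len(u), function(i) substr(doubled, i, i + u - 1), character(1))
}

#' Canonical class of a microsatellite motif
#'
#' Repeat units that describe the same tract read in either phase or on
#' either strand are grouped into one class. The canonical representative is
#' the lexicographically smallest string among all cyclic rotations of the
#' motif and of its reverse complement; the class label pairs it with the
#' smallest rotation of its own reverse complement, e.g. the class holding
#' TC, CT, GA and AG is labelled `"AG/CT"`.
#'
#' @param motif A primitive repeat unit of length 2-6 over `{A,C,G,T}`.
#' @return The class label, vectorised over `motif`.
#' @export
canonical_class <- function(motif) {
  vapply(as.character(motif), function(m) {
    u <- nchar(m)
    if (u < 2 || u > 6) stop("motif length must be 2-6: ", m)
    if (grepl("[^ACGT]", m)) stop("motif must be over {A,C,G,T}: ", m)
    if (smallest_period(m) < u)
      stop("motif is not primitive: ", m)
    canon <- min(c(all_rotations(m), all_rotations(revcomp(m))))
    paste0(canon, "/", min(all_rotations(revcomp(canon))))
  }, character(1), USE.NAMES = FALSE)
}

#' Detect perfect microsatellite loci in one sequence
#'
#' Finds every maximal perfect tandem repeat with a primitive unit of
#' `min_unit`..`max_unit` bp repeated at least `min_repeats` times. Tracts
#' are maximal (not extendable by a full unit on either side), reported once
#' at their leftmost start with the unit as it appears there, and trimmed to
#' whole units (a 11-bp AC run is AC x 5). `N` never participates in a
#' tract; mononucleotide runs are not reported.
#'
#' @param seq A sequence string over `{A,C,G,T,N}` (or a single-row
#'   [seq_records]).
#' @param seq_id Identifier used in the output (ignored when `seq` is a
#'   record).
#' @param min_unit,max_unit Repeat-unit length bounds in bp.
#' @param min_repeats Minimum number of complete unit copies.
#' @param min_gap Minimum bp between the end of one reported tract and the
#'   start of the next; with the default 0 adjacent distinct tracts are both
#'   reported, otherwise later tracts closer than `min_gap` are dropped.
#' @return Data frame with columns `seq_id`, `start`, `end` (1-based
#'   inclusive), `motif`, `unit_length`, `repeat_count`, `canonical_class`,
#'   ordered by `start`.
#' @export
find_ssr_loci <- function(seq, seq_id = "seq", min_unit = 2, max_unit = 6,
                          min_repeats = 5, min_gap = 0) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq_id <- seq$id
    seq <- seq$seq
  }
  seq <- toupper(seq)
  n <- nchar(seq)
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_length = integer(), repeat_count = integer(),
                      canonical_class = character(),
                      stringsAsFactors = FALSE)
  if (n < min_unit * min_repeats) return(empty)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- ch %in% c("A", "C", "G", "T")
  out <- vector("list", 0)
  for (u in min_unit:max_unit) {
    if (n < u * min_repeats) break
    lag_ok <- ch[seq_len(n - u)] == ch[(u + 1):n] &
      ok[seq_len(n - u)] & ok[(u + 1):n]
    r <- rle(lag_ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & (r$lengths + u) >= u * min_repeats)
    for (h in hit) {
      i <- starts[h]                      # tract spans i .. ends[h] + u
      tract_len <- r$lengths[h] + u
      rc <- tract_len %/% u
      motif <- substr(seq, i, i + u - 1L)
      if (smallest_period(motif) != u) next   # non-primitive or mono-base
      out[[length(out) + 1L]] <- list(start = i, end = i + rc * u - 1L,
                                      motif = motif, unit_length = u,
                                      repeat_count = rc)
    }
  }
  if (length(out) == 0) return(empty)
  df <- data.frame(seq_id = seq_id,
                   start = vapply(out, `[[`, 1L, "start"),
                   end = vapply(out, `[[`, 1L, "end"),
                   motif = vapply(out, `[[`, "", "motif"),
                   unit_length = vapply(out, `[[`, 1L, "unit_length"),
                   repeat_count = vapply(out, `[[`, 1L, "repeat_count"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$unit_length), , drop = FALSE]
  if (min_gap > 0 && nrow(df) > 1) {
    keep <- rep(TRUE, nrow(df))
    last_end <- df$end[1]
    for (i in 2:nrow(df)) {
      if (df$start[i] - last_end - 1L < min_gap) keep[i] <- FALSE
      else last_end <- df$end[i]
    }
    df <- df[keep, , drop = FALSE]
  }
  df$canonical_class <- canonical_class(df$motif)
  rownames(df) <- NULL
  df
}

#' Detect microsatellites across a whole assembly
#'
#' Applies [find_ssr_loci()] to every record and binds the results.
#'
#' @param records A [seq_records] data frame.
#' @inheritParams find_ssr_loci
#' @return Combined locus table (see [find_ssr_loci()]).
#' @export
scan_ssrs <- function(records, min_unit = 2, max_unit = 6, min_repeats = 5,
                      min_gap = 0) {
  res <- lapply(seq_len(nrow(records)), function(i)
    find_ssr_loci(records$seq[i], records$id[i], min_unit, max_unit,
                  min_repeats, min_gap))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Summarise motif composition of a locus table
#'
#' @param loci A locus table from [scan_ssrs()].
#' @param top_n Keep only the `top_n` most frequent classes (default: all).
#' @param by Group by `"canonical_class"` (default) or raw `"motif"`.
#' @return Data frame (class label, count, fraction of all loci), count
#'   descending, ties broken by label.
#' @export
summarize_motifs <- function(loci, top_n = Inf, by = c("canonical_class",
                                                       "motif")) {
  by <- match.arg(by)
  if (nrow(loci) == 0)
    return(data.frame(class = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  tab <- table(loci[[by]])
  df <- data.frame(class = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$class), , drop = FALSE]
  df$fraction <- df$count / sum(df$count)
  if (is.finite(top_n)) df <- utils::head(df, top_n)
  rownames(df) <- NULL
  df
}

#' Write a locus table as GFF3
#'
#' One `microsatellite` feature per locus, 1-based inclusive coordinates,
#' attributes `motif`, `repeat_count` and `canonical_class`.
#'
#' @param loci A locus table.
#' @param path Optional output path; when `NULL` the GFF3 text is returned.
#' @return The GFF3 text (invisibly when written to `path`).
#' @export
loci_to_gff <- function(loci, path = NULL) {
  header <- "##gff-version 3"
  lines <- character(0)
  if (nrow(loci) > 0) {
    lines <- sprintf(
      "%s\tfloramark\tmicrosatellite\t%d\t%d\t.\t+\t.\tmotif=%s;repeat_count=%d;canonical_class=%s",
      loci$seq_id, loci$start, loci$end, loci$motif, loci$repeat_count,
      loci$canonical_class)
  }
  txt <- paste(c(header, lines), collapse = "\n")
  if (!is.null(path)) {
    writeLines(c(header, lines), path)
    return(invisible(txt))
  }
  txt
}

#' Parse microsatellite features from GFF3 text
#'
#' Inverse of [loci_to_gff()].
#'
#' @param x GFF3 text, or a path to a GFF3 file.
#' @return A locus table (see [find_ssr_loci()]).
#' @export
gff_to_loci <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x)
           else strsplit(x, "\n", fixed = TRUE)[[1]]
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(find_ssr_loci(""))
  f <- strsplit(lines, "\t", fixed = TRUE)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "=([^;]+)"), attrs))
    vapply(m, function(g) if (length(g) == 2) g[2] else NA_character_, "")
  }
  attrs <- vapply(f, `[`, "", 9)
  motif <- attr_get(attrs, "motif")
  df <- data.frame(seq_id = vapply(f, `[`, "", 1),
                   start = as.integer(vapply(f, `[`, "", 4)),
                   end = as.integer(vapply(f, `[`, "", 5)),
                   motif = motif,
                   unit_length = nchar(motif),
                   repeat_count = as.integer(attr_get(attrs, "repeat_count")),
                   canonical_class = attr_get(attrs, "canonical_class"),
                   stringsAsFactors = FALSE)
  df
}

#' Write / read a locus table as TSV
#'
#' @param loci A locus table.
#' @param path File path.
#' @return `path` invisibly for the writer; the locus table for the reader.
#' @export
write_loci <- function(loci, path) {
  utils::write.table(loci, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_loci
#' @export
read_loci <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(seq_id = "character",
                                   motif = "character"))
}
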