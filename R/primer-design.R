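#' Primer design constraints
#'
#' The constraint set used to search SSR flanks for primer pairs: primer
#' length 18-20 bp (optimum 20), GC content 45-65\% (optimum 50\%), melting
#' temperature 60 C within `tm_window`, product size 120-400 bp spanning the
#' whole repeat tract.
#'
#' @param primer_len_min,primer_len_max,primer_len_opt Primer length bounds
#'   and optimum, bp.
#' @param gc_min,gc_max,gc_opt GC-content bounds and optimum, percent.
#' @param tm_opt Target melting temperature, degrees C.
#' @param tm_window Allowed deviation from `tm_opt`, degrees C.
#' @param product_min,product_max Product size window, bp.
#' @param flank_window bp searched on each side of the tract.
#' @param tm_method Melting-temperature model, see [melting_temp()].
#' @return A list of class `design_config`.
#' @export
design_config <- function(primer_len_min = 18, primer_len_max = 20,
                          primer_len_opt = 20, gc_min = 45, gc_max = 65,
                          gc_opt = 50, tm_opt = 60, tm_window = 3,
                          product_min = 120, product_max = 400,
                          flank_window = 250,
                          tm_method = c("nearest_neighbor", "wallace")) {
  tm_method <- match.arg(tm_method)
  stopifnot(primer_len_min <= primer_len_opt,
            primer_len_opt <= primer_len_max,
            gc_min <= gc_opt, gc_opt <= gc_max,
            product_min < product_max,
            product_min > 2 * primer_len_max,
            tm_window > 0, flank_window >= primer_len_min)
  structure(list(primer_len_min = primer_len_min,
                 primer_len_max = primer_len_max,
                 primer_len_opt = primer_len_opt,
                 gc_min = gc_min, gc_max = gc_max, gc_opt = gc_opt,
                 tm_opt = tm_opt, tm_window = tm_window,
                 product_min = product_min, product_max = product_max,
                 flank_window = flank_window, tm_method = tm_method),
            class = "design_config")
}

#' GC content of an oligo
#'
#' @param seq Oligo sequence(s) over `{A,C,G,T}`.
#' @return Percent G+C, vectorised.
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  if (any(!nzchar(seq))) stop("empty oligo")
  if (any(grepl("[^ACGT]", seq))) stop("ambiguous base in oligo")
  100 * (nchar(gsub("[AT]", "", seq))) / nchar(seq)
}

# Allawi & SantaLucia 1997 unified nearest-neighbour parameters,
# dH kcal/mol and dS cal/(mol K), keyed by the top-strand dinucleotide
.nn_dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Oligo melting temperature
#'
#' `wallace`: Tm = 2(A+T) + 4(G+C). `nearest_neighbor`: duplex Tm from the
#' unified nearest-neighbour parameter set (Allawi & SantaLucia 1997) with
#' terminal initiation terms, Tm = 1000 dH / (dS + R ln(CT/4)) - 273.15,
#' with the entropic salt correction dS + 0.368 (N-1) ln[Na+]. Default
#' conditions: 50 nM total strand concentration (25 nM each strand) and
#' 50 mM monovalent cation.
#'
#' @param seq Oligo sequence(s) over `{A,C,G,T}`, length >= 8 for the
#'   nearest-neighbour model.
#' @param method `"nearest_neighbor"` (default) or `"wallace"`.
#' @param primer_nM Total strand concentration in nM.
#' @param na_mM Monovalent cation concentration in mM.
#' @return Melting temperature(s) in degrees C.
#' @export
melting_temp <- function(seq, method = c("nearest_neighbor", "wallace"),
                         primer_nM = 50, na_mM = 50) {
  method <- match.arg(method)
  seq <- toupper(seq)
  if (any(grepl("[^ACGT]", seq))) stop("ambiguous base in oligo")
  if (method == "wallace") {
    at <- nchar(gsub("[GC]", "", seq))
    gc <- nchar(seq) - at
    return(2 * at + 4 * gc)
  }
  if (any(nchar(seq) < 8)) stop("nearest-neighbour Tm needs length >= 8")
  vapply(seq, function(s) {
    n <- nchar(s)
    dinuc <- substring(s, 1:(n - 1), 2:n)
    dh <- sum(.nn_dh[dinuc])
    ds <- sum(.nn_ds[dinuc])
    for (term in c(substr(s, 1, 1), substr(s, n, n))) {
      if (term %in% c("G", "C")) { dh <- dh + 0.1;  ds <- ds - 2.8 }
      else                       { dh <- dh + 2.3;  ds <- ds + 4.1 }
    }
    ds <- ds + 0.368 * (n - 1) * log(na_mM / 1000)
    ct <- primer_nM * 1e-9
    1000 * dh / (ds + 1.98722 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

# candidate windows on one side of a tract passing the per-primer constraints
.candidate_windows <- function(template, lo, hi, config) {
  # all substrings with start in [lo, hi] region, lengths len_min..len_max,
  # fully inside [lo, hi]
  out <- list()
  for (len in config$primer_len_min:config$primer_len_max) {
    starts <- seq.int(lo, hi - len + 1L)
    starts <- starts[starts >= lo]
    if (length(starts) == 0 || hi - len + 1L < lo) next
    oligo <- substring(template, starts, starts + len - 1L)
    keep <- !grepl("[^ACGT]", oligo)
    if (!any(keep)) next
    starts <- starts[keep]; oligo <- oligo[keep]
    gc <- gc_content(oligo)
    keep <- gc >= config$gc_min & gc <= config$gc_max
    if (!any(keep)) next
    starts <- starts[keep]; oligo <- oligo[keep]; gc <- gc[keep]
    tm <- melting_temp(oligo, config$tm_method)
    keep <- abs(tm - config$tm_opt) <= config$tm_window
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[keep], len = len, oligo = oligo[keep],
      gc = gc[keep], tm = tm[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Design the best flanking primer pair for one SSR locus
#'
#' Exhaustively enumerates forward windows upstream and reverse windows
#' downstream of the tract (within `flank_window` bp of it, never
#' overlapping it), keeps candidates meeting every length/GC/Tm constraint,
#' pairs them under the product-size window, and returns the minimum-penalty
#' pair, where
#' penalty = sum |len - len_opt| + sum |gc - gc_opt|/5 + sum |tm - tm_opt|
#' over both primers. Ties go to the smaller product, then the leftmost
#' forward start. Deterministic; returns `NULL` when no pair satisfies the
#' constraints.
#'
#' @param template A sequence string or single-row [seq_records] the locus
#'   lies on.
#' @param locus One row of a locus table (list or data frame row with
#'   `start`, `end`).
#' @param config A [design_config()].
#' @return A one-row data frame (`pair_id`, `seq_id`, `locus_start`,
#'   `locus_end`, `motif`, `fwd_seq`, `rev_seq`, `fwd_start`, `rev_end`,
#'   `product_bp`, `tm_fwd`, `tm_rev`, `gc_fwd`, `gc_rev`, `penalty`) or
#'   `NULL`.
#' @export
design_primer_pair <- function(template, locus, config = design_config()) {
  seq_id <- if (is.data.frame(template)) template$id[1] else
    if (!is.null(locus$seq_id)) locus$seq_id else "seq"
  seq <- if (is.data.frame(template)) template$seq[1] else toupper(template)
  n <- nchar(seq)
  s <- as.integer(locus$start); e <- as.integer(locus$end)
  if (s < 1 || e > n || s > e) stop("locus coordinates outside template")
  f_lo <- max(1L, s - config$flank_window)
  f_hi <- s - 1L
  r_lo <- e + 1L
  r_hi <- min(n, e + config$flank_window)
  if (f_hi - f_lo + 1L < config$primer_len_min ||
      r_hi - r_lo + 1L < config$primer_len_min) return(NULL)
  fwd <- .candidate_windows(seq, f_lo, f_hi, config)
  if (is.null(fwd)) return(NULL)
  rev_tmpl <- .candidate_windows(seq, r_lo, r_hi, config)
  if (is.null(rev_tmpl)) return(NULL)
  # pair: product = rev_end - fwd_start + 1, spans the tract by construction
  best <- NULL
  fwd$pen1 <- abs(fwd$len - config$primer_len_opt) +
    abs(fwd$gc - config$gc_opt) / 5 + abs(fwd$tm - config$tm_opt)
  rev_tmpl$pen1 <- abs(rev_tmpl$len - config$primer_len_opt) +
    abs(rev_tmpl$gc - config$gc_opt) / 5 + abs(rev_tmpl$tm - config$tm_opt)
  rev_end_all <- rev_tmpl$start + rev_tmpl$len - 1L
  for (i in order(fwd$pen1, fwd$start)) {
    if (!is.null(best) && fwd$pen1[i] > best$penalty) break
    prod <- rev_end_all - fwd$start[i] + 1L
    ok <- prod >= config$product_min & prod <= config$product_max
    if (!any(ok)) next
    pen <- fwd$pen1[i] + rev_tmpl$pen1[ok]
    cand <- data.frame(j = which(ok), pen = pen, prod = prod[ok])
    cand <- cand[order(cand$pen, cand$prod,
                       rev_tmpl$start[cand$j]), , drop = FALSE]
    top <- cand[1, ]
    if (is.null(best) || top$pen < best$penalty - 1e-12 ||
        (abs(top$pen - best$penalty) <= 1e-12 &&
         (top$prod < best$product_bp ||
          (top$prod == best$product_bp && fwd$start[i] < best$fwd_start)))) {
      j <- top$j
      best <- data.frame(
        pair_id = sprintf("%s_%d_%d", seq_id, s, e),
        seq_id = seq_id, locus_start = s, locus_end = e,
        motif = if (!is.null(locus$motif)) locus$motif else NA_character_,
        fwd_seq = fwd$oligo[i],
        rev_seq = revcomp(rev_tmpl$oligo[j]),
        fwd_start = fwd$start[i],
        rev_end = rev_end_all[j],
        product_bp = top$prod,
        tm_fwd = fwd$tm[i], tm_rev = rev_tmpl$tm[j],
        gc_fwd = fwd$gc[i], gc_rev = rev_tmpl$gc[j],
        penalty = top$pen,
        stringsAsFactors = FALSE)
    }
  }
  best
}

#' Design primers for every locus in a table
#'
#' At most one pair per locus; loci with no constraint-satisfying pair are
#' skipped.
#'
#' @param records A [seq_records] assembly.
#' @param loci A locus table from [scan_ssrs()].
#' @param config A [design_config()].
#' @return A primer-pair table, one row per designable locus.
#' @export
design_primers <- function(records, loci, config = design_config()) {
  seqs <- stats::setNames(records$seq, records$id)
  res <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    if (!l$seq_id %in% names(seqs))
      stop("locus references unknown sequence: ", l$seq_id)
    design_primer_pair(seqs[[l$seq_id]],
                       list(seq_id = l$seq_id, start = l$start,
                            end = l$end, motif = l$motif), config)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0)
    return(data.frame(pair_id = character(), seq_id = character(),
                      locus_start = integer(), locus_end = integer(),
                      motif = character(), fwd_seq = character(),
                      rev_seq = character(), fwd_start = integer(),
                      rev_end = integer(), product_bp = integer(),
                      tm_fwd = numeric(), tm_rev = numeric(),
                      gc_fwd = numeric(), gc_rev = numeric(),
                      penalty = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Write / read a primer-pair table as TSV
#'
#' @param pairs A primer-pair table.
#' @param path File path.
#' @return `path` invisibly for the writer; the pair table for the reader.
#' @export
write_primers <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_primers
#' @export
read_primers <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(pair_id = "character",
                                   seq_id = "character",
                                   fwd_seq = "character",
                                   rev_seq = "character"))
}
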