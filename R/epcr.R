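#' Primer-site match policy for electronic PCR
#'
#' Controls how primers are allowed to anneal. The default is exact
#' full-length matching on both strands. For transcript cross-referencing
#' the screening rule tolerates a single mismatch at the 5'-terminal base of
#' the reverse primer and none at its 3' end
#' (`reverse_5prime_mismatch_allowed = TRUE`).
#'
#' @param max_total_mismatches Mismatches allowed anywhere outside the
#'   3'-exact zone (default 0).
#' @param reverse_5prime_mismatch_allowed Allow one extra mismatch, only at
#'   the 5'-terminal base of a reverse-role primer.
#' @param three_prime_exact_bases Number of 3'-terminal bases where
#'   mismatches are never allowed; `NULL` means every base when
#'   `max_total_mismatches = 0`, else 1.
#' @param amplicon_min_bp,amplicon_max_bp Product-size window for amplicon
#'   enumeration (defaults 50 and 5000).
#' @return A list of class `match_policy`.
#' @export
match_policy <- function(max_total_mismatches = 0,
                         reverse_5prime_mismatch_allowed = FALSE,
                         three_prime_exact_bases = NULL,
                         amplicon_min_bp = 50, amplicon_max_bp = 5000) {
  stopifnot(max_total_mismatches >= 0,
            amplicon_min_bp < amplicon_max_bp,
            is.null(three_prime_exact_bases) || three_prime_exact_bases >= 1)
  structure(list(max_total_mismatches = as.integer(max_total_mismatches),
                 reverse_5prime_mismatch_allowed =
                   isTRUE(reverse_5prime_mismatch_allowed),
                 three_prime_exact_bases = three_prime_exact_bases,
                 amplicon_min_bp = as.integer(amplicon_min_bp),
                 amplicon_max_bp = as.integer(amplicon_max_bp)),
            class = "match_policy")
}

.empty_sites <- function() {
  data.frame(seq_id = character(), start = integer(), strand = character(),
             mismatches = integer(), role = character(),
             stringsAsFactors = FALSE)
}

#' Locate all annealing sites of a primer in a sequence database
#'
#' Full-length ungapped placements on both strands with Hamming mismatches
#' obeying the [match_policy()]: no mismatch within the 3'-exact zone, and
#' the optional single extra mismatch only at the 5'-terminal base of a
#' reverse-role primer. `start` is the template position of the primer's
#' 5'-most base (the match end for minus-strand sites).
#'
#' @param primer Oligo sequence, length >= 10.
#' @param db A [seq_records] database.
#' @param policy A [match_policy()].
#' @param role `"forward"` or `"reverse"`; decides whether the 5' allowance
#'   applies.
#' @return Data frame `seq_id`, `start`, `strand`, `mismatches`, `role`.
#' @export
find_sites <- function(primer, db, policy = match_policy(),
                       role = c("forward", "reverse")) {
  role <- match.arg(role)
  primer <- toupper(primer)
  L <- nchar(primer)
  if (L < 10) stop("primer length must be >= 10")
  extra <- role == "reverse" && policy$reverse_5prime_mismatch_allowed
  max_mm <- policy$max_total_mismatches + as.integer(extra)
  tpe <- policy$three_prime_exact_bases
  if (is.null(tpe)) tpe <- if (policy$max_total_mismatches == 0) L else 1L
  tpe <- min(tpe, L)
  if (nrow(db) == 0) return(.empty_sites())
  subj <- Biostrings::DNAStringSet(db$seq)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    pchars <- strsplit(pat, "", fixed = TRUE)[[1]]
    m <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mm,
                                   fixed = TRUE)
    for (si in seq_along(m)) {
      r <- m[[si]]
      if (length(r) == 0) next
      st <- BiocGenerics::start(r)
      en <- BiocGenerics::end(r)
      inb <- st >= 1 & en <= nchar(db$seq[si])
      st <- st[inb]; en <- en[inb]
      for (j in seq_along(st)) {
        if (max_mm == 0) {
          mmpos <- integer(0)
        } else {
          fchars <- strsplit(substr(db$seq[si], st[j], en[j]), "",
                             fixed = TRUE)[[1]]
          sub_pos <- which(pchars != fchars)
          mmpos <- if (strand == "+") sub_pos else L - sub_pos + 1L
        }
        p <- mmpos
        if (extra) p <- setdiff(p, 1L)  # the tolerated 5'-terminal mismatch
        if (length(p) > policy$max_total_mismatches) next
        if (any(p > L - tpe)) next
        out[[length(out) + 1L]] <- data.frame(
          seq_id = db$id[si],
          start = if (strand == "+") st[j] else en[j],
          strand = strand, mismatches = length(mmpos), role = role,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(.empty_sites())
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.empty_amplicons <- function() {
  data.frame(pair_id = character(), seq_id = character(), start = integer(),
             end = integer(), length_bp = integer(),
             fwd_mismatches = integer(), rev_mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Enumerate all potential amplicons of a primer pair
#'
#' Every combination of a plus-strand forward-primer site and a
#' minus-strand reverse-primer site on the same sequence, forward before
#' reverse, with non-overlapping primers and product length within the
#' policy window.
#'
#' @param pair One row of a primer-pair table (needs `pair_id`, `fwd_seq`,
#'   `rev_seq`).
#' @param db A [seq_records] database.
#' @param policy A [match_policy()].
#' @return Data frame `pair_id`, `seq_id`, `start`, `end`, `length_bp`,
#'   `fwd_mismatches`, `rev_mismatches`.
#' @export
enumerate_amplicons <- function(pair, db, policy = match_policy()) {
  lf <- nchar(pair$fwd_seq); lr <- nchar(pair$rev_seq)
  f <- find_sites(pair$fwd_seq, db, policy, "forward")
  f <- f[f$strand == "+", , drop = FALSE]
  if (nrow(f) == 0) return(.empty_amplicons())
  r <- find_sites(pair$rev_seq, db, policy, "reverse")
  r <- r[r$strand == "-", , drop = FALSE]
  if (nrow(r) == 0) return(.empty_amplicons())
  min_len <- max(policy$amplicon_min_bp, lf + lr)
  out <- list()
  for (sid in intersect(unique(f$seq_id), unique(r$seq_id))) {
    fs <- f[f$seq_id == sid, , drop = FALSE]
    rs <- r[r$seq_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(fs))) {
      len <- rs$start - fs$start[i] + 1L
      ok <- len >= min_len & len <= policy$amplicon_max_bp
      if (!any(ok)) next
      out[[length(out) + 1L]] <- data.frame(
        pair_id = pair$pair_id, seq_id = sid,
        start = fs$start[i], end = rs$start[ok],
        length_bp = len[ok],
        fwd_mismatches = fs$mismatches[i],
        rev_mismatches = rs$mismatches[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(.empty_amplicons())
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$seq_id, res$start, res$end), , drop = FALSE]
}

#' Classify primer pairs by in-silico amplification uniqueness
#'
#' Runs [enumerate_amplicons()] for every pair against the database and
#' classifies each as `none` (no amplicon), `unique` (exactly one amplicon
#' across the whole database; these are the retained pairs) or `multiple`.
#'
#' @param pairs A primer-pair table.
#' @param db A [seq_records] database.
#' @param policy A [match_policy()].
#' @return An object of class `epcr_result`: list with `classification`
#'   (data frame `pair_id`, `n_amplicons`, `classification`), `amplicons`
#'   (all enumerated amplicons) and `retained` (pair ids classified
#'   unique).
#' @export
classify_pairs <- function(pairs, db, policy = match_policy()) {
  amp <- lapply(seq_len(nrow(pairs)), function(i)
    enumerate_amplicons(pairs[i, ], db, policy))
  n <- vapply(amp, nrow, 1L)
  cls <- ifelse(n == 0, "none", ifelse(n == 1, "unique", "multiple"))
  classification <- data.frame(pair_id = pairs$pair_id, n_amplicons = n,
                               classification = cls,
                               stringsAsFactors = FALSE)
  structure(list(classification = classification,
                 amplicons = do.call(rbind,
                                     c(amp, list(make.row.names = FALSE))),
                 retained = pairs$pair_id[cls == "unique"]),
            class = "epcr_result")
}

#' @export
print.epcr_result <- function(x, ...) {
  tab <- table(factor(x$classification$classification,
                      levels = c("unique", "multiple", "none")))
  cat(sprintf(
    "e-PCR of %d primer pairs: %d unique (retained), %d multiple, %d none\n",
    nrow(x$classification), tab["unique"], tab["multiple"], tab["none"]))
  invisible(x)
}

#' Screen marker transferability against a foreign genome
#'
#' A pair "maps" onto a foreign genome when it yields at least one in-silico
#' amplicon there under the policy.
#'
#' @param pairs A primer-pair table (typically the retained unique pairs).
#' @param foreign_db A [seq_records] foreign genome, or a named list of
#'   them.
#' @param policy A [match_policy()].
#' @return For one genome: list with `summary` (data frame `genome`,
#'   `n_pairs`, `n_mapped`), `mapped` (per-pair amplicon counts) and
#'   `sites` (amplicon locations). For a named list: the same with rows /
#'   entries per genome.
#' @export
transferability_screen <- function(pairs, foreign_db,
                                   policy = match_policy()) {
  if (is.data.frame(foreign_db)) foreign_db <- list(genome = foreign_db)
  summaries <- list(); mapped <- list(); sites <- list()
  for (g in names(foreign_db)) {
    amp <- lapply(seq_len(nrow(pairs)), function(i)
      enumerate_amplicons(pairs[i, ], foreign_db[[g]], policy))
    n <- vapply(amp, nrow, 1L)
    summaries[[g]] <- data.frame(genome = g, n_pairs = nrow(pairs),
                                 n_mapped = sum(n > 0),
                                 stringsAsFactors = FALSE)
    mapped[[g]] <- data.frame(genome = g, pair_id = pairs$pair_id,
                              n_amplicons = n, mapped = n > 0,
                              stringsAsFactors = FALSE)
    s <- do.call(rbind, c(amp, list(make.row.names = FALSE)))
    if (!is.null(s) && nrow(s)) s$genome <- g
    sites[[g]] <- s
  }
  list(summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       mapped = do.call(rbind, c(mapped, list(make.row.names = FALSE))),
       sites = do.call(rbind, c(sites, list(make.row.names = FALSE))))
}

#' Cross-reference retained pairs against transcripts (gene-targeted markers)
#'
#' Every retained genomic pair that produces at least one amplicon on the
#' transcript contigs becomes a gene-targeted-marker (GTM) record listing
#' all transcripts it amplifies. Joining an annotation table marks records
#' functional. The transcript-screen policy must allow the single
#' 5'-terminal reverse-primer mismatch.
#'
#' @param retained_pairs Primer-pair table of retained (unique) pairs.
#' @param transcript_db A [seq_records] set of transcript contigs.
#' @param tx_policy A [match_policy()] with
#'   `reverse_5prime_mismatch_allowed = TRUE`.
#' @param annotations Optional data frame `transcript_id`, `gene`.
#' @return An object of class `gtm_result`: list with `records` (data frame
#'   `pair_id`, `transcript_ids` (comma separated), `n_transcripts`,
#'   `gene`, `is_functional`) and `summary` (`n_gtm_pairs`,
#'   `n_transcripts`, `n_genes`).
#' @export
gtm_cross_reference <- function(retained_pairs, transcript_db,
                                tx_policy = match_policy(
                                  reverse_5prime_mismatch_allowed = TRUE),
                                annotations = NULL) {
  if (!tx_policy$reverse_5prime_mismatch_allowed)
    stop("transcript screening requires the 5'-terminal reverse-primer ",
         "mismatch allowance (reverse_5prime_mismatch_allowed = TRUE)")
  ann <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(annotations$transcript_id, transcript_db$id)
    if (length(unknown)) {
      warning("annotation rows for unknown transcripts ignored: ",
              paste(utils::head(unknown, 5), collapse = ", "))
      annotations <- annotations[!annotations$transcript_id %in% unknown, ,
                                 drop = FALSE]
    }
    ann <- stats::setNames(as.character(annotations$gene),
                           annotations$transcript_id)
  }
  rec <- list()
  for (i in seq_len(nrow(retained_pairs))) {
    amp <- enumerate_amplicons(retained_pairs[i, ], transcript_db, tx_policy)
    if (nrow(amp) == 0) next
    tx <- sort(unique(amp$seq_id))
    genes <- if (is.null(ann)) character(0) else
      sort(unique(ann[tx[tx %in% names(ann)]]))
    rec[[length(rec) + 1L]] <- data.frame(
      pair_id = retained_pairs$pair_id[i],
      transcript_ids = paste(tx, collapse = ","),
      n_transcripts = length(tx),
      gene = if (length(genes)) paste(genes, collapse = ",")
             else NA_character_,
      is_functional = length(genes) > 0,
      stringsAsFactors = FALSE)
  }
  records <- if (length(rec))
    do.call(rbind, c(rec, list(make.row.names = FALSE)))
  else data.frame(pair_id = character(), transcript_ids = character(),
                  n_transcripts = integer(), gene = character(),
                  is_functional = logical(), stringsAsFactors = FALSE)
  all_tx <- unique(unlist(strsplit(records$transcript_ids, ",",
                                   fixed = TRUE)))
  all_genes <- unique(unlist(strsplit(records$gene[!is.na(records$gene)],
                                      ",", fixed = TRUE)))
  structure(list(records = records,
                 summary = list(n_gtm_pairs = nrow(records),
                                n_transcripts = length(all_tx),
                                n_genes = length(all_genes))),
            class = "gtm_result")
}

#' @export
print.gtm_result <- function(x, ...) {
  cat(sprintf(
    "%d gene-targeted marker pairs annealing to %d transcripts (%d annotated genes)\n",
    x$summary$n_gtm_pairs, x$summary$n_transcripts, x$summary$n_genes))
  invisible(x)
}
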