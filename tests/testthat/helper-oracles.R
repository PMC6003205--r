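# Independent reference implementations used to cross-check the package.
# These deliberately use different mechanisms from the implementation
# (regex backtracking, per-position loops, closed forms).

# SSR scan oracle: regex backreference search per unit length, then
# primitivity via the doubled-string rotation trick and containment dedupe.
oracle_scan_ssrs <- function(seq, seq_id = "seq", min_unit = 2,
                             max_unit = 6, min_repeats = 5) {
  seq <- toupper(seq)
  hits <- list()
  for (u in min_unit:max_unit) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, min_repeats - 1)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[1] == -1) next
    for (i in seq_along(m)) {
      st <- m[i]
      len <- attr(m, "match.length")[i]
      motif <- substr(seq, st, st + u - 1)
      # primitive iff motif does not occur inside doubled(motif) except at
      # the two trivial offsets
      doubled <- paste0(motif, motif)
      interior <- substr(doubled, 2, 2 * u - 1)
      if (grepl(motif, interior, fixed = TRUE)) next
      hits[[length(hits) + 1L]] <- data.frame(
        seq_id = seq_id, start = st, end = st + len - 1L, motif = motif,
        unit_length = u, repeat_count = len %/% u,
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_length = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(hits, list(make.row.names = FALSE)))
}

# brute-force N50 straight from the definition: largest L among observed
# lengths such that the total length in sequences >= L covers half
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# exhaustive canonical k-mer tabulation via Biostrings views
oracle_kmer_hist <- function(reads, k) {
  kmers <- character(0)
  for (s in reads$seq) {
    for (piece in strsplit(s, "N+")[[1]]) {
      if (nchar(piece) < k) next
      d <- Biostrings::DNAString(piece)
      v <- Biostrings::Views(d, start = 1:(nchar(piece) - k + 1), width = k)
      fwd <- as.character(v)
      rev <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(v)))
      kmers <- c(kmers, mapply(function(a, b) {
        if (chartr("ACGT", "0123", a) <= chartr("ACGT", "0123", b)) a else b
      }, fwd, rev, USE.NAMES = FALSE))
    }
  }
  table(table(kmers))
}

# per-position Hamming distances of a pattern against a sequence
oracle_hamming_scan <- function(pattern, seq) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(seq, "")[[1]]
  L <- length(p); n <- length(s)
  if (n < L) return(integer(0))
  vapply(1:(n - L + 1), function(i) sum(s[i:(i + L - 1)] != p),
         integer(1))
}

# brute-force amplicon enumeration under exact matching: double scan with
# per-position Hamming distances, forward on plus, reverse on minus
oracle_amplicons <- function(fwd, rev, seq, min_bp, max_bp) {
  lf <- nchar(fwd); lr <- nchar(rev)
  fpos <- which(oracle_hamming_scan(fwd, seq) == 0)          # 5' at fpos
  rts <- which(oracle_hamming_scan(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(rev))), seq) == 0)
  rpos <- rts + lr - 1L                                      # 5' at match end
  out <- list()
  for (f in fpos) for (r in rpos) {
    len <- r - f + 1L
    if (len >= max(min_bp, lf + lr) && len <= max_bp)
      out[[length(out) + 1L]] <- c(start = f, end = r, length_bp = len)
  }
  if (length(out) == 0)
    return(data.frame(start = integer(), end = integer(),
                      length_bp = integer()))
  as.data.frame(do.call(rbind, out))
}

# one-way ANOVA F from first principles (sums of squares)
oracle_anova_F <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ss_between / df1) / (ss_within / df2)
}

# audit a designed pair against every constraint in the config
audit_pair <- function(pair, template_seq, locus, config) {
  ok <- TRUE
  note <- function(cond, what) {
    if (!cond) {
      ok <<- FALSE
      message("constraint violated: ", what)
    }
  }
  lf <- nchar(pair$fwd_seq); lr <- nchar(pair$rev_seq)
  note(lf >= config$primer_len_min && lf <= config$primer_len_max,
       "fwd length")
  note(lr >= config$primer_len_min && lr <= config$primer_len_max,
       "rev length")
  for (s in c(pair$fwd_seq, pair$rev_seq)) {
    gc <- 100 * nchar(gsub("[AT]", "", s)) / nchar(s)
    note(gc >= config$gc_min && gc <= config$gc_max, "GC window")
    note(abs(melting_temp(s, config$tm_method) - config$tm_opt) <=
           config$tm_window + 1e-9, "Tm window")
  }
  note(pair$product_bp >= config$product_min &&
         pair$product_bp <= config$product_max, "product size")
  note(pair$fwd_start + lf - 1 < locus$start, "fwd overlaps tract")
  note(pair$rev_end - lr + 1 > locus$end, "rev overlaps tract")
  note(pair$fwd_start <= locus$start && pair$rev_end >= locus$end,
       "product spans tract")
  note(substr(template_seq, pair$fwd_start, pair$fwd_start + lf - 1) ==
         pair$fwd_seq, "fwd equals template substring")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pair$rev_seq)))
  note(substr(template_seq, pair$rev_end - lr + 1, pair$rev_end) == rc,
       "rev equals revcomp of template substring")
  note(pair$product_bp == pair$rev_end - pair$fwd_start + 1,
       "product arithmetic")
  ok
}

# all internal node heights of an upgma_tree (one per merge)
unique_heights <- function(tree) {
  hs <- numeric(0)
  walk <- function(node) {
    if (is.null(node$label)) {
      hs <<- c(hs, node$height)
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  hs
}

revcomp_test <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# smallest period via the doubled-string occurrence trick
smallest_period_test <- function(m) {
  u <- nchar(m)
  doubled <- paste0(m, m)
  hit <- regexpr(m, substr(doubled, 2, 2 * u), fixed = TRUE)
  as.integer(hit)
}

# random sequence helper for property tests
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# standard duplication fixture: plant n_loci designable SSRs ~1 kb apart,
# design pairs, duplicate the amplicon regions of the first n_dup designed
# pairs; returns pairs, the augmented assembly and the duplicated pair ids
make_dup_fixture <- function(n_loci = 25, n_dup = 5, seed = 7,
                             config = design_config()) {
  motifs <- c("AC", "AG", "AAG", "AAT", "AGAT")
  glen <- 1000 * (n_loci + 2)
  g <- simulate_genome(glen, gc = 0.5, seed = seed)
  spec <- data.frame(motif = rep(motifs, length.out = n_loci),
                     repeat_count = 5 + (seq_len(n_loci) %% 4),
                     position = 1000 * seq_len(n_loci))
  fx <- plant_ssrs(g, spec)
  pairs <- design_primers(fx$genome, fx$truth$planted, config)
  stopifnot(nrow(pairs) >= n_dup)
  dup <- pairs[seq_len(n_dup), , drop = FALSE]
  inj <- inject_duplications(
    fx$genome,
    data.frame(seq_id = dup$seq_id, start = dup$fwd_start,
               end = dup$rev_end),
    n_copies = 1)
  list(genome = fx$genome, assembly = inj$assembly, pairs = pairs,
       dup_ids = dup$pair_id, fixture = fx)
}
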