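# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Simulate a random genome sequence
#'
#' I.i.d. bases with the requested GC content; deterministic for a fixed
#' seed. Repeats can arise by chance: scan the result (or use
#' [plant_ssrs()], which records them in its truth table).
#'
#' @param length Genome length in bp (>= 1000).
#' @param gc GC fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A single-row [seq_records].
#' @export
simulate_genome <- function(length, gc = 0.4, seed = 1, id = "ctg1") {
  if (length < 1000) stop("genome length must be >= 1000")
  if (gc < 0 || gc >= 1) stop("gc must be in [0, 1)")
  bases <- with_seed(seed,
    sample(c("A", "T", "C", "G"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)))
  seq_records(id, paste(bases, collapse = ""))
}

#' Plant perfect SSR tracts into a genome at known coordinates
#'
#' Writes each requested tract into the sequence and forces the flanking
#' base on each side to differ from the tract's cyclic continuation, so
#' every planted tract is maximal and its truth coordinates are exact.
#' Tracts formed by chance in the background are detected at generation
#' time and recorded in the truth table rather than forbidden.
#'
#' @param genome A single-row [seq_records].
#' @param spec Data frame with columns `motif`, `repeat_count`, `position`
#'   (1-based start).
#' @param min_repeats Detection threshold used to build the truth table.
#' @return A list of class `ssr_fixture`: `genome` (modified records),
#'   `truth` with `planted` (locus table of the planted tracts),
#'   `chance` (other detectable loci) and `all_loci`.
#' @export
plant_ssrs <- function(genome, spec, min_repeats = 5) {
  seq <- genome$seq[1]
  n <- nchar(seq)
  if (nrow(spec) == 0) {
    loci <- find_ssr_loci(seq, genome$id[1], min_repeats = min_repeats)
    return(structure(list(genome = genome,
                          truth = list(planted = loci[0, ], chance = loci,
                                       all_loci = loci)),
                     class = "ssr_fixture"))
  }
  spec$motif <- toupper(as.character(spec$motif))
  len <- nchar(spec$motif) * spec$repeat_count
  starts <- as.integer(spec$position)
  ends <- starts + len - 1L
  if (any(starts < 2) || any(ends > n - 1))
    stop("planted tracts must leave >= 1 bp of flank inside the genome")
  o <- order(starts)
  if (any(starts[o][-1] - ends[o][-length(o)] < 3))
    stop("planted tracts overlap or touch (need >= 2 bp between tracts)")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  for (i in seq_len(nrow(spec))) {
    m <- spec$motif[i]
    u <- nchar(m)
    tract <- strsplit(strrep(m, spec$repeat_count[i]), "",
                      fixed = TRUE)[[1]]
    ch[starts[i]:ends[i]] <- tract
    # break the period on both sides
    lastb <- substr(m, u, u); firstb <- substr(m, 1, 1)
    if (ch[starts[i] - 1L] == lastb) ch[starts[i] - 1L] <- other(lastb)
    if (ch[ends[i] + 1L] == firstb) ch[ends[i] + 1L] <- other(firstb)
  }
  genome$seq[1] <- paste(ch, collapse = "")
  all_loci <- find_ssr_loci(genome$seq[1], genome$id[1],
                            min_repeats = min_repeats)
  key <- paste(all_loci$start, all_loci$end, all_loci$motif)
  pkey <- paste(starts, ends, spec$motif)
  if (!all(pkey %in% key))
    stop("internal error: a planted tract was not recovered as planted; ",
         "check the planting spec for interacting tracts")
  planted <- all_loci[match(pkey, key), , drop = FALSE]
  rownames(planted) <- NULL
  chance <- all_loci[!key %in% pkey, , drop = FALSE]
  rownames(chance) <- NULL
  structure(list(genome = genome,
                 truth = list(planted = planted, chance = chance,
                              all_loci = all_loci)),
            class = "ssr_fixture")
}

#' Re-derive and verify a fixture's truth table
#'
#' Rescans the fixture genome and asserts that the recorded truth (planted
#' plus chance loci) matches exactly.
#'
#' @param fixture An `ssr_fixture` from [plant_ssrs()].
#' @return `TRUE`, invisibly; errors on mismatch.
#' @export
fixture_selfcheck <- function(fixture) {
  rescanned <- find_ssr_loci(fixture$genome$seq[1], fixture$genome$id[1])
  want <- fixture$truth$all_loci
  if (!identical(rescanned[order(rescanned$start, rescanned$unit_length),
                           c("start", "end", "motif")],
                 want[order(want$start, want$unit_length),
                      c("start", "end", "motif")]))
    stop("fixture truth table does not match a rescan of the genome")
  invisible(TRUE)
}

#' Copy regions of an assembly into new contigs
#'
#' Appends `n_copies` copies of each interval as new contigs, creating the
#' duplicated-region condition under which primer pairs amplify multiple
#' products.
#'
#' @param assembly A [seq_records] assembly.
#' @param intervals Data frame `seq_id`, `start`, `end`.
#' @param n_copies Copies appended per interval.
#' @return List with `assembly` (original plus copy contigs) and `truth`
#'   (data frame `seq_id`, `start`, `end`, `copy_id`).
#' @export
inject_duplications <- function(assembly, intervals, n_copies = 1) {
  if (nrow(intervals) == 0)
    return(list(assembly = assembly,
                truth = data.frame(seq_id = character(), start = integer(),
                                   end = integer(), copy_id = character(),
                                   stringsAsFactors = FALSE)))
  seqs <- stats::setNames(assembly$seq, assembly$id)
  rows <- list()
  new_id <- character(0); new_seq <- character(0)
  k <- 0L
  for (i in seq_len(nrow(intervals))) {
    src <- seqs[[intervals$seq_id[i]]]
    if (is.null(src)) stop("unknown sequence: ", intervals$seq_id[i])
    if (intervals$start[i] < 1 || intervals$end[i] > nchar(src))
      stop("interval outside sequence bounds")
    frag <- substr(src, intervals$start[i], intervals$end[i])
    for (cp in seq_len(n_copies)) {
      k <- k + 1L
      id <- sprintf("dup_%d", k)
      new_id <- c(new_id, id); new_seq <- c(new_seq, frag)
      rows[[k]] <- data.frame(seq_id = intervals$seq_id[i],
                              start = intervals$start[i],
                              end = intervals$end[i], copy_id = id,
                              stringsAsFactors = FALSE)
    }
  }
  list(assembly = seq_records(c(assembly$id, new_id),
                              c(assembly$seq, new_seq)),
       truth = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Simulate transcript contigs covering a subset of SSR loci
#'
#' One transcript per chosen locus spanning the tract plus `flank_bp` on
#' each side (truncated with a warning at contig edges); a stated fraction
#' of transcripts receives a gene annotation row.
#'
#' @param genome A single-row [seq_records].
#' @param loci_subset Locus table rows to express.
#' @param flank_bp Flank captured on each side of the tract.
#' @param annotation_fraction Fraction of transcripts annotated.
#' @param seed Integer seed (selects which transcripts are annotated).
#' @return List with `transcripts` ([seq_records]), `annotations` (data
#'   frame `transcript_id`, `gene`) and `truth` (data frame `transcript_id`,
#'   `locus_start`, `locus_end`, `annotated`).
#' @export
simulate_transcripts <- function(genome, loci_subset, flank_bp = 300,
                                 annotation_fraction = 0.5, seed = 1) {
  n <- nchar(genome$seq[1])
  nl <- nrow(loci_subset)
  if (nl == 0)
    return(list(transcripts = seq_records(character(), character()),
                annotations = data.frame(transcript_id = character(),
                                         gene = character(),
                                         stringsAsFactors = FALSE),
                truth = data.frame(transcript_id = character(),
                                   locus_start = integer(),
                                   locus_end = integer(),
                                   annotated = logical(),
                                   stringsAsFactors = FALSE)))
  lo <- pmax(1L, loci_subset$start - flank_bp)
  hi <- pmin(n, loci_subset$end + flank_bp)
  if (any(lo > loci_subset$start - flank_bp) ||
      any(hi < loci_subset$end + flank_bp))
    warning("transcript flank truncated at contig edge")
  ids <- sprintf("tx_%d", seq_len(nl))
  tx <- seq_records(ids, substring(genome$seq[1], lo, hi))
  n_ann <- round(annotation_fraction * nl)
  ann_idx <- with_seed(seed, sample(nl, n_ann))
  annotations <- data.frame(transcript_id = ids[ann_idx],
                            gene = sprintf("gene_%d", sort(ann_idx)),
                            stringsAsFactors = FALSE)
  annotations <- annotations[order(annotations$transcript_id), ,
                             drop = FALSE]
  list(transcripts = tx,
       annotations = annotations,
       truth = data.frame(transcript_id = ids,
                          locus_start = loci_subset$start,
                          locus_end = loci_subset$end,
                          annotated = seq_len(nl) %in% ann_idx,
                          stringsAsFactors = FALSE))
}

#' Simulate whole-genome shotgun reads
#'
#' Uniform start positions, random strand, constant per-base quality
#' consistent with the error rate (Q40 when error-free), and uniform
#' substitution errors.
#'
#' @param genome A single-row [seq_records].
#' @param coverage Target mean coverage (> 0).
#' @param read_len Read length (>= 17).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A [seq_records] of reads with qualities; read count =
#'   `round(coverage * genome_length / read_len)`.
#' @export
simulate_reads <- function(genome, coverage, read_len = 150,
                           error_rate = 0, seed = 1) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (read_len < 17) stop("read_len must be >= 17")
  glen <- nchar(genome$seq[1])
  if (read_len > glen) stop("read_len exceeds genome length")
  n_reads <- round(coverage * glen / read_len)
  q <- if (error_rate <= 0) 40L else
    as.integer(min(40, round(-10 * log10(error_rate))))
  with_seed(seed, {
    starts <- sample.int(glen - read_len + 1L, n_reads, replace = TRUE)
    minus <- sample(c(TRUE, FALSE), n_reads, replace = TRUE)
    reads <- substring(genome$seq[1], starts, starts + read_len - 1L)
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
    if (error_rate > 0) {
      alt <- c(A = "C", C = "G", G = "T", T = "A")
      for (i in seq_len(n_reads)) {
        hit <- which(stats::runif(read_len) < error_rate)
        if (length(hit)) {
          ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
          ch[hit] <- alt[ch[hit]]
          reads[i] <- paste(ch, collapse = "")
        }
      }
    }
    seq_records(sprintf("read_%d", seq_len(n_reads)), reads,
                rep(list(rep(q, read_len)), n_reads))
  })
}

#' Simulate a multi-allelic band-score panel with a ploidy effect
#'
#' Each accession draws allele copies from the marker's allele-frequency
#' profile: diploids draw 2 copies, tetraploids `2 + tetraploid_extra_draws`
#' (so the expected number of distinct alleles per accession is higher in
#' tetraploids; an effect of 0 makes the groups exchangeable). The observed
#' cell is the set of distinct alleles drawn.
#'
#' @param n_diploid,n_tetraploid Accessions per ploidy group (>= 2).
#' @param n_markers Number of markers (>= 2).
#' @param alleles_per_marker Size of each marker's allele universe.
#' @param carriage_model `"equal"` (uniform allele frequencies, default) or
#'   `"dirichlet"` (per-marker frequencies drawn from a symmetric Dirichlet
#'   with parameter `dirichlet_alpha`).
#' @param tetraploid_extra_draws Extra allele draws for tetraploids (the
#'   ploidy effect size; 0 = no effect).
#' @param dirichlet_alpha Dirichlet concentration under
#'   `carriage_model = "dirichlet"`.
#' @param seed Integer seed.
#' @return List with `genotypes` (a [genotype_matrix]) and `truth`
#'   (generating frequencies, draw counts per group, seed).
#' @export
simulate_genotypes <- function(n_diploid = 17, n_tetraploid = 30,
                               n_markers = 37, alleles_per_marker = 3,
                               carriage_model = c("equal", "dirichlet"),
                               tetraploid_extra_draws = 2,
                               dirichlet_alpha = 1, seed = 1) {
  carriage_model <- match.arg(carriage_model)
  if (n_diploid < 2 || n_tetraploid < 2 || n_markers < 2)
    stop("need >= 2 accessions per group and >= 2 markers")
  n_acc <- n_diploid + n_tetraploid
  ploidy <- c(rep("2x", n_diploid), rep("4x", n_tetraploid))
  copies <- ifelse(ploidy == "2x", 2L, 2L + as.integer(tetraploid_extra_draws))
  A <- alleles_per_marker
  with_seed(seed, {
    freqs <- matrix(0, n_markers, A)
    for (m in seq_len(n_markers)) {
      freqs[m, ] <- if (carriage_model == "equal") rep(1 / A, A) else {
        g <- stats::rgamma(A, shape = dirichlet_alpha)
        g / sum(g)
      }
    }
    cells <- matrix(list(), n_acc, n_markers)
    acc_of_draw <- rep(seq_len(n_acc), copies)
    for (m in seq_len(n_markers)) {
      draws <- sample.int(A, sum(copies), replace = TRUE, prob = freqs[m, ])
      sets <- split(draws, acc_of_draw)
      for (i in seq_len(n_acc))
        cells[[i, m]] <- paste0("a", sort(unique(sets[[as.character(i)]])))
    }
    gm <- genotype_matrix(sprintf("acc_%02d", seq_len(n_acc)),
                          sprintf("mk_%02d", seq_len(n_markers)),
                          cells, ploidy)
    list(genotypes = gm,
         truth = list(frequencies = freqs,
                      copies_diploid = 2L,
                      copies_tetraploid = 2L +
                        as.integer(tetraploid_extra_draws),
                      carriage_model = carriage_model, seed = seed))
  })
}
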