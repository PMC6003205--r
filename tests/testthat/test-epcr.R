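test_that("primer sites are found exactly where planted", {
  set.seed(1)
  primer <- random_seq(20)
  bg <- random_seq(3000)
  seq <- paste0(substr(bg, 1, 1000), primer, substr(bg, 1001, 3000))
  db <- seq_records("ctg", seq)
  sites <- find_sites(primer, db)
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$start, 1001L)
  expect_equal(plus$mismatches, 0L)

  expect_equal(nrow(find_sites(random_seq(20), db)), 0L)
})

test_that("site finding equals a sliding-window Hamming oracle", {
  set.seed(2)
  for (rep in 1:25) {
    seq <- random_seq(1500)
    # half the time plant the primer (sometimes on the minus strand)
    primer <- if (rep %% 2 == 0) {
      p <- substr(seq, 700, 719)
      if (rep %% 4 == 0) revcomp_test(p) else p
    } else random_seq(sample(18:20, 1))
    db <- seq_records("s", seq)
    got <- find_sites(primer, db)
    f <- which(oracle_hamming_scan(primer, seq) == 0)
    r <- which(oracle_hamming_scan(revcomp_test(primer), seq) == 0) +
      nchar(primer) - 1L
    expect_setequal(got$start[got$strand == "+"], f)
    expect_setequal(got$start[got$strand == "-"], r)
  }
})

test_that("amplicon enumeration matches the brute-force double scan", {
  set.seed(6)
  policy <- match_policy()
  for (rep in 1:25) {
    seq <- random_seq(2000)
    fwd <- substr(seq, 300, 319)
    rstart <- sample(400:600, 1)
    rev <- revcomp_test(substr(seq, rstart, rstart + 19))
    pair <- data.frame(pair_id = "p", fwd_seq = fwd, rev_seq = rev,
                       stringsAsFactors = FALSE)
    got <- enumerate_amplicons(pair, seq_records("s", seq), policy)
    want <- oracle_amplicons(fwd, rev, seq, policy$amplicon_min_bp,
                             policy$amplicon_max_bp)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_setequal(paste(got$start, got$end),
                      paste(want$start, want$end))
    }
  }
})

test_that("orientation rules: same-strand sites produce no amplicon", {
  set.seed(10)
  core <- random_seq(300)
  fwd <- substr(core, 1, 20)
  inner <- substr(core, 151, 170)           # same strand as fwd
  seq <- paste0(random_seq(100), core, random_seq(100))
  pair <- data.frame(pair_id = "p", fwd_seq = fwd, rev_seq = inner,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_amplicons(pair, seq_records("s", seq))), 0L)
})

test_that("duplicating a region flips unique to multiple", {
  fx <- make_dup_fixture(n_loci = 8, n_dup = 2, seed = 19)
  before <- classify_pairs(fx$pairs, fx$genome)
  expect_true(all(before$classification$classification == "unique"))
  after <- classify_pairs(fx$pairs, fx$assembly)
  cls <- after$classification
  expect_setequal(cls$pair_id[cls$classification == "multiple"], fx$dup_ids)
  expect_equal(cls$n_amplicons[cls$pair_id %in% fx$dup_ids], rep(2L, 2))
  # pairs evaluated against a database lacking their source contig
  other <- seq_records("other", strrep("ACGTT", 400))
  none <- classify_pairs(fx$pairs, other)
  expect_true(all(none$classification$classification == "none"))
})

test_that("n_copies = 3 yields four amplicons for affected pairs", {
  fx <- make_dup_fixture(n_loci = 6, n_dup = 1, seed = 23)
  dup <- fx$pairs[1, ]
  inj <- inject_duplications(fx$genome,
                             data.frame(seq_id = dup$seq_id,
                                        start = dup$fwd_start,
                                        end = dup$rev_end),
                             n_copies = 3)
  amp <- enumerate_amplicons(dup, inj$assembly)
  expect_equal(nrow(amp), 4L)
  # zero intervals leave the classification unchanged
  inj0 <- inject_duplications(fx$genome, data.frame(seq_id = character(),
                                                    start = integer(),
                                                    end = integer()))
  expect_identical(inj0$assembly, fx$genome)
})

test_that("classification is invariant under database record order", {
  fx <- make_dup_fixture(n_loci = 6, n_dup = 2, seed = 31)
  a <- classify_pairs(fx$pairs, fx$assembly)
  shuffled <- fx$assembly[rev(seq_len(nrow(fx$assembly))), ]
  b <- classify_pairs(fx$pairs, shuffled)
  expect_equal(a$classification$classification,
               b$classification$classification)
  expect_equal(a$classification$n_amplicons, b$classification$n_amplicons)
})

test_that("transferability screening obeys planted truth", {
  fx <- make_dup_fixture(n_loci = 8, n_dup = 0, seed = 37)
  retained <- fx$pairs
  # self-transfer: every retained pair maps back onto its own assembly
  self <- transferability_screen(retained, fx$genome)
  expect_equal(self$summary$n_mapped, nrow(retained))

  # a random foreign genome shares no 18-mer: zero mapped
  rnd <- simulate_genome(100000, gc = 0.5, seed = 41, id = "foreign")
  expect_equal(transferability_screen(retained, rnd)$summary$n_mapped, 0L)

  # a foreign genome built from three amplicon regions maps exactly those
  take <- retained[c(1, 3, 5), ]
  frag <- substring(fx$genome$seq, take$fwd_start, take$rev_end)
  foreign <- seq_records(paste0("chr", 1:3),
                         paste0(strrep("GATTACA", 30), frag,
                                strrep("TTAGGCA", 30)))
  tr <- transferability_screen(retained, list(planted = foreign))
  expect_equal(tr$summary$n_mapped, 3L)
  expect_setequal(tr$mapped$pair_id[tr$mapped$mapped], take$pair_id)
})

test_that("GTM policy tolerates a 5'-terminal reverse mismatch, not 3'", {
  fx <- make_dup_fixture(n_loci = 6, n_dup = 0, seed = 43)
  pair <- fx$pairs[1, ]
  amp_region <- substring(fx$genome$seq, pair$fwd_start, pair$rev_end)
  tx_policy <- match_policy(reverse_5prime_mismatch_allowed = TRUE)
  alt <- c(A = "C", C = "G", G = "T", T = "A")

  # exact transcript containing the amplicon: flagged
  tx <- seq_records("tx_exact", paste0("GAT", amp_region, "TTC"))
  g <- gtm_cross_reference(pair, tx, tx_policy)
  expect_equal(g$records$transcript_ids, "tx_exact")

  # reverse primer's 5'-terminal base = last base of the amplicon region
  n <- nchar(amp_region)
  mm5 <- amp_region
  substr(mm5, n, n) <- alt[[substr(mm5, n, n)]]
  g5 <- gtm_cross_reference(pair, seq_records("tx_mm5", mm5), tx_policy)
  expect_equal(g5$summary$n_gtm_pairs, 1L)

  # reverse primer's 3'-terminal base: first base of its annealing site
  mm3 <- amp_region
  pos3 <- n - nchar(pair$rev_seq) + 1L
  substr(mm3, pos3, pos3) <- alt[[substr(mm3, pos3, pos3)]]
  g3 <- gtm_cross_reference(pair, seq_records("tx_mm3", mm3), tx_policy)
  expect_equal(g3$summary$n_gtm_pairs, 0L)

  # the allowance is mandatory for transcript screening
  expect_error(gtm_cross_reference(pair, tx, match_policy()), "mismatch")
})

test_that("GTM records join annotations and tally transcripts and genes", {
  fx <- make_dup_fixture(n_loci = 10, n_dup = 0, seed = 47)
  loci <- fx$fixture$truth$planted
  designed_loci <- loci[paste(loci$seq_id, loci$start, loci$end) %in%
                          paste(fx$pairs$seq_id, fx$pairs$locus_start,
                                fx$pairs$locus_end), ]
  sim <- simulate_transcripts(fx$genome, designed_loci, flank_bp = 300,
                              annotation_fraction = 0.5, seed = 53)
  g <- gtm_cross_reference(fx$pairs, sim$transcripts,
                           annotations = sim$annotations)
  expect_equal(g$summary$n_gtm_pairs, nrow(fx$pairs))
  expect_equal(sum(g$records$is_functional),
               sum(sim$truth$annotated))
  # GTM pairs are a subset of the pairs screened
  expect_true(all(g$records$pair_id %in% fx$pairs$pair_id))
  # unknown transcripts in the annotation table are ignored with a warning
  bad_ann <- rbind(sim$annotations,
                   data.frame(transcript_id = "tx_ghost", gene = "g"))
  expect_warning(gtm_cross_reference(fx$pairs, sim$transcripts,
                                     annotations = bad_ann), "unknown")
})
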