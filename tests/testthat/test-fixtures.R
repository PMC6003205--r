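test_that("genome simulation is seeded, GC-faithful and composable", {
  g1 <- simulate_genome(5000, gc = 0.5, seed = 101)
  g2 <- simulate_genome(5000, gc = 0.5, seed = 101)
  expect_identical(g1$seq, g2$seq)
  expect_false(identical(g1$seq,
                         simulate_genome(5000, gc = 0.5, seed = 102)$seq))

  g <- simulate_genome(100000, gc = 0.5, seed = 103)
  gc <- assembly_stats(g)$gc_fraction
  expect_lt(abs(gc - 0.5), 0.01)

  at <- simulate_genome(2000, gc = 0, seed = 104)
  expect_false(grepl("[CG]", at$seq))
  expect_error(simulate_genome(500, seed = 1), ">= 1000")
})

test_that("planting writes non-extendable tracts with exact truth", {
  g <- simulate_genome(10000, gc = 0.5, seed = 105)
  fx <- plant_ssrs(g, data.frame(motif = "AC", repeat_count = 7,
                                 position = 501))
  got <- fx$truth$planted
  expect_equal(got[, c("start", "end", "motif", "repeat_count")],
               data.frame(start = 501L, end = 514L, motif = "AC",
                          repeat_count = 7L))

  empty <- plant_ssrs(g, data.frame(motif = character(),
                                    repeat_count = integer(),
                                    position = integer()))
  expect_identical(empty$genome$seq, g$seq)

  expect_error(plant_ssrs(g, data.frame(motif = c("AC", "AG"),
                                        repeat_count = c(5, 5),
                                        position = c(100, 105))),
               "overlap")
})

test_that("fifty planted tracts are all recovered and self-check passes", {
  g <- simulate_genome(60000, gc = 0.45, seed = 107)
  spec <- data.frame(motif = rep(c("AC", "AG", "AAT", "AAG", "AGAT"), 10),
                     repeat_count = rep(5:9, 10),
                     position = seq(1000, 59000, length.out = 50))
  fx <- plant_ssrs(g, spec)
  expect_equal(nrow(fx$truth$planted), 50L)
  expect_true(fixture_selfcheck(fx))
  # nothing outside truth: the scan is exactly planted + chance
  rescanned <- find_ssr_loci(fx$genome$seq, fx$genome$id)
  expect_equal(nrow(rescanned),
               nrow(fx$truth$planted) + nrow(fx$truth$chance))
})

test_that("transcript simulation is seeded and links loci to annotations", {
  g <- simulate_genome(30000, gc = 0.5, seed = 109)
  fx <- plant_ssrs(g, data.frame(motif = rep("AAG", 10),
                                 repeat_count = 6,
                                 position = seq(2000, 28000,
                                                length.out = 10)))
  s1 <- simulate_transcripts(fx$genome, fx$truth$planted, seed = 111)
  s2 <- simulate_transcripts(fx$genome, fx$truth$planted, seed = 111)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$annotations, s2$annotations)
  expect_equal(nrow(s1$transcripts), 10L)
  expect_equal(sum(s1$truth$annotated), 5L)
  s0 <- simulate_transcripts(fx$genome, fx$truth$planted[0, ])
  expect_equal(nrow(s0$transcripts), 0L)
})

test_that("read simulation respects count arithmetic and exactness", {
  g <- simulate_genome(10000, gc = 0.5, seed = 113)
  reads <- simulate_reads(g, coverage = 5, read_len = 100, seed = 115)
  expect_equal(nrow(reads), round(5 * 10000 / 100))
  expect_identical(reads$seq,
                   simulate_reads(g, coverage = 5, read_len = 100,
                                  seed = 115)$seq)
  # error-free reads are exact substrings of the genome or its complement
  fwd <- vapply(reads$seq[1:50], grepl, logical(1), x = g$seq,
                fixed = TRUE)
  rev <- vapply(revcomp_test(reads$seq[1:50]), grepl, logical(1),
                x = g$seq, fixed = TRUE)
  expect_true(all(fwd | rev))
  # errors lower the qualities and change bases
  noisy <- simulate_reads(g, coverage = 1, read_len = 100,
                          error_rate = 0.01, seed = 117)
  expect_equal(noisy$qual[[1]][1], 20L)
})

test_that("genotype simulation is seeded with truthful frequencies", {
  s1 <- simulate_genotypes(seed = 119)
  s2 <- simulate_genotypes(seed = 119)
  expect_identical(s1$genotypes$cells, s2$genotypes$cells)
  expect_equal(dim(s1$truth$frequencies), c(37, 3))
  expect_equal(rowSums(s1$truth$frequencies), rep(1, 37))
  expect_equal(s1$truth$copies_tetraploid, 4L)
  dir <- simulate_genotypes(carriage_model = "dirichlet", seed = 121)
  expect_equal(rowSums(dir$truth$frequencies), rep(1, 37))
})
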