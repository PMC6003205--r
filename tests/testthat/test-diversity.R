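test_that("PIC follows the carriage-proportion formula", {
  mono <- replicate(10, "a1", simplify = FALSE)
  expect_equal(pic(mono), 0)

  col <- c(replicate(8, "a1", simplify = FALSE),
           replicate(2, "a2", simplify = FALSE))
  expect_equal(pic(col), 1 - (0.8^2 + 0.2^2))   # 0.32

  # missing accessions are excluded from the denominator
  col_na <- c(col, list(NA_character_))
  expect_equal(pic(col_na), 0.32)
  expect_error(pic(list(NA_character_, NA_character_)), "missing")

  # oracle equality on random small columns (multi-band cells included)
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    col <- lapply(seq_len(n), function(i)
      paste0("a", sample(1:4, sample(1:3, 1))))
    alleles <- unique(unlist(col))
    p <- vapply(alleles, function(a)
      sum(vapply(col, function(v) a %in% v, TRUE)) / n, numeric(1))
    expect_equal(pic(col), 1 - sum(p^2))
  }
})

test_that("overall gene diversity averages normalised marker diversities", {
  cells <- matrix(list(), 4, 2)
  for (i in 1:4) { cells[[i, 1]] <- "a1"; cells[[i, 2]] <- "a1" }
  gm <- genotype_matrix(paste0("x", 1:4), c("m1", "m2"), cells)
  expect_equal(total_gene_diversity(gm), 0)

  cells <- matrix(list(), 4, 1)
  cells[[1, 1]] <- "a1"; cells[[2, 1]] <- "a1"
  cells[[3, 1]] <- "a2"; cells[[4, 1]] <- "a2"
  gm <- genotype_matrix(paste0("x", 1:4), "m1", cells)
  expect_equal(total_gene_diversity(gm), 0.5)

  # recovery of the generating diversity at n = 200
  sim <- simulate_genotypes(n_diploid = 100, n_tetraploid = 100,
                            n_markers = 20, alleles_per_marker = 4,
                            tetraploid_extra_draws = 0, seed = 59)
  expect_lt(abs(total_gene_diversity(sim$genotypes) - 0.75), 0.03)
})

test_that("Nei 1972 distance has its closed forms and degenerate cases", {
  expect_equal(nei72_distance(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(nei72_distance(c(1, 1, 0, 0), c(1, 0, 1, 0)), log(2))
  expect_equal(nei72_distance(c(1, 0), c(0, 1)), Inf)
  expect_equal(nei72_distance(c(1, 0), c(0, 1), "cap", cap = 7), 7)
  expect_error(nei72_distance(c(0, 0), c(1, 0)), "zero")

  # symmetry and overlap monotonicity on 0/1 profiles of fixed marginals
  set.seed(19)
  for (rep in 1:20) {
    x <- as.numeric(sample(c(0, 1), 12, TRUE)); x[1] <- 1
    y <- as.numeric(sample(c(0, 1), 12, TRUE)); y[1] <- 1
    expect_equal(nei72_distance(x, y), nei72_distance(y, x))
  }
  base <- c(1, 1, 1, 0, 0, 0)
  less <- c(1, 1, 0, 1, 0, 0)   # same number of bands, less overlap
  expect_lt(nei72_distance(base, base), nei72_distance(base, less))
})

test_that("UPGMA reproduces hand-computed merges and serialises exactly", {
  d <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d)
  expect_equal(t2$root$height, 0.5)
  expect_equal(write_newick(t2), "(A:0.5,B:0.5);")

  d3 <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$root$height, 3)
  expect_equal(write_newick(t3), "((A:1.0,B:1.0):2.0,C:3.0);")

  coph <- cophenetic_upgma(t3)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 6)
})

test_that("UPGMA recovers ultrametric inputs exactly", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    # build a random ultrametric matrix from a random tree of merges
    labs <- paste0("t", 1:n)
    h <- sort(runif(n - 1, 0.1, 5))
    cl <- as.list(labs)
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    for (k in 1:(n - 1)) {
      ij <- sample(length(cl), 2)
      for (a in cl[[ij[1]]]) for (b in cl[[ij[2]]])
        d[a, b] <- d[b, a] <- 2 * h[k]
      cl[[ij[1]]] <- c(cl[[ij[1]]], cl[[ij[2]]])
      cl[[ij[2]]] <- NULL
    }
    tree <- upgma(d)
    expect_equal(cophenetic_upgma(tree)[labs, labs], d)
  }
})

test_that("UPGMA agrees with average-linkage hclust heights", {
  set.seed(29)
  p <- matrix(runif(7 * 5), 7, dimnames = list(paste0("s", 1:7), NULL))
  d <- as.matrix(dist(p))
  tree <- upgma(d)
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(sort(2 * unique_heights(tree)), sort(hc$height))
})

test_that("UPGMA is invariant under label permutation", {
  set.seed(31)
  p <- matrix(runif(6 * 4), 6, dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(p))
  perm <- sample(6)
  t1 <- upgma(d)
  t2 <- upgma(d[perm, perm])
  expect_equal(cophenetic_upgma(t1)[paste0("s", 1:6), paste0("s", 1:6)],
               cophenetic_upgma(t2)[paste0("s", 1:6), paste0("s", 1:6)])
})

test_that("Newick output round-trips through an independent parser", {
  skip_if_not_installed("ape")
  set.seed(37)
  p <- matrix(runif(6 * 4), 6, dimnames = list(paste0("s", 1:6), NULL))
  d <- as.matrix(dist(p))
  tree <- upgma(d)
  ph <- ape::read.tree(text = write_newick(tree))
  expect_setequal(ph$tip.label, tree$labels)
  coph <- as.matrix(ape::cophenetic.phylo(ph))
  labs <- tree$labels
  expect_equal(coph[labs, labs], cophenetic_upgma(tree)[labs, labs],
               tolerance = 1e-8)
})

test_that("genotype TSV round-trips cells, missing flags and ploidy", {
  sim <- simulate_genotypes(n_diploid = 4, n_tetraploid = 4,
                            n_markers = 5, seed = 61)
  gm <- sim$genotypes
  gm$cells[[2, 3]] <- character(0)      # explicit no-band
  gm$missing[1, 2] <- TRUE; gm$cells[[1, 2]] <- character(0)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(gm, tmp)
  back <- read_genotypes(tmp)
  expect_equal(back$cells, gm$cells)
  expect_equal(back$missing, gm$missing)
  expect_equal(back$ploidy, gm$ploidy)
})

test_that("ploidy report: identical groups give F = 0, oracle F matches", {
  cells <- matrix(list(), 6, 4)
  for (j in 1:4) for (i in 1:6)
    cells[[i, j]] <- paste0("a", seq_len(1 + j %% 3))
  gm <- genotype_matrix(paste0("x", 1:6), paste0("m", 1:4), cells,
                        ploidy = rep(c("2x", "4x"), each = 3))
  rep0 <- ploidy_allele_report(gm)
  expect_equal(rep0$anova_F, 0)
  expect_equal(rep0$anova_p, 1)

  sim <- simulate_genotypes(n_diploid = 8, n_tetraploid = 8,
                            n_markers = 10, tetraploid_extra_draws = 2,
                            seed = 67)
  rp <- ploidy_allele_report(sim$genotypes)
  y <- rp$per_marker$mean_alleles_per_accession
  expect_equal(rp$anova_F, oracle_anova_F(y, rp$per_marker$group),
               tolerance = 1e-9)

  # marker order permutation leaves the test untouched
  gm2 <- sim$genotypes
  perm <- sample(length(gm2$markers))
  gm2$markers <- gm2$markers[perm]
  gm2$cells <- gm2$cells[, perm, drop = FALSE]
  gm2$missing <- gm2$missing[, perm, drop = FALSE]
  rp2 <- ploidy_allele_report(gm2)
  expect_equal(rp2$anova_F, rp$anova_F)
  expect_equal(sort(rp2$group_means), sort(rp$group_means))
})

test_that("tetraploid accessions show the higher allele mean (sign recovery)", {
  sim <- simulate_genotypes(seed = 71)   # panel defaults, effect size 2
  rp <- ploidy_allele_report(sim$genotypes)
  expect_gt(rp$group_means[["4x"]], rp$group_means[["2x"]])
  expect_lt(rp$anova_p, 0.05)
})
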