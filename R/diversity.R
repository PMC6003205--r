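#' Construct a genotype (band-score) matrix
#'
#' Accessions x markers container for dominant band data: each cell holds
#' the set of allele identifiers observed for that accession at that marker
#' (an empty set meaning "no band"), with an explicit marker-level missing
#' flag distinct from "no band".
#'
#' @param accessions Character vector of accession identifiers.
#' @param markers Character vector of marker identifiers.
#' @param cells A list-matrix (accessions x markers) of character vectors of
#'   allele ids; `NA` entries are recorded as missing.
#' @param ploidy Optional per-accession ploidy labels from `{"2x","4x"}`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(accessions, markers, cells, ploidy = NULL) {
  accessions <- as.character(accessions)
  markers <- as.character(markers)
  if (!is.null(ploidy)) {
    ploidy <- as.character(ploidy)
    if (length(ploidy) != length(accessions))
      stop("one ploidy label per accession required")
    if (!all(ploidy %in% c("2x", "4x")))
      stop("ploidy labels must be '2x' or '4x'")
  }
  if (!is.matrix(cells) ||
      nrow(cells) != length(accessions) || ncol(cells) != length(markers))
    stop("`cells` must be an accessions x markers list-matrix")
  missing <- matrix(FALSE, nrow(cells), ncol(cells))
  for (i in seq_len(nrow(cells))) for (j in seq_len(ncol(cells))) {
    v <- cells[[i, j]]
    if (length(v) == 1 && is.na(v)) {
      missing[i, j] <- TRUE
      cells[[i, j]] <- character(0)
    } else cells[[i, j]] <- as.character(v)
  }
  dimnames(cells) <- list(accessions, markers)
  dimnames(missing) <- list(accessions, markers)
  structure(list(accessions = accessions, markers = markers,
                 ploidy = ploidy, cells = cells, missing = missing),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d accessions x %d markers",
              length(x$accessions), length(x$markers)))
  if (!is.null(x$ploidy))
    cat(sprintf(" (%d diploid, %d tetraploid)",
                sum(x$ploidy == "2x"), sum(x$ploidy == "4x")))
  cat(sprintf(", %d missing cells\n", sum(x$missing)))
  invisible(x)
}

#' Write / read a genotype matrix as TSV
#'
#' One row per accession: columns `accession`, `ploidy`, then one column
#' per marker holding a comma-separated allele list (`-` for no band, `NA`
#' for missing).
#'
#' @param gm A `genotype_matrix`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `genotype_matrix` for the
#'   reader.
#' @export
write_genotypes <- function(gm, path) {
  cellstr <- matrix("", length(gm$accessions), length(gm$markers))
  for (i in seq_along(gm$accessions)) for (j in seq_along(gm$markers)) {
    cellstr[i, j] <- if (gm$missing[i, j]) "NA"
      else if (length(gm$cells[[i, j]]) == 0) "-"
      else paste(gm$cells[[i, j]], collapse = ",")
  }
  df <- data.frame(accession = gm$accessions,
                   ploidy = if (is.null(gm$ploidy)) "" else gm$ploidy,
                   cellstr, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("accession", "ploidy", gm$markers)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  markers <- setdiff(names(df), c("accession", "ploidy"))
  cells <- matrix(list(), nrow(df), length(markers))
  for (i in seq_len(nrow(df))) for (j in seq_along(markers)) {
    v <- df[[markers[j]]][i]
    cells[[i, j]] <- if (v == "NA") NA_character_
      else if (v == "-" || v == "") character(0)
      else strsplit(v, ",", fixed = TRUE)[[1]]
  }
  ploidy <- if (all(df$ploidy == "")) NULL else df$ploidy
  genotype_matrix(df$accession, markers, cells, ploidy)
}

#' Polymorphism information content of one marker
#'
#' PIC = 1 - sum(Pi^2) where Pi is the proportion of non-missing accessions
#' carrying allele i. Carriage proportions are used exactly as observed
#' (multi-band accessions contribute to several alleles, so the Pi need not
#' sum to 1 and the value can fall below 0 for strongly multi-allelic
#' columns).
#'
#' @param marker_column List of per-accession allele sets (`NA` = missing).
#' @return The PIC value.
#' @export
pic <- function(marker_column) {
  miss <- vapply(marker_column,
                 function(v) length(v) == 1 && is.na(v), TRUE)
  col <- marker_column[!miss]
  if (length(col) == 0) stop("all accessions missing for this marker")
  alleles <- unique(unlist(col))
  if (length(alleles) == 0) return(1)
  p <- vapply(alleles, function(a)
    mean(vapply(col, function(v) a %in% v, TRUE)), numeric(1))
  1 - sum(p^2)
}

#' Per-marker PIC report
#'
#' @param gm A `genotype_matrix`.
#' @return Data frame `marker`, `n_alleles`, `pic`, `sum_p_gt_1` (flagging
#'   columns whose carriage proportions exceed 1, where PIC can be
#'   negative).
#' @export
pic_report <- function(gm) {
  res <- lapply(seq_along(gm$markers), function(j) {
    column <- lapply(seq_along(gm$accessions), function(i)
      if (gm$missing[i, j]) NA_character_ else gm$cells[[i, j]])
    miss <- vapply(column, function(v) length(v) == 1 && is.na(v), TRUE)
    col <- column[!miss]
    alleles <- unique(unlist(col))
    p <- if (length(alleles) == 0) numeric(0) else
      vapply(alleles, function(a)
        mean(vapply(col, function(v) a %in% v, TRUE)), numeric(1))
    data.frame(marker = gm$markers[j], n_alleles = length(alleles),
               pic = pic(column), sum_p_gt_1 = sum(p) > 1 + 1e-12,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Overall gene diversity H_T
#'
#' Per marker, allele carriage counts are normalised to frequencies summing
#' to one and the marker diversity is 1 - sum(p^2); H_T is the unweighted
#' mean over markers (Nei 1973).
#'
#' @param gm A `genotype_matrix`.
#' @return The overall gene diversity.
#' @export
total_gene_diversity <- function(gm) {
  if (length(gm$markers) == 0) stop("no markers")
  h <- vapply(seq_along(gm$markers), function(j) {
    counts <- table(unlist(gm$cells[, j][!gm$missing[, j]]))
    if (length(counts) == 0) return(0)
    p <- counts / sum(counts)
    1 - sum(p^2)
  }, numeric(1))
  mean(h)
}

#' Nei (1972) genetic distance between two profiles
#'
#' D = -ln( sum(x*y) / sqrt(sum(x^2) * sum(y^2)) ) over two allele-presence
#' (0/1) or allele-frequency profiles on the same ordered allele universe.
#'
#' @param x,y Numeric profiles in `[0, 1]`.
#' @param infinite_policy How to handle zero overlap (identity 0):
#'   `"sentinel"` returns `Inf`, `"cap"` returns `cap`.
#' @param cap Finite distance substituted under the `"cap"` policy.
#' @return The distance (0 for identical profiles).
#' @export
nei72_distance <- function(x, y, infinite_policy = c("sentinel", "cap"),
                           cap = 10) {
  infinite_policy <- match.arg(infinite_policy)
  if (length(x) != length(y)) stop("profiles differ in length")
  if (all(x == 0) || all(y == 0)) stop("all-zero profile")
  j <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  if (j <= 0) {
    return(if (infinite_policy == "sentinel") Inf else cap)
  }
  max(0, -log(min(j, 1)))
}

# 0/1 presence profile of one accession over marker-scoped allele columns
.presence_profiles <- function(gm) {
  universe <- lapply(seq_along(gm$markers), function(j)
    sort(unique(unlist(gm$cells[, j]))))
  cols <- unlist(lapply(seq_along(gm$markers), function(j)
    if (length(universe[[j]]))
      paste(gm$markers[j], universe[[j]], sep = ":") else character(0)))
  prof <- matrix(0, length(gm$accessions), length(cols),
                 dimnames = list(gm$accessions, cols))
  markcol <- rep(seq_along(gm$markers),
                 vapply(universe, length, 1L))
  for (i in seq_along(gm$accessions)) {
    k <- 0
    for (j in seq_along(gm$markers)) {
      nu <- length(universe[[j]])
      if (nu == 0) next
      prof[i, k + seq_len(nu)] <- as.numeric(universe[[j]] %in%
                                               gm$cells[[i, j]])
      k <- k + nu
    }
  }
  list(profiles = prof, marker_of_col = markcol)
}

#' Pairwise Nei 1972 distance matrix between accessions
#'
#' Accession profiles are 0/1 allele-presence vectors over all
#' marker-scoped alleles; markers missing in either accession of a pair are
#' dropped from that comparison (pairwise-complete deletion).
#'
#' @param gm A `genotype_matrix`.
#' @param infinite_policy,cap Passed to [nei72_distance()].
#' @return A symmetric, zero-diagonal distance matrix with accession
#'   dimnames.
#' @export
nei72_matrix <- function(gm, infinite_policy = c("sentinel", "cap"),
                         cap = 10) {
  infinite_policy <- match.arg(infinite_policy)
  pp <- .presence_profiles(gm)
  n <- length(gm$accessions)
  d <- matrix(0, n, n, dimnames = list(gm$accessions, gm$accessions))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    use <- !(pp$marker_of_col %in%
               which(gm$missing[a, ] | gm$missing[b, ]))
    d[a, b] <- d[b, a] <- nei72_distance(pp$profiles[a, use],
                                         pp$profiles[b, use],
                                         infinite_policy, cap)
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Repeatedly merges the closest pair of clusters; the distance from the
#' merged cluster to any other is the size-weighted arithmetic mean of the
#' member distances (unweighted pair-group average), and each internal node
#' sits at half its merge distance. Ties are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled
#' by its smallest leaf).
#'
#' @param d A square symmetric distance matrix with labelled dimnames, or a
#'   `dist` object.
#' @return An object of class `upgma_tree`: a binary merge tree with node
#'   heights; leaves carry the input labels.
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(!is.finite(d)))
    stop("non-finite distances; recompute with infinite_policy = \"cap\"")
  n <- nrow(d)
  if (n < 2) stop("need at least two taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- lapply(labels, function(l) list(label = l, height = 0))
  tag <- labels              # smallest leaf label per active cluster
  size <- rep(1L, n)
  dm <- d
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL
    for (ai in seq_along(active)) for (bi in seq_along(active)) {
      if (bi <= ai) next
      a <- active[ai]; b <- active[bi]
      dist_ab <- dm[a, b]
      pair <- sort(c(tag[a], tag[b]))
      if (is.null(best) || dist_ab < best$d - 1e-12 ||
          (abs(dist_ab - best$d) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(a = a, b = b, d = dist_ab, pair = pair)
      }
    }
    a <- best$a; b <- best$b
    merged <- list(left = nodes[[a]], right = nodes[[b]],
                   height = best$d / 2)
    nodes[[a]] <- merged
    for (k in active) {
      if (k == a || k == b) next
      dm[a, k] <- dm[k, a] <-
        (size[a] * dm[a, k] + size[b] * dm[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    tag[a] <- min(tag[a], tag[b])
    active <- setdiff(active, b)
  }
  structure(list(root = nodes[[active]], labels = sort(labels),
                 n = n), class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("UPGMA tree over %d taxa, root height %.4g\n%s\n",
              x$n, x$root$height, write_newick(x)))
  invisible(x)
}

.fmt_bl <- function(x) {
  s <- sub("0+$", "", sprintf("%.10f", x))
  if (endsWith(s, ".")) s <- paste0(s, "0")
  s
}

.newick_node <- function(node, parent_height) {
  bl <- .fmt_bl(parent_height - node$height)
  if (!is.null(node$label))
    return(paste0(node$label, ":", bl))
  paste0("(", .newick_node(node$left, node$height), ",",
         .newick_node(node$right, node$height), "):", bl)
}

#' Serialise a UPGMA tree as Newick
#'
#' Branch lengths are parent height minus child height, so leaf-to-root
#' path lengths equal node heights (ultrametric).
#'
#' @param tree An `upgma_tree`.
#' @param path Optional file to write to.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  root <- tree$root
  txt <- if (!is.null(root$label)) paste0(root$label, ";")
  else paste0("(", .newick_node(root$left, root$height), ",",
              .newick_node(root$right, root$height), ");")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Cophenetic distances implied by a UPGMA tree
#'
#' The cophenetic distance between two leaves is twice the height of their
#' lowest common ancestor (the merge distance).
#'
#' @param tree An `upgma_tree`.
#' @return A symmetric matrix over the leaf labels.
#' @export
cophenetic_upgma <- function(tree) {
  labs <- tree$labels
  m <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  walk <- function(node) {
    if (!is.null(node$label)) return(node$label)
    l <- walk(node$left); r <- walk(node$right)
    m[l, r] <<- m[r, l] <<- 2 * node$height
    c(l, r)
  }
  walk(tree$root)
  m
}

#' Plot a UPGMA tree
#'
#' Requires the `ape` package.
#'
#' @param x An `upgma_tree`.
#' @param ... Passed to `ape::plot.phylo`.
#' @export
plot.upgma_tree <- function(x, ...) {
  if (!requireNamespace("ape", quietly = TRUE))
    stop("plotting needs the 'ape' package")
  plot(ape::read.tree(text = write_newick(x)), ...)
}

#' Per-ploidy allele statistics and one-way ANOVA
#'
#' For each marker and ploidy group, reports the number of distinct alleles
#' detected in the group and the mean number of alleles per accession; then
#' tests whether the per-marker mean allele count per accession differs
#' between ploidy groups with a standard one-way ANOVA (observations =
#' markers within groups).
#'
#' @param gm A `genotype_matrix` with ploidy labels and >= 2 groups.
#' @param response Which per-marker summary to test:
#'   `"per_accession_mean"` (default; what band patterns show per
#'   accession) or `"group_distinct"` (distinct alleles seen in the whole
#'   group).
#' @return A list of class `ploidy_report`: `per_marker` (data frame
#'   `marker`, `group`, `n_alleles_group`, `mean_alleles_per_accession`),
#'   `group_means`, `anova_F`, `anova_p`.
#' @export
ploidy_allele_report <- function(gm, response = c("per_accession_mean",
                                                  "group_distinct")) {
  response <- match.arg(response)
  if (is.null(gm$ploidy)) stop("genotype matrix has no ploidy labels")
  groups <- sort(unique(gm$ploidy))
  if (length(groups) < 2) stop("need at least two ploidy groups")
  if (length(gm$markers) < 2)
    stop("need at least two markers per group for the ANOVA")
  rows <- list()
  for (g in groups) {
    acc <- which(gm$ploidy == g)
    for (j in seq_along(gm$markers)) {
      obs <- acc[!gm$missing[acc, j]]
      per_acc <- vapply(obs, function(i) length(gm$cells[[i, j]]),
                        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = gm$markers[j], group = g,
        n_alleles_group = length(unique(unlist(gm$cells[obs, j]))),
        mean_alleles_per_accession = mean(per_acc),
        stringsAsFactors = FALSE)
    }
  }
  per_marker <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  y <- if (response == "per_accession_mean")
    per_marker$mean_alleles_per_accession else per_marker$n_alleles_group
  fit <- stats::aov(y ~ factor(per_marker$group))
  s <- summary(fit)[[1]]
  gmeans <- tapply(y, per_marker$group, mean)
  structure(list(per_marker = per_marker,
                 group_means = gmeans,
                 response = response,
                 anova_F = s[["F value"]][1],
                 anova_p = s[["Pr(>F)"]][1]),
            class = "ploidy_report")
}

#' @export
print.ploidy_report <- function(x, ...) {
  cat("Alleles per marker by ploidy group (response:", x$response, ")\n")
  for (g in names(x$group_means))
    cat(sprintf("  %s: mean %.3f\n", g, x$group_means[[g]]))
  cat(sprintf("  one-way ANOVA: F = %.4g, p = %.4g\n",
              x$anova_F, x$anova_p))
  invisible(x)
}
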