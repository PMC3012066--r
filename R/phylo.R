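# Tamura-Nei distances, neighbor-joining with bootstrap and midpoint
# rooting, domain partitioning, clade checks, and a chi-square
# recombination-breakpoint scan.

#' Tamura-Nei (TN93) pairwise distances
#'
#' Closed-form TN93 distances (unequal base frequencies, separate purine
#' and pyrimidine transition classes) between all sequence pairs, with
#' pairwise deletion of gap/N sites by default. Saturated pairs, where the
#' correction's logarithm is undefined, are set to a finite ceiling with a
#' warning rather than left non-finite.
#'
#' @param aln Alignment (see [as_alignment()]).
#' @param deletion `"pairwise"` (default) or `"complete"` site deletion.
#' @param ceiling Distance assigned to saturated pairs (substitutions/site).
#' @return Symmetric numeric matrix of substitutions/site with a zero
#'   diagonal, labelled by sequence id.
#' @export
tn93_distance <- function(aln, deletion = c("pairwise", "complete"),
                          ceiling = 5.0) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  if (nrow(aln) < 2) stop("need at least 2 sequences")
  if (deletion == "complete") {
    keep <- colSums(valid_cells(aln)) == nrow(aln)
    if (!any(keep)) stop("no usable sites after complete deletion")
    aln <- aln[, keep, drop = FALSE]
  }
  db <- ape::as.DNAbin(tolower(aln))
  D <- ape::dist.dna(db, model = "TN93", pairwise.deletion = (deletion == "pairwise"),
                     as.matrix = TRUE)
  bad <- !is.finite(D)
  if (any(bad)) {
    warning(sum(bad[upper.tri(bad)]), " saturated pair(s) set to ceiling ", ceiling)
    D[bad] <- ceiling
  }
  diag(D) <- 0
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler criterion). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit transferred to the sister branch so that path
#' lengths through the parent are preserved as closely as possible.
#'
#' @param D Symmetric distance matrix (or `dist`) with labels.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (nrow(D) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(D)
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the
#' tree with the same builder as the point estimate, and reports the
#' percentage of replicates containing each internal bipartition of the
#' point-estimate tree. Supports are stored in `node.label`.
#'
#' @param aln Alignment.
#' @param builder Function alignment -> `phylo`; default NJ on TN93
#'   distances with the given deletion mode.
#' @param B Number of bootstrap replicates.
#' @param seed Optional RNG seed for reproducible resampling.
#' @param deletion Site-deletion mode for the default builder.
#' @return The point-estimate `phylo` with `node.label` set to bootstrap
#'   percentages (root label empty).
#' @export
bootstrap_support <- function(aln, builder = NULL, B = 500, seed = NULL,
                              deletion = "pairwise") {
  aln <- as_alignment(aln)
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(builder)) {
    builder <- function(a) nj_tree(tn93_distance(a, deletion = deletion))
  }
  point <- builder(aln)
  reps <- vector("list", B)
  L <- ncol(aln)
  for (b in seq_len(B)) {
    reps[[b]] <- builder(aln[, sample.int(L, L, replace = TRUE), drop = FALSE])
  }
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / B, 1)
  point$node.label <- as.character(support)
  point$node.label[1] <- ""   # root of the unrooted representation
  point
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path,
#' keeping any support values attached to the correct bipartitions.
#'
#' @param t A `phylo` tree (>= 2 leaves).
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(t) {
  stopifnot(inherits(t, "phylo"))
  if (length(t$tip.label) < 2) stop("need at least 2 leaves")
  if (length(t$tip.label) == 2) {
    t$root.edge <- 0
    return(t)
  }
  phangorn::midpoint(t, node.labels = "support")
}

#' Split an alignment into named domains
#'
#' Slices the alignment into the named column intervals of a domain
#' partition (for example exon-by-exon, with intron 6 subdivided), for
#' independent per-domain tree building.
#'
#' @param aln Alignment.
#' @param part Data frame with columns `name`, `start`, `end` (1-based
#'   inclusive alignment columns); intervals must lie within the alignment
#'   and not overlap.
#' @return Named list of sub-alignments.
#' @export
partition_by_domains <- function(aln, part) {
  aln <- as_alignment(aln)
  part <- as.data.frame(part)
  if (nrow(part) == 0) return(list())
  if (!all(c("name", "start", "end") %in% names(part))) {
    stop("partition needs columns name, start, end")
  }
  if (any(part$start < 1 | part$end > ncol(aln) | part$start > part$end)) {
    stop("partition interval outside the alignment")
  }
  o <- order(part$start)
  if (nrow(part) > 1 && any(part$start[o][-1] <= part$end[o][-nrow(part)])) {
    stop("partition intervals overlap")
  }
  out <- lapply(seq_len(nrow(part)), function(i) {
    aln[, part$start[i]:part$end[i], drop = FALSE]
  })
  names(out) <- part$name
  out
}

#' Read a BED-like domain partition table
#'
#' Tab-separated `name`, `start`, `end` with 0-based half-open coordinates
#' (the BED convention), converted to the 1-based inclusive columns used
#' internally.
#'
#' @param path Path to the TSV (no header).
#' @return Data frame with `name`, `start`, `end` (1-based inclusive).
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "start", "end"),
                          stringsAsFactors = FALSE)
  data.frame(name = df$name, start = df$start + 1L, end = df$end)
}

#' Do a set of leaves form a clade?
#'
#' Tests whether `labels` is exactly the leaf set of some node of the
#' rooted tree, and reports the support attached to that bipartition when
#' available.
#'
#' @param t A rooted `phylo`, optionally with `node.label` support values.
#' @param labels Character vector of leaf labels (subset of the tips).
#' @return List with `is_clade` (logical) and `support` (numeric or `NA`).
#' @export
clade_by_label_check <- function(t, labels) {
  stopifnot(inherits(t, "phylo"))
  unknown <- setdiff(labels, t$tip.label)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tips <- match(labels, t$tip.label)
  if (length(tips) == 1) {
    return(list(is_clade = TRUE, support = NA_real_))
  }
  node <- ape::getMRCA(t, tips)
  clade_tips <- ape::extract.clade(t, node)$tip.label
  is_clade <- setequal(clade_tips, labels)
  support <- NA_real_
  if (is_clade && !is.null(t$node.label)) {
    lab <- t$node.label[node - length(t$tip.label)]
    s <- suppressWarnings(as.numeric(lab))
    if (length(s) == 1 && !is.na(s)) support <- s
  }
  list(is_clade = is_clade, support = support)
}

# which alignment columns are informative for a bipartition: both sides
# monomorphic (over unambiguous bases) at two distinct states
columns_supporting <- function(aln, side) {
  ok <- valid_cells(aln)
  in_g <- rownames(aln) %in% side
  vapply(seq_len(ncol(aln)), function(j) {
    a <- unique(aln[in_g, j][ok[in_g, j]])
    b <- unique(aln[!in_g, j][ok[!in_g, j]])
    length(a) == 1 && length(b) == 1 && a != b
  }, logical(1))
}

max_split_chisq <- function(pos, type, L) {
  # pos: sorted positions of informative columns; type: 1 or 2
  n1 <- cumsum(type == 1)
  n2 <- cumsum(type == 2)
  T1 <- n1[length(n1)]
  T2 <- n2[length(n2)]
  best <- c(stat = -Inf, split = NA_real_)
  # candidate splits: between consecutive informative columns; the reported
  # split is the midpoint of the uninformative gap (any column inside the
  # gap yields the same table, so the midpoint is the natural point estimate)
  for (k in seq_len(length(pos) - 1)) {
    a <- n1[k]; b <- n2[k]; cc <- T1 - a; d <- T2 - b
    tab <- matrix(c(a, b, cc, d), 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    stat <- if (any(e == 0)) 0 else sum((tab - e)^2 / e)
    if (stat > best["stat"]) {
      best <- c(stat = stat, split = floor((pos[k] + pos[k + 1]) / 2))
    }
  }
  best
}

#' Scan an alignment for a recombination breakpoint
#'
#' Scores every column as supporting one of two candidate leaf bipartitions
#' (a column supports a bipartition when both of its sides are monomorphic
#' at two distinct bases) and finds the split position maximising the
#' 2x2 chi-square statistic of grouping-1 versus grouping-2 support counts
#' to the left and right. Significance is assessed by permuting the order
#' of the informative columns.
#'
#' @param aln Alignment containing the putative recombinant and its
#'   candidate parental clades.
#' @param grouping1,grouping2 Character vectors of leaf labels giving one
#'   side of each candidate bipartition (e.g. recombinant-with-clade-A
#'   versus recombinant-with-clade-B).
#' @param n_perm Number of permutations for the null distribution.
#' @param seed Optional RNG seed.
#' @return A `kir_breakpoint_scan`: list with `breakpoint` (last column of
#'   the left segment), `score` (max chi-square), `p_value`,
#'   `n_informative`, and the per-column support table `profile`.
#' @export
breakpoint_scan <- function(aln, grouping1, grouping2, n_perm = 999,
                            seed = NULL) {
  aln <- as_alignment(aln)
  if (!is.null(seed)) set.seed(seed)
  s1 <- columns_supporting(aln, grouping1)
  s2 <- columns_supporting(aln, grouping2)
  both <- s1 & s2
  s1[both] <- FALSE
  s2[both] <- FALSE
  pos <- which(s1 | s2)
  if (length(pos) == 0) stop("no informative columns for either grouping")
  type <- ifelse(s1[pos], 1L, 2L)
  if (length(pos) < 2 || length(unique(type)) < 2) {
    # all informative sites favour one grouping: no breakpoint signal
    return(structure(list(breakpoint = NA_integer_, score = 0,
                          p_value = 1, n_informative = length(pos),
                          profile = data.frame(column = pos, grouping = type)),
                     class = "kir_breakpoint_scan"))
  }
  obs <- max_split_chisq(pos, type, ncol(aln))
  null_ge <- 0L
  for (p in seq_len(n_perm)) {
    stat <- max_split_chisq(pos, sample(type), ncol(aln))["stat"]
    if (stat >= obs["stat"]) null_ge <- null_ge + 1L
  }
  structure(
    list(breakpoint = as.integer(obs["split"]),
         score = unname(obs["stat"]),
         p_value = (1 + null_ge) / (1 + n_perm),
         n_informative = length(pos),
         profile = data.frame(column = pos, grouping = type)),
    class = "kir_breakpoint_scan"
  )
}

#' @export
print.kir_breakpoint_scan <- function(x, ...) {
  cat(sprintf("breakpoint after column %s (chi-square %.2f, p = %.4f, %d informative sites)\n",
              ifelse(is.na(x$breakpoint), "NA", x$breakpoint),
              x$score, x$p_value, x$n_informative))
  invisible(x)
}
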