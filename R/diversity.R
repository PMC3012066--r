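# Nucleotide diversity (pi) with sampling variance, over whole alignments,
# sliding windows, and annotated gene extracts grouped by motif residence.

VALID_BASES <- c("A", "C", "G", "T")

#' Construct/validate an alignment object
#'
#' Alignments are plain character matrices over {A,C,G,T,-,N}: one row per
#' sequence (rownames are sequence ids), one column per alignment column.
#' Accepts a character matrix, a named character vector of equal-length
#' strings, or an `ape` `DNAbin` matrix.
#'
#' @param x Alignment in any of the accepted forms.
#' @return Character matrix (upper case, `U` converted to `T`).
#' @export
as_alignment <- function(x) {
  if (inherits(x, "DNAbin")) {
    x <- as.character(as.matrix(x))
  }
  if (is.character(x) && !is.matrix(x)) {
    lens <- nchar(x)
    if (length(unique(lens)) != 1) {
      bad <- names(x)[which(lens != lens[1])[1]]
      stop("sequences have unequal lengths (e.g. '", bad, "')")
    }
    x <- do.call(rbind, strsplit(x, ""))
  }
  if (!is.matrix(x) || !is.character(x)) stop("cannot interpret input as an alignment")
  x <- toupper(x)
  x[x == "U"] <- "T"
  unknown <- !(x %in% c(VALID_BASES, "-", "N"))
  if (any(unknown)) {
    warning(sum(unknown), " unknown character(s) converted to N")
    x[unknown] <- "N"
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
  x
}

# logical matrix: which cells are unambiguous bases
valid_cells <- function(aln) {
  matrix(aln %in% VALID_BASES, nrow = nrow(aln), dimnames = dimnames(aln))
}

#' Nucleotide diversity of an alignment
#'
#' Estimates pi, the average number of nucleotide differences per site
#' between two sequences: the mean over all sequence pairs of the
#' proportion of differing sites. Under `"complete"` deletion (default)
#' all columns containing a gap or N are removed first and every pair is
#' compared over the same sites; under `"pairwise"` deletion each pair is
#' compared over the sites where both members are unambiguous.
#'
#' The sampling variance combines the stochastic and sampling components
#' for pi from a sample of n sequences and L sites:
#' \deqn{V(\hat\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}
#'
#' @param aln Alignment (see [as_alignment()]); at least 2 sequences.
#' @param deletion `"complete"` or `"pairwise"` treatment of gaps/Ns.
#' @return A `kir_diversity`: list with `pi`, `variance`, `se`, `n`,
#'   `sites_used` (columns retained under complete deletion; columns usable
#'   in at least one pair under pairwise deletion).
#' @examples
#' aln <- as_alignment(c(a = "AAAA", b = "AAAT"))
#' nucleotide_diversity(aln)$pi
#' @export
nucleotide_diversity <- function(aln, deletion = c("complete", "pairwise")) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  n <- nrow(aln)
  if (n < 2) stop("diversity needs at least 2 sequences")
  ok <- valid_cells(aln)
  npairs <- n * (n - 1) / 2

  if (deletion == "complete") {
    keep <- colSums(ok) == n
    L <- sum(keep)
    if (L == 0) stop("no usable sites after complete deletion")
    sub <- aln[, keep, drop = FALSE]
    # per-column pairwise difference count via base tallies
    tabs <- vapply(VALID_BASES, function(b) colSums(sub == b), numeric(L))
    if (L == 1) tabs <- matrix(tabs, nrow = 1)
    diffs_per_col <- npairs - rowSums(tabs * (tabs - 1) / 2)
    pi <- sum(diffs_per_col) / (npairs * L)
    L_var <- L
    sites_used <- L
  } else {
    ratios <- numeric(0)
    Ls <- numeric(0)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        both <- ok[i, ] & ok[j, ]
        Lij <- sum(both)
        if (Lij == 0) stop("pair (", rownames(aln)[i], ", ", rownames(aln)[j],
                           ") shares no usable sites")
        ratios <- c(ratios, sum(aln[i, both] != aln[j, both]) / Lij)
        Ls <- c(Ls, Lij)
      }
    }
    pi <- mean(ratios)
    L_var <- mean(Ls)
    sites_used <- sum(colSums(ok) >= 2)
  }

  variance <- (n + 1) / (3 * (n - 1) * L_var) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  structure(
    list(pi = pi, variance = variance, se = sqrt(variance),
         n = n, sites_used = sites_used, deletion = deletion),
    class = "kir_diversity"
  )
}

#' @export
print.kir_diversity <- function(x, ...) {
  cat(sprintf("pi = %.5f (SE %.5f), n = %d, sites = %d [%s deletion]\n",
              x$pi, x$se, x$n, x$sites_used, x$deletion))
  invisible(x)
}

#' Sliding-window nucleotide diversity profile
#'
#' Tiles the alignment with windows of `window` columns advanced by `step`
#' columns (a trailing window that would extend past the end is dropped)
#' and computes [nucleotide_diversity()] in each.
#'
#' @inheritParams nucleotide_diversity
#' @param window Window width in alignment columns.
#' @param step Step between window starts, in columns.
#' @return Data frame with `start`, `end`, `midpoint`, `pi`, `se`, `n`,
#'   `sites_used` per window (1-based inclusive columns).
#' @export
sliding_pi <- function(aln, window = 500, step = 100,
                       deletion = c("complete", "pairwise")) {
  aln <- as_alignment(aln)
  deletion <- match.arg(deletion)
  if (window < 1) stop("window must be >= 1")
  L <- ncol(aln)
  if (window > L) stop("window exceeds alignment length")
  starts <- seq(1L, L, by = step)
  starts <- starts[starts + window - 1L <= L]
  rows <- lapply(starts, function(s) {
    d <- nucleotide_diversity(aln[, s:(s + window - 1L), drop = FALSE], deletion)
    data.frame(start = s, end = s + window - 1L,
               midpoint = s + (window - 1) / 2,
               pi = d$pi, se = d$se, n = d$n, sites_used = d$sites_used)
  })
  do.call(rbind, rows)
}

#' Gene annotation for region extraction
#'
#' Coordinates are 1-based inclusive alignment columns (the GFF3
#' convention, used internally throughout).
#'
#' @param gene Gene identifier.
#' @param start_codon Column of the first base of the start codon.
#' @param exons Data frame/matrix with columns `start`, `end`: sorted,
#'   non-overlapping exon intervals.
#' @param polyA Column of the polyadenylation site.
#' @param strand `"+"` or `"-"`.
#' @param truncated Does the annotated sequence end at exon 5 (as for the
#'   3DP1 pseudogene) rather than at a polyadenylation site?
#' @return A `kir_gene_annotation`.
#' @export
kir_gene_annotation <- function(gene, start_codon, exons, polyA,
                                strand = "+", truncated = FALSE) {
  exons <- as.data.frame(exons)
  if (!all(c("start", "end") %in% names(exons))) {
    stop("exons need 'start' and 'end' columns")
  }
  if (nrow(exons) > 1) {
    if (is.unsorted(exons$start) ||
        any(exons$start[-1] <= exons$end[-nrow(exons)])) {
      stop("exons must be sorted and non-overlapping")
    }
  }
  if (any(exons$end < exons$start)) stop("exon end before start")
  if (!is.na(polyA) && start_codon > polyA) stop("start_codon must be <= polyA")
  structure(list(gene = gene, start_codon = as.integer(start_codon),
                 exons = exons, polyA = as.integer(polyA),
                 strand = strand, truncated = isTRUE(truncated)),
            class = "kir_gene_annotation")
}

#' Extract the analysis region of a gene from an alignment
#'
#' Slices the columns from 250 bp upstream of the start codon through the
#' polyadenylation site (inclusive). When the annotation is flagged
#' truncated (3DP1-style sequences, which end naturally at exon 5), the
#' region instead ends at the end of exon 5. If fewer than 250 columns
#' precede the start codon, the extract is clamped to the alignment start
#' with a warning.
#'
#' @param aln Alignment.
#' @param ann A `kir_gene_annotation`.
#' @param upstream Columns to include upstream of the start codon.
#' @return Sub-alignment (character matrix).
#' @export
extract_gene_region <- function(aln, ann, upstream = 250) {
  aln <- as_alignment(aln)
  stopifnot(inherits(ann, "kir_gene_annotation"))
  end <- if (ann$truncated) {
    if (nrow(ann$exons) < 5) stop("truncated gene annotation needs 5 exons")
    ann$exons$end[5]
  } else {
    ann$polyA
  }
  if (end > ncol(aln) || ann$start_codon > ncol(aln) || ann$start_codon < 1) {
    stop("annotation lies outside the alignment")
  }
  start <- ann$start_codon - upstream
  if (start < 1) {
    warning("fewer than ", upstream, " columns upstream of start codon; ",
            "clamping to alignment start")
    start <- 1L
  }
  aln[, start:end, drop = FALSE]
}

#' Summarise per-gene diversity by locus segment group
#'
#' Groups per-gene pi estimates by their segment residence (Cen-A, Cen-B,
#' Tel-A, Tel-B) and reports the arithmetic group means alongside the
#' individual points, the quantities plotted in segment-level diversity
#' comparisons.
#'
#' @param per_gene Named list of `kir_diversity` objects (or named numeric
#'   vector of pi values), one per gene.
#' @param grouping Named character vector mapping every gene to a group.
#' @return List with `means` (named numeric, one per group) and `points`
#'   (named list of per-group named pi vectors).
#' @export
segment_group_summary <- function(per_gene, grouping) {
  pis <- if (is.numeric(per_gene)) per_gene
         else vapply(per_gene, function(d) d$pi, numeric(1))
  genes <- names(pis)
  missing <- setdiff(genes, names(grouping))
  if (length(missing)) {
    stop("no group for gene(s): ", paste(missing, collapse = ", "))
  }
  groups <- unique(unname(grouping[genes]))
  points <- lapply(stats::setNames(groups, groups), function(g) {
    pis[genes[grouping[genes] == g]]
  })
  if (any(vapply(points, length, integer(1)) == 0)) stop("empty group")
  list(means = vapply(points, mean, numeric(1)), points = points)
}
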