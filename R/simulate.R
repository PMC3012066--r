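# Seeded generators: typed cohorts from haplotype frequencies, alignments
# evolved on dated trees under a two-parameter substitution process, mosaic
# recombinants, and the A/B multi-gene diversity fixture.

#' Reference haplotype-frequency vector
#'
#' Pooled haplotype frequencies of the seven gene-content haplotypes plus
#' the unassigned ("other") class in a 384-chromosome multi-ethnic
#' reference panel, derived from the published chromosome counts
#' (232, 45, 10, 34, 28, 13, 2 and 21 "other", normalised to sum to 1).
#'
#' @return Named numeric vector summing to 1 (last element `"other"`).
#' @export
kir_reference_frequencies <- function() {
  counts <- c("cA01|tA01" = 232, "cA01|tB01" = 45, "cB01|tB01" = 10,
              "cB02|tA01" = 34, "cB01|tA01" = 28, "cB02|tB01" = 13,
              "cB03|tA01" = 2, "other" = 21)
  counts / sum(counts)
}

# random gene content for an unregistered haplotype: framework plus a
# random subset of the remaining loci, never equal to a registered
# structure's content
random_other_content <- function(registry) {
  nonfw <- setdiff(registry$loci$locus_id, registry$framework)
  reg_contents <- lapply(registry$structures, function(s) {
    get_structure(registry, s)$gene_content
  })
  repeat {
    content <- c(registry$framework, nonfw[stats::runif(length(nonfw)) < 0.5])
    if (!any(vapply(reg_contents, setequal, logical(1), y = content))) {
      return(sort(content))
    }
  }
}

#' Simulate a gene-content typed cohort
#'
#' Draws 2n chromosomes i.i.d. from a haplotype-frequency vector (which may
#' include an `"other"` class of unregistered haplotypes), computes each
#' individual's typing signature under the assay panel, and retains the
#' true haplotype pair for recovery scoring. An `"other"` chromosome gets a
#' random unregistered gene content; because its gene order is unknown it
#' contributes locus presence but no linking signal.
#'
#' @param n Number of individuals.
#' @param registry A `kir_registry`.
#' @param freqs Named frequency vector over registered structure names,
#'   optionally with a final `"other"` entry; must sum to 1. Defaults to
#'   [kir_reference_frequencies()].
#' @param panel Assay panel used for typing.
#' @param populations Population label per individual (recycled);
#'   default a single pooled population.
#' @param seed Optional RNG seed.
#' @return A `kir_cohort` whose `truth` holds the true name pairs.
#' @export
simulate_cohort <- function(n = 192, registry, freqs = kir_reference_frequencies(),
                            panel = default_assay_panel(registry),
                            populations = "pooled", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n > 0)
  known <- setdiff(names(freqs), "other")
  if (!all(known %in% registry$structures)) {
    stop("frequency vector names must be registered structures (plus 'other')")
  }
  if (abs(sum(freqs) - 1) > 1e-6) stop("frequencies must sum to 1")

  sts <- lapply(stats::setNames(known, known), get_structure, registry = registry)
  contents <- lapply(sts, `[[`, "gene_content")
  links <- lapply(sts, haplotype_links, registry = registry, panel = panel)

  draws <- sample(names(freqs), 2 * n, replace = TRUE, prob = freqs)
  h1 <- draws[seq_len(n) * 2 - 1]
  h2 <- draws[seq_len(n) * 2]
  sigs <- vector("list", n)
  for (i in seq_len(n)) {
    content <- character(0); lk <- character(0)
    for (h in c(h1[i], h2[i])) {
      if (h == "other") {
        content <- union(content, random_other_content(registry))
      } else {
        content <- union(content, contents[[h]])
        lk <- union(lk, links[[h]])
      }
    }
    presence <- stats::setNames(panel$presence %in% content, panel$presence)
    sigs[[i]] <- structure(list(presence = presence, links = sort(lk)),
                           class = "kir_signature")
  }
  kir_cohort(
    id = sprintf("ind%04d", seq_len(n)),
    population = rep_len(populations, n),
    signatures = sigs,
    truth = Map(c, h1, h2)
  )
}

# K2P transition probabilities for a branch of expected d substitutions/site
# with transition/transversion rate ratio kappa: returns c(same, transition,
# each transversion)
k2p_probs <- function(d, kappa) {
  beta <- d / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta)
  e2 <- exp(-2 * (alpha + beta))
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)
}

# evolve integer-coded sequence (1=A,2=C,3=G,4=T) along one branch
evolve_branch <- function(seq, d, kappa) {
  if (d == 0) return(seq)
  p <- k2p_probs(d, kappa)
  ts_partner <- c(3L, 4L, 1L, 2L)
  L <- length(seq)
  u <- stats::runif(L)
  out <- seq
  is_ts <- u >= p["same"] & u < p["same"] + p["ts"]
  is_tv <- u >= p["same"] + p["ts"]
  out[is_ts] <- ts_partner[seq[is_ts]]
  if (any(is_tv)) {
    # pick one of the two transversion targets uniformly
    pick <- stats::runif(sum(is_tv)) < 0.5
    tv1 <- c(2L, 1L, 2L, 1L)  # first transversion partner per state
    tv2 <- c(4L, 3L, 4L, 3L)  # second
    s <- seq[is_tv]
    out[is_tv] <- ifelse(pick, tv1[s], tv2[s])
  }
  out
}

#' Simulate an alignment evolved on a dated tree
#'
#' Evolves sequences site-independently along a rooted tree whose branch
#' lengths are in million years, under a Kimura two-parameter substitution
#' process with per-lineage rate `rate` substitutions/site/My and
#' transition/transversion rate ratio `kappa`. The expected number of
#' substitutions on a branch of b My is `rate * b` per site.
#'
#' @param tree A rooted `phylo` with non-negative branch lengths in My.
#' @param rate Substitution rate (substitutions/site/My, per lineage).
#' @param length Number of sites.
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param base_freq Root base composition (A, C, G, T).
#' @param seed Optional RNG seed.
#' @return List with `alignment` (character matrix, rows = tips) and
#'   `tree` (the input tree).
#' @export
simulate_alignment_on_tree <- function(tree, rate, length, kappa = 2,
                                       base_freq = rep(0.25, 4), seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (rate < 0) stop("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  seqs <- vector("list", nnode)
  seqs[[root]] <- sample.int(4L, length, replace = TRUE, prob = base_freq)
  # preorder: ape trees in cladewise order already list parents before children
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    seqs[[child]] <- evolve_branch(seqs[[parent]], rate * ord$edge.length[e], kappa)
  }
  bases <- c("A", "C", "G", "T")
  aln <- do.call(rbind, lapply(seq_len(ntip), function(i) bases[seqs[[i]]]))
  rownames(aln) <- tree$tip.label
  list(alignment = aln, tree = tree)
}

#' Construct a mosaic (recombinant) sequence
#'
#' Copies alternating segments from two equal-length parent sequences,
#' starting with parent a: a breakpoint at position k means columns up to
#' and including k come from the current parent and the switch happens
#' after column k.
#'
#' @param parent_a,parent_b Character vectors (one element per column) or
#'   single strings of equal length.
#' @param breakpoints Sorted positions (1 <= k < length) after which the
#'   template switches; empty for a clean copy of parent a.
#' @return Character vector of the mosaic sequence.
#' @export
make_mosaic <- function(parent_a, parent_b, breakpoints = integer(0)) {
  if (length(parent_a) == 1 && nchar(parent_a) > 1) parent_a <- strsplit(parent_a, "")[[1]]
  if (length(parent_b) == 1 && nchar(parent_b) > 1) parent_b <- strsplit(parent_b, "")[[1]]
  L <- length(parent_a)
  if (length(parent_b) != L) stop("parents must have equal length")
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE)) stop("breakpoints must be sorted")
    if (any(breakpoints < 1 | breakpoints >= L)) stop("breakpoint out of range")
  }
  bounds <- c(0, breakpoints, L)
  out <- parent_a
  from_a <- TRUE
  for (s in seq_len(length(bounds) - 1)) {
    idx <- (bounds[s] + 1):bounds[s + 1]
    out[idx] <- if (from_a) parent_a[idx] else parent_b[idx]
    from_a <- !from_a
  }
  out
}

#' Simulate the A/B multi-gene diversity fixture
#'
#' Generates one alignment per KIR gene with a specified expected
#' nucleotide diversity, organised into the four segment groups (Cen-A,
#' Cen-B, Tel-A, Tel-B), so that segment-level diversity ranking can be
#' tested against known truth. Each gene's sequences are independent
#' mutated copies of a random ancestor: with per-site mutation probability
#' p, the expected pairwise diversity is approximately 2p, so p is set to
#' half the target diversity.
#'
#' @param genes Named character vector mapping gene name to group; default
#'   a representative assignment of the motif-characteristic genes.
#' @param group_scale Named multiplier per group applied to
#'   `base_divergence` (e.g. `c("Tel-A" = 3)` to triple Tel-A diversity).
#' @param base_divergence Baseline expected pairwise diversity per gene.
#' @param n_per_gene Sequences per gene alignment.
#' @param length Columns per gene alignment.
#' @param seed Optional RNG seed.
#' @return List with `alignments` (named list of character matrices),
#'   `grouping` (gene -> group), `theta` (gene -> expected diversity).
#' @export
simulate_ab_gene_fixture <- function(genes = NULL,
                                     group_scale = c("Cen-A" = 1, "Cen-B" = 1,
                                                     "Tel-A" = 1, "Tel-B" = 1),
                                     base_divergence = 0.005,
                                     n_per_gene = 8, length = 1500,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genes)) {
    genes <- c("2DL3" = "Cen-A", "2DP1" = "Cen-A", "2DL1" = "Cen-A",
               "2DS2" = "Cen-B", "2DL2" = "Cen-B", "2DL5B" = "Cen-B", "2DS5" = "Cen-B",
               "3DL1" = "Tel-A", "2DS4" = "Tel-A",
               "3DS1" = "Tel-B", "2DS1" = "Tel-B", "2DL5A" = "Tel-B")
  }
  if (n_per_gene < 2) stop("need at least 2 sequences per gene")
  miss <- setdiff(unname(genes), names(group_scale))
  if (length(miss)) stop("no scale for group(s): ", paste(miss, collapse = ", "))
  bases <- c("A", "C", "G", "T")
  theta <- base_divergence * group_scale[unname(genes)]
  names(theta) <- names(genes)
  alignments <- lapply(names(genes), function(g) {
    p <- theta[[g]] / 2
    anc <- sample(bases, length, replace = TRUE)
    aln <- do.call(rbind, lapply(seq_len(n_per_gene), function(i) {
      mut <- stats::runif(length) < p
      s <- anc
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(bases, b), 1), character(1))
      }
      s
    }))
    rownames(aln) <- paste0(g, "_", seq_len(n_per_gene))
    aln
  })
  names(alignments) <- names(genes)
  list(alignments = alignments, grouping = genes, theta = theta)
}
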