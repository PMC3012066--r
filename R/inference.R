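# Haplotype-pair deduction from gene-content typing, ambiguity enumeration,
# and EM haplotype-frequency estimation.

#' Default STS-style assay panel
#'
#' Builds the typing panel used throughout: one presence/absence assay per
#' registered locus and one linking (cis) assay per adjacent gene pair
#' within each motif's gene order. Linking assays are allele-alias resolved
#' (an assay spanning 2DS2-2DL2 is distinct from one spanning 3DL3-2DL3).
#'
#' By default no assay crosses the central 3DP1-2DL4 framework junction, so
#' centromeric and telomeric motifs cannot be phased against each other --
#' the origin of the classic cA01|tA01-cB01|tB01 versus cA01|tB01-cB01|tA01
#' ambiguity. Setting `cross_central = TRUE` adds a junction-spanning assay
#' per haplotype (last centromeric gene to first telomeric gene beyond 2DL4),
#' which resolves those ambiguities.
#'
#' @param registry A `kir_registry`.
#' @param cross_central Include linking assays across the central framework?
#' @return A `kir_assay_panel`: list with `presence` (locus ids assayed),
#'   `links` (character vector of `"a>b"` alias-level adjacencies) and
#'   `cross_central`.
#' @export
default_assay_panel <- function(registry, cross_central = FALSE) {
  links <- character(0)
  for (m in registry$motifs) {
    go <- m$gene_order
    if (length(go) >= 2) {
      links <- c(links, paste0(go[-length(go)], ">", go[-1]))
    }
  }
  structure(
    list(
      presence = registry$loci$locus_id,
      links = sort(unique(links)),
      cross_central = isTRUE(cross_central)
    ),
    class = "kir_assay_panel"
  )
}

# links of one haplotype structure under a panel: within-motif adjacencies
# (alias level), plus a junction-spanning link when the panel has one
haplotype_links <- function(registry, st, panel) {
  out <- character(0)
  for (mid in c(st$cen, st$tel)) {
    go <- registry$motifs[[mid]]$gene_order
    if (length(go) >= 2) out <- c(out, paste0(go[-length(go)], ">", go[-1]))
  }
  out <- intersect(out, panel$links)
  if (isTRUE(panel$cross_central)) {
    cen_go <- registry$motifs[[st$cen]]$gene_order
    tel_go <- registry$motifs[[st$tel]]$gene_order
    tel_first <- if (length(tel_go) >= 2) tel_go[2] else tel_go[1]
    out <- c(out, paste0(cen_go[length(cen_go)], ">>", tel_first))
  }
  sort(unique(out))
}

#' Observable typing signature of a haplotype pair
#'
#' Computes the genotype signature an assay panel would report for an
#' individual carrying haplotypes `h1` and `h2` (or a single haplotype):
#' locus presence is the union of the gene contents restricted to assayed
#' loci, and detected links are the union of within-haplotype adjacencies
#' covered by the panel. Presence/absence typing cannot distinguish one from
#' two copies, so homozygotes and hemizygotes share signatures.
#'
#' @param registry A `kir_registry`.
#' @param h1,h2 Structure names or `kir_structure` objects; `h2` may be
#'   `NULL` for a single chromosome.
#' @param panel A `kir_assay_panel`.
#' @return A `kir_signature`: list with `presence` (named logical over
#'   assayed loci) and `links` (sorted character vector).
#' @export
signature_of <- function(registry, h1, h2 = NULL, panel = default_assay_panel(registry)) {
  if (is.character(h1)) h1 <- get_structure(registry, h1)
  if (!is.null(h2) && is.character(h2)) h2 <- get_structure(registry, h2)
  content <- h1$gene_content
  links <- haplotype_links(registry, h1, panel)
  if (!is.null(h2)) {
    content <- union(content, h2$gene_content)
    links <- union(links, haplotype_links(registry, h2, panel))
  }
  presence <- stats::setNames(panel$presence %in% content, panel$presence)
  structure(list(presence = presence, links = sort(links)),
            class = "kir_signature")
}

#' @export
print.kir_signature <- function(x, ...) {
  cat("present:", paste(names(x$presence)[x$presence], collapse = " "), "\n")
  cat("links:  ", paste(x$links, collapse = " "), "\n")
  invisible(x)
}

signature_key <- function(sig) {
  paste(paste(names(sig$presence)[sig$presence], collapse = ","),
        paste(sig$links, collapse = ","), sep = " / ")
}

# all unordered pairs (with replacement) of structure names, lexicographic
unordered_pairs <- function(structures) {
  s <- sort(structures)
  out <- list()
  for (i in seq_along(s)) {
    for (j in i:length(s)) out[[length(out) + 1L]] <- c(s[i], s[j])
  }
  out
}

# signature keys for every unordered pair of candidate structures
pair_signature_keys <- function(registry, panel, structures) {
  sts <- lapply(stats::setNames(structures, structures), get_structure,
                registry = registry)
  pairs <- unordered_pairs(structures)
  keys <- vapply(pairs, function(p) {
    signature_key(signature_of(registry, sts[[p[1]]], sts[[p[2]]], panel))
  }, character(1))
  list(pairs = pairs, keys = keys)
}

#' Haplotype pairs compatible with a typing signature
#'
#' Enumerates all unordered pairs (with replacement) of candidate haplotype
#' structures whose predicted signature under the panel equals the observed
#' one. An empty result flags an "other" genotype carrying at least one
#' haplotype outside the candidate set.
#'
#' @param registry A `kir_registry`.
#' @param sig A `kir_signature`.
#' @param panel A `kir_assay_panel`.
#' @param structures Candidate structure names (default: registered).
#' @return List of length-2 character vectors, lexicographically ordered.
#' @export
compatible_pairs <- function(registry, sig, panel = default_assay_panel(registry),
                             structures = registry$structures) {
  ps <- pair_signature_keys(registry, panel, structures)
  ps$pairs[ps$keys == signature_key(sig)]
}

#' Enumerate signature-collision (ambiguity) classes
#'
#' Exhaustively computes the signature of every unordered pair of candidate
#' structures and reports the classes of two or more pairs sharing one
#' signature: genotypes the panel cannot tell apart. Under the default
#' panel (no cross-central linking) these are cen/tel phase ambiguities.
#'
#' @inheritParams compatible_pairs
#' @return List of classes; each class is a list of haplotype-name pairs,
#'   ordered lexicographically, classes ordered by their first pair.
#' @export
enumerate_ambiguity_classes <- function(registry,
                                        panel = default_assay_panel(registry),
                                        structures = registry$structures) {
  ps <- pair_signature_keys(registry, panel, structures)
  classes <- split(ps$pairs, ps$keys)
  classes <- Filter(function(cl) length(cl) >= 2, classes)
  classes <- lapply(classes, function(cl) {
    cl[order(vapply(cl, paste, character(1), collapse = "-"))]
  })
  first <- vapply(classes, function(cl) paste(cl[[1]], collapse = "-"), character(1))
  unname(classes[order(first)])
}

# ---- cohorts --------------------------------------------------------------

#' Construct a cohort of typed individuals
#'
#' @param id Character vector of unique individual ids.
#' @param population Population label per individual.
#' @param signatures List of `kir_signature`, one per individual.
#' @param truth Optional list of true haplotype-name pairs (simulation).
#' @return A `kir_cohort`.
#' @export
kir_cohort <- function(id, population, signatures, truth = NULL) {
  if (anyDuplicated(id)) stop("individual ids must be unique")
  if (length(id) != length(signatures) || length(id) != length(population)) {
    stop("id, population and signatures must have equal length")
  }
  structure(list(id = as.character(id), population = as.character(population),
                 signatures = signatures, truth = truth),
            class = "kir_cohort")
}

#' @export
print.kir_cohort <- function(x, ...) {
  cat("KIR cohort:", length(x$id), "individuals,",
      length(unique(x$population)), "population(s)\n")
  invisible(x)
}

#' @export
length.kir_cohort <- function(x) length(x$id)

subset_cohort <- function(obs, keep) {
  kir_cohort(obs$id[keep], obs$population[keep], obs$signatures[keep],
             truth = if (is.null(obs$truth)) NULL else obs$truth[keep])
}

# ---- EM -------------------------------------------------------------------

# Candidate pair table for EM. Full-pair matches take precedence; a
# signature matching no full pair is explained as (h, OTHER) for every
# one-sided-compatible h (all of h's loci present and all of h's links
# detected) plus (OTHER, OTHER).
em_candidates <- function(registry, panel, structures, sigs, other_class) {
  ps <- pair_signature_keys(registry, panel, structures)
  pair_idx <- lapply(ps$pairs, function(p) match(p, structures))
  sts <- lapply(stats::setNames(structures, structures), get_structure,
                registry = registry)
  h_presence <- lapply(sts, function(st) {
    intersect(st$gene_content, panel$presence)
  })
  h_links <- lapply(sts, haplotype_links, registry = registry, panel = panel)

  K <- length(structures)
  other <- K + 1L
  keys <- vapply(sigs, signature_key, character(1))
  ukeys <- unique(keys)
  cand <- lapply(ukeys, function(k) {
    hit <- which(ps$keys == k)
    if (length(hit) > 0) {
      return(list(pairs = pair_idx[hit], matched = TRUE))
    }
    if (!other_class) return(list(pairs = list(), matched = FALSE))
    sig <- sigs[[match(k, keys)]]
    present <- names(sig$presence)[sig$presence]
    ok <- vapply(seq_len(K), function(i) {
      all(h_presence[[i]] %in% present) && all(h_links[[i]] %in% sig$links)
    }, logical(1))
    pairs <- lapply(which(ok), function(i) c(i, other))
    pairs[[length(pairs) + 1L]] <- c(other, other)
    list(pairs = pairs, matched = FALSE)
  })
  list(keys = keys, ukeys = ukeys, cand = cand, other = other)
}

#' EM estimation of haplotype frequencies from typed cohorts
#'
#' Maximum-likelihood haplotype frequencies under Hardy-Weinberg random
#' pairing, by expectation-maximisation over the closed set of registered
#' haplotype structures. The E-step distributes each individual over its
#' compatible unordered haplotype pairs with posterior weight proportional
#' to \eqn{2 f_i f_j} (\eqn{i \neq j}) or \eqn{f_i^2}; the M-step counts
#' expected chromosomes. Iteration stops when the log-likelihood improves
#' by less than `tol` or after `max_iter` iterations; the log-likelihood is
#' checked to be non-decreasing at every step.
#'
#' Individuals whose signature matches no pair of registered haplotypes
#' carry at least one unregistered ("other") haplotype. With
#' `other_class = TRUE` (default) an explicit other-frequency class is
#' estimated: such an individual is explained as (h, other) for each
#' registered h whose full presence and linking signature is contained in
#' the observation, or as (other, other). With `other_class = FALSE`
#' unmatched individuals are excluded from the likelihood and only counted.
#'
#' @param obs A `kir_cohort`.
#' @param registry A `kir_registry`.
#' @param panel A `kir_assay_panel`.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param other_class Model unregistered haplotypes as an explicit class?
#' @param structures Candidate structure names (default: registered).
#' @return A `kir_freq_estimate`: list with `freqs` (named, summing to 1;
#'   includes `"other"` when modelled), `loglik` (trace), `iterations`,
#'   `unresolved_chromosomes` (expected number of chromosomes not matching
#'   any registered haplotype), `n_unmatched` (individuals with no full-pair
#'   match), `n_used`, and the settings used.
#' @examples
#' reg <- load_registry()
#' cohort <- simulate_cohort(n = 50, registry = reg, seed = 1)
#' em_estimate(cohort, reg)$freqs
#' @export
em_estimate <- function(obs, registry, panel = default_assay_panel(registry),
                        tol = 1e-8, max_iter = 1000, other_class = TRUE,
                        structures = registry$structures) {
  stopifnot(inherits(obs, "kir_cohort"))
  K <- length(structures)
  cc <- em_candidates(registry, panel, structures, obs$signatures, other_class)

  n_sig <- as.vector(table(factor(cc$keys, levels = cc$ukeys)))
  usable <- vapply(cc$cand, function(x) length(x$pairs) > 0, logical(1))
  n_unmatched <- sum(n_sig[!vapply(cc$cand, `[[`, logical(1), "matched")])
  n_excluded <- sum(n_sig[!usable])
  if (all(!usable)) stop("no individual has a compatible haplotype pair")

  nclass <- if (other_class) K + 1L else K
  class_names <- c(structures, if (other_class) "other")
  f <- rep(1 / nclass, nclass)
  loglik <- numeric(0)
  expected <- numeric(nclass)
  for (iter in seq_len(max_iter)) {
    expected[] <- 0
    ll <- 0
    for (u in which(usable)) {
      pairs <- cc$cand[[u]]$pairs
      w <- vapply(pairs, function(p) {
        if (p[1] == p[2]) f[p[1]]^2 else 2 * f[p[1]] * f[p[2]]
      }, numeric(1))
      tot <- sum(w)
      if (!is.finite(tot) || tot <= 0) stop("non-finite likelihood contribution")
      ll <- ll + n_sig[u] * log(tot)
      post <- w / tot
      for (k in seq_along(pairs)) {
        p <- pairs[[k]]
        expected[p[1]] <- expected[p[1]] + n_sig[u] * post[k]
        expected[p[2]] <- expected[p[2]] + n_sig[u] * post[k]
      }
    }
    if (length(loglik) && ll < loglik[length(loglik)] - 1e-9) {
      stop("EM log-likelihood decreased; this should not happen")
    }
    converged <- length(loglik) && abs(ll - loglik[length(loglik)]) < tol
    loglik <- c(loglik, ll)
    f <- expected / sum(expected)
    if (converged) break
  }

  unresolved <- if (other_class) expected[K + 1L] else 2 * n_excluded
  structure(
    list(
      freqs = stats::setNames(f, class_names),
      loglik = loglik,
      iterations = length(loglik),
      unresolved_chromosomes = unresolved,
      n_unmatched = n_unmatched,
      n_used = length(obs$id) - n_excluded,
      other_class = other_class,
      structures = structures,
      tol = tol
    ),
    class = "kir_freq_estimate"
  )
}

#' @export
print.kir_freq_estimate <- function(x, ...) {
  cat("EM haplotype-frequency estimate (", x$iterations, " iterations)\n", sep = "")
  print(round(x$freqs, 4))
  invisible(x)
}

#' Per-population and pooled haplotype-frequency table
#'
#' Reproduces the layout of a reference-cohort frequency table: one row per
#' haplotype plus an "other" row, estimated chromosome counts per
#' population (frequency times 2n), a pooled total, and pooled percentages
#' rounded to one decimal. Per-population estimates are obtained by running
#' the same EM on each population subset; the pooled column comes from
#' `est` (or a pooled re-fit when `est` is `NULL`).
#'
#' @param est A pooled `kir_freq_estimate`, or `NULL` to fit one.
#' @param obs The `kir_cohort` the estimate came from.
#' @param registry,panel Registry and panel used for estimation.
#' @param ... Further arguments passed to [em_estimate()].
#' @return Data frame with one row per class: per-population counts, `total`
#'   and `percent`.
#' @export
frequency_report <- function(est, obs, registry,
                             panel = default_assay_panel(registry), ...) {
  if (is.null(est)) est <- em_estimate(obs, registry, panel, ...)
  pops <- unique(obs$population)
  classes <- names(est$freqs)
  counts <- sapply(pops, function(p) {
    sub <- subset_cohort(obs, obs$population == p)
    e <- em_estimate(sub, registry, panel,
                     other_class = est$other_class,
                     structures = est$structures, tol = est$tol)
    e$freqs[classes] * 2 * length(sub$id)
  })
  counts <- matrix(counts, nrow = length(classes),
                   dimnames = list(classes, pops))
  total <- est$freqs * 2 * length(obs$id)
  data.frame(
    haplotype = classes,
    counts,
    total = unname(total),
    percent = unname(round(100 * total / sum(total), 1)),
    row.names = NULL,
    check.names = FALSE
  )
}

#' Pool a per-population chromosome-count table
#'
#' Utility for frequency tables given as per-population chromosome counts
#' (possibly fractional): sums across populations and appends the pooled
#' percentage at one-decimal rounding.
#'
#' @param counts Numeric matrix, rows = haplotype classes, columns =
#'   populations.
#' @param total_chromosomes Denominator for the percentages; defaults to
#'   the grand total of `counts`. Give 2n explicitly when the table counts
#'   fewer chromosomes than the cohort carries.
#' @return Data frame with `haplotype`, the input columns, `total`,
#'   `percent`.
#' @examples
#' m <- rbind("cA01|tA01" = c(52, 61, 59, 60), other = c(13, 6, 1, 1))
#' pool_frequency_counts(m)
#' @export
pool_frequency_counts <- function(counts, total_chromosomes = NULL) {
  counts <- as.matrix(counts)
  total <- rowSums(counts)
  if (is.null(total_chromosomes)) total_chromosomes <- sum(total)
  data.frame(
    haplotype = rownames(counts),
    counts,
    total = total,
    percent = round(100 * total / total_chromosomes, 1),
    row.names = NULL,
    check.names = FALSE
  )
}
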