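# Readers/writers shared by all stages: FASTA alignments, GFF3 gene
# annotations, Newick trees, cohort TSVs, and the seeded end-to-end
# pipeline with its JSON manifest.

#' Read a FASTA alignment
#'
#' Reads aligned FASTA, normalises to upper case, converts U to T and any
#' unknown character to N (with a warning). Ragged inputs are rejected
#' naming the offending record.
#'
#' @param path FASTA file path.
#' @return Character matrix alignment (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  seqs <- seqinr::read.fasta(path, forceDNAtolower = FALSE)
  if (length(seqs) == 0) stop("empty FASTA file: ", path)
  strings <- vapply(seqs, paste, character(1), collapse = "")
  as_alignment(stats::setNames(strings, names(seqs)))
}

#' Write a FASTA alignment
#'
#' @param aln Alignment.
#' @param path Output file path.
#' @export
write_alignment <- function(aln, path) {
  aln <- as_alignment(aln)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(c(paste0(">", rownames(aln)[i]),
                 paste(aln[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Expects features of type `start_codon`, `exon` and `polyA_site` on one
#' sequence region, in 1-based inclusive alignment-column coordinates.
#' A `gene` attribute filter selects one gene when the file annotates
#' several.
#'
#' @param path GFF3 file path.
#' @param gene Optional gene id; rows are kept when their attribute string
#'   contains `gene` (required if the file holds several genes).
#' @param truncated Mark the gene as ending at exon 5 (3DP1-style).
#' @return A `kir_gene_annotation`.
#' @export
read_gene_annotation <- function(path, gene = NULL, truncated = FALSE) {
  gff <- ape::read.gff(path)
  if (!is.null(gene)) {
    gff <- gff[grepl(gene, gff$attributes, fixed = TRUE), , drop = FALSE]
    if (nrow(gff) == 0) stop("no features for gene '", gene, "' in ", path)
  } else {
    gene <- "gene"
  }
  sc <- gff[gff$type == "start_codon", , drop = FALSE]
  ex <- gff[gff$type == "exon", , drop = FALSE]
  pa <- gff[gff$type == "polyA_site", , drop = FALSE]
  if (nrow(sc) != 1) stop("need exactly one start_codon feature")
  if (nrow(ex) == 0) stop("need at least one exon feature")
  if (nrow(pa) > 1) stop("at most one polyA_site feature")
  ex <- ex[order(ex$start), ]
  kir_gene_annotation(
    gene = gene,
    start_codon = sc$start[1],
    exons = data.frame(start = ex$start, end = ex$end),
    polyA = if (nrow(pa)) pa$start[1] else NA_integer_,
    strand = as.character(sc$strand[1]),
    truncated = truncated
  )
}

#' Write a tree to Newick
#'
#' Branch lengths are written with 6 significant digits; any `node.label`
#' support values are written as internal-node labels.
#'
#' @param t A `phylo`.
#' @param path Output file path.
#' @export
write_tree <- function(t, path) {
  stopifnot(inherits(t, "phylo"))
  ape::write.tree(t, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return A `phylo`.
#' @export
read_tree <- function(path) {
  ape::read.tree(path)
}

#' Write a cohort to TSV
#'
#' One row per individual: `id`, `population`, a 0/1 column per presence
#' assay (`locus_<id>`) and per linking assay (`link_<a>.<b>`).
#'
#' @param obs A `kir_cohort`.
#' @param path Output file path.
#' @param panel The assay panel defining the columns.
#' @export
write_cohort_tsv <- function(obs, path, panel) {
  pres <- t(vapply(obs$signatures, function(s) as.integer(s$presence),
                   integer(length(panel$presence))))
  colnames(pres) <- paste0("locus_", panel$presence)
  lk <- t(vapply(obs$signatures, function(s) as.integer(panel$links %in% s$links),
                 integer(length(panel$links))))
  colnames(lk) <- paste0("link_", gsub(">", ".", panel$links, fixed = TRUE))
  df <- data.frame(id = obs$id, population = obs$population, pres, lk,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from TSV
#'
#' @param path TSV written by [write_cohort_tsv()] (or by hand in the same
#'   layout).
#' @param panel The assay panel the columns refer to.
#' @return A `kir_cohort`.
#' @export
read_cohort_tsv <- function(path, panel) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  pres_cols <- paste0("locus_", panel$presence)
  link_cols <- paste0("link_", gsub(">", ".", panel$links, fixed = TRUE))
  miss <- setdiff(c("id", "population", pres_cols), names(df))
  if (length(miss)) stop("cohort TSV lacks column(s): ", paste(miss, collapse = ", "))
  link_cols <- intersect(link_cols, names(df))
  sigs <- lapply(seq_len(nrow(df)), function(i) {
    presence <- stats::setNames(as.logical(unlist(df[i, pres_cols])), panel$presence)
    links_on <- panel$links[as.logical(unlist(df[i, link_cols]))]
    structure(list(presence = presence, links = sort(links_on)),
              class = "kir_signature")
  })
  kir_cohort(df$id, df$population, sigs)
}

#' Run the simulate-infer-report pipeline
#'
#' End-to-end seeded run: simulates a typed cohort from a frequency vector,
#' estimates haplotype frequencies by EM, writes the cohort TSV, the
#' frequency table TSV and a JSON manifest recording inputs, seed, package
#' version, parameters and output checksums. Identical configuration and
#' seed give identical outputs.
#'
#' @param config List with optional elements `n` (individuals), `freqs`
#'   (named frequency vector), `registry_path`, `seed`, `outdir`.
#' @return Invisibly, a list with `report`, `estimate`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  n <- if (is.null(config$n)) 192 else config$n
  seed <- if (is.null(config$seed)) 1L else config$seed
  outdir <- if (is.null(config$outdir)) tempfile("kirhaplo_run_") else config$outdir
  if (!is.null(config$registry_path) && !file.exists(config$registry_path)) {
    stop("registry file not found: ", config$registry_path)
  }
  registry <- load_registry(config$registry_path)
  freqs <- if (is.null(config$freqs)) kir_reference_frequencies() else config$freqs
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  panel <- default_assay_panel(registry)

  cohort <- simulate_cohort(n = n, registry = registry, freqs = freqs,
                            panel = panel, seed = seed)
  est <- em_estimate(cohort, registry, panel)
  report <- frequency_report(est, cohort, registry, panel)

  cohort_path <- file.path(outdir, "cohort.tsv")
  report_path <- file.path(outdir, "frequencies.tsv")
  write_cohort_tsv(cohort, cohort_path, panel)
  utils::write.table(report, report_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(
    package = "kirhaplo",
    version = as.character(utils::packageVersion("kirhaplo")),
    seed = seed,
    parameters = list(n = n, freqs = as.list(freqs)),
    outputs = list(
      cohort = unname(tools::md5sum(cohort_path)),
      frequencies = unname(tools::md5sum(report_path))
    )
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(report = report, estimate = est, manifest = manifest,
                 outdir = outdir))
}
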