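#' @keywords internal
"_PACKAGE"

# The four framework loci anchor the locus ends (3DL3, 3DL2) and its centre
# (3DP1-2DL4); every haplotype structure carries all four.
FRAMEWORK_LOCI <- c("3DL3", "3DP1", "2DL4", "3DL2")

#' Load a KIR locus/motif registry
#'
#' Reads a structured registry document (YAML or JSON) describing the KIR
#' loci, their allele-level aliases, the centromeric (Cen) and telomeric
#' (Tel) gene-content motifs, and the known haplotype structures, and
#' validates it. The packaged default registry describes the 13 loci
#' (11 genes, 2 pseudogenes), four Cen motifs (cA01, cB01, cB02, cB03) and
#' two Tel motifs (tA01, tB01), and the seven observed Cen|Tel combinations.
#'
#' Motif gene orders are written at allele-alias resolution where the allele
#' identity defines the motif (cA01 carries 2DL3, cB01 carries 2DL2; both
#' resolve to the single locus 2DL2L3 for gene-content arithmetic).
#'
#' @param path Path to a registry YAML/JSON document. `NULL` loads the
#'   packaged default.
#' @return An object of class `kir_registry`: a list with elements `loci`
#'   (data frame), `aliases` (named character vector alias -> locus),
#'   `motifs` (named list), `structures` (character vector of registered
#'   `cen|tel` names), and `framework`.
#' @examples
#' reg <- load_registry()
#' sum(reg$loci$kind == "gene")   # 11
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kir_registry.yaml", package = "kirhaplo")
  }
  doc <- yaml::read_yaml(path)
  if (is.null(doc$loci) || is.null(doc$motifs)) {
    stop("registry document must contain 'loci:' and 'motifs:' sections")
  }

  loci <- do.call(rbind, lapply(doc$loci, function(l) {
    data.frame(
      locus_id = l$locus_id,
      kind = if (is.null(l$kind)) "gene" else l$kind,
      framework = isTRUE(l$framework),
      stringsAsFactors = FALSE
    )
  }))
  if (anyDuplicated(loci$locus_id)) {
    stop("duplicate locus_id in registry: ",
         paste(unique(loci$locus_id[duplicated(loci$locus_id)]), collapse = ", "))
  }
  if (!setequal(loci$locus_id[loci$framework], FRAMEWORK_LOCI)) {
    stop("framework loci must be exactly {", paste(FRAMEWORK_LOCI, collapse = ", "), "}")
  }

  aliases <- character(0)
  for (l in doc$loci) {
    for (a in l$allele_aliases) {
      if (a %in% names(aliases)) {
        stop("alias '", a, "' mapped to two loci: ", aliases[[a]], " and ", l$locus_id)
      }
      aliases[[a]] <- l$locus_id
    }
  }
  if (any(names(aliases) %in% loci$locus_id)) {
    stop("alias names must not collide with locus_ids")
  }

  motifs <- list()
  for (m in doc$motifs) {
    if (m$motif_id %in% names(motifs)) stop("duplicate motif_id: ", m$motif_id)
    if (!m$side %in% c("Cen", "Tel")) stop("motif side must be Cen or Tel: ", m$motif_id)
    go <- as.character(m$gene_order)
    if (length(go) == 0) stop("motif ", m$motif_id, " has empty gene_order")
    resolved <- vapply(go, function(g) {
      if (g %in% loci$locus_id) g
      else if (g %in% names(aliases)) aliases[[g]]
      else stop("motif ", m$motif_id, " refers to unknown locus/alias '", g, "'")
    }, character(1))
    if (m$side == "Cen" && resolved[1] != "3DL3") {
      stop("Cen motif ", m$motif_id, " must begin with 3DL3")
    }
    if (m$side == "Tel" &&
        (resolved[1] != "2DL4" || resolved[length(resolved)] != "3DL2")) {
      stop("Tel motif ", m$motif_id, " must begin with 2DL4 and end with 3DL2")
    }
    motifs[[m$motif_id]] <- list(
      motif_id = m$motif_id, side = m$side,
      gene_order = go, loci = unname(resolved)
    )
  }

  reg <- structure(
    list(
      loci = loci,
      aliases = aliases,
      motifs = motifs,
      structures = character(0),
      framework = FRAMEWORK_LOCI,
      combos = new.env(parent = emptyenv())
    ),
    class = "kir_registry"
  )
  structures <- if (is.null(doc$structures)) character(0) else unlist(doc$structures)
  for (s in structures) {
    ct <- parse_structure_name(s)
    # validates motif existence and sides
    invisible(compose_structure(reg, ct[1], ct[2]))
  }
  reg$structures <- structures
  reg
}

#' @export
print.kir_registry <- function(x, ...) {
  cat("KIR registry:", nrow(x$loci), "loci (",
      sum(x$loci$kind == "gene"), "genes,",
      sum(x$loci$kind == "pseudogene"), "pseudogenes ),",
      sum(vapply(x$motifs, function(m) m$side == "Cen", logical(1))), "Cen +",
      sum(vapply(x$motifs, function(m) m$side == "Tel", logical(1))),
      "Tel motifs,", length(x$structures), "registered structures\n")
  invisible(x)
}

#' Resolve allele aliases to locus identifiers
#'
#' Maps a vector of locus names and/or allele-level aliases (e.g. `2DL2`,
#' `3DS1`) to canonical locus identifiers (`2DL2L3`, `3DL1S1`).
#'
#' @param registry A `kir_registry`.
#' @param x Character vector of locus ids and/or aliases.
#' @return Character vector of locus ids.
#' @export
resolve_locus <- function(registry, x) {
  vapply(as.character(x), function(g) {
    if (g %in% registry$loci$locus_id) g
    else if (g %in% names(registry$aliases)) registry$aliases[[g]]
    else stop("unknown locus or alias: '", g, "'")
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a `cen|tel` haplotype structure name
#'
#' @param name A structure name such as `"cA01|tA01"`.
#' @return Character vector `c(cen, tel)`.
#' @export
parse_structure_name <- function(name) {
  parts <- strsplit(name, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("not a cen|tel structure name: '", name, "'")
  parts
}

#' Compose a haplotype structure from a Cen and a Tel motif
#'
#' The gene content of the structure is the union of the two motifs' loci
#' plus the four framework loci (3DP1, at the centromeric edge of the central
#' framework, belongs to every structure even where a motif gene order does
#' not list it).
#'
#' @param registry A `kir_registry`.
#' @param cen Id of a Cen-side motif.
#' @param tel Id of a Tel-side motif.
#' @return A `kir_structure`: list with `cen`, `tel`, `name`,
#'   `gene_content` (locus-level) and `gene_order_aliases` (allele-level
#'   entries of both motifs).
#' @examples
#' reg <- load_registry()
#' compose_structure(reg, "cA01", "tA01")$gene_content
#' @export
compose_structure <- function(registry, cen, tel) {
  for (m in c(cen, tel)) {
    if (!m %in% names(registry$motifs)) stop("unknown motif: '", m, "'")
  }
  if (registry$motifs[[cen]]$side != "Cen" || registry$motifs[[tel]]$side != "Tel") {
    stop("side mismatch: need one Cen and one Tel motif, got (",
         registry$motifs[[cen]]$side, ", ", registry$motifs[[tel]]$side, ")")
  }
  content <- unique(c(registry$motifs[[cen]]$loci, registry$motifs[[tel]]$loci,
                      registry$framework))
  structure(
    list(
      cen = cen, tel = tel,
      name = paste0(cen, "|", tel),
      gene_content = sort(content),
      gene_order_aliases = c(registry$motifs[[cen]]$gene_order,
                             registry$motifs[[tel]]$gene_order)
    ),
    class = "kir_structure"
  )
}

#' @export
print.kir_structure <- function(x, ...) {
  cat(x$name, ": ", paste(x$gene_content, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Retrieve a registered haplotype structure by name
#'
#' @param registry A `kir_registry`.
#' @param name Structure name, e.g. `"cB02|tA01"`.
#' @return A `kir_structure`.
#' @export
get_structure <- function(registry, name) {
  ct <- parse_structure_name(name)
  compose_structure(registry, ct[1], ct[2])
}

#' Decompose a gene-content set into matching haplotype structures
#'
#' Finds all registered (cen, tel) motif combinations whose locus-level gene
#' content equals the input set. Input entries may be locus ids or
#' allele-level aliases; where an alias is given (say `2DL2`), motifs
#' requiring a different allele of the same locus (`2DL3`) are excluded, so
#' allele information sharpens the decomposition exactly as in gene-content
#' typing.
#'
#' @param registry A `kir_registry`.
#' @param genes Character vector of loci and/or aliases. Must contain the
#'   four framework loci.
#' @param structures Candidate structure names; defaults to the registered
#'   structures. Use `all_structure_names(registry)` for every Cen x Tel
#'   combination.
#' @return Character vector of matching structure names, sorted.
#' @examples
#' reg <- load_registry()
#' decompose_content(reg, compose_structure(reg, "cA01", "tA01")$gene_content)
#' @export
decompose_content <- function(registry, genes,
                              structures = registry$structures) {
  genes <- as.character(genes)
  loci_in <- unique(resolve_locus(registry, genes))
  if (!all(registry$framework %in% loci_in)) {
    stop("input lacks framework loci: ",
         paste(setdiff(registry$framework, loci_in), collapse = ", "))
  }
  aliases_in <- genes[genes %in% names(registry$aliases)]
  alias_loci <- unname(registry$aliases[aliases_in])

  ok <- vapply(structures, function(s) {
    st <- get_structure(registry, s)
    if (!setequal(st$gene_content, loci_in)) return(FALSE)
    # alias compatibility: for any locus the input constrains at allele level,
    # the structure must not demand an allele absent from the input
    for (entry in st$gene_order_aliases) {
      if (entry %in% names(registry$aliases)) {
        loc <- registry$aliases[[entry]]
        if (loc %in% alias_loci && !entry %in% aliases_in) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  sort(structures[ok])
}

#' All Cen x Tel structure names expressible from registered motifs
#'
#' @param registry A `kir_registry`.
#' @return Character vector of `cen|tel` names (Cen motifs crossed with Tel
#'   motifs), sorted.
#' @export
all_structure_names <- function(registry) {
  cen <- sort(names(Filter(function(m) m$side == "Cen", registry$motifs)))
  tel <- sort(names(Filter(function(m) m$side == "Tel", registry$motifs)))
  sort(as.character(outer(cen, tel, function(a, b) paste0(a, "|", b))))
}

# ---- allele-level nomenclature -------------------------------------------

allele_vector_key <- function(alleles, loci) {
  loci <- sort(loci)
  paste(paste0(loci, "*", vapply(loci, function(l) as.character(alleles[[l]]),
                                 character(1))), collapse = ";")
}

#' Name an allele-level haplotype under the motif nomenclature
#'
#' Assigns (or re-uses) three-digit allele-combination numbers for the
#' centromeric and telomeric motif of a haplotype: the first distinct allele
#' vector registered for a motif gets 001, the next 002, and so on; an
#' identical allele vector always re-uses its number. The full name is
#' `cXnn:mmm|tXnn:mmm`. 3DP1 alleles are counted with the centromeric
#' vector; the remaining framework alleles belong to the motif whose gene
#' order carries them (3DL3 to Cen; 2DL4 and 3DL2 to Tel).
#'
#' Combination numbering is stateful: the registry records every vector it
#' has seen, in registration order.
#'
#' @param registry A `kir_registry`.
#' @param structure A `kir_structure` (or structure name).
#' @param alleles Named list/vector mapping each locus of the structure's
#'   gene content to an allele designation.
#' @return A `kir_allele_haplotype`: list with `structure`, `alleles`,
#'   `cen_combo`, `tel_combo`, `full_name`.
#' @export
name_allele_haplotype <- function(registry, structure, alleles) {
  if (is.character(structure)) structure <- get_structure(registry, structure)
  alleles <- as.list(alleles)
  extra <- setdiff(names(alleles), structure$gene_content)
  if (length(extra)) {
    stop("allele given for locus absent from structure: ",
         paste(extra, collapse = ", "))
  }
  missing <- setdiff(structure$gene_content, names(alleles))
  if (length(missing)) {
    stop("alleles must cover every locus in the structure; missing: ",
         paste(missing, collapse = ", "))
  }
  cen_loci <- unique(c(registry$motifs[[structure$cen]]$loci, "3DP1"))
  tel_loci <- unique(registry$motifs[[structure$tel]]$loci)

  combo_number <- function(motif_id, key) {
    seen <- if (exists(motif_id, envir = registry$combos, inherits = FALSE)) {
      get(motif_id, envir = registry$combos)
    } else character(0)
    idx <- match(key, seen)
    if (is.na(idx)) {
      seen <- c(seen, key)
      assign(motif_id, seen, envir = registry$combos)
      idx <- length(seen)
    }
    sprintf("%03d", idx)
  }
  cen_combo <- combo_number(structure$cen, allele_vector_key(alleles, cen_loci))
  tel_combo <- combo_number(structure$tel, allele_vector_key(alleles, tel_loci))
  structure(
    list(
      structure = structure,
      alleles = alleles,
      cen_combo = cen_combo,
      tel_combo = tel_combo,
      full_name = paste0(structure$cen, ":", cen_combo, "|",
                         structure$tel, ":", tel_combo)
    ),
    class = "kir_allele_haplotype"
  )
}

#' @export
print.kir_allele_haplotype <- function(x, ...) {
  cat(x$full_name, "\n")
  invisible(x)
}

#' Parse an allele-level haplotype name
#'
#' Inverse of the `full_name` produced by [name_allele_haplotype()].
#'
#' @param full_name String like `"cA01:001|tA01:001"`.
#' @return List with `cen`, `cen_combo`, `tel`, `tel_combo`, `structure_name`.
#' @export
parse_allele_name <- function(full_name) {
  parts <- strsplit(full_name, "|", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("not a full allele-haplotype name: ", full_name)
  sp <- lapply(parts, function(p) {
    q <- strsplit(p, ":", fixed = TRUE)[[1]]
    if (length(q) != 2 || !grepl("^[0-9]{3}$", q[2])) {
      stop("malformed motif:combo component: ", p)
    }
    q
  })
  list(cen = sp[[1]][1], cen_combo = sp[[1]][2],
       tel = sp[[2]][1], tel_combo = sp[[2]][2],
       structure_name = paste0(sp[[1]][1], "|", sp[[2]][1]))
}

#' Find haplotypes sharing identical full allele content
#'
#' Groups a panel of allele-level haplotypes by their complete locus->allele
#' vector and returns only the groups of two or more, i.e. haplotypes that
#' are indistinguishable at full allele resolution.
#'
#' @param panel List of `kir_allele_haplotype` objects.
#' @return List of integer vectors (indices into `panel`), ordered by first
#'   occurrence; empty list when all haplotypes are distinct.
#' @export
find_identical_allele_content <- function(panel) {
  if (length(panel) == 0) stop("panel must be non-empty")
  keys <- vapply(panel, function(h) {
    allele_vector_key(h$alleles, names(h$alleles))
  }, character(1))
  groups <- split(seq_along(panel), factor(keys, levels = unique(keys)))
  unname(Filter(function(g) length(g) >= 2, groups))
}
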