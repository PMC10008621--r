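#' Gene-set registry
#'
#' A registry is a named collection of gene sets (character vectors of gene
#' symbols) with a one-line source note per set. It backs both the mutation
#' biomarkers (HRR pathway, chromatin remodeling) and the transcriptomic
#' scoring (housekeeping, immune-cell metagenes, immunotherapy signatures).
#'
#' @param sets named list of character vectors (gene symbols); duplicate
#'   symbols within a set are an error.
#' @param metadata optional named character vector of source notes, one per
#'   set name.
#' @return an object of class `gene_set_registry`.
#' @export
gene_set_registry <- function(sets, metadata = NULL) {
  stopifnot(is.list(sets), length(sets) > 0)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (!is.character(s) || length(s) == 0)
      stop("gene set '", nm, "' must be a non-empty character vector")
    if (anyDuplicated(s))
      stop("gene set '", nm, "' contains duplicate symbols")
  }
  if (is.null(metadata)) metadata <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, metadata = metadata), class = "gene_set_registry")
}

#' Look up a gene set by name
#'
#' @param registry a [gene_set_registry()].
#' @param name set name; unknown names raise an error.
#' @return character vector of gene symbols.
#' @export
get_gene_set <- function(registry, name) {
  stopifnot(inherits(registry, "gene_set_registry"))
  if (!name %in% names(registry$sets))
    stop("unknown gene set: '", name, "'")
  registry$sets[[name]]
}

#' @export
print.gene_set_registry <- function(x, ...) {
  cat("Gene-set registry:", length(x$sets), "sets\n")
  for (nm in names(x$sets))
    cat(sprintf("  %-28s %3d genes\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Default gene sets for the immuno-chemotherapy biomarker pipeline
#'
#' Ships the gene lists the pipeline needs out of the box: the HRR
#' (homologous recombination repair) pathway genes and chromatin-remodeling
#' complex genes used for pathway mutation status; the fixed 7-gene HRD
#' transcriptomic set (ATM, BLM, BRCA1, BRCA2, BRIP1, NBN, RAD51); a
#' housekeeping set for panel normalization; 14 immune-cell metagene sets;
#' and 7 published immunotherapy-response signatures (6-gene IFN-gamma,
#' 18-gene inflamed T cell, 3-gene effector T cell, chemokine, cytolytic
#' activity, cytotoxic T cell, angiogenesis).
#'
#' Immune-cell and signature memberships are representative placeholder
#' lists assembled from the published literature on these panels; users
#' re-analyzing real panel data should replace them (via [read_gmt()]) with
#' the exact memberships of their assay.
#'
#' @return a [gene_set_registry()].
#' @export
default_gene_sets <- function() {
  sets <- list(
    housekeeping = c("ACTB", "GAPDH", "TUBB", "POLR2A", "RPL19", "SDHA",
                     "TBP", "PGK1", "GUSB", "HPRT1"),
    hrr_pathway = c("ATM", "BAP1", "BRCA1", "BRCA2", "PALB2", "BLM",
                    "RECQL4", "BRIP1", "NBN", "RAD51", "CHEK2", "FANCA"),
    chromatin_remodeling = c("ARID1A", "ARID1B", "ARID2", "PBRM1",
                             "SMARCA4", "SMARCB1", "BAP1", "KMT2C",
                             "KMT2D", "SETD2"),
    hrd_transcriptomic = c("ATM", "BLM", "BRCA1", "BRCA2", "BRIP1",
                           "NBN", "RAD51"),
    # 14 immune-cell metagenes (panel-style placeholder memberships)
    t_cells = c("CD3D", "CD3E", "CD3G", "CD6", "SH2D1A", "TRAT1"),
    b_cells = c("CD19", "MS4A1", "CD79A", "CD79B", "BLK"),
    mast_cells = c("TPSAB1", "TPSB2", "CPA3", "MS4A2", "HDC"),
    dendritic_cells = c("CCL13", "CD209", "HSD11B1"),
    macrophages = c("CD68", "CD84", "CD163", "MS4A4A"),
    neutrophils = c("FPR1", "S100A12", "CEACAM3", "FCGR3B"),
    cytotoxic_cells = c("KLRB1", "KLRD1", "KLRK1", "GZMA", "GZMH", "NKG7"),
    exhausted_cd8 = c("LAG3", "PDCD1", "HAVCR2", "CD244", "EOMES"),
    nk_cd56dim = c("KIR2DL3", "KIR3DL1", "KIR3DL2", "IL21R"),
    cd8_t_cells = c("CD8A", "CD8B"),
    cd45 = c("PTPRC"),
    th1_cells = c("TBX21", "IFNG", "IL12RB2", "STAT4"),
    nk_cells = c("NCR1", "XCL1", "XCL2", "SPN"),
    treg_cells = c("FOXP3", "IL2RA", "CTLA4", "IKZF2"),
    # 7 immunotherapy-response signatures
    ifng_6gene = c("IDO1", "CXCL10", "CXCL9", "HLA-DRA", "STAT1", "IFNG"),
    inflamed_t_cell_18gene = c("CCL5", "CD27", "CD274", "CD276", "CD8A",
                               "CMKLR1", "CXCL9", "CXCR6", "HLA-DQA1",
                               "HLA-DRB1", "HLA-E", "IDO1", "LAG3", "NKG7",
                               "PDCD1LG2", "PSMB10", "STAT1", "TIGIT"),
    effector_t_cell_3gene = c("CD8A", "GZMB", "PRF1"),
    chemokine = c("CCL2", "CCL3", "CCL4", "CXCL9", "CXCL10", "CXCL11",
                  "CXCL13"),
    cytolytic_activity = c("GZMA", "PRF1"),
    cytotoxic_t_cell = c("CD8A", "GZMA", "GZMB", "IFNG", "PRF1", "TNF"),
    angiogenesis = c("VEGFA", "VEGFB", "KDR", "FLT1", "ANGPT2", "TEK")
  )
  meta <- setNames(rep("representative placeholder membership; replace for real panel reanalysis",
                       length(sets)), names(sets))
  meta[c("hrr_pathway", "chromatin_remodeling")] <-
    "pathway membership for mutation biomarkers; editable"
  meta["hrd_transcriptomic"] <- "fixed 7-gene HRD transcriptomic set"
  meta["housekeeping"] <- "panel housekeeping genes for normalization"
  gene_set_registry(sets, meta)
}

#' Read gene sets from a GMT file
#'
#' GMT format: one set per line, tab-separated `name`, `description`, then
#' member gene symbols.
#'
#' @param path file path.
#' @return a [gene_set_registry()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list(); meta <- character()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line (need name, description, >=1 gene): ", ln)
    sets[[f[1]]] <- f[-(1:2)]
    meta[f[1]] <- f[2]
  }
  gene_set_registry(sets, meta)
}

#' Write a gene-set registry to a GMT file
#'
#' @param registry a [gene_set_registry()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(registry, path) {
  stopifnot(inherits(registry, "gene_set_registry"))
  lines <- vapply(names(registry$sets), function(nm) {
    paste(c(nm, registry$metadata[[nm]], registry$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
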