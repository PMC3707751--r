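#' Candidate gene panel and outcome signatures
#'
#' A `gene_panel` is an ordered character vector of gene symbols together with
#' the subsets that form the overall-survival (OS) and disease-free-survival
#' (DFS) signatures. The default panel is the 32-gene breast-carcinoma
#' candidate list assembled from recurring members of published expression
#' profiles (plus PGR, included for its established clinical role). The
#' default OS signature is PGR, GABRP, TBC1D9, SLC39A6 and LRBA; the DFS
#' signature additionally carries NAT1.
#'
#' @param genes character vector of unique gene symbols.
#' @param os_signature,dfs_signature character vectors; must be subsets of
#'   `genes`.
#' @return An object of class `gene_panel`: a character vector with
#'   `os_signature` and `dfs_signature` attributes.
#' @examples
#' p <- gene_panel()
#' length(p)            # 32
#' attr(p, "os_signature")
#' @export
gene_panel <- function(genes = survsig_default_genes,
                       os_signature = c("PGR", "GABRP", "TBC1D9", "SLC39A6", "LRBA"),
                       dfs_signature = c("PGR", "NAT1", "GABRP", "TBC1D9", "SLC39A6", "LRBA")) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    stop("duplicate gene symbols in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  for (sig in list(os = os_signature, dfs = dfs_signature)) {
    bad <- setdiff(sig, genes)
    if (length(bad)) stop("signature genes not in panel: ", paste(bad, collapse = ", "))
  }
  structure(genes,
            os_signature = as.character(os_signature),
            dfs_signature = as.character(dfs_signature),
            class = "gene_panel")
}

#' Default 32-gene candidate panel
#'
#' Ordered as in the study's expression summary table.
#' @export
survsig_default_genes <- c(
  "RABEP1", "PGR", "NAT1", "PTP4A2", "SLC39A6", "ESR1", "EVL", "TBC1D9",
  "FUT8", "SCUBE2", "GATA3", "MELK", "TCEAL1", "XBP1", "PLK1", "IL6ST",
  "DSC2", "CX3CL1", "ATAD2", "BUB1", "CENPA", "CKS2", "GABRP", "GMPS",
  "LRBA", "MAPRE2", "MCM6", "PFKP", "ST8SIA1", "TPBG", "TRIM29", "YBX1"
)

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel:", length(x), "genes\n")
  cat(strwrap(paste(unclass(x), collapse = ", "), width = 70, prefix = "  "), sep = "\n")
  cat("OS signature: ", paste(attr(x, "os_signature"), collapse = ", "), "\n")
  cat("DFS signature:", paste(attr(x, "dfs_signature"), collapse = ", "), "\n")
  invisible(x)
}
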