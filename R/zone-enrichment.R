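## Meristem-vs-differentiation enrichment of gene expression from a zonated
## RNA-seq table (zone x gene FPKM). Expression is transformed as
## log10(3 x FPKM) with FPKM floored at 1/3 so that zero-FPKM genes map to
## a transformed value of 0; the enrichment score of a gene is the mean
## transformed meristem expression divided by the mean transformed
## differentiation-zone expression. Both the log base and the floor, and a
## raw-FPKM-ratio mode, are exposed because the transform choice is
## material to the score.

.ZONES <- c("meristem", "elongation", "differentiation")

#' Transform FPKM for enrichment scoring
#'
#' `log(3 * max(fpkm, floor), base)`; with the default floor of 1/3 the
#' transformed floor is exactly 0.
#'
#' @param fpkm non-negative FPKM value(s)
#' @param floorFpkm lower floor applied before the transform (default 1/3)
#' @param base logarithm base (default 10)
#' @return transformed expression value(s)
#' @examples
#' transformExpression(c(0, 1/3, 10/3))  # 0, 0, 1
#' @export
transformExpression <- function(fpkm, floorFpkm = 1 / 3, base = 10) {
    if (any(fpkm < 0)) stop("FPKM must be non-negative")
    log(3 * pmax(fpkm, floorFpkm), base = base)
}

#' Read a zone x gene expression table
#'
#' @param path delimited text file with header columns `gene_id`, `zone`,
#'   `replicate`, `fpkm`
#' @param sep field separator (default auto: tab or comma by extension)
#' @return validated data.frame
#' @export
readZoneExpression <- function(path, sep = NULL) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    need <- c("gene_id", "zone", "replicate", "fpkm")
    if (!all(need %in% names(tab)))
        stop("expression table must have columns: ",
             paste(need, collapse = ", "))
    bad <- setdiff(unique(tab$zone), .ZONES)
    if (length(bad))
        stop("unknown zone label(s): ", paste(bad, collapse = ", "),
             " (expected ", paste(.ZONES, collapse = "/"), ")")
    if (any(tab$fpkm < 0)) stop("FPKM must be non-negative")
    if (anyDuplicated(tab[c("gene_id", "zone", "replicate")]))
        stop("duplicate (gene_id, zone, replicate) rows")
    tab
}

#' Meristem enrichment score of genes
#'
#' For each requested gene, averages the (transformed) expression over
#' replicates within the meristem and within the differentiation zone and
#' reports the ratio meristem / differentiation.
#'
#' @param table a zone x gene expression data.frame
#'   (see [readZoneExpression()])
#' @param genes character vector of gene ids (default: all genes in the
#'   table)
#' @param transform `"log3fpkm"` (default; see [transformExpression()]) or
#'   `"raw"` for a ratio of raw FPKM means
#' @param floorFpkm,base passed to [transformExpression()]
#' @return data.frame with columns `gene_id`, `meristem_expr`,
#'   `differentiation_expr`, `enrichment`, `undefined` (TRUE where the
#'   differentiation mean is zero and the ratio is undefined, reported NA)
#' @export
zoneEnrichment <- function(table, genes = NULL,
                           transform = c("log3fpkm", "raw"),
                           floorFpkm = 1 / 3, base = 10) {
    transform <- match.arg(transform)
    if (is.null(genes)) genes <- unique(table$gene_id)
    out <- lapply(genes, function(g) {
        sub <- table[table$gene_id == g, ]
        mer <- sub$fpkm[sub$zone == "meristem"]
        dif <- sub$fpkm[sub$zone == "differentiation"]
        if (!length(mer) || !length(dif))
            stop("gene '", g, "' missing in the ",
                 if (!length(mer)) "meristem" else "differentiation",
                 " zone")
        if (transform == "log3fpkm") {
            mer <- transformExpression(mer, floorFpkm, base)
            dif <- transformExpression(dif, floorFpkm, base)
        }
        m <- mean(mer); d <- mean(dif)
        und <- d == 0
        data.frame(gene_id = g, meristem_expr = m,
                   differentiation_expr = d,
                   enrichment = if (und) NA_real_ else m / d,
                   undefined = und, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}
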