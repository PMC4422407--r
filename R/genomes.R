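#' The study genome set
#'
#' An ordered set of genome codes with one designated reference genome.
#' The default is the nine-species panel spanning yeast to human used
#' throughout the package: Saccharomyces cerevisiae (sce),
#' Schizosaccharomyces pombe (spo), Caenorhabditis elegans (cel),
#' Drosophila melanogaster (dme), Danio rerio (dre), Canis familiaris
#' (cfa), Mus musculus (mmu), Pan troglodytes (ptr) and Homo sapiens
#' (hsa), with human as the reference.
#'
#' @param codes Character vector of genome codes, ordered.
#' @param reference Reference genome code; must be an element of `codes`.
#' @return An object of class `genome_set`.
#' @examples
#' g <- genome_set()
#' g$reference  # "hsa"
#' @export
genome_set <- function(codes = c("sce", "spo", "cel", "dme", "dre",
                                 "cfa", "mmu", "ptr", "hsa"),
                       reference = "hsa") {
  codes <- as.character(codes)
  if (anyDuplicated(codes))
    stop("genome codes must be unique")
  if (!reference %in% codes)
    stop("reference genome '", reference, "' is not in the genome set")
  structure(list(codes = codes, reference = reference),
            class = "genome_set")
}

#' @export
print.genome_set <- function(x, ...) {
  cat("<genome_set> ", paste(x$codes, collapse = ", "),
      " (reference: ", x$reference, ")\n", sep = "")
  invisible(x)
}

# Non-reference genome codes, in set order.
.nonref_codes <- function(genomes) {
  setdiff(genomes$codes, genomes$reference)
}

# Recycle a scalar probability to a named per-genome vector over the
# non-reference genomes (or all genomes if ref = FALSE not needed).
.per_genome <- function(x, genomes, what = "probability") {
  codes <- .nonref_codes(genomes)
  if (length(x) == 1L && is.null(names(x)))
    x <- stats::setNames(rep(as.numeric(x), length(codes)), codes)
  if (is.null(names(x)) || !all(codes %in% names(x)))
    stop(what, " must be a scalar or named by the non-reference genome codes")
  x <- x[codes]
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " values must lie in [0, 1]")
  x
}
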