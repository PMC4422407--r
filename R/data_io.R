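# Readers and writers for the pipeline's tables and alignment files.
# All residue positions are 1-based on ungapped sequences; alignment
# columns are 1-based. The only gap character is "-"; "." is normalized
# to "-" on read. Sequences are upper-cased on read.

#' Construct an ortholog family
#'
#' An ortholog family is one ortholog cluster: a set of proteins from the
#' study genomes together with one multiple sequence alignment. A genome
#' may contribute several members (in-paralogs); all are kept.
#'
#' @param cluster_id Cluster label.
#' @param genome Character vector of genome codes, one per member.
#' @param protein_id Character vector of member protein ids.
#' @param rows Character vector of aligned rows (equal lengths, gaps `-`).
#' @return An object of class `ortholog_family`.
#' @export
ortholog_family <- function(cluster_id, genome, protein_id, rows) {
  stopifnot(length(genome) == length(protein_id),
            length(genome) == length(rows))
  if (length(rows) == 0L)
    stop("ortholog family '", cluster_id, "' has no members")
  w <- unique(nchar(rows))
  if (length(w) != 1L)
    stop("malformed alignment in family '", cluster_id,
         "': rows have unequal lengths (", paste(w, collapse = ", "), ")")
  structure(list(cluster_id = as.character(cluster_id),
                 genome = as.character(genome),
                 protein_id = as.character(protein_id),
                 rows = toupper(chartr(".", "-", rows)),
                 width = w),
            class = "ortholog_family")
}

#' @export
print.ortholog_family <- function(x, ...) {
  cat("<ortholog_family> ", x$cluster_id, ": ", length(x$rows),
      " members over ", length(unique(x$genome)), " genomes, ",
      x$width, " columns\n", sep = "")
  invisible(x)
}

#' Read per-cluster multiple alignments from aligned FASTA
#'
#' Each file holds the alignment of one ortholog cluster (the cluster id
#' is the file stem). Sequence headers carry `genome_code|protein_id`
#' (configurable delimiter); anything after the first whitespace is
#' ignored. Members with genome codes outside `genomes` are skipped with
#' a warning. Rows of unequal length raise a malformed-alignment error
#' naming the file.
#'
#' @param paths Character vector of aligned-FASTA file paths.
#' @param genomes A [genome_set()].
#' @param delim Delimiter between genome code and protein id in headers.
#' @return A named list of [ortholog_family()] objects (names are
#'   cluster ids).
#' @export
read_alignment_families <- function(paths, genomes = genome_set(),
                                    delim = "|") {
  fams <- lapply(paths, function(path) {
    aa <- Biostrings::readAAStringSet(path)
    if (length(aa) == 0L)
      stop("empty alignment file: ", path)
    ids <- sub("\\s.*$", "", names(aa))
    parts <- strsplit(ids, delim, fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad))
      stop("header '", ids[bad][[1L]], "' in ", path,
           " lacks the '", delim, "' genome/protein delimiter")
    genome <- vapply(parts, `[[`, character(1L), 1L)
    protein <- vapply(parts, function(p) paste(p[-1L], collapse = delim),
                      character(1L))
    keep <- genome %in% genomes$codes
    if (!all(keep)) {
      warning("skipping ", sum(!keep), " member(s) with unknown genome ",
              "code(s) [", paste(unique(genome[!keep]), collapse = ", "),
              "] in ", path)
      if (!any(keep))
        stop("no members with known genome codes in ", path)
    }
    rows <- unname(as.character(aa)[keep])
    w <- unique(nchar(rows))
    if (length(w) != 1L)
      stop("malformed alignment in ", path, ": rows have unequal lengths")
    ortholog_family(tools::file_path_sans_ext(basename(path)),
                    genome[keep], protein[keep], rows)
  })
  names(fams) <- vapply(fams, `[[`, character(1L), "cluster_id")
  fams
}

#' Write one ortholog family as aligned FASTA
#'
#' Headers are `genome|protein_id`. The inverse of
#' [read_alignment_families()] for a single cluster.
#'
#' @param family An [ortholog_family()].
#' @param path Output file path.
#' @param delim Header delimiter.
#' @return `path`, invisibly.
#' @export
write_alignment_family <- function(family, path, delim = "|") {
  stopifnot(inherits(family, "ortholog_family"))
  aa <- Biostrings::AAStringSet(family$rows)
  names(aa) <- paste(family$genome, family$protein_id, sep = delim)
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

# Deterministic TSV writer: fixed column order, fixed row sort, numeric
# columns formatted to 6 significant digits. Same input, same bytes.
.write_tsv <- function(df, path, sort_by = names(df)) {
  stopifnot(is.data.frame(df))
  if (nrow(df) > 0L && length(sort_by)) {
    ord <- do.call(order, unname(df[sort_by]))
    df <- df[ord, , drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 6L, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_tsv <- function(path, required, what) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a phosphosite table
#'
#' TSV with mandatory header `protein_id`, `position`, `residue`,
#' `status`. Positions are 1-based on the ungapped protein sequence;
#' residues must be S, T or Y; status is `known` or `potential`.
#'
#' @param path TSV file path.
#' @return data.frame with typed, validated columns.
#' @export
read_site_table <- function(path) {
  df <- .read_tsv(path, c("protein_id", "position", "residue", "status"),
                  "phosphosite")
  pos <- suppressWarnings(as.integer(df$position))
  if (anyNA(pos) || any(pos != as.numeric(df$position)))
    stop("non-integer position in site table ", path)
  if (any(pos < 1L))
    stop("positions must be >= 1 in site table ", path)
  residue <- toupper(df$residue)
  if (!all(residue %in% .ACCEPTOR_RESIDUES))
    stop("residue outside {S, T, Y} in site table ", path)
  status <- tolower(df$status)
  if (!all(status %in% c("known", "potential")))
    stop("status outside {known, potential} in site table ", path)
  data.frame(protein_id = as.character(df$protein_id), position = pos,
             residue = residue, status = status, stringsAsFactors = FALSE)
}

#' Write a phosphosite table
#'
#' Deterministic inverse of [read_site_table()]: rows sorted by protein,
#' position and status.
#'
#' @param sites data.frame with columns `protein_id`, `position`,
#'   `residue`, `status`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  .write_tsv(sites[c("protein_id", "position", "residue", "status")], path,
             sort_by = c("protein_id", "position", "status"))
}

#' Read a motif table
#'
#' TSV with header `motif_id`, `pattern` and optional `acceptor_index`
#' (0-based override of the acceptor position).
#'
#' @param path TSV file path.
#' @return Named list of `motif_pattern` objects.
#' @export
read_motif_table <- function(path) {
  df <- .read_tsv(path, c("motif_id", "pattern"), "motif")
  has_idx <- "acceptor_index" %in% names(df)
  pats <- lapply(seq_len(nrow(df)), function(i) {
    idx <- NULL
    if (has_idx && !is.na(df$acceptor_index[[i]]) &&
        nzchar(as.character(df$acceptor_index[[i]])))
      idx <- as.integer(df$acceptor_index[[i]])
    parse_motif_pattern(df$pattern[[i]], as.character(df$motif_id[[i]]), idx)
  })
  names(pats) <- as.character(df$motif_id)
  if (anyDuplicated(names(pats)))
    stop("duplicate motif_id in motif table ", path)
  pats
}

#' Write a motif table
#'
#' @param patterns Named list of `motif_pattern` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(patterns, path) {
  df <- data.frame(
    motif_id = vapply(patterns, `[[`, character(1L), "motif_id"),
    pattern = vapply(patterns, `[[`, character(1L), "raw"),
    acceptor_index = vapply(patterns, `[[`, integer(1L), "acceptor_offset"),
    stringsAsFactors = FALSE
  )
  .write_tsv(df, path, sort_by = "motif_id")
}

#' Read a kinase classification table
#'
#' TSV with header `kinase_id`, `group`, `family`, followed by one 0/1
#' presence column per genome code (ortholog presence flags).
#'
#' @param path TSV file path.
#' @param genomes A [genome_set()]; presence columns are required for all
#'   of its codes.
#' @return data.frame with logical presence columns.
#' @export
read_kinase_table <- function(path, genomes = genome_set()) {
  df <- .read_tsv(path, c("kinase_id", "group", "family", genomes$codes),
                  "kinase")
  if (any(!nzchar(df$group)))
    stop("empty kinase group label in ", path)
  for (g in genomes$codes)
    df[[g]] <- as.logical(as.integer(df[[g]]))
  df
}

#' Read a kinase-substrate edge table
#'
#' TSV with header `kinase_id`, `protein_id`, `position`, `residue`:
#' site-level kinase-substrate relationships.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_kinase_substrate_edges <- function(path) {
  df <- .read_tsv(path, c("kinase_id", "protein_id", "position", "residue"),
                  "kinase-substrate edge")
  df$position <- as.integer(df$position)
  df$residue <- toupper(df$residue)
  df
}

#' Read an undirected protein-interaction edge list
#'
#' TSV with header `protein_a`, `protein_b` and optional `source`.
#' Self-loops are dropped and duplicate undirected pairs collapsed.
#'
#' @param path TSV file path.
#' @return data.frame with normalized (`protein_a` <= `protein_b`) unique
#'   undirected edges.
#' @export
read_interaction_edges <- function(path) {
  df <- .read_tsv(path, c("protein_a", "protein_b"), "interaction")
  a <- as.character(df$protein_a)
  b <- as.character(df$protein_b)
  keep <- a != b
  a2 <- pmin(a[keep], b[keep])
  b2 <- pmax(a[keep], b[keep])
  out <- unique(data.frame(protein_a = a2, protein_b = b2,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Read a protein-to-term annotation table
#'
#' TSV with header `protein_id`, `term` (pre-propagated annotations are
#' taken as given).
#'
#' @param path TSV file path.
#' @return data.frame with unique (protein, term) rows.
#' @export
read_annotation_table <- function(path) {
  df <- .read_tsv(path, c("protein_id", "term"), "annotation")
  unique(data.frame(protein_id = as.character(df$protein_id),
                    term = as.character(df$term), stringsAsFactors = FALSE))
}

#' Recover a member's ungapped sequence from an ortholog family
#'
#' @param family An [ortholog_family()].
#' @param protein_id Member protein id.
#' @return Ungapped residue string.
#' @export
ungapped_sequence <- function(family, protein_id) {
  i <- match(protein_id, family$protein_id)
  if (is.na(i))
    stop("protein '", protein_id, "' not in family '", family$cluster_id, "'")
  gsub("-", "", family$rows[[i]], fixed = TRUE)
}
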