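# Conservation core: project human phosphosites through ortholog-cluster
# alignments, call per-genome motif conservation, and compute conservation
# rates C_q, reference rates R_q and the conservation index
# CI = sum over genomes q of (C_q - R_q).
#
# Conventions (all fixed across the package):
#  * a site in a protein with no ortholog family, or a genome absent from
#    the family, counts as NOT conserved but stays in the denominator
#    (the same rule applies to reference rates, so the bias largely
#    cancels inside C_q - R_q); a switch `denominator = "aligned_only"`
#    restricts denominators to sites with an ortholog present;
#  * conservation calls are strict alignment-column matches: the
#    ortholog's residues at the human motif window's columns must satisfy
#    the pattern position-by-position, any gap means not conserved;
#  * a genome with several members in a family is conserved if ANY member
#    matches; rates are exact integer ratios until the final CI sum.

#' Map an ungapped position to its alignment column
#'
#' @param aligned_row Gapped residue string (gap `-`).
#' @param position 1-based index into the ungapped sequence.
#' @return 1-based column index holding that residue.
#' @examples
#' ungapped_to_column("AC-DE", 3)  # 4
#' @export
ungapped_to_column <- function(aligned_row, position) {
  chars <- strsplit(aligned_row, "", fixed = TRUE)[[1L]]
  ng <- which(chars != .GAP)
  position <- as.integer(position)
  if (position < 1L || position > length(ng))
    stop("position ", position, " exceeds ungapped length ", length(ng))
  ng[[position]]
}

#' Map an alignment column to its ungapped position
#'
#' @param aligned_row Gapped residue string.
#' @param column 1-based column index.
#' @return 1-based ungapped position, or `NA` if the column holds a gap.
#' @export
column_to_ungapped <- function(aligned_row, column) {
  chars <- strsplit(aligned_row, "", fixed = TRUE)[[1L]]
  column <- as.integer(column)
  if (column < 1L || column > length(chars))
    stop("column ", column, " out of range 1..", length(chars))
  if (chars[[column]] == .GAP) return(NA_integer_)
  sum(chars[seq_len(column)] != .GAP)
}

#' Index proteins of the reference genome across ortholog families
#'
#' Builds the protein -> family assignment used by all rate computations.
#' A reference-genome protein occurring in several clusters is assigned
#' to the cluster covering the most genomes; ties break on the
#' lexicographically smallest cluster id. Reassignments are reported via
#' `message()`.
#'
#' @param families List of [ortholog_family()] objects.
#' @param genomes A [genome_set()].
#' @return Named integer vector: protein id -> index into `families`.
#' @export
build_family_index <- function(families, genomes = genome_set()) {
  ref <- genomes$reference
  idx <- integer(0)
  cov <- integer(0)
  cid <- character(0)
  for (f in seq_along(families)) {
    fam <- families[[f]]
    n_genomes <- length(unique(fam$genome))
    for (p in unique(fam$protein_id[fam$genome == ref])) {
      j <- match(p, names(idx))
      if (is.na(j)) {
        idx[p] <- f; cov[p] <- n_genomes; cid[p] <- fam$cluster_id
      } else if (n_genomes > cov[[j]] ||
                 (n_genomes == cov[[j]] && fam$cluster_id < cid[[j]])) {
        message("protein '", p, "': preferring cluster '", fam$cluster_id,
                "' over '", cid[[j]], "'")
        idx[p] <- f; cov[p] <- n_genomes; cid[p] <- fam$cluster_id
      }
    }
  }
  idx
}

# Vectorized verdict engine. `sites` is a data.frame with protein_id,
# position; `patterns` a list of motif_pattern; `pattern_idx` maps each
# site to its pattern. Returns a character matrix (site x genome code)
# with entries "conserved" / "not_conserved" / "no_ortholog". The
# reference genome column is "conserved" (the human window is required to
# match; violations raise an error).
.conserve_sites <- function(families, sites, patterns, genomes,
                            pattern_idx = NULL, family_index = NULL) {
  codes <- genomes$codes
  ref <- genomes$reference
  n <- nrow(sites)
  if (is.null(pattern_idx)) pattern_idx <- rep(1L, n)
  if (is.null(family_index)) family_index <- build_family_index(families, genomes)
  verdicts <- matrix("no_ortholog", nrow = n, ncol = length(codes),
                     dimnames = list(NULL, codes))
  verdicts[, ref] <- "conserved"
  fidx <- family_index[sites$protein_id]
  nonref <- .nonref_codes(genomes)
  for (f in unique(fidx[!is.na(fidx)])) {
    fam <- families[[f]]
    chars <- strsplit(fam$rows, "", fixed = TRUE)
    ref_rows <- which(fam$genome == ref)
    ref_ng <- lapply(ref_rows, function(i) which(chars[[i]] != .GAP))
    names(ref_ng) <- fam$protein_id[ref_rows]
    members_of <- lapply(nonref, function(q) which(fam$genome == q))
    names(members_of) <- nonref
    for (s in which(!is.na(fidx) & fidx == f)) {
      pat <- patterns[[pattern_idx[[s]]]]
      hrow <- ref_rows[match(sites$protein_id[[s]], fam$protein_id[ref_rows])]
      if (is.na(hrow))
        stop("protein '", sites$protein_id[[s]], "' is not a ", ref,
             " member of family '", fam$cluster_id, "'")
      ng <- ref_ng[[sites$protein_id[[s]]]]
      upos <- sites$position[[s]] + seq_along(pat$positions) - 1L -
        pat$acceptor_offset
      if (upos[[1L]] < 1L || upos[[length(upos)]] > length(ng))
        stop("human window for motif '", pat$motif_id, "' at ",
             sites$protein_id[[s]], ":", sites$position[[s]],
             " runs off the sequence")
      cols <- ng[upos]
      if (!.window_satisfies(chars[[hrow]][cols], pat$positions))
        stop("human window at ", sites$protein_id[[s]], ":",
             sites$position[[s]], " does not match motif '",
             pat$motif_id, "'")
      for (q in nonref) {
        mem <- members_of[[q]]
        if (length(mem) == 0L) next  # stays no_ortholog
        ok <- FALSE
        for (m in mem) {
          if (.window_satisfies(chars[[m]][cols], pat$positions)) {
            ok <- TRUE
            break
          }
        }
        verdicts[s, q] <- if (ok) "conserved" else "not_conserved"
      }
    }
  }
  verdicts
}

#' Call conservation of one site in one genome
#'
#' Projects the human motif window into alignment columns and checks,
#' for every member of `genome` in the family, whether the residues at
#' those columns are all non-gap and satisfy the pattern position by
#' position. The verdict is `conserved` if any member matches,
#' `no_ortholog` if the genome has no member in the family, and
#' `not_conserved` otherwise.
#'
#' @param family An [ortholog_family()].
#' @param human_member Protein id of the reference-genome member holding
#'   the site.
#' @param site List or one-row data.frame with `position` (1-based,
#'   ungapped).
#' @param pattern A `motif_pattern`; the human window must match it.
#' @param genome Genome code to evaluate.
#' @param genomes A [genome_set()].
#' @return List with elements `protein_id`, `position`, `genome`,
#'   `verdict`.
#' @export
call_site_conservation <- function(family, human_member, site, pattern,
                                   genome, genomes = genome_set()) {
  stopifnot(inherits(family, "ortholog_family"),
            inherits(pattern, "motif_pattern"))
  if (!genome %in% genomes$codes)
    stop("unknown genome code '", genome, "'")
  fams <- list(family)
  fi <- stats::setNames(1L, human_member)
  if (!human_member %in% family$protein_id[family$genome == genomes$reference])
    stop("protein '", human_member, "' is not a ", genomes$reference,
         " member of family '", family$cluster_id, "'")
  sites <- data.frame(protein_id = human_member,
                      position = as.integer(site$position),
                      stringsAsFactors = FALSE)
  v <- .conserve_sites(fams, sites, list(pattern), genomes,
                       family_index = fi)
  list(protein_id = human_member, position = as.integer(site$position),
       genome = genome, verdict = unname(v[1L, genome]))
}

#' Per-genome conservation rates of a motif's phosphosites
#'
#' For each genome q, the conservation rate C_q is the number of the
#' motif's human phosphosites whose motif window is conserved in q
#' divided by the number of human phosphosites. Sites in proteins
#' without any ortholog family, and genomes absent from a family, count
#' as not conserved under the default `denominator = "all"`;
#' `"aligned_only"` drops them from that genome's denominator instead.
#'
#' @param families List of [ortholog_family()] objects.
#' @param sites data.frame of human sites (`protein_id`, `position`,
#'   `residue`) already filtered to those matching `pattern`.
#' @param pattern A `motif_pattern`.
#' @param genomes A [genome_set()].
#' @param class Site class label (`"known"` or `"potential"`); derived
#'   from a uniform `sites$status` column when absent.
#' @param denominator `"all"` (default) or `"aligned_only"`.
#' @param family_index Optional precomputed [build_family_index()].
#' @return An object of class `conservation_profile`: per-genome
#'   `conserved`, `total` and `rate`, the site count, the acceptor
#'   residue mix, and the per-site `calls` data.frame.
#' @export
motif_conservation_rates <- function(families, sites, pattern,
                                     genomes = genome_set(), class = NULL,
                                     denominator = c("all", "aligned_only"),
                                     family_index = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(sites) || nrow(sites) == 0L)
    stop("cannot compute conservation rates for motif '", pattern$motif_id,
         "': empty site list")
  if (is.null(class)) {
    class <- if ("status" %in% names(sites) &&
                 length(unique(sites$status)) == 1L)
      sites$status[[1L]] else "mixed"
  }
  v <- .conserve_sites(families, sites, list(pattern), genomes,
                       family_index = family_index)
  codes <- genomes$codes
  conserved <- colSums(v == "conserved")
  total <- if (denominator == "all")
    stats::setNames(rep(nrow(sites), length(codes)), codes)
  else
    colSums(v != "no_ortholog")
  if (any(total == 0L))
    stop("motif '", pattern$motif_id, "': zero denominator for genome(s) ",
         paste(codes[total == 0L], collapse = ", "),
         " under aligned_only denominators")
  calls <- data.frame(
    protein_id = rep(sites$protein_id, times = length(codes)),
    position = rep(sites$position, times = length(codes)),
    genome = rep(codes, each = nrow(sites)),
    verdict = as.vector(v),
    stringsAsFactors = FALSE
  )
  mix <- if ("residue" %in% names(sites))
    table(factor(sites$residue, levels = .ACCEPTOR_RESIDUES))
  else NULL
  structure(list(motif_id = pattern$motif_id, class = class,
                 genomes = genomes, conserved = conserved, total = total,
                 rate = conserved / total, n_sites = nrow(sites),
                 acceptor_mix = mix, calls = calls),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile> motif ", x$motif_id, " [", x$class, "], ",
      x$n_sites, " sites\n", sep = "")
  print(round(x$rate, 4L))
  invisible(x)
}

#' Enumerate potential phosphosites (all STY residues)
#'
#' Scans the reference-genome rows of the families for every serine,
#' threonine and tyrosine residue — the background against which
#' reference conservation rates are computed, and the definition of
#' potential phosphosites ("all STY residues in proteins harboring known
#' phosphosites" when `proteins` is restricted accordingly).
#'
#' @param families List of [ortholog_family()] objects.
#' @param genomes A [genome_set()].
#' @param proteins Optional character vector restricting the scan.
#' @return data.frame with `protein_id`, `position`, `residue`.
#' @export
enumerate_sty_sites <- function(families, genomes = genome_set(),
                                proteins = NULL) {
  ref <- genomes$reference
  out <- list()
  seen <- character(0)
  for (fam in families) {
    for (i in which(fam$genome == ref)) {
      p <- fam$protein_id[[i]]
      if (!is.null(proteins) && !p %in% proteins) next
      if (p %in% seen) next
      seen <- c(seen, p)
      seq <- gsub("-", "", fam$rows[[i]], fixed = TRUE)
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      hits <- which(chars %in% .ACCEPTOR_RESIDUES)
      if (length(hits))
        out[[length(out) + 1L]] <- data.frame(
          protein_id = p, position = hits, residue = chars[hits],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reference conservation rates of S, T and Y residues
#'
#' For each genome q and residue type r, R_q(r) is the fraction of
#' background sites of type r conserved in q when each site is treated
#' as a single-residue motif (same gap, any-member and missing-ortholog
#' rules as the motif rates). The reference genome's rate is 1 by
#' construction. Residue types with no background sites are flagged
#' unavailable (`NA`); a later CI computation that needs them errors.
#'
#' @param families List of [ortholog_family()] objects.
#' @param background_sites data.frame (`protein_id`, `position`,
#'   `residue`) of background STY sites, e.g. from
#'   [enumerate_sty_sites()].
#' @param genomes A [genome_set()].
#' @param denominator `"all"` or `"aligned_only"` (see
#'   [motif_conservation_rates()]).
#' @param family_index Optional precomputed [build_family_index()].
#' @return An object of class `reference_rates`: `rate`, `conserved`,
#'   `total` matrices (rows S, T, Y; columns genome codes).
#' @export
reference_rates <- function(families, background_sites,
                            genomes = genome_set(),
                            denominator = c("all", "aligned_only"),
                            family_index = NULL) {
  denominator <- match.arg(denominator)
  if (is.null(family_index))
    family_index <- build_family_index(families, genomes)
  codes <- genomes$codes
  rate <- conserved <- total <- matrix(
    NA_real_, nrow = 3L, ncol = length(codes),
    dimnames = list(.ACCEPTOR_RESIDUES, codes))
  single <- lapply(.ACCEPTOR_RESIDUES, function(r) {
    structure(list(motif_id = paste0("ref_", r), raw = r,
                   positions = list(r), acceptor_offset = 0L),
              class = "motif_pattern")
  })
  names(single) <- .ACCEPTOR_RESIDUES
  for (r in .ACCEPTOR_RESIDUES) {
    sub <- background_sites[background_sites$residue == r, , drop = FALSE]
    if (nrow(sub) == 0L) next  # unavailable, stays NA
    prof <- motif_conservation_rates(families, sub, single[[r]], genomes,
                                     class = "background",
                                     denominator = denominator,
                                     family_index = family_index)
    rate[r, ] <- prof$rate
    conserved[r, ] <- prof$conserved
    total[r, ] <- prof$total
  }
  structure(list(rate = rate, conserved = conserved, total = total,
                 genomes = genomes),
            class = "reference_rates")
}

#' @export
print.reference_rates <- function(x, ...) {
  cat("<reference_rates>\n")
  print(round(x$rate, 4L))
  invisible(x)
}

#' The motif conservation index
#'
#' CI = sum over genomes q of (C_q - R_q), where C_q is the motif's
#' conservation rate in q and R_q the reference conservation rate of the
#' corresponding acceptor residue. For motifs whose acceptor admits
#' several residue types (e.g. S/T), R_q is the count-weighted mixture of
#' the per-type reference rates over the motif's actual human sites.
#' The reference genome contributes exactly zero (C = R = 1).
#'
#' @param profile A `conservation_profile` from
#'   [motif_conservation_rates()].
#' @param refs A `reference_rates` object over the same genome set.
#' @param acceptor_mix Named counts of the motif's sites per acceptor
#'   residue type; defaults to the mix recorded in `profile`.
#' @return An object of class `ci_record`: `ci`, per-genome `C`, `R`
#'   and `terms` (C_q - R_q).
#' @examples
#' # CI of two genomes with C = {0.8, 0.6} and R = {0.5, 0.5} is 0.4.
#' @export
conservation_index <- function(profile, refs, acceptor_mix = NULL) {
  stopifnot(inherits(profile, "conservation_profile"),
            inherits(refs, "reference_rates"))
  codes <- profile$genomes$codes
  if (!all(codes %in% colnames(refs$rate)))
    stop("reference rates are missing genome(s): ",
         paste(setdiff(codes, colnames(refs$rate)), collapse = ", "))
  if (is.null(acceptor_mix)) acceptor_mix <- profile$acceptor_mix
  if (is.null(acceptor_mix))
    stop("acceptor residue mix unavailable: supply acceptor_mix")
  mix <- as.numeric(acceptor_mix[.ACCEPTOR_RESIDUES])
  mix[is.na(mix)] <- 0
  names(mix) <- .ACCEPTOR_RESIDUES
  if (sum(mix) <= 0)
    stop("acceptor mix has no sites")
  w <- mix / sum(mix)
  used <- names(w)[w > 0]
  if (anyNA(refs$rate[used, codes]))
    stop("reference rate unavailable for residue type(s) ",
         paste(used[apply(is.na(refs$rate[used, codes, drop = FALSE]), 1L,
                          any)], collapse = ", "))
  R <- as.vector(w[used] %*% refs$rate[used, codes, drop = FALSE])
  names(R) <- codes
  C <- profile$rate[codes]
  terms <- C - R
  structure(list(motif_id = profile$motif_id, class = profile$class,
                 ci = sum(terms), C = C, R = R, terms = terms,
                 weights = w, genomes = profile$genomes,
                 n_sites = profile$n_sites),
            class = "ci_record")
}

#' @export
print.ci_record <- function(x, ...) {
  cat("<ci_record> motif ", x$motif_id, " [", x$class, "]: CI = ",
      format(x$ci, digits = 4L), " over ", x$n_sites, " sites\n", sep = "")
  invisible(x)
}

#' Binomial standard error of a conservation index
#'
#' Treats each genome's C_q and R_q(r) as independent binomial
#' proportions (distinct genomes are independent draws in the simulator;
#' C and R come from disjoint site sets) and propagates:
#' SE^2 = sum over non-reference q of C_q(1-C_q)/n + sum_r w_r^2
#' R_q(r)(1-R_q(r))/m_r.
#'
#' @param profile `conservation_profile` for the motif.
#' @param refs `reference_rates` used for the CI.
#' @param acceptor_mix Optional acceptor mix override (see
#'   [conservation_index()]).
#' @return Standard error (numeric scalar).
#' @export
ci_standard_error <- function(profile, refs, acceptor_mix = NULL) {
  if (is.null(acceptor_mix)) acceptor_mix <- profile$acceptor_mix
  mix <- as.numeric(acceptor_mix[.ACCEPTOR_RESIDUES])
  mix[is.na(mix)] <- 0
  names(mix) <- .ACCEPTOR_RESIDUES
  w <- mix / sum(mix)
  nonref <- .nonref_codes(profile$genomes)
  v <- 0
  for (q in nonref) {
    C <- profile$rate[[q]]
    v <- v + C * (1 - C) / profile$total[[q]]
    for (r in names(w)[w > 0]) {
      R <- refs$rate[r, q]
      v <- v + w[[r]]^2 * R * (1 - R) / refs$total[r, q]
    }
  }
  sqrt(v)
}

#' One-call motif CI
#'
#' Convenience wrapper: computes the conservation profile, the CI record
#' and its standard error for one motif and site set.
#'
#' @inheritParams motif_conservation_rates
#' @param refs A `reference_rates` object.
#' @return List with `profile`, `record`, `se`.
#' @export
motif_ci <- function(families, sites, pattern, refs,
                     genomes = genome_set(), class = NULL,
                     denominator = c("all", "aligned_only"),
                     family_index = NULL) {
  prof <- motif_conservation_rates(families, sites, pattern, genomes,
                                   class = class,
                                   denominator = denominator,
                                   family_index = family_index)
  rec <- conservation_index(prof, refs)
  list(profile = prof, record = rec,
       se = ci_standard_error(prof, refs))
}
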