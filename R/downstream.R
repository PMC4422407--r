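# Derived analyses over CI records: known-vs-potential comparison,
# CI-rank binning by motif structure, kinase substrate tabulations,
# term enrichment and the motif-sharing network statistic.

.ci_table <- function(records) {
  if (inherits(records, "ci_record")) records <- list(records)
  data.frame(
    motif_id = vapply(records, `[[`, character(1L), "motif_id"),
    ci = vapply(records, `[[`, numeric(1L), "ci"),
    stringsAsFactors = FALSE
  )
}

#' Compare CIs of known versus potential phosphosites
#'
#' Pairs the two CI sets by motif, reports the Pearson correlation and
#' counts motifs above and below the y = x diagonal (known CI greater,
#' smaller, or equal to the potential CI). Motifs whose known sites are
#' conserved above the residue background while their potential sites are
#' not plot above the diagonal.
#'
#' @param ci_known,ci_potential Lists of `ci_record` objects (or data
#'   frames with `motif_id`, `ci`).
#' @return List with `pairs` (data.frame `motif_id`, `ci_known`,
#'   `ci_potential`), `pearson_r` (`NA` with `correlation_available =
#'   FALSE` when fewer than 3 pairs), `n_above`, `n_below`, `n_equal`.
#' @export
compare_known_vs_potential <- function(ci_known, ci_potential) {
  k <- if (is.data.frame(ci_known)) ci_known else .ci_table(ci_known)
  p <- if (is.data.frame(ci_potential)) ci_potential else .ci_table(ci_potential)
  common <- intersect(k$motif_id, p$motif_id)
  if (length(common) == 0L)
    stop("no motifs shared between the known and potential CI sets")
  pairs <- data.frame(
    motif_id = common,
    ci_known = k$ci[match(common, k$motif_id)],
    ci_potential = p$ci[match(common, p$motif_id)],
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$motif_id), , drop = FALSE]
  rownames(pairs) <- NULL
  available <- nrow(pairs) >= 3L
  r <- NA_real_
  if (available) {
    r <- stats::cor(pairs$ci_known, pairs$ci_potential)
  } else {
    warning("fewer than 3 motif pairs: correlation unavailable")
  }
  list(pairs = pairs, pearson_r = r, correlation_available = available,
       n_above = sum(pairs$ci_known > pairs$ci_potential),
       n_below = sum(pairs$ci_known < pairs$ci_potential),
       n_equal = sum(pairs$ci_known == pairs$ci_potential))
}

#' Bin motifs by CI rank and tabulate structural classes
#'
#' Motifs are ordered by decreasing CI (ties broken by motif id) and cut
#' into successive classes of `class_size` motifs (the last class may be
#' smaller). Each class reports its mean CI, the number of
#' proline-directed motifs and the number of basophilic motifs — the
#' structure of the CI-rank histogram contrasting S/T-P against
#' basic-residue motifs.
#'
#' @param ci_records List of `ci_record` objects.
#' @param patterns Named list of `motif_pattern` objects covering every
#'   record's motif.
#' @param class_size Motifs per class (default 10).
#' @return List with `bins` (data.frame `bin`, `n`, `mean_ci`,
#'   `n_proline_directed`, `n_basic`) and `order` (motif ids, CI-sorted;
#'   concatenating the bins in order reproduces it exactly).
#' @export
bin_ci_distribution <- function(ci_records, patterns, class_size = 10L) {
  tab <- .ci_table(ci_records)
  missing <- setdiff(tab$motif_id, names(patterns))
  if (length(missing))
    stop("no pattern classification for motif(s): ",
         paste(missing, collapse = ", "))
  ord <- order(-tab$ci, tab$motif_id)
  tab <- tab[ord, , drop = FALSE]
  flags <- t(vapply(patterns[tab$motif_id], classify_pattern, logical(4L)))
  basic <- flags[, "basic_minus2"] | flags[, "basic_minus3"] |
    flags[, "basic_minus4"]
  bin <- ceiling(seq_len(nrow(tab)) / class_size)
  bins <- data.frame(
    bin = sort(unique(bin)),
    n = as.integer(tabulate(bin)),
    mean_ci = as.numeric(tapply(tab$ci, bin, mean)),
    n_proline_directed = as.integer(tapply(flags[, "proline_directed"],
                                           bin, sum)),
    n_basic = as.integer(tapply(basic, bin, sum))
  )
  members <- split(tab$motif_id, bin)
  list(bins = bins, order = tab$motif_id, members = members)
}

#' Kinase group or family fractions for a motif's substrates
#'
#' Tabulates kinase-substrate edges restricted to one motif's sites by
#' kinase group (or family) and reports the top fractions. The counting
#' unit is the edge (site-level kinase-substrate pair) by default;
#' `unit = "protein"` counts distinct substrate proteins per label
#' instead. Edges whose kinase lacks a classification are counted under
#' `"unclassified"` with a warning.
#'
#' @param edges data.frame of kinase-substrate edges (`kinase_id`,
#'   `protein_id`, `position`, `residue`) restricted to one motif.
#' @param kinases data.frame with `kinase_id`, `group`, `family`.
#' @param level `"group"` or `"family"`.
#' @param top_k Number of top rows to return (default 3).
#' @param unit `"edge"` (default) or `"protein"`.
#' @return List with `table` (all labels: `label`, `count`, `fraction`,
#'   `percent`), `top` (first `top_k` rows), `n_substrates` (total count
#'   in the chosen unit), `level`, `unit`.
#' @export
kinase_fractions <- function(edges, kinases, level = c("group", "family"),
                             top_k = 3L, unit = c("edge", "protein")) {
  level <- match.arg(level)
  unit <- match.arg(unit)
  if (is.null(edges) || nrow(edges) == 0L)
    stop("empty kinase-substrate edge set")
  lab <- kinases[[level]][match(edges$kinase_id, kinases$kinase_id)]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)), " edge(s) with unclassified kinase")
    lab[is.na(lab)] <- "unclassified"
  }
  if (unit == "edge") {
    counts <- table(lab)
  } else {
    counts <- vapply(split(edges$protein_id, lab),
                     function(p) length(unique(p)), integer(1L))
    counts <- as.table(counts)
  }
  total <- sum(counts)
  tab <- data.frame(label = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$fraction <- tab$count / total
  tab$percent <- round(100 * tab$fraction)
  tab <- tab[order(-tab$count, tab$label), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, top = utils::head(tab, top_k), n_substrates = total,
       level = level, unit = unit)
}

#' CI of each kinase group's pooled substrate sites
#'
#' Pools the substrate phosphosites of every kinase group and computes a
#' conservation index for the pooled site set using acceptor-residue
#' matching (each site is its own single-residue motif) — the same
#' machinery as motif CIs applied to a site set rather than a pattern.
#' Groups with fewer than `min_sites` resolvable sites are flagged
#' low-support; groups with none are omitted with a warning.
#'
#' @param edges Kinase-substrate edge data.frame (`kinase_id`,
#'   `protein_id`, `position`, `residue`).
#' @param kinases Kinase table with `kinase_id`, `group`.
#' @param families List of [ortholog_family()] objects.
#' @param refs A `reference_rates` object.
#' @param genomes A [genome_set()].
#' @param min_sites Low-support threshold (default 10).
#' @param family_index Optional precomputed [build_family_index()].
#' @return data.frame with `group`, `n_sites`, `ci`, `se`,
#'   `low_support`.
#' @export
kinase_group_substrate_ci <- function(edges, kinases, families, refs,
                                      genomes = genome_set(),
                                      min_sites = 10L,
                                      family_index = NULL) {
  if (is.null(family_index))
    family_index <- build_family_index(families, genomes)
  grp <- kinases$group[match(edges$kinase_id, kinases$kinase_id)]
  if (anyNA(grp)) {
    warning(sum(is.na(grp)), " edge(s) with unclassified kinase dropped")
    edges <- edges[!is.na(grp), , drop = FALSE]
    grp <- grp[!is.na(grp)]
  }
  single <- lapply(.ACCEPTOR_RESIDUES, function(r) {
    structure(list(motif_id = paste0("site_", r), raw = r,
                   positions = list(r), acceptor_offset = 0L),
              class = "motif_pattern")
  })
  names(single) <- .ACCEPTOR_RESIDUES
  out <- list()
  for (g in sort(unique(grp))) {
    sub <- unique(edges[grp == g, c("protein_id", "position", "residue")])
    # only sites resolvable in an ortholog family can be verified against
    # the human sequence; others are unresolvable and dropped
    resolvable <- sub$protein_id %in% names(family_index)
    sub <- sub[resolvable, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("kinase group '", g, "' has no resolvable substrate sites; ",
              "omitted")
      next
    }
    codes <- genomes$codes
    v <- .conserve_sites(families, sub, single, genomes,
                         pattern_idx = match(sub$residue, names(single)),
                         family_index = family_index)
    conserved <- colSums(v == "conserved")
    total <- stats::setNames(rep(nrow(sub), length(codes)), codes)
    mix <- table(factor(sub$residue, levels = .ACCEPTOR_RESIDUES))
    prof <- structure(list(motif_id = g, class = "substrates",
                           genomes = genomes, conserved = conserved,
                           total = total, rate = conserved / total,
                           n_sites = nrow(sub), acceptor_mix = mix,
                           calls = NULL),
                      class = "conservation_profile")
    rec <- conservation_index(prof, refs)
    out[[g]] <- data.frame(group = g, n_sites = nrow(sub), ci = rec$ci,
                           se = ci_standard_error(prof, refs),
                           low_support = nrow(sub) < min_sites,
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    stop("no kinase group has resolvable substrate sites")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Kinase group counts and fractions per genome
#'
#' From kinase ortholog-presence flags: for each genome, the total number
#' of kinases present and each group's fraction of that total — the
#' expansion profile of the kinome across the genome panel.
#'
#' @param kinases Kinase table with `kinase_id`, `group` and one logical
#'   presence column per genome code.
#' @param genomes A [genome_set()].
#' @return data.frame with `genome`, `group`, `count`, `total`,
#'   `fraction`; genomes ordered as in `genomes`, groups alphabetical.
#' @export
kinase_expansion_table <- function(kinases, genomes = genome_set()) {
  missing <- setdiff(genomes$codes, names(kinases))
  if (length(missing))
    stop("kinase table lacks presence column(s): ",
         paste(missing, collapse = ", "))
  groups <- sort(unique(kinases$group))
  rows <- list()
  for (g in genomes$codes) {
    present <- as.logical(kinases[[g]])
    total <- sum(present)
    for (grp in groups) {
      count <- sum(present & kinases$group == grp)
      rows[[length(rows) + 1L]] <- data.frame(
        genome = g, group = grp, count = count, total = total,
        fraction = if (total > 0L) count / total else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment of a motif's protein set
#'
#' For each annotation term, the upper-tail hypergeometric p-value of the
#' overlap between the motif's proteins and the term's proteins within
#' the background, with Benjamini-Hochberg adjustment across terms.
#' Significance requires both p < `alpha_p` and FDR < `alpha_fdr`.
#' Annotations for proteins outside the background are skipped with a
#' warning.
#'
#' @param motif_proteins Character vector, a subset of `background`.
#' @param annotations data.frame with `protein_id`, `term`.
#' @param background Character vector of all eligible proteins.
#' @param alpha_p Raw p-value threshold (default 0.01).
#' @param alpha_fdr FDR threshold (default 0.01).
#' @return data.frame with `term`, `overlap`, `set_size`, `term_size`,
#'   `background_size`, `p_value`, `fdr`, `significant`, ordered by
#'   p-value then term.
#' @export
term_enrichment <- function(motif_proteins, annotations, background,
                            alpha_p = 0.01, alpha_fdr = 0.01) {
  background <- unique(as.character(background))
  motif_proteins <- unique(as.character(motif_proteins))
  if (!all(motif_proteins %in% background))
    stop("motif proteins must be a subset of the background")
  outside <- !(annotations$protein_id %in% background)
  if (any(outside)) {
    warning(sum(outside), " annotation row(s) for proteins outside the ",
            "background skipped")
    annotations <- annotations[!outside, , drop = FALSE]
  }
  annotations <- unique(annotations[c("protein_id", "term")])
  if (nrow(annotations) == 0L)
    stop("no annotations within the background")
  N <- length(background)
  n <- length(motif_proteins)
  terms <- sort(unique(annotations$term))
  term_prot <- split(annotations$protein_id, annotations$term)
  res <- lapply(terms, function(tm) {
    prot <- unique(term_prot[[tm]])
    K <- length(prot)
    k <- length(intersect(prot, motif_proteins))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, set_size = n, term_size = K,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < alpha_p & res$fdr < alpha_fdr
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Permutation statistic for motif-sharing interactions
#'
#' Counts interaction edges whose two endpoints both carry the motif and
#' compares the count with a null of equally sized protein sets drawn
#' uniformly without replacement from the network's nodes:
#' p = (1 + #\{null >= observed\}) / (1 + n_perm). Small p means
#' proteins sharing the motif interact more than randomly selected
#' proteins. A degree-weighted null (nodes sampled with probability
#' proportional to degree) is available as a sensitivity switch.
#'
#' @param interactions Undirected edge data.frame (`protein_a`,
#'   `protein_b`), e.g. from [read_interaction_edges()].
#' @param motif_proteins Character vector of proteins carrying the motif;
#'   must not exceed the node set. Proteins absent from the network carry
#'   no edges and are dropped from the set (the set size used for the
#'   null is the retained size).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer RNG seed; the result is reproducible.
#' @param null `"uniform"` (default) or `"degree_weighted"`.
#' @return List with `observed`, `p_value`, `n_perm`, `set_size`,
#'   `subnetwork` (edge data.frame among motif proteins), `null_counts`.
#' @export
motif_network_statistic <- function(interactions, motif_proteins, n_perm,
                                    seed, null = c("uniform",
                                                   "degree_weighted")) {
  null <- match.arg(null)
  if (n_perm < 100L)
    stop("n_perm must be at least 100")
  a <- as.character(interactions$protein_a)
  b <- as.character(interactions$protein_b)
  nodes <- sort(unique(c(a, b)))
  motif_proteins <- unique(as.character(motif_proteins))
  if (length(motif_proteins) > length(nodes))
    stop("motif protein set (", length(motif_proteins),
         ") exceeds the network node set (", length(nodes), ")")
  set <- intersect(motif_proteins, nodes)
  in_set <- a %in% set & b %in% set
  observed <- sum(in_set)
  m <- length(set)
  weights <- NULL
  if (null == "degree_weighted") {
    deg <- table(factor(c(a, b), levels = nodes))
    weights <- as.numeric(deg)
  }
  set.seed(as.integer(seed))
  null_counts <- vapply(seq_len(n_perm), function(i) {
    s <- sample(nodes, m, replace = FALSE, prob = weights)
    sum(a %in% s & b %in% s)
  }, integer(1L))
  p <- (1 + sum(null_counts >= observed)) / (1 + n_perm)
  sub <- interactions[in_set, , drop = FALSE]
  rownames(sub) <- NULL
  list(observed = observed, p_value = p, n_perm = as.integer(n_perm),
       set_size = m, subnetwork = sub, null_counts = null_counts)
}
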