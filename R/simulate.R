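# Synthetic ortholog families with planted conservation. Each planted
# motif occurrence lives in its own protein / ortholog cluster. Per
# occurrence and genome, one Bernoulli draw decides whether the whole
# motif window is copied into the ortholog (conserved) or the acceptor
# is substituted with a residue outside the acceptor set (not
# conserved), so the window-level conservation probability is exactly
# the configured value. Background positions are retained independently
# with probability p_bg, else substituted uniformly among the 19 other
# residues — background single-residue conservation is exactly p_bg.
# Wildcard window positions are filled with non-STY residues so planted
# windows never add stray background phosphosites.

#' Simulator configuration
#'
#' Defines the conditions under which synthetic ortholog families are
#' generated: the genome panel, the motifs to plant, how many known and
#' potential occurrences of each, the per-genome conservation
#' probabilities of planted windows and of background residues, ortholog
#' loss, optional indel decoration of the alignments, and the RNG seed
#' (mandatory; the simulator has no implicit entropy).
#'
#' @param genomes A [genome_set()].
#' @param motifs Character vector of pattern strings or list of
#'   `motif_pattern` objects.
#' @param n_known Planted known-site occurrences per motif (recycled).
#' @param n_potential Planted potential-site occurrences per motif
#'   (recycled; these are genuine motif matches labeled `potential`).
#' @param p_known Window conservation probability of known occurrences:
#'   scalar, per-genome named vector, or per-motif list thereof.
#' @param p_potential Same for planted potential occurrences (required
#'   when `n_potential > 0`).
#' @param p_bg Background per-residue conservation probability (scalar or
#'   per-genome named vector).
#' @param protein_length Length 2 integer vector: min/max protein length.
#' @param ortholog_loss Probability that a genome is absent from a family
#'   (scalar or per-genome).
#' @param indel_rate Expected number of decorative single-column
#'   insertions per family (Poisson); insertions never touch planted
#'   windows, so planted truth is preserved.
#' @param known_rate Probability that a planted known occurrence is
#'   labeled `known` (otherwise it is labeled `potential`).
#' @param seed Integer RNG seed (mandatory).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genomes = genome_set(),
                       motifs = c("R-X-X-S/T", "S/T-P"),
                       n_known = 20L, n_potential = 0L,
                       p_known = 0.8, p_potential = NULL,
                       p_bg = 0.5,
                       protein_length = c(200L, 400L),
                       ortholog_loss = 0, indel_rate = 0,
                       known_rate = 1, seed) {
  if (missing(seed) || is.null(seed))
    stop("sim_config requires an explicit integer seed")
  if (is.character(motifs))
    motifs <- lapply(motifs, parse_motif_pattern)
  stopifnot(all(vapply(motifs, inherits, logical(1L), "motif_pattern")))
  names(motifs) <- vapply(motifs, `[[`, character(1L), "motif_id")
  if (anyDuplicated(names(motifs)))
    stop("motif ids must be unique")
  nm <- length(motifs)
  n_known <- rep_len(as.integer(n_known), nm)
  n_potential <- rep_len(as.integer(n_potential), nm)
  as_per_motif <- function(x, what) {
    if (!is.list(x)) x <- list(x)
    x <- rep_len(x, nm)
    lapply(x, .per_genome, genomes = genomes, what = what)
  }
  p_known <- as_per_motif(p_known, "p_known")
  if (any(n_potential > 0L)) {
    if (is.null(p_potential))
      stop("p_potential is required when potential occurrences are planted")
    p_potential <- as_per_motif(p_potential, "p_potential")
  } else {
    p_potential <- NULL
  }
  protein_length <- as.integer(protein_length)
  stopifnot(length(protein_length) == 2L,
            protein_length[[1L]] >= 1L,
            protein_length[[2L]] >= protein_length[[1L]])
  maxw <- max(vapply(motifs, function(m) length(m$positions), integer(1L)))
  if (maxw > protein_length[[1L]])
    stop("motif window (", maxw, ") longer than the minimum protein length")
  stopifnot(known_rate >= 0, known_rate <= 1, indel_rate >= 0)
  structure(list(
    genomes = genomes, motifs = motifs,
    n_known = n_known, n_potential = n_potential,
    p_known = p_known, p_potential = p_potential,
    p_bg = .per_genome(p_bg, genomes, "p_bg"),
    protein_length = protein_length,
    ortholog_loss = .per_genome(ortholog_loss, genomes, "ortholog_loss"),
    indel_rate = indel_rate, known_rate = known_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Uniform substitution among the 19 residues other than the current one.
.substitute_residues <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  cur <- match(chars[idx], .AA20)
  r <- sample.int(19L, length(idx), replace = TRUE)
  chars[idx] <- .AA20[r + (r >= cur)]
  chars
}

# Concrete residue window for a pattern: wildcards get non-STY residues
# so planting never creates extra background phosphosites.
.realize_window <- function(pattern) {
  non_sty <- setdiff(.AA20, .ACCEPTOR_RESIDUES)
  vapply(pattern$positions, function(set) {
    if (.is_wildcard(set)) sample(non_sty, 1L) else sample(set, 1L)
  }, character(1L))
}

#' Closed-form expected CI of a simulator configuration
#'
#' E[CI] = sum over non-reference genomes q of
#' (1 - loss_q) * (p_site(q) - p_bg(q)): the planted window conserves
#' with probability p_site when the ortholog is present and counts as
#' not conserved when the gene is lost, and the reference rate estimates
#' (1 - loss_q) * p_bg(q).
#'
#' @param config A [sim_config()].
#' @return data.frame with `motif_id`, `class`, `expected_ci`.
#' @export
sim_expected_ci <- function(config) {
  loss <- config$ortholog_loss
  rows <- list()
  for (i in seq_along(config$motifs)) {
    id <- names(config$motifs)[[i]]
    if (config$n_known[[i]] > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = id, class = "known",
        expected_ci = sum((1 - loss) * (config$p_known[[i]] - config$p_bg)),
        stringsAsFactors = FALSE)
    if (config$n_potential[[i]] > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        motif_id = id, class = "potential",
        expected_ci = sum((1 - loss) *
                            (config$p_potential[[i]] - config$p_bg)),
        stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate ortholog families with planted motif conservation
#'
#' Generates one protein (and one ortholog family) per planted motif
#' occurrence. Human sequences are uniform over the 20 residues outside
#' the planted window; each non-reference ortholog retains the planted
#' window as a block with the configured conservation probability (else
#' the acceptor is substituted outside the acceptor set) and every
#' background position independently with probability `p_bg`.
#' Alignments are gap-free stacks plus optional single-column insertions
#' in non-reference rows between planted windows (exercising column
#' mapping without altering planted truth). Fully reproducible from the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with `families` (named list of [ortholog_family()]),
#'   `sites` (data.frame `protein_id`, `position`, `residue`, `status`,
#'   `motif_id` — `NA` for background STY sites), `truth` (list with
#'   `expected_ci`, per-occurrence per-genome `draws`, and the config).
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genomes <- config$genomes
  ref <- genomes$reference
  nonref <- .nonref_codes(genomes)
  families <- list()
  site_rows <- list()
  draw_rows <- list()
  k <- 0L
  for (mi in seq_along(config$motifs)) {
    pat <- config$motifs[[mi]]
    wlen <- length(pat$positions)
    occ_status <- c(rep("known", config$n_known[[mi]]),
                    rep("potential", config$n_potential[[mi]]))
    for (oi in seq_along(occ_status)) {
      k <- k + 1L
      status <- occ_status[[oi]]
      p_site <- if (status == "known") config$p_known[[mi]]
                else config$p_potential[[mi]]
      if (status == "known" && config$known_rate < 1 &&
          stats::runif(1L) > config$known_rate)
        status <- "potential"
      pid <- sprintf("P%05d", k)
      cid <- sprintf("OC%05d", k)
      L <- config$protein_length[[1L]] +
        sample.int(config$protein_length[[2L]] -
                     config$protein_length[[1L]] + 1L, 1L) - 1L
      chars <- sample(.AA20, L, replace = TRUE)
      start <- sample.int(L - wlen + 1L, 1L)
      widx <- start:(start + wlen - 1L)
      chars[widx] <- .realize_window(pat)
      apos <- start + pat$acceptor_offset
      acc_res <- chars[[apos]]
      acc_set <- pat$positions[[pat$acceptor_offset + 1L]]
      rows <- list(chars)
      row_genome <- ref
      row_protein <- pid
      for (q in nonref) {
        present <- stats::runif(1L) >= config$ortholog_loss[[q]]
        conserved <- FALSE
        if (present) {
          qchars <- chars
          keep <- stats::runif(L) < config$p_bg[[q]]
          sub_idx <- setdiff(which(!keep), widx)
          qchars <- .substitute_residues(qchars, sub_idx)
          conserved <- stats::runif(1L) < p_site[[q]]
          if (!conserved) {
            qchars[widx] <- chars[widx]
            qchars[setdiff(widx, apos)] <-
              .substitute_residues(chars, setdiff(widx, apos))[
                setdiff(widx, apos)]
            qchars[[apos]] <- sample(setdiff(.AA20, acc_set), 1L)
            # per-position background churn outside the acceptor keeps the
            # failed window looking natural; the acceptor substitution
            # guarantees the pattern (and the acceptor residue) mismatch
            qchars[setdiff(widx, apos)] <- ifelse(
              keep[setdiff(widx, apos)],
              chars[setdiff(widx, apos)],
              qchars[setdiff(widx, apos)])
          }
          rows[[length(rows) + 1L]] <- qchars
          row_genome <- c(row_genome, q)
          row_protein <- c(row_protein, paste0(pid, "_", q))
        }
        draw_rows[[length(draw_rows) + 1L]] <- data.frame(
          cluster_id = cid, protein_id = pid, motif_id = pat$motif_id,
          status = status, genome = q, present = present,
          conserved = conserved, stringsAsFactors = FALSE)
      }
      # decorative insertions: single columns outside the planted window,
      # residue in one non-reference row, gap everywhere else
      if (config$indel_rate > 0 && length(rows) > 1L) {
        n_ins <- stats::rpois(1L, config$indel_rate)
        if (n_ins > 0L) {
          allowed <- setdiff(0:L, start:(start + wlen - 2L))
          pts <- allowed[sample.int(length(allowed), n_ins, replace = TRUE)]
          targets <- 1L + sample.int(length(rows) - 1L, n_ins,
                                     replace = TRUE)
          ins_res <- sample(setdiff(.AA20, .ACCEPTOR_RESIDUES), n_ins,
                            replace = TRUE)
          for (e in order(pts, decreasing = TRUE)) {
            p <- pts[[e]]
            for (ri in seq_along(rows)) {
              ins <- if (ri == targets[[e]]) ins_res[[e]] else .GAP
              rows[[ri]] <- append(rows[[ri]], ins, after = p)
            }
          }
        }
      }
      families[[cid]] <- ortholog_family(
        cid, row_genome, row_protein,
        vapply(rows, paste, character(1L), collapse = ""))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        protein_id = pid, position = apos, residue = acc_res,
        status = status, motif_id = pat$motif_id, stringsAsFactors = FALSE)
      bg <- setdiff(which(chars %in% .ACCEPTOR_RESIDUES), apos)
      if (length(bg))
        site_rows[[length(site_rows) + 1L]] <- data.frame(
          protein_id = pid, position = bg, residue = chars[bg],
          status = "potential", motif_id = NA_character_,
          stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, site_rows)
  rownames(sites) <- NULL
  truth <- list(expected_ci = sim_expected_ci(config),
                draws = do.call(rbind, draw_rows),
                config = config)
  list(families = families, sites = sites, truth = truth)
}

#' Random fixed-position motif patterns
#'
#' Generates distinct patterns with `n_flank` fixed non-STY residues on
#' each side of an S/T acceptor (e.g. `"A-C-S/T-D-E"`). With four or
#' more fixed positions such patterns essentially never match by chance,
#' which makes them convenient for planting paired known/potential
#' occurrences whose conservation is fully controlled.
#'
#' @param n Number of patterns.
#' @param n_flank Fixed residues on each side of the acceptor.
#' @param seed Integer RNG seed.
#' @return Named list of `motif_pattern` objects with ids `sim001`, ...
#' @export
random_motif_patterns <- function(n, n_flank = 2L, seed) {
  set.seed(as.integer(seed))
  non_sty <- setdiff(.AA20, .ACCEPTOR_RESIDUES)
  texts <- character(0)
  while (length(texts) < n) {
    flanks <- sample(non_sty, 2L * n_flank, replace = TRUE)
    txt <- paste(c(flanks[seq_len(n_flank)], "S/T",
                   flanks[n_flank + seq_len(n_flank)]), collapse = "-")
    if (!txt %in% texts) texts <- c(texts, txt)
  }
  pats <- lapply(seq_len(n), function(i)
    parse_motif_pattern(texts[[i]], sprintf("sim%03d", i)))
  names(pats) <- vapply(pats, `[[`, character(1L), "motif_id")
  pats
}

#' Simulate kinase classifications and kinase-substrate edges
#'
#' Edges are assigned to kinase groups by a multinomial draw with the
#' given probabilities; each group holds a few kinases split over two
#' families, and per-genome ortholog presence flags are Bernoulli draws
#' (the reference genome is always present).
#'
#' @param group_probs Named probability vector over kinase groups
#'   (sums to 1).
#' @param n_edges Number of kinase-substrate edges (>= 1).
#' @param genomes A [genome_set()].
#' @param n_kinases_per_group Kinases per group (default 3).
#' @param presence_prob Ortholog-presence probability per non-reference
#'   genome (scalar or named).
#' @param seed Integer RNG seed.
#' @return List with `kinases` (classification and presence table) and
#'   `edges` (kinase-substrate edge table).
#' @export
simulate_kinase_data <- function(group_probs, n_edges,
                                 genomes = genome_set(),
                                 n_kinases_per_group = 3L,
                                 presence_prob = 1, seed) {
  if (is.null(names(group_probs)) || any(!nzchar(names(group_probs))))
    stop("group_probs must be named by kinase group")
  if (abs(sum(group_probs) - 1) > 1e-8)
    stop("group probabilities must sum to 1")
  n_edges <- as.integer(n_edges)
  if (n_edges < 1L)
    stop("at least one kinase-substrate edge is required")
  set.seed(as.integer(seed))
  presence_prob <- .per_genome(presence_prob, genomes, "presence_prob")
  groups <- names(group_probs)
  kin <- do.call(rbind, lapply(groups, function(g) {
    data.frame(
      kinase_id = sprintf("K_%s_%02d", g, seq_len(n_kinases_per_group)),
      group = g,
      family = sprintf("%s_fam%d", g,
                       (seq_len(n_kinases_per_group) - 1L) %% 2L + 1L),
      stringsAsFactors = FALSE)
  }))
  for (q in genomes$codes) {
    kin[[q]] <- if (q == genomes$reference) TRUE
                else stats::runif(nrow(kin)) < presence_prob[[q]]
  }
  edge_group <- sample(groups, n_edges, replace = TRUE, prob = group_probs)
  kinase_id <- vapply(edge_group, function(g) {
    sample(kin$kinase_id[kin$group == g], 1L)
  }, character(1L))
  edges <- data.frame(
    kinase_id = kinase_id,
    protein_id = sprintf("SUB%05d",
                         sample.int(max(1L, n_edges %/% 3L), n_edges,
                                    replace = TRUE)),
    position = sample.int(500L, n_edges, replace = TRUE),
    residue = sample(c("S", "T", "Y"), n_edges, replace = TRUE,
                     prob = c(0.45, 0.45, 0.1)),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(kinases = kin, edges = edges)
}

#' Simulate a protein-interaction edge list
#'
#' Uniform random undirected edges over a protein set (self-loops and
#' duplicates removed).
#'
#' @param proteins Character vector of node ids.
#' @param n_edges Number of edges to draw (before deduplication).
#' @param seed Integer RNG seed.
#' @return data.frame with `protein_a`, `protein_b`.
#' @export
simulate_interactions <- function(proteins, n_edges, seed) {
  set.seed(as.integer(seed))
  a <- sample(proteins, n_edges, replace = TRUE)
  b <- sample(proteins, n_edges, replace = TRUE)
  keep <- a != b
  out <- unique(data.frame(protein_a = pmin(a[keep], b[keep]),
                           protein_b = pmax(a[keep], b[keep]),
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Simulate a protein-to-term annotation table
#'
#' Each term annotates a uniform random subset of the proteins.
#'
#' @param proteins Character vector of protein ids.
#' @param n_terms Number of terms.
#' @param term_size_range Min/max proteins per term.
#' @param seed Integer RNG seed.
#' @return data.frame with `protein_id`, `term`.
#' @export
simulate_annotations <- function(proteins, n_terms = 20L,
                                 term_size_range = c(5L, 50L), seed) {
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(n_terms), function(i) {
    hi <- min(term_size_range[[2L]], length(proteins))
    size <- term_size_range[[1L]] +
      sample.int(hi - term_size_range[[1L]] + 1L, 1L) - 1L
    data.frame(protein_id = sample(proteins, size),
               term = sprintf("TERM%04d", i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated study as a pipeline input bundle
#'
#' Emits exactly the file formats the readers consume: one aligned FASTA
#' per family under `families/`, plus `sites.tsv`, `motifs.tsv` and a
#' `truth.tsv` sidecar with the planted expectations; optionally kinase,
#' interaction and annotation tables.
#'
#' @param sim Output of [simulate_families()].
#' @param dir Output directory (created if needed).
#' @param kinase_sim Optional output of [simulate_kinase_data()].
#' @param interactions Optional interaction edge data.frame.
#' @param annotations Optional annotation data.frame.
#' @return Named list of written paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir, kinase_sim = NULL,
                             interactions = NULL, annotations = NULL) {
  fam_dir <- file.path(dir, "families")
  dir.create(fam_dir, recursive = TRUE, showWarnings = FALSE)
  for (fam in sim$families)
    write_alignment_family(fam, file.path(fam_dir,
                                          paste0(fam$cluster_id, ".fasta")))
  paths <- list(families_dir = fam_dir,
                sites = file.path(dir, "sites.tsv"),
                motifs = file.path(dir, "motifs.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_site_table(sim$sites, paths$sites)
  write_motif_table(sim$truth$config$motifs, paths$motifs)
  .write_tsv(sim$truth$expected_ci, paths$truth,
             sort_by = c("motif_id", "class"))
  if (!is.null(kinase_sim)) {
    paths$kinases <- file.path(dir, "kinases.tsv")
    kin <- kinase_sim$kinases
    for (g in sim$truth$config$genomes$codes)
      kin[[g]] <- as.integer(kin[[g]])
    .write_tsv(kin, paths$kinases, sort_by = "kinase_id")
    paths$kinase_edges <- file.path(dir, "kinase_edges.tsv")
    .write_tsv(kinase_sim$edges, paths$kinase_edges,
               sort_by = c("kinase_id", "protein_id", "position"))
  }
  if (!is.null(interactions)) {
    paths$interactions <- file.path(dir, "interactions.tsv")
    .write_tsv(interactions, paths$interactions,
               sort_by = c("protein_a", "protein_b"))
  }
  if (!is.null(annotations)) {
    paths$annotations <- file.path(dir, "annotations.tsv")
    .write_tsv(annotations, paths$annotations,
               sort_by = c("term", "protein_id"))
  }
  invisible(paths)
}
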