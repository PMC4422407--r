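# End-to-end orchestration: match -> conserve -> ci -> compare -> bin ->
# kinases -> enrich -> network, with a declarative validated config,
# deterministic outputs and a machine-readable run manifest.

#' Validated pipeline configuration
#'
#' Collects input paths, the genome set, analysis switches and the seed.
#' Referenced paths are checked at construction time; a missing path is a
#' validation error (class `phosmoca_validation_error`) raised before any
#' computation.
#'
#' @param motifs Path to the motif table TSV.
#' @param sites Path to the phosphosite table TSV.
#' @param families_dir Directory of per-cluster aligned FASTA files.
#' @param out_dir Output directory (created by [run_pipeline()]).
#' @param kinases,kinase_edges,interactions,annotations Optional input
#'   table paths; the corresponding stages are skipped when absent.
#' @param genomes A [genome_set()].
#' @param seed Integer seed for the stochastic stages (background
#'   subsampling, network permutations).
#' @param class_size CI-rank bin size (default 10).
#' @param alpha_p,alpha_fdr Enrichment thresholds (default 0.01 each).
#' @param n_perm Network permutations (default 999).
#' @param denominator `"all"` or `"aligned_only"` (see
#'   [motif_conservation_rates()]).
#' @param fraction_unit `"edge"` or `"protein"` (see
#'   [kinase_fractions()]).
#' @param background_max Cap on background STY sites used for reference
#'   rates; larger backgrounds are subsampled with the run seed.
#' @param min_sites Minimum sites per motif and class for a CI.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(motifs, sites, families_dir, out_dir,
                            kinases = NULL, kinase_edges = NULL,
                            interactions = NULL, annotations = NULL,
                            genomes = genome_set(), seed = 1L,
                            class_size = 10L, alpha_p = 0.01,
                            alpha_fdr = 0.01, n_perm = 999L,
                            denominator = "all", fraction_unit = "edge",
                            background_max = 20000L, min_sites = 3L) {
  fail <- function(...) {
    stop(structure(class = c("phosmoca_validation_error", "error",
                             "condition"),
                   list(message = paste0(...), call = sys.call(-1L))))
  }
  need_file <- function(path, what) {
    if (!is.null(path) && !file.exists(path))
      fail("config: ", what, " path does not exist: ", path)
    path
  }
  if (!dir.exists(families_dir))
    fail("config: families directory does not exist: ", families_dir)
  if (!denominator %in% c("all", "aligned_only"))
    fail("config: unknown denominator '", denominator, "'")
  if (!fraction_unit %in% c("edge", "protein"))
    fail("config: unknown fraction_unit '", fraction_unit, "'")
  structure(list(
    motifs = need_file(motifs, "motif table"),
    sites = need_file(sites, "site table"),
    families_dir = families_dir,
    kinases = need_file(kinases, "kinase table"),
    kinase_edges = need_file(kinase_edges, "kinase-substrate edge table"),
    interactions = need_file(interactions, "interaction table"),
    annotations = need_file(annotations, "annotation table"),
    out_dir = out_dir, genomes = genomes, seed = as.integer(seed),
    class_size = as.integer(class_size), alpha_p = alpha_p,
    alpha_fdr = alpha_fdr, n_perm = as.integer(n_perm),
    denominator = denominator, fraction_unit = fraction_unit,
    background_max = as.integer(background_max),
    min_sites = as.integer(min_sites)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  for (key in c("motifs", "sites", "families_dir", "kinases",
                "kinase_edges", "interactions", "annotations", "out_dir"))
    raw[[key]] <- resolve(raw[[key]])
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

.log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the full conservation pipeline
#'
#' Executes the stages in order — match, conserve, ci, compare, bin,
#' kinases, enrich, network — writing each stage's TSV output under
#' `out_dir` before the next stage starts, and finally a `manifest.json`
#' recording the config, seed and per-stage row counts. Stages whose
#' optional inputs are absent are recorded as skipped. Rerunning with an
#' identical config and seed reproduces byte-identical outputs. Progress
#' is logged to standard error; results never are.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  genomes <- config$genomes
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "phosmoca",
                   version = as.character(utils::packageVersion("phosmoca")),
                   seed = config$seed,
                   genomes = genomes$codes,
                   reference = genomes$reference,
                   denominator = config$denominator,
                   stages = list())
  note <- function(stage, status, rows) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = stage, status = status, rows = as.integer(rows))
  }
  run_stage <- function(stage, expr) {
    .log_stage(stage, "running")
    tryCatch(expr, error = function(e) {
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(name) file.path(config$out_dir, name)
  results <- list()

  # ---- stage 1: match motifs to phosphosites -------------------------
  matches <- run_stage("match", {
    patterns <- read_motif_table(config$motifs)
    sites <- read_site_table(config$sites)
    fasta <- sort(list.files(config$families_dir,
                             pattern = "\\.(fa|fasta|afa)$",
                             full.names = TRUE))
    if (length(fasta) == 0L)
      stop("no alignment files in ", config$families_dir)
    families <- read_alignment_families(fasta, genomes)
    family_index <- build_family_index(families, genomes)
    seqs <- new.env(parent = emptyenv())
    seq_of <- function(p) {
      if (is.null(seqs[[p]])) {
        fi <- family_index[[p]]
        seqs[[p]] <- ungapped_sequence(families[[fi]], p)
      }
      seqs[[p]]
    }
    usable <- sites$protein_id %in% names(family_index)
    rows <- list()
    for (mid in names(patterns)) {
      pat <- patterns[[mid]]
      acc <- pat$positions[[pat$acceptor_offset + 1L]]
      cand <- which(usable & sites$residue %in% acc)
      hit <- vapply(cand, function(i) {
        match_at(pat, seq_of(sites$protein_id[[i]]), sites$position[[i]])
      }, logical(1L))
      if (any(hit))
        rows[[mid]] <- cbind(motif_id = mid,
                             sites[cand[hit], , drop = FALSE])
    }
    tab <- if (length(rows)) do.call(rbind, rows) else
      data.frame(motif_id = character(0), protein_id = character(0),
                 position = integer(0), residue = character(0),
                 status = character(0))
    rownames(tab) <- NULL
    .write_tsv(tab, out("matches.tsv"),
               sort_by = c("motif_id", "protein_id", "position", "status"))
    note("match", "ok", nrow(tab))
    list(patterns = patterns, sites = sites, families = families,
         family_index = family_index, matches = tab)
  })
  results$matches <- matches$matches

  # ---- stage 2: per-site conservation calls --------------------------
  profiles <- run_stage("conserve", {
    profs <- list()
    calls <- list()
    for (mid in unique(matches$matches$motif_id)) {
      for (cls in c("known", "potential")) {
        ms <- matches$matches[matches$matches$motif_id == mid &
                                matches$matches$status == cls, ,
                              drop = FALSE]
        if (nrow(ms) < config$min_sites) next
        prof <- motif_conservation_rates(
          matches$families, ms, matches$patterns[[mid]], genomes,
          class = cls, denominator = config$denominator,
          family_index = matches$family_index)
        profs[[paste(mid, cls, sep = "|")]] <- prof
        calls[[paste(mid, cls, sep = "|")]] <-
          cbind(motif_id = mid, class = cls, prof$calls)
      }
    }
    call_tab <- if (length(calls)) do.call(rbind, calls) else
      data.frame(motif_id = character(0), class = character(0),
                 protein_id = character(0), position = integer(0),
                 genome = character(0), verdict = character(0))
    rownames(call_tab) <- NULL
    .write_tsv(call_tab, out("conservation_calls.tsv"),
               sort_by = c("motif_id", "class", "protein_id", "position",
                           "genome"))
    note("conserve", "ok", nrow(call_tab))
    profs
  })

  # ---- stage 3: reference rates and conservation indices -------------
  ci_records <- run_stage("ci", {
    known_prot <- unique(matches$sites$protein_id[
      matches$sites$status == "known"])
    if (length(known_prot) == 0L)
      known_prot <- unique(matches$sites$protein_id)
    bg <- enumerate_sty_sites(matches$families, genomes,
                              proteins = known_prot)
    if (nrow(bg) > config$background_max) {
      set.seed(config$seed)
      bg <- bg[sort(sample.int(nrow(bg), config$background_max)), ,
               drop = FALSE]
    }
    refs <- reference_rates(matches$families, bg, genomes,
                            denominator = config$denominator,
                            family_index = matches$family_index)
    recs <- lapply(profiles, conservation_index, refs = refs)
    tab <- do.call(rbind, lapply(recs, function(r) {
      row <- data.frame(motif_id = r$motif_id, class = r$class,
                        n_sites = r$n_sites, ci = r$ci,
                        stringsAsFactors = FALSE)
      for (q in genomes$codes) {
        row[[paste0("C_", q)]] <- r$C[[q]]
        row[[paste0("R_", q)]] <- r$R[[q]]
      }
      row
    }))
    if (is.null(tab))
      tab <- data.frame(motif_id = character(0), class = character(0),
                        n_sites = integer(0), ci = numeric(0))
    rownames(tab) <- NULL
    .write_tsv(tab, out("ci.tsv"), sort_by = c("motif_id", "class"))
    note("ci", "ok", nrow(tab))
    list(records = recs, refs = refs, table = tab, background = bg)
  })
  results$ci <- ci_records$table

  # ---- stage 4: known versus potential comparison --------------------
  results$compare <- run_stage("compare", {
    recs <- ci_records$records
    cls <- vapply(recs, `[[`, character(1L), "class")
    known <- recs[cls == "known"]
    pot <- recs[cls == "potential"]
    shared <- length(known) > 0L && length(pot) > 0L &&
      length(intersect(vapply(known, `[[`, character(1L), "motif_id"),
                       vapply(pot, `[[`, character(1L), "motif_id"))) > 0L
    if (!shared) {
      note("compare", "skipped", 0L)
      NULL
    } else {
      cmp <- compare_known_vs_potential(known, pot)
      .write_tsv(cmp$pairs, out("compare.tsv"), sort_by = "motif_id")
      note("compare", "ok", nrow(cmp$pairs))
      cmp
    }
  })

  # ---- stage 5: CI-rank bins -----------------------------------------
  results$bins <- run_stage("bin", {
    recs <- ci_records$records
    known <- recs[vapply(recs, `[[`, character(1L), "class") == "known"]
    if (length(known) == 0L) {
      note("bin", "skipped", 0L)
      NULL
    } else {
      b <- bin_ci_distribution(known, matches$patterns, config$class_size)
      .write_tsv(b$bins, out("bins.tsv"), sort_by = "bin")
      note("bin", "ok", nrow(b$bins))
      b
    }
  })

  # ---- stage 6: kinase tabulations -----------------------------------
  results$kinases <- run_stage("kinases", {
    if (is.null(config$kinases) || is.null(config$kinase_edges)) {
      note("kinases", "skipped", 0L)
      NULL
    } else {
      kin <- read_kinase_table(config$kinases, genomes)
      edges <- read_kinase_substrate_edges(config$kinase_edges)
      frac_rows <- list()
      key <- paste(matches$matches$protein_id, matches$matches$position)
      for (mid in unique(matches$matches$motif_id)) {
        mk <- key[matches$matches$motif_id == mid]
        me <- edges[paste(edges$protein_id, edges$position) %in% mk, ,
                    drop = FALSE]
        if (nrow(me) == 0L) next
        for (lvl in c("group", "family")) {
          kf <- kinase_fractions(me, kin, level = lvl,
                                 unit = config$fraction_unit)
          frac_rows[[paste(mid, lvl)]] <- cbind(
            motif_id = mid, n_substrates = kf$n_substrates, level = lvl,
            kf$top)
        }
      }
      # motif assignment needs site-level overlap between the edge table
      # and matched sites; absent overlap yields an empty fraction table
      frac <- if (length(frac_rows)) do.call(rbind, frac_rows) else
        data.frame(motif_id = character(0), n_substrates = integer(0),
                   level = character(0), label = character(0),
                   count = integer(0), fraction = numeric(0),
                   percent = numeric(0))
      rownames(frac) <- NULL
      .write_tsv(frac, out("kinase_fractions.tsv"),
                 sort_by = c("motif_id", "level", "label"))
      exp_tab <- kinase_expansion_table(kin, genomes)
      .write_tsv(exp_tab, out("kinase_expansion.tsv"),
                 sort_by = c("genome", "group"))
      note("kinases", "ok", nrow(frac) + nrow(exp_tab))
      list(fractions = frac, expansion = exp_tab)
    }
  })

  # ---- stage 7: term enrichment --------------------------------------
  results$enrichment <- run_stage("enrich", {
    if (is.null(config$annotations)) {
      note("enrich", "skipped", 0L)
      NULL
    } else {
      ann <- read_annotation_table(config$annotations)
      background <- sort(unique(matches$sites$protein_id))
      ann <- ann[ann$protein_id %in% background, , drop = FALSE]
      rows <- list()
      for (mid in unique(matches$matches$motif_id)) {
        prot <- unique(matches$matches$protein_id[
          matches$matches$motif_id == mid &
            matches$matches$status == "known"])
        if (length(prot) == 0L) next
        enr <- term_enrichment(prot, ann, background,
                               alpha_p = config$alpha_p,
                               alpha_fdr = config$alpha_fdr)
        rows[[mid]] <- cbind(motif_id = mid, enr)
      }
      tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(motif_id = character(0), term = character(0))
      rownames(tab) <- NULL
      .write_tsv(tab, out("enrichment.tsv"),
                 sort_by = c("motif_id", "term"))
      note("enrich", "ok", nrow(tab))
      tab
    }
  })

  # ---- stage 8: motif-sharing network statistic ----------------------
  results$network <- run_stage("network", {
    if (is.null(config$interactions)) {
      note("network", "skipped", 0L)
      NULL
    } else {
      inter <- read_interaction_edges(config$interactions)
      nodes <- unique(c(inter$protein_a, inter$protein_b))
      rows <- list()
      subnets <- list()
      mids <- sort(unique(matches$matches$motif_id))
      for (i in seq_along(mids)) {
        mid <- mids[[i]]
        prot <- intersect(unique(matches$matches$protein_id[
          matches$matches$motif_id == mid]), nodes)
        if (length(prot) < 2L) next
        st <- motif_network_statistic(inter, prot, config$n_perm,
                                      seed = config$seed + i)
        rows[[mid]] <- data.frame(
          motif_id = mid, n_proteins = st$set_size,
          observed_edges = st$observed, p_value = st$p_value,
          n_perm = st$n_perm, stringsAsFactors = FALSE)
        if (nrow(st$subnetwork))
          subnets[[mid]] <- cbind(motif_id = mid, st$subnetwork)
      }
      tab <- if (length(rows)) do.call(rbind, rows) else
        data.frame(motif_id = character(0), n_proteins = integer(0),
                   observed_edges = integer(0), p_value = numeric(0),
                   n_perm = integer(0))
      rownames(tab) <- NULL
      .write_tsv(tab, out("network.tsv"), sort_by = "motif_id")
      sub <- if (length(subnets)) do.call(rbind, subnets) else
        data.frame(motif_id = character(0), protein_a = character(0),
                   protein_b = character(0))
      rownames(sub) <- NULL
      .write_tsv(sub, out("network_edges.tsv"),
                 sort_by = c("motif_id", "protein_a", "protein_b"))
      note("network", "ok", nrow(tab))
      tab
    }
  })

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .log_stage("done", length(manifest$stages), " stages recorded")
  results$manifest <- manifest
  invisible(results)
}
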