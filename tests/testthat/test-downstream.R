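fake_record <- function(id, ci, class = "known") {
  structure(list(motif_id = id, class = class, ci = ci,
                 n_sites = 10L), class = "ci_record")
}

test_that("known-vs-potential comparison handles identity and few pairs", {
  k <- lapply(1:5, function(i) fake_record(paste0("m", i), i / 2))
  cmp <- compare_known_vs_potential(k, k)
  expect_equal(cmp$pearson_r, 1)
  expect_identical(cmp$n_above, 0L)
  expect_identical(cmp$n_below, 0L)
  expect_identical(cmp$n_equal, 5L)

  p <- lapply(1:5, function(i) fake_record(paste0("m", i), i / 2 - 1))
  cmp2 <- compare_known_vs_potential(k, p)
  expect_identical(cmp2$n_above, 5L)

  expect_warning(cmp3 <- compare_known_vs_potential(k[1:2], k[1:2]),
                 "correlation unavailable")
  expect_true(is.na(cmp3$pearson_r))
  expect_false(cmp3$correlation_available)
  expect_error(compare_known_vs_potential(k[1:2],
                                          list(fake_record("zz", 1))),
               "no motifs shared")
})

test_that("CI-rank bins chunk deterministically and partition the ranking", {
  pats <- c(lapply(1:12, function(i)
              parse_motif_pattern("R-X-X-S/T", sprintf("bas%02d", i))),
            lapply(1:13, function(i)
              parse_motif_pattern("S/T-P", sprintf("stp%02d", i))))
  names(pats) <- vapply(pats, `[[`, character(1), "motif_id")
  set.seed(8)
  recs <- lapply(names(pats), function(id)
    fake_record(id, runif(1, -2, 2)))
  b <- bin_ci_distribution(recs, pats, class_size = 10)
  expect_identical(b$bins$n, c(10L, 10L, 5L))
  # concatenating bins in order reproduces the CI-sorted list exactly
  expect_identical(unname(unlist(b$members)), b$order)
  cis <- vapply(recs, `[[`, numeric(1), "ci")
  names(cis) <- names(pats)
  expect_identical(b$order, names(cis)[order(-cis, names(cis))])
  expect_true(all(diff(cis[b$order]) <= 0))
  # structural counts add up
  expect_identical(sum(b$bins$n_basic), 12L)
  expect_identical(sum(b$bins$n_proline_directed), 13L)
  # 20 motifs, class 10 -> two full bins
  b2 <- bin_ci_distribution(recs[1:20], pats, class_size = 10)
  expect_identical(b2$bins$n, c(10L, 10L))
})

test_that("kinase fractions tabulate edges, proteins and the unclassified", {
  kin <- data.frame(kinase_id = c("k1", "k2", "k3"),
                    group = c("CMGC", "CMGC", "AGC"),
                    family = c("MAPK", "CDK", "PKA"),
                    stringsAsFactors = FALSE)
  edges <- data.frame(
    kinase_id = c("k1", "k1", "k2", "k2", "k3"),
    protein_id = c("A", "B", "B", "C", "D"),
    position = 1:5, residue = "S", stringsAsFactors = FALSE)
  kf <- kinase_fractions(edges, kin, level = "group")
  expect_equal(kf$table$fraction[kf$table$label == "CMGC"], 0.8)
  expect_equal(kf$table$percent[kf$table$label == "CMGC"], 80)
  expect_identical(kf$n_substrates, 5L)
  expect_equal(sum(kf$table$fraction), 1)
  kff <- kinase_fractions(edges, kin, level = "family", top_k = 2)
  expect_identical(nrow(kff$top), 2L)
  # distinct-protein counting
  kfp <- kinase_fractions(edges, kin, level = "group", unit = "protein")
  expect_equal(kfp$table$count[kfp$table$label == "CMGC"], 3L)
  # unclassified kinases are warned and kept; fractions still sum to 1
  edges2 <- rbind(edges, data.frame(kinase_id = "k9", protein_id = "E",
                                    position = 6L, residue = "S"))
  expect_warning(kf2 <- kinase_fractions(edges2, kin), "unclassified")
  expect_equal(sum(kf2$table$fraction), 1)
  expect_true("unclassified" %in% kf2$table$label)
  expect_error(kinase_fractions(edges[0, ], kin), "empty")
})

test_that("kinase expansion tabulates counts and renormalized fractions", {
  g <- genome_set(c("mmu", "hsa"), "hsa")
  kin <- data.frame(kinase_id = paste0("k", 1:10),
                    group = rep(c("AGC", "CMGC"), each = 5),
                    family = "f",
                    mmu = TRUE, hsa = TRUE, stringsAsFactors = FALSE)
  tab <- kinase_expansion_table(kin, g)
  expect_true(all(tab$total == 10L))
  expect_true(all(tab$fraction == 0.5))
  # removing one group's kinases from one genome renormalizes the rest
  kin$mmu[kin$group == "CMGC"] <- FALSE
  tab2 <- kinase_expansion_table(kin, g)
  expect_equal(tab2$total[tab2$genome == "mmu"][1], 5L)
  expect_equal(tab2$fraction[tab2$genome == "mmu" & tab2$group == "AGC"], 1)
  agg <- tapply(tab2$fraction, tab2$genome, sum)
  expect_true(all(abs(agg - 1) < 1e-12))
  # random presence tables match an independent tally
  set.seed(13)
  kin$mmu <- runif(10) < 0.6
  tab3 <- kinase_expansion_table(kin, g)
  for (grp in c("AGC", "CMGC")) {
    expect_identical(
      tab3$count[tab3$genome == "mmu" & tab3$group == grp],
      sum(kin$mmu & kin$group == grp))
  }
})

test_that("hypergeometric enrichment equals direct mass summation", {
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(10:50, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    background <- sprintf("P%02d", 1:N)
    term_prot <- sample(background, K)
    setp <- sample(background, n)
    ann <- data.frame(protein_id = term_prot, term = "T1",
                      stringsAsFactors = FALSE)
    res <- term_enrichment(setp, ann, background, alpha_p = 1, alpha_fdr = 1)
    k <- length(intersect(term_prot, setp))
    expect_identical(res$overlap, as.integer(k))
    expect_equal(res$p_value, direct_hyper_tail(k, K, N, n),
                 tolerance = 1e-12)
  }
  # a term fully private to the set is maximally significant
  background <- sprintf("P%02d", 1:30)
  ann <- data.frame(protein_id = background[1:5], term = "T1")
  res <- term_enrichment(background[1:5], ann, background)
  expect_equal(res$p_value, 1 / choose(30, 5), tolerance = 1e-12)
  expect_true(res$significant)
  # zero overlap with a large term is never significant
  ann2 <- data.frame(protein_id = background[6:30], term = "T2")
  res2 <- term_enrichment(background[1:5], ann2, background)
  expect_gt(res2$p_value, 0.99)
  expect_false(res2$significant)
})

test_that("BH adjustment is monotone and both cutoffs gate significance", {
  background <- sprintf("P%03d", 1:100)
  set.seed(23)
  ann <- do.call(rbind, lapply(1:8, function(i)
    data.frame(protein_id = sample(background, sample(10:40, 1)),
               term = paste0("T", i), stringsAsFactors = FALSE)))
  res <- term_enrichment(sample(background, 20), ann, background)
  expect_true(all(res$fdr >= res$p_value - 1e-12))
  expect_true(all(diff(res$fdr[order(res$p_value)]) >= -1e-12))
  expect_true(all(res$significant == (res$p_value < 0.01 & res$fdr < 0.01)))
  expect_error(term_enrichment(c("QQQ"), ann, background), "subset")
  expect_warning(
    term_enrichment(background[1:3],
                    rbind(ann, data.frame(protein_id = "ZZZ", term = "T9")),
                    background),
    "outside the background")
})

test_that("network statistic saturates, is deterministic and label-invariant", {
  set.seed(29)
  nodes <- sprintf("N%03d", 1:60)
  inter <- simulate_interactions(nodes, 150, seed = 5)
  st <- motif_network_statistic(inter, nodes, n_perm = 199, seed = 1)
  expect_identical(st$observed, nrow(inter))
  expect_equal(st$p_value, 1)
  st1 <- motif_network_statistic(inter, nodes[1:15], n_perm = 199, seed = 7)
  st2 <- motif_network_statistic(inter, nodes[1:15], n_perm = 199, seed = 7)
  expect_identical(st1$p_value, st2$p_value)
  expect_identical(st1$null_counts, st2$null_counts)
  # node relabeling leaves the p-value untouched
  relabel <- stats::setNames(sprintf("Z%03d", seq_along(nodes)), nodes)
  inter_r <- data.frame(protein_a = pmin(relabel[inter$protein_a],
                                         relabel[inter$protein_b]),
                        protein_b = pmax(relabel[inter$protein_a],
                                         relabel[inter$protein_b]),
                        stringsAsFactors = FALSE)
  st3 <- motif_network_statistic(inter_r, unname(relabel[nodes[1:15]]),
                                 n_perm = 199, seed = 7)
  expect_identical(st3$observed, st1$observed)
  # proteins absent from the network are dropped from the set
  st4 <- motif_network_statistic(inter, c(nodes[1:15], "EXTRA1", "EXTRA2"),
                                 n_perm = 199, seed = 7)
  expect_identical(st4$set_size, 15L)
  expect_identical(st4$observed, st1$observed)
  expect_error(motif_network_statistic(inter, sprintf("M%03d", 1:100),
                                       n_perm = 199, seed = 1), "exceeds")
  expect_error(motif_network_statistic(inter, nodes[1:5], n_perm = 10,
                                       seed = 1), "at least 100")
})

test_that("kinase group substrate CI depends only on the site set", {
  sim <- tiny_sim(seed = 41, n_known = 12, indel_rate = 0)
  g <- genome_set()
  fi <- build_family_index(sim$families, g)
  refs <- reference_rates(sim$families, background_sites(sim, 1500), g,
                          family_index = fi)
  known <- sim$sites[sim$sites$status == "known", , drop = FALSE]
  kin <- data.frame(kinase_id = c("kA", "kB"), group = c("G1", "G2"),
                    family = "f", stringsAsFactors = FALSE)
  # two groups with identical substrate sets get identical CIs
  edges <- rbind(
    data.frame(kinase_id = "kA", protein_id = known$protein_id,
               position = known$position, residue = known$residue),
    data.frame(kinase_id = "kB", protein_id = known$protein_id,
               position = known$position, residue = known$residue))
  res <- kinase_group_substrate_ci(edges, kin, sim$families, refs, g,
                                   family_index = fi)
  expect_identical(nrow(res), 2L)
  expect_equal(res$ci[1], res$ci[2], tolerance = 1e-12)
  expect_false(any(res$low_support[res$n_sites >= 10]))
  # unresolvable substrates are dropped; an all-unresolvable group warns
  edges2 <- rbind(edges[edges$kinase_id == "kA", ],
                  data.frame(kinase_id = "kB", protein_id = "NOPE",
                             position = 3L, residue = "S"))
  expect_warning(res2 <- kinase_group_substrate_ci(edges2, kin,
                                                   sim$families, refs, g,
                                                   family_index = fi),
                 "G2")
  expect_identical(res2$group, "G1")
})
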