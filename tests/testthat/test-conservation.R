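test_that("ungapped/column maps invert each other", {
  expect_identical(ungapped_to_column("AC-DE", 3), 4L)
  expect_identical(ungapped_to_column("ACDE", 2), 2L)  # identity, no gaps
  expect_error(ungapped_to_column("AC-DE", 5), "exceeds")
  expect_identical(column_to_ungapped("AC-DE", 4), 3L)
  expect_true(is.na(column_to_ungapped("AC-DE", 3)))
  expect_error(column_to_ungapped("AC-DE", 9), "out of range")

  set.seed(2)
  for (i in 1:100) {
    n <- sample.int(40, 1) + 5
    chars <- sample(c(ORACLE_AA, "-", "-"), n, replace = TRUE)
    if (!any(chars != "-")) chars[1] <- "A"
    row <- paste(chars, collapse = "")
    ung <- sum(chars != "-")
    pos <- sample.int(ung, 1)
    col <- ungapped_to_column(row, pos)
    expect_identical(column_to_ungapped(row, col), pos)
  }
})

test_that("single-site conservation calls honor gaps and missing orthologs", {
  pat <- parse_motif_pattern("R-X-X-S/T")
  fam <- ortholog_family("OC1",
    c("hsa", "mmu", "dre"),
    c("P1", "P1_mmu", "P1_dre"),
    c("AR--PGSAP",
      "AR--PGSAP",    # identical: conserved
      "ARA-PG-AP"))   # gap in a motif column: not conserved
  # human window: R at ungapped 2, S at ungapped 5
  expect_identical(
    call_site_conservation(fam, "P1", list(position = 5), pat, "mmu")$verdict,
    "conserved")
  expect_identical(
    call_site_conservation(fam, "P1", list(position = 5), pat, "dre")$verdict,
    "not_conserved")
  expect_identical(
    call_site_conservation(fam, "P1", list(position = 5), pat, "cel")$verdict,
    "no_ortholog")
  # violated precondition: the human window must match the pattern
  expect_error(
    call_site_conservation(fam, "P1", list(position = 4), pat, "mmu"),
    "does not match")
  expect_error(
    call_site_conservation(fam, "P2", list(position = 5), pat, "mmu"),
    "P2")
})

test_that("any member of a genome can carry the conserved window", {
  pat <- parse_motif_pattern("S/T-P")
  fam <- ortholog_family("OC1",
    c("hsa", "mmu", "mmu"),
    c("P1", "P1_mmu_a", "P1_mmu_b"),
    c("ASPA", "AAAA", "ASPA"))
  expect_identical(
    call_site_conservation(fam, "P1", list(position = 2), pat, "mmu")$verdict,
    "conserved")
})

test_that("conservation rates count sites exactly", {
  pat <- parse_motif_pattern("S/T-P")
  mk <- function(i, mouse) ortholog_family(
    paste0("OC", i), c("hsa", "mmu"), c(paste0("P", i), paste0("P", i, "m")),
    c("ASPA", mouse))
  fams <- list(mk(1, "ASPA"), mk(2, "ASPA"), mk(3, "ASPA"), mk(4, "AAPA"))
  sites <- data.frame(protein_id = paste0("P", 1:4), position = 2L,
                      residue = "S", status = "known",
                      stringsAsFactors = FALSE)
  prof <- motif_conservation_rates(fams, sites, pat)
  expect_equal(unname(prof$conserved[["mmu"]]), 3)
  expect_equal(prof$rate[["mmu"]], 0.75)
  expect_equal(prof$rate[["hsa"]], 1)          # reference self-conservation
  expect_equal(prof$rate[["dre"]], 0)          # absent genome stays in the
  expect_equal(unname(prof$total[["dre"]]), 4L)  # denominator
  expect_error(motif_conservation_rates(fams, sites[0, ], pat), "empty")

  # aligned_only drops missing orthologs from the denominator
  expect_error(
    motif_conservation_rates(fams, sites, pat, denominator = "aligned_only"),
    "zero denominator")
})

test_that("reference rates are exact on identical rows and 1 for the reference", {
  fams <- list(ortholog_family("OC1", c("hsa", "mmu"), c("P1", "P1m"),
                               c("ASTYA", "ASTYA")))
  bg <- enumerate_sty_sites(fams)
  expect_identical(nrow(bg), 3L)
  refs <- reference_rates(fams, bg)
  expect_equal(unname(refs$rate[, "mmu"]), c(1, 1, 1))
  expect_equal(unname(refs$rate[, "hsa"]), c(1, 1, 1))
  expect_equal(unname(refs$rate["S", "dre"]), 0)  # no ortholog counts against
})

test_that("the conservation index is the sum of C - R differences", {
  g2 <- genome_set(c("mmu", "dre", "hsa"), "hsa")
  prof <- structure(list(
    motif_id = "m", class = "known", genomes = g2,
    conserved = c(mmu = 8, dre = 6, hsa = 10),
    total = c(mmu = 10, dre = 10, hsa = 10),
    rate = c(mmu = 0.8, dre = 0.6, hsa = 1),
    n_sites = 10L, acceptor_mix = c(S = 10, T = 0, Y = 0), calls = NULL),
    class = "conservation_profile")
  refs <- structure(list(
    rate = matrix(c(0.5, 0.5, 1, 0.5, 0.5, 1, 0.5, 0.5, 1), nrow = 3,
                  byrow = TRUE,
                  dimnames = list(c("S", "T", "Y"), c("mmu", "dre", "hsa"))),
    conserved = NULL,
    total = matrix(100, 3, 3,
                   dimnames = list(c("S", "T", "Y"), c("mmu", "dre", "hsa"))),
    genomes = g2), class = "reference_rates")
  rec <- conservation_index(prof, refs)
  expect_equal(rec$ci, 0.4)
  expect_equal(unname(rec$terms[["hsa"]]), 0)  # reference contributes zero
  # null case: C = R everywhere
  prof$rate <- c(mmu = 0.5, dre = 0.5, hsa = 1)
  refs$rate["S", "hsa"] <- 1
  rec0 <- conservation_index(prof, refs)
  expect_equal(rec0$ci - rec0$terms[["hsa"]], 0)
})

test_that("CI matches an arithmetic oracle and is monotone in C_q", {
  set.seed(4)
  g <- genome_set()
  codes <- g$codes
  for (i in 1:20) {
    C <- stats::setNames(c(runif(8), 1), codes)
    Rmat <- matrix(runif(27), 3, 9,
                   dimnames = list(c("S", "T", "Y"), codes))
    Rmat[, "hsa"] <- 1
    mix <- c(S = sample(0:5, 1), T = sample(0:5, 1), Y = sample(0:5, 1))
    if (sum(mix) == 0) mix["S"] <- 1
    prof <- structure(list(motif_id = "m", class = "known", genomes = g,
                           conserved = C * 100, total = rep(100, 9),
                           rate = C, n_sites = 100L, acceptor_mix = mix,
                           calls = NULL), class = "conservation_profile")
    refs <- structure(list(rate = Rmat, total = matrix(100, 3, 9,
                             dimnames = dimnames(Rmat)), genomes = g),
                      class = "reference_rates")
    rec <- conservation_index(prof, refs)
    w <- mix / sum(mix)
    expected <- 0
    for (q in codes) {
      Rq <- sum(w * Rmat[, q])
      expected <- expected + (C[[q]] - Rq)
    }
    expect_equal(rec$ci, expected, tolerance = 1e-12)
    expect_true(abs(rec$ci) <= length(codes))
    # strictly increasing in any single C_q
    q <- sample(codes[codes != "hsa"], 1)
    prof2 <- prof
    prof2$rate[[q]] <- min(1, prof$rate[[q]] + 0.05)
    if (prof2$rate[[q]] > prof$rate[[q]])
      expect_gt(conservation_index(prof2, refs)$ci, rec$ci)
  }
})

test_that("verdicts equal the brute-force oracle on simulated families", {
  sim <- tiny_sim(seed = 21, n_known = 25, indel_rate = 2)
  g <- genome_set()
  fi <- build_family_index(sim$families, g)
  for (mid in names(sim$truth$config$motifs)) {
    pat <- sim$truth$config$motifs[[mid]]
    sites <- planted_sites(sim, mid)
    if (nrow(sites) == 0) next
    prof <- motif_conservation_rates(sim$families, sites, pat,
                                     family_index = fi)
    for (i in seq_len(nrow(sites))) {
      fam <- sim$families[[fi[[sites$protein_id[i]]]]]
      for (q in g$codes) {
        got <- prof$calls$verdict[prof$calls$protein_id == sites$protein_id[i] &
                                    prof$calls$position == sites$position[i] &
                                    prof$calls$genome == q]
        expect_identical(got, oracle_verdict(fam, sites$protein_id[i],
                                             sites$position[i], pat, q))
      }
    }
  }
})

test_that("estimated rates concentrate around planted probabilities", {
  cfg <- sim_config(motifs = "R-X-X-S/T", n_known = 400, p_known = 0.8,
                    p_bg = 0.5, protein_length = c(150L, 250L), seed = 31)
  sim <- simulate_families(cfg)
  g <- genome_set()
  fi <- build_family_index(sim$families, g)
  sites <- planted_sites(sim, "R-X-X-S/T")
  prof <- motif_conservation_rates(sim$families, sites,
                                   cfg$motifs[[1]], family_index = fi)
  tol <- 3 * sqrt(0.8 * 0.2 / nrow(sites))
  for (q in setdiff(g$codes, "hsa"))
    expect_lt(abs(prof$rate[[q]] - 0.8), tol)
  bg <- background_sites(sim, 2000)
  refs <- reference_rates(sim$families, bg, g, family_index = fi)
  for (q in setdiff(g$codes, "hsa")) {
    m <- refs$total["S", q]
    expect_lt(abs(refs$rate["S", q] - 0.5), 3 * sqrt(0.25 / m))
  }
  expect_equal(unname(refs$rate[, "hsa"]), c(1, 1, 1))
})
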