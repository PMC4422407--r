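# Independent reference implementations used as oracles. They share no
# code with the package internals: motif matching goes through regular
# expressions, column mapping through explicit character walks, and the
# CI through plain loops.

ORACLE_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Regex for one parsed pattern position ("X" is the wildcard sentinel).
oracle_position_regex <- function(set) {
  if (identical(set, "X")) "[^-]" else paste0("[", paste(set, collapse = ""), "]")
}

# All acceptor positions of `pattern` in `sequence`, via a lookahead
# regex over the full window (overlapping matches included).
oracle_scan <- function(pattern, sequence) {
  rx <- paste0("(?=", paste(vapply(pattern$positions, oracle_position_regex,
                                   character(1)), collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) + pattern$acceptor_offset
}

# Column indices of the window around ungapped `position`, by walking the
# row character by character.
oracle_window_columns <- function(aligned_row, position, pattern) {
  chars <- strsplit(aligned_row, "")[[1]]
  want <- position + seq_along(pattern$positions) - 1 - pattern$acceptor_offset
  cols <- integer(length(want))
  seen <- 0
  for (col in seq_along(chars)) {
    if (chars[col] != "-") {
      seen <- seen + 1
      hit <- which(want == seen)
      if (length(hit)) cols[hit] <- col
    }
  }
  if (any(want < 1) || any(want > seen)) return(NULL)
  cols
}

# Conservation verdict of one site in one genome, re-deriving columns and
# matching the extracted window with a regex.
oracle_verdict <- function(family, human_protein, position, pattern, genome,
                           reference = "hsa") {
  if (genome == reference) return("conserved")
  hrow <- family$rows[family$protein_id == human_protein &
                        family$genome == reference]
  cols <- oracle_window_columns(hrow[1], position, pattern)
  stopifnot(!is.null(cols))
  rx <- paste0("^", paste(vapply(pattern$positions, oracle_position_regex,
                                 character(1)), collapse = ""), "$")
  members <- which(family$genome == genome)
  if (length(members) == 0) return("no_ortholog")
  for (m in members) {
    win <- paste(strsplit(family$rows[m], "")[[1]][cols], collapse = "")
    if (grepl(rx, win)) return("conserved")
  }
  "not_conserved"
}

# From-scratch C_q, R_q and CI over a family list: plain loops, missing
# orthologs count as not conserved, R_q is the acceptor-mix-weighted
# background rate.
oracle_ci <- function(families, sites, pattern, bg_sites, codes,
                      reference = "hsa") {
  fam_of <- list()
  for (f in families) {
    for (p in f$protein_id[f$genome == reference]) {
      if (is.null(fam_of[[p]]) ||
          length(unique(f$genome)) >
            length(unique(fam_of[[p]]$genome)))
        fam_of[[p]] <- f
    }
  }
  rate_of <- function(tab, pat) {
    sapply(codes, function(q) {
      hits <- 0
      for (i in seq_len(nrow(tab))) {
        f <- fam_of[[tab$protein_id[i]]]
        v <- if (is.null(f)) {
          if (q == reference) "conserved" else "no_ortholog"
        } else {
          oracle_verdict(f, tab$protein_id[i], tab$position[i], pat, q,
                         reference)
        }
        if (v == "conserved") hits <- hits + 1
      }
      hits / nrow(tab)
    })
  }
  C <- rate_of(sites, pattern)
  single <- function(r) structure(
    list(motif_id = r, raw = r, positions = list(r), acceptor_offset = 0L),
    class = "motif_pattern")
  Rtypes <- list()
  for (r in unique(bg_sites$residue))
    Rtypes[[r]] <- rate_of(bg_sites[bg_sites$residue == r, , drop = FALSE],
                           single(r))
  mix <- table(sites$residue)
  w <- mix / sum(mix)
  R <- rep(0, length(codes)); names(R) <- codes
  for (r in names(w)) R <- R + as.numeric(w[[r]]) * Rtypes[[r]]
  list(C = C, R = R, ci = sum(C - R))
}

# Upper-tail hypergeometric probability by direct mass summation.
direct_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Small deterministic simulated study reused by several test files.
tiny_sim <- function(seed = 7, n_known = 8, indel_rate = 2) {
  cfg <- sim_config(n_known = n_known, p_known = 0.8, p_bg = 0.5,
                    protein_length = c(60L, 90L), indel_rate = indel_rate,
                    seed = seed)
  simulate_families(cfg)
}

# Planted known sites of one motif from a simulation.
planted_sites <- function(sim, motif_id, status = "known") {
  s <- sim$sites
  s[!is.na(s$motif_id) & s$motif_id == motif_id & s$status == status, ,
    drop = FALSE]
}

# Background (unplanted) STY sites from a simulation.
background_sites <- function(sim, n = NULL, seed = 1) {
  s <- sim$sites[is.na(sim$sites$motif_id), c("protein_id", "position",
                                              "residue")]
  if (!is.null(n) && nrow(s) > n) {
    set.seed(seed)
    s <- s[sort(sample.int(nrow(s), n)), , drop = FALSE]
  }
  s
}
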