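# Independent brute-force oracle for the fitting restriction-map alignment:
# enumerates every monotone block decomposition of the query against every
# reference window by plain recursion (with a sound branch-and-bound cutoff)
# and returns the minimal total cost under the same scoring definition.
oracle_fit_cost <- function(q, r, sigma_rel, cut_penalty, delta_max) {
  m <- length(q); n <- length(r)
  best <- Inf
  block_cost <- function(sq, sr, nq, nr, boundary) {
    d <- sq - sr
    sizing <- if (boundary && d <= 0) 0 else d^2 / (2 * (sigma_rel * sr)^2)
    sizing + cut_penalty * ((nq - 1) + (nr - 1))
  }
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible(NULL))
    if (i == m) { best <<- acc; return(invisible(NULL)) }
    for (a in seq_len(min(delta_max, m - i))) {
      for (b in seq_len(min(delta_max, n - j))) {
        boundary <- (i == 0L) || (i + a == m)
        sq <- sum(q[(i + 1):(i + a)])
        sr <- sum(r[(j + 1):(j + b)])
        rec(i + a, j + b, acc + block_cost(sq, sr, a, b, boundary))
      }
    }
  }
  for (s in 0:(n - 1L)) rec(0L, s, 0)
  best
}

# minimal cost reachable by the DP core (forward orientation)
dp_fit_cost <- function(q, r, sigma_rel, cut_penalty, delta_max) {
  min(omfinish:::.rmap_fit_dp(q, r, sigma_rel, cut_penalty,
                              delta_max)$cost_by_end)
}

# fabricate a map_alignment for layout tests without running the aligner
fake_alignment <- function(query_id, ref_id, start, end, cost, p = 0.01,
                           n_frags = 10L, orientation = "forward",
                           query_bp = end - start) {
  structure(list(query_id = query_id, ref_id = ref_id,
                 orientation = orientation,
                 blocks = data.frame(q_start = 1L, q_end = n_frags,
                                     r_start = 1L, r_end = 1L),
                 cost = cost, ref_start_bp = start, ref_end_bp = end,
                 anchors = cbind(ref_bp = c(start, end),
                                 q_bp = c(0, query_bp)),
                 query_bp = query_bp, n_query_frags = as.integer(n_frags),
                 p_value = p), class = "map_alignment")
}

# small collapsed-repeat simulation shared by FRC tests
collapsed_fixture <- function(seed, coverage = 20) {
  cfg <- sim_config(
    chrom_lengths = 300000, seed = seed,
    repeats = list(list(length = 30000, copies = 2, identity = 1.0,
                        chrom = 1, start = 120000)),
    errors = list(list(type = "collapse_repeat", repeat_id = 1)),
    tiling = list(mean_contig = 80000, min_contig = 40000),
    reads = list(read_len = 100, mu = 3000, sd = 300, coverage = coverage))
  tr <- simulate_genome(cfg)
  bad <- fragment_assembly(tr, cfg)
  cfg0 <- cfg; cfg0$errors <- list()
  good <- fragment_assembly(tr, cfg0, seed = cfg$seed + 10L)
  list(cfg = cfg, truth = tr, collapsed = bad, errorfree = good)
}
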