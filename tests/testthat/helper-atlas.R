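# Shared fixtures: a small atlas for fast unit tests, built once per run.

small_sim_config <- function(seed = 101, ...) {
  defaults <- list(n_genes = 600, n_specific_per_domain = 5,
                   archetype_counts = c(CZ = 10, PZ = 10, OC = 10,
                                        core = 10, leaf_up = 10,
                                        leaf_down = 10),
                   n_tf = 60, n_families = 10, genes_per_chrom = 100,
                   n_snps = 60, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

small_atlas <- function() {
  fixture("small_atlas", function() {
    simulate_atlas(small_sim_config(), genome = FALSE, snps = TRUE)
  })
}

small_norm <- function() {
  fixture("small_norm", function() {
    a <- small_atlas()
    normalize_rpm(a$counts, a$design)
  })
}

# direct transliteration of the entropy formula, kept independent of the
# package implementation (explicit loop, no matrix path)
entropy_oracle <- function(x) {
  p <- x / sum(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log2(pi)
  h
}

# brute-force BH oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}
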