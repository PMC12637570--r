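# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (brute-force summation / scanning) and independent of the package
# implementation paths they check.

# Brute-force Poisson upper tail P(X >= k) by pmf summation.
oracle_poisson_upper <- function(k, lambda, k_max = 5000) {
  if (k <= 0) return(1)
  sum(dpois(seq(k, k_max), lambda))
}

# Brute-force Benjamini-Hochberg step-up q-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force single-linkage merge (>= 1 bp overlap) of 0-based half-open
# intervals on one chromosome; returns merged intervals with the set of
# contributing row indices.
oracle_merge <- function(start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && start[i] < end[j] && start[j] < end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), comp), function(idx) {
    list(start = min(start[idx]), end = max(end[idx]), members = idx)
  })
}

# Brute-force two-sided Fisher exact p by hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  a_obs <- tab[1, 1]
  as <- max(0, k - n):min(k, m)
  probs <- dhyper(as, m, n, k)
  p_obs <- dhyper(a_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force both-strand NGG protospacer scan over one sequence.
oracle_protospacers <- function(s) {
  n <- nchar(s)
  out <- list()
  for (i in seq_len(max(0, n - 22))) {
    if (substr(s, i + 21, i + 22) == "GG") {
      out[[length(out) + 1]] <- data.frame(
        protospacer = substr(s, i, i + 19), strand = "+", start = i - 1,
        stringsAsFactors = FALSE)
    }
  }
  rc <- crtkit::revcomp(s)
  for (i in seq_len(max(0, n - 22))) {
    if (substr(rc, i + 21, i + 22) == "GG") {
      out[[length(out) + 1]] <- data.frame(
        protospacer = substr(rc, i, i + 19), strand = "-",
        start = n - (i + 19), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Minimal MPRA design: n_test test tiles + n_scr scrambled tiles.
make_tiles <- function(n_test, n_scr = 0) {
  data.frame(
    tile_id = c(sprintf("t%04d", seq_len(n_test)),
                if (n_scr > 0) sprintf("s%04d", seq_len(n_scr))),
    class = c(rep("test", n_test), rep("scrambled", n_scr)),
    stringsAsFactors = FALSE
  )
}

# Small screen with known structure for testing.
make_screen <- function(n_cells = 2000, n_guides = 60, effects = numeric(),
                        seed = 1, ntc_fraction = 0.1, ...) {
  targets <- data.frame(
    grna_id = paste0("g", seq_len(n_guides)),
    target_gene = paste0("tg", rep(seq_len(ceiling(n_guides / 2)),
                                   each = 2)[seq_len(n_guides)]),
    stringsAsFactors = FALSE
  )
  scr <- gen_screen(targets, n_cells = n_cells,
                    planted_effects = effects,
                    ntc_fraction = ntc_fraction, seed = seed, ...)
  scr$targets <- targets
  scr
}
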