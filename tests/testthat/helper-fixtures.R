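# Shared fixture builders and independent oracles for the test suite.

ss <- hepvalid:::substream_seed

# Small synthetic session for pipeline tests (fast to build).
tiny_session <- function(seed = 1, k = 0, len = 200, ...) {
  assemble_session(sim_config(session_length = len, seed = seed, k = k, ...))
}

# A recording holding a deterministic ramp on one channel, for closed-form
# epoch checks.
ramp_recording <- function(n = 2000, fs = 250, slope = 1) {
  continuous_recording(matrix(slope * (seq_len(n) - 1), 1), fs, "Cz")
}

# ---- independent oracles ---------------------------------------------------

# Brute-force connected components of a channels x time mask by flood fill
# over explicit neighbour offsets. Deliberately naive: used to validate
# find_clusters on small random maps.
oracle_components <- function(mask, adj) {
  nch <- nrow(mask); len <- ncol(mask)
  lab <- matrix(0L, nch, len)
  cur <- 0L
  for (c0 in seq_len(nch)) for (t0 in seq_len(len)) {
    if (!mask[c0, t0] || lab[c0, t0] > 0L) next
    cur <- cur + 1L
    queue <- list(c(c0, t0)); lab[c0, t0] <- cur
    while (length(queue)) {
      node <- queue[[1]]; queue <- queue[-1]
      ch <- node[1]; tt <- node[2]
      nbrs <- list()
      if (tt > 1) nbrs <- c(nbrs, list(c(ch, tt - 1)))
      if (tt < len) nbrs <- c(nbrs, list(c(ch, tt + 1)))
      if (nch > 1) for (ch2 in which(adj[ch, ])) nbrs <- c(nbrs, list(c(ch2, tt)))
      for (nb in nbrs) {
        if (mask[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
          lab[nb[1], nb[2]] <- cur
          queue <- c(queue, list(nb))
        }
      }
    }
  }
  lab
}

# Exhaustive sign-flip cluster permutation p for the paired design: paired t
# per sample, threshold, 1-D clusters, all 2^n assignments. Independent of
# the package's engine (plain loops).
oracle_signflip_p <- function(A, B, cluster_alpha = 0.05) {
  D <- A - B
  n <- nrow(D)
  tcrit <- qt(1 - cluster_alpha / 2, n - 1)
  tstat <- function(M) {
    m <- colMeans(M); s <- apply(M, 2, sd)
    ifelse(s > 0, m / (s / sqrt(n)), 0)
  }
  max_sum <- function(tv) {
    best <- 0
    for (pol in c(1, -1)) {
      run <- 0
      for (x in tv * pol) {
        if (x > tcrit) run <- run + x else { best <- max(best, run); run <- 0 }
      }
      best <- max(best, run)
    }
    best
  }
  obs <- max_sum(tstat(D))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  null <- apply(signs, 1, function(s) max_sum(tstat(D * s)))
  list(observed = obs, p = sum(null >= obs) / length(null))
}
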