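# Shared fixtures and independent oracles for the test suite.
# Expensive renders are memoized per test session.

# ---- configurations -------------------------------------------------------

# noise-free, blur-free config: geometry and amplitudes are exact
noiseless_cfg <- function(seed = 7L, n_cells = 5L, n_beads = 10L,
                          field = c(1024L, 1024L)) {
  simulation_config(psf_sigma = 0, read_noise_sd = 0, shot_noise_gain = 0,
                    background_level = 0, n_cells = n_cells,
                    n_beads_per_class = n_beads, field_size = field,
                    rng_seed = seed)
}

# small cell-compartment config for pattern / titer wells
cell_cfg <- function(seed, n_cells = 24L) {
  simulation_config(field_size = c(704L, 704L), n_cells = n_cells,
                    n_beads_per_class = 3L, rng_seed = seed)
}

# memoized renders shared across tests
.render_cache <- new.env(parent = emptyenv())
cached_render <- function(key, spec, cfg) {
  if (is.null(.render_cache[[key]]))
    .render_cache[[key]] <- render_sample(spec, cfg)
  .render_cache[[key]]
}

noiseless_well <- function() {
  cached_render("noiseless",
                sample_spec(pr3_conc = 25, mpo_conc = 0, pattern = "C",
                            titer = 320),
                noiseless_cfg(seed = 7L, n_cells = 25L, n_beads = 20L))
}

# ---- independent oracles --------------------------------------------------

# brute-force pixel labeling of a noiseless plane: flood-fill connected
# components above half the plane maximum, return area-equivalent diameters
# and centroids (deliberately independent of detect_beads)
pixel_count_oracle <- function(plane, pixel_scale) {
  thr <- max(plane) / 2
  mask <- plane > thr
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  h <- nrow(mask)
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      row <- (p - 1L) %% h + 1L; col <- (p - 1L) %/% h + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- row + d[1]; cc <- col + d[2]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= ncol(mask)) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  do.call(rbind, lapply(seq_len(cur), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    data.frame(x = mean(idx[, 2]), y = mean(idx[, 1]),
               diameter_um = 2 * sqrt(nrow(idx) / pi) * pixel_scale)
  }))
}

# brute-force AUC by enumerating all case-control pairs
auc_bruteforce <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  mean(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exact two-sided McNemar p by full binomial enumeration
mcnemar_enumeration <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- 0:n
  sum(stats::dbinom(k[abs(k - n / 2) >= abs(b - n / 2)], n, 0.5))
}

# direct-formula kappa (independent arithmetic, no shared code path)
kappa_by_hand <- function(m) {
  n <- sum(m)
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  (po - pe) / (1 - pe)
}

# match detections to ground-truth objects by nearest center
match_truth <- function(det, truth) {
  vapply(seq_len(nrow(det)), function(i) {
    d <- sqrt((truth$x - det$x[i])^2 + (truth$y - det$y[i])^2)
    which.min(d)
  }, integer(1))
}
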