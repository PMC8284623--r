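# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation.

# Connected components by iterative min-label propagation (fixpoint),
# not flood fill: each foreground pixel starts with a unique label and
# repeatedly takes the minimum over its neighborhood until stable.
oracle_components <- function(mask, connectivity) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask != 0] <- seq_len(sum(mask != 0))
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (lab[r, cc] == 0L) next
      for (k in seq_len(nrow(nb))) {
        r2 <- r + nb[k, 1]; c2 <- cc + nb[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (lab[r2, c2] > 0L && lab[r2, c2] < lab[r, cc]) {
          lab[r, cc] <- lab[r2, c2]; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(lab[lab > 0L]))
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments
# (distinct values assumed). Doubling convention: p = min(1, 2 * min tail).
oracle_mann_whitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Log-rank p by permutation of group labels (Monte-Carlo null).
oracle_logrank_perm <- function(records, group_col, n_perm = 2000,
                                seed = 42) {
  obs <- logrank_test(records, group_col)$chisq
  set.seed(seed)
  stat <- replicate(n_perm, {
    rec <- records
    rec[[group_col]] <- sample(rec[[group_col]])
    logrank_test(rec, group_col)$chisq
  })
  mean(stat >= obs)
}

# Small well-separated two-population spec used in several tests.
separated_spec <- function(n_mg = 30, n_tam = 30, seed = 1, ...) {
  args <- list(width_px = 256L, height_px = 256L,
               n_microglia = n_mg, n_tam = n_tam,
               marker_panel = c("Iba1", "P2RY12", "CD163"),
               background_level = 0, noise_sd = 0, blur_sigma_px = 0,
               seed = seed)
  do.call(image_sim_spec, utils::modifyList(args, list(...)))
}

default_scheme <- function(split_lo = 90, master_lo = 1) {
  gating_scheme(gate("master", "Iba1", lo = master_lo),
                gate("mg_split", "P2RY12", lo = split_lo))
}
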