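# Small simulation configuration for desk-speed unit tests
tiny_config <- function(seed = 1, ...) {
  defaults <- list(seed = seed, n_subjects = 40L, n_proteins = 60L,
                   n_true_pos = 6L, n_true_neg = 6L,
                   samples_per_donor = 36L, n_decoy_sets = 6L,
                   geneset_size = 10L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Independent OLS oracle: explicit normal equations, no QR
ols_oracle <- function(y, X) {
  xtx <- t(X) %*% X
  xtx_inv <- solve(xtx)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  list(coefficients = beta, se = se,
       p_value = 2 * pt(-abs(tval), df), df_residual = df)
}

# Independent hypergeometric right-tail oracle: direct enumeration of the
# tail sum; exact in double arithmetic for the small N it is used with
hyper_tail_oracle <- function(k, K, n, N) {
  i <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  sum(pmf[i >= k])
}

# Independent Spearman: midranks then explicit Pearson on the ranks
spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# Independent differential stability: plain loops over donor pairs
ds_oracle <- function(profiles) {
  probe_ids <- sort(unique(profiles$probe_id))
  donors <- sort(unique(profiles$donor_id))
  out <- numeric(length(probe_ids))
  for (pi in seq_along(probe_ids)) {
    rhos <- c()
    for (i in seq_along(donors)) for (j in seq_along(donors)) {
      if (i >= j) next
      a <- profiles[profiles$probe_id == probe_ids[pi] &
                      profiles$donor_id == donors[i], ]
      b <- profiles[profiles$probe_id == probe_ids[pi] &
                      profiles$donor_id == donors[j], ]
      common <- intersect(a$region_id, b$region_id)
      if (length(common) < 3) next
      rhos <- c(rhos, spearman_oracle(a$mean_expr[match(common, a$region_id)],
                                      b$mean_expr[match(common, b$region_id)]))
    }
    out[pi] <- if (length(rhos)) mean(rhos) else NA_real_
  }
  data.frame(probe_id = probe_ids, ds = out)
}

# Independent sample-to-region assignment: per-sample loops mirroring the
# rule (in-voxel first, else nearest labeled voxel center within tolerance).
# Labeled voxels are enumerated once by a plain triple loop; the per-sample
# search then loops over them with explicit tie-breaking.
assign_oracle <- function(samples, vol, max_dist_mm = 2.0) {
  inv <- solve(vol$affine)
  dims <- dim(vol$labels)
  vox <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
    for (kk in seq_len(dims[3])) {
      lab <- vol$labels[i, j, kk]
      if (lab > 0)
        vox[[length(vox) + 1L]] <-
          c(lab, i, j, kk, drop(vol$affine %*% c(i - 1, j - 1, kk - 1, 1))[1:3])
    }
  out <- rep(NA_integer_, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    xyz <- as.numeric(samples[s, c("mni_x", "mni_y", "mni_z")])
    v <- round(drop(inv %*% c(xyz, 1))[1:3]) + 1
    if (all(v >= 1) && all(v <= dims) && vol$labels[v[1], v[2], v[3]] > 0) {
      out[s] <- vol$labels[v[1], v[2], v[3]]
      next
    }
    best_d2 <- Inf; best <- NA_integer_
    best_key <- c(Inf, Inf, Inf, Inf)
    for (vx in vox) {
      d2 <- sum((vx[5:7] - xyz)^2)
      key <- vx[1:4]
      tie <- abs(d2 - best_d2) <= 1e-9
      lex_less <- FALSE
      for (q in 1:4) {
        if (key[q] < best_key[q]) { lex_less <- TRUE; break }
        if (key[q] > best_key[q]) break
      }
      if (d2 < best_d2 - 1e-9 || (tie && lex_less)) {
        best_d2 <- d2; best <- vx[1]; best_key <- key
      }
    }
    if (sqrt(best_d2) <= max_dist_mm + 1e-12) out[s] <- best
  }
  storage.mode(out) <- "integer"
  out
}

# Planted-truth recount of oligo-lineage involvement among hit genes
oligo_recount_oracle <- function(truth, hit_genes) {
  n <- 0L
  for (g in hit_genes) {
    cells <- truth$enriched_cells[[g]]
    if (length(cells) == 0) next
    has_oligo <- any(cells %in% c("oligodendrocyte", "OPC"))
    if ((length(cells) == 1 && has_oligo) ||
        (length(cells) >= 2 && has_oligo))
      n <- n + 1L
  }
  n
}
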