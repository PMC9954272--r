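# Independent brute-force oracles, coded with explicit loops and kept
# deliberately naive; they share only the biomarker definitions with the
# package, never its code paths.

oracle_extract <- function(log, scene = log$scene) {
  x <- log$samples$x; y <- log$samples$y
  n <- length(x)
  sr <- scene$sample_rate_hz
  ev <- log$events
  complete <- nrow(ev) == 4
  te <- if (complete) ev$sample_index[4] / sr else scene$T_max_s
  te_idx <- if (complete) ev$sample_index[4] + 1L else n  # 1-based R index

  dist1 <- function(i, j) sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)

  med <- 0
  if (te_idx >= 2) for (k in 1:(te_idx - 1)) med <- med + dist1(k, k + 1)

  met1 <- if (nrow(ev) >= 1) ev$sample_index[1] / sr else NA_real_
  mee <- NA_real_
  if (nrow(ev) >= 1) {
    cube <- scene$cube_centers[[ev$cube_id[1]]]
    D <- sqrt((cube[1] - scene$sphere_start[1])^2 +
              (cube[2] - scene$sphere_start[2])^2) -
      (scene$sphere_radius_px + scene$cube_half_size_px)
    fi <- ev$sample_index[1] + 1L
    num <- 0
    if (fi >= 2) for (k in 1:(fi - 1)) num <- num + dist1(k, k + 1)
    mee <- num / D
  }

  oy <- scene$obstacle_y_px
  cross_k <- NA_integer_             # 1-based index of last at-or-below sample
  if (te_idx >= 2) for (k in 1:(te_idx - 1)) {
    if (y[k] <= oy && y[k + 1] > oy) { cross_k <- k; break }
  }
  if (is.na(cross_k)) {
    etc <- NA_real_; edc <- NA_real_; tcr <- NA_real_
  } else {
    tcr <- cross_k / sr              # = t of sample cross_k + 1 (0-based k)
    etc <- te - tcr
    edc <- 0
    if (cross_k + 1 <= te_idx - 1)
      for (k in (cross_k + 1):(te_idx - 1)) edc <- edc + dist1(k, k + 1)
  }

  eta <- 0; eda <- 0
  if (te_idx >= 2) for (k in 1:(te_idx - 1)) {
    if (y[k] > oy && y[k + 1] > oy) {
      eta <- eta + 1 / sr
      eda <- eda + dist1(k, k + 1)
    }
  }

  list(metr_total = te / scene$T_max_s, met_first_s = met1,
       et_crossing_s = etc, et_above_s = eta, med_total_px = med,
       mee_first = mee, ed_crossing_px = edc, ed_above_px = eda,
       crossing_t_s = tcr, complete = complete)
}

# exhaustive concordant-pair AUC (ties count one half)
oracle_auc_pairs <- function(scores, labels, positive = "MCI") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# tie-corrected two-group Kruskal-Wallis H from first principles
oracle_kw_h <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  r <- rank(pooled)
  R1 <- sum(r[seq_along(x)]); R2 <- sum(r[-seq_along(x)])
  H <- 12 / (N * (N + 1)) * (R1^2 / length(x) + R2^2 / length(y)) - 3 * (N + 1)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# permutation p-value of the KW H statistic
oracle_kw_perm_p <- function(x, y, n_perm = 1e5) {
  H_obs <- oracle_kw_h(x, y)
  pooled <- c(x, y)
  n1 <- length(x)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n1)
    H <- oracle_kw_h(pooled[idx], pooled[-idx])
    if (H >= H_obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# rel. comparison treating two NAs as equal
expect_field_equal <- function(a, b, tol = 1e-9, label = "") {
  if (is.na(a) || is.na(b)) {
    expect_true(is.na(a) && is.na(b), label = paste(label, "missingness"))
  } else {
    denom <- max(abs(b), 1e-12)
    expect_lt(abs(a - b) / denom, tol, label = paste(label, "value"))
  }
}
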