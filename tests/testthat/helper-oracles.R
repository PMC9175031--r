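# Independent oracles used by the unit and acceptance tests. Each one
# recomputes a quantity along a different computational path than the
# package implementation.

# --- 1-ms grid-scan timeline oracle -----------------------------------------
# Scans the trial on a 1-ms grid, run-length encodes the four raw states and
# applies the same transition-relabelling rule by brute force. Exact for
# logs whose times lie on the millisecond lattice.
grid_scan_oracle <- function(log, trial_duration, tau_overlap = 0.4) {
  step <- 1e-3
  mids <- seq(step / 2, trial_duration, by = step)
  in_button <- function(b) {
    sel <- log$button == b
    on <- log$t_on[sel]
    off <- log$t_off[sel]
    out <- rep(FALSE, length(mids))
    for (i in seq_along(on)) out <- out | (mids >= on[i] & mids < off[i])
    out
  }
  state <- 1L * in_button("LEFT") + 2L * in_button("RIGHT")
  r <- rle(state)
  ends <- cumsum(r$lengths) * step
  starts <- c(0, ends[-length(ends)])
  lab <- c("UNREPORTED", "GROUPED_H", "GROUPED_V", "BOTH")[r$values + 1L]
  for (i in which(lab == "BOTH")) {
    short <- (ends[i] - starts[i]) < tau_overlap - 1e-12
    flanked <- i > 1L && i < length(lab) &&
      lab[i - 1L] %in% c("GROUPED_H", "GROUPED_V") &&
      lab[i + 1L] %in% c("GROUPED_H", "GROUPED_V") &&
      lab[i - 1L] != lab[i + 1L]
    lab[i] <- if (short && flanked) "TRANSITION" else "UNGROUPED"
  }
  data.frame(t_start = starts, t_end = ends, label = lab)
}

# Random button log on the 1-ms lattice (so the grid scan is exact).
fuzz_log <- function(n_intervals = 8, trial_duration = 20) {
  k <- sample.int(n_intervals, 1L)
  t_on <- round(runif(k, 0, trial_duration - 0.2), 3)
  len <- round(runif(k, 0.001, trial_duration / 2), 3)
  tibble::tibble(
    button = sample(c("LEFT", "RIGHT"), k, replace = TRUE),
    t_on = t_on,
    t_off = pmin(round(t_on + len, 3), trial_duration)
  ) |> dplyr::filter(t_off > t_on)
}

# --- projection-matrix GLM oracle for the split-plot ANOVA ------------------
# Computes every univariate split-plot F directly from Type III quadratic
# forms on the cell-mean matrix, using orthonormal within-effect contrasts.
orthonormal_contrasts <- function(k) {
  qr.Q(qr(cbind(1, stats::contr.helmert(k))))[, -1, drop = FALSE]
}

ss_type3 <- function(X, Y, cols) {
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  L <- diag(ncol(X))[cols, , drop = FALSE]
  mid <- solve(L %*% XtXi %*% t(L))
  sum(vapply(seq_len(ncol(Y)), function(j) {
    lb <- L %*% B[, j, drop = FALSE]
    as.numeric(t(lb) %*% mid %*% lb)
  }, numeric(1)))
}

rss_cols <- function(X, Y) {
  H <- X %*% solve(crossprod(X)) %*% t(X)
  sum((Y - H %*% Y)^2)
}

# data: long table; within: 1 or 2 factor names; returns data.frame with
# effect names matching mixed_anova() output and brute-force F values.
glm_anova_oracle <- function(data, dv, within, between, subject) {
  for (w in within) data[[w]] <- factor(data[[w]], levels = unique(data[[w]]))
  data[[between]] <- factor(data[[between]], levels = unique(data[[between]]))
  levs <- lapply(within, function(w) levels(data[[w]]))
  grid <- do.call(expand.grid, c(rev(levs), list(stringsAsFactors = FALSE)))
  grid <- grid[, rev(seq_along(within)), drop = FALSE] # first factor slowest
  names(grid) <- within
  subjects <- unique(data[[subject]])
  K <- nrow(grid)
  Y <- matrix(NA_real_, nrow = length(subjects), ncol = K)
  grp <- character(length(subjects))
  for (i in seq_along(subjects)) {
    di <- data[data[[subject]] == subjects[i], ]
    grp[i] <- as.character(di[[between]][1L])
    for (j in seq_len(K)) {
      sel <- rep(TRUE, nrow(di))
      for (w in within) sel <- sel & di[[w]] == grid[[w]][j]
      Y[i, j] <- di[[dv]][sel]
    }
  }
  grp <- factor(grp, levels = levels(data[[between]]))
  g <- nlevels(grp)
  n <- length(subjects)
  X <- stats::model.matrix(~grp, contrasts.arg = list(grp = "contr.sum"))
  int_col <- 1L
  grp_cols <- 1L + seq_len(g - 1L)

  ks <- vapply(levs, length, integer(1))
  cons <- lapply(ks, orthonormal_contrasts)
  ones <- lapply(ks, function(k) matrix(1 / sqrt(k), nrow = k))
  effect_M <- list()
  if (length(within) == 1L) {
    effect_M[[within[1L]]] <- cons[[1L]]
  } else {
    effect_M[[within[1L]]] <- kronecker(cons[[1L]], ones[[2L]])
    effect_M[[within[2L]]] <- kronecker(ones[[1L]], cons[[2L]])
    effect_M[[paste(within, collapse = ":")]] <- kronecker(cons[[1L]], cons[[2L]])
  }

  rows <- list()
  # between-subject effect on the subject means
  Tm <- Y %*% matrix(1 / sqrt(K), nrow = K)
  ssb <- ss_type3(X, Tm, grp_cols)
  sseb <- rss_cols(X, Tm)
  rows[[between]] <- data.frame(
    effect = between, f = (ssb / (g - 1)) / (sseb / (n - g))
  )
  for (nm in names(effect_M)) {
    M <- effect_M[[nm]]
    d <- ncol(M)
    YM <- Y %*% M
    sse <- rss_cols(X, YM)
    dfe <- (n - g) * d
    f_within <- (ss_type3(X, YM, int_col) / d) / (sse / dfe)
    f_inter <- (ss_type3(X, YM, grp_cols) / (d * (g - 1))) / (sse / dfe)
    rows[[nm]] <- data.frame(effect = nm, f = f_within)
    rows[[paste(between, nm, sep = ":")]] <-
      data.frame(effect = paste(between, nm, sep = ":"), f = f_inter)
  }
  do.call(rbind, rows)
}

# --- classic sample formula for the Greenhouse-Geisser epsilon --------------
gg_epsilon_oracle <- function(S) {
  k <- ncol(S)
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  srow <- rowMeans(S)
  num <- k^2 * (sdiag - sbar)^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2)
  num / den
}

# --- Mann-Whitney enumeration oracle ----------------------------------------
# U by explicit pair counting; exact two-sided p by enumeration over all
# group assignments of the pooled sample.
mwu_oracle <- function(x, y) {
  count_u <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai < bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- min(count_u(x, y), count_u(y, x))
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(ii) {
    a <- pool[ii]
    b <- pool[-ii]
    min(count_u(a, b), count_u(b, a))
  })
  # two-sided exact p: mass of assignments whose min-U is at most the
  # observed one (equals twice the lower tail of either one-sided U)
  list(u = u_obs, p = min(1, mean(us <= u_obs + 1e-12)))
}

# --- renewal expectation for the single-zone observer -----------------------
# Second-order renewal-function expansion for the expected switch count.
renewal_rate_oracle <- function(epoch_mean, shape, mixed_prob, mixed_mean, duration) {
  m <- epoch_mean + mixed_prob * mixed_mean
  v <- epoch_mean^2 / shape + mixed_prob * 2 * mixed_mean^2 - (mixed_prob * mixed_mean)^2
  (duration / m + (v - m^2) / (2 * m^2)) * 60 / duration
}

noiseless_params <- function(...) {
  defaults <- list(
    press_latency_mean = 0, press_latency_sd = 0,
    overlap_mean = 0, overlap_sd = 0, lapse_prob = 0
  )
  do.call(observer_params, utils::modifyList(defaults, list(...)))
}
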