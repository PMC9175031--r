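#' Mixed factorial ANOVA with Greenhouse-Geisser correction
#'
#' Fits the split-plot (mixed) factorial ANOVA used throughout the
#' analysis: one between-subject factor (group), one or two within-subject
#' factors, and an optional between-subject covariate. Sums of squares are
#' Type III with sum-to-zero contrasts (the groups are unbalanced); within
#' effects are tested against their subject-interaction error terms.
#' Greenhouse-Geisser epsilon, corrected degrees of freedom and corrected
#' p-values are reported for every within effect (epsilon is exactly 1 for
#' two-level effects), alongside the uncorrected values and Mauchly's
#' sphericity p as auxiliary output. Partial eta-squared is attached to
#' every effect row.
#'
#' With a covariate, the covariate is centred and only the
#' between-subject test is covariate-adjusted (the covariate enters the
#' between-subject model); within effects are reported from the
#' unadjusted model.
#'
#' @param data Long-format data frame: one row per participant x
#'   within-cell.
#' @param dv Name of the dependent-variable column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param between Name of the between-subject factor column.
#' @param subject Name of the participant-id column.
#' @param covariate Optional name of a between-subject covariate column.
#' @return A `rivalry_anova` object; see [tidy.rivalry_anova()].
#' @export
mixed_anova <- function(data, dv, within, between, subject, covariate = NULL) {
  data <- as_tibble(data)
  cols <- c(dv, within, between, subject, covariate)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("`data` is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors.")
  if (anyNA(data[[dv]])) abort("`dv` contains missing values.")

  for (w in within) data[[w]] <- factor(data[[w]], levels = unique(data[[w]]))
  data[[between]] <- factor(data[[between]], levels = unique(data[[between]]))
  if (nlevels(data[[between]]) < 2L) abort("`between` needs at least 2 levels.")

  cell_grid <- do.call(tidyr::expand_grid, setNames(lapply(within, function(w) levels(data[[w]])), within))
  cell_grid$.cell <- apply(cell_grid[within], 1L, paste, collapse = ".")
  data$.cell <- apply(as.data.frame(data[within]), 1L, paste, collapse = ".")

  counts <- dplyr::count(data, .data[[subject]], .data$.cell)
  dup <- filter(counts, .data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf(
      "duplicated within-cells: %s",
      paste(sprintf("%s/%s", dup[[subject]], dup$.cell), collapse = ", ")
    ))
  }
  full <- tidyr::expand_grid(
    !!subject := unique(data[[subject]]),
    .cell = cell_grid$.cell
  )
  miss <- dplyr::anti_join(full, counts, by = c(subject, ".cell"))
  if (nrow(miss)) {
    abort(sprintf(
      "missing within-cells: %s",
      paste(sprintf("%s/%s", miss[[subject]], miss$.cell), collapse = ", ")
    ))
  }
  grp_sizes <- dplyr::count(dplyr::distinct(data, .data[[subject]], .data[[between]]), .data[[between]])
  if (any(grp_sizes$n < 2L)) abort("need at least 2 participants per group.")

  wide <- tidyr::pivot_wider(
    select(data, all_of(c(subject, between, covariate)), ".cell", all_of(dv)),
    names_from = ".cell", values_from = all_of(dv)
  )
  wide <- arrange(wide, .data[[subject]])
  Y <- as.matrix(wide[cell_grid$.cell])
  if (var(as.vector(Y)) < 1e-24) {
    abort("singular design: the dependent value has zero variance.")
  }

  idata <- as.data.frame(lapply(cell_grid[within], function(x) factor(x, levels = unique(x))))
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  grp <- wide[[between]]

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit_summary <- function(rhs_df) {
    mod <- lm(Y ~ ., data = rhs_df)
    a <- car::Anova(mod, idata = idata, idesign = idesign, type = 3)
    # the Huynh-Feldt epsilon is not reported; silence its >1 clamping note
    withCallingHandlers(
      summary(a, multivariate = FALSE),
      warning = function(w) {
        if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
      }
    )
  }
  s <- fit_summary(data.frame(grp = grp))
  ut <- s$univariate.tests
  rn <- sub("grp", between, rownames(ut))
  rownames(ut) <- rn

  s_cov <- NULL
  if (!is.null(covariate)) {
    cov_c <- wide[[covariate]] - mean(wide[[covariate]])
    s_cov <- fit_summary(data.frame(grp = grp, .cov = cov_c))
    utc <- s_cov$univariate.tests
    rownames(utc) <- sub("grp", between, sub("\\.cov", covariate, rownames(utc)))
    # covariate-adjusted between-subject rows replace/extend the unadjusted ones
    ut <- rbind(
      ut[rn == "(Intercept)", , drop = FALSE],
      utc[rownames(utc) %in% c(between, covariate), , drop = FALSE],
      ut[!(rn %in% c("(Intercept)", between)), , drop = FALSE]
    )
  }

  effects <- setdiff(rownames(ut), "(Intercept)")
  is_within <- vapply(effects, function(e) {
    any(vapply(within, function(w) w %in% strsplit(e, ":", fixed = TRUE)[[1]], logical(1)))
  }, logical(1))

  if (any(!is.finite(ut[effects, "F value"])) || any(ut[effects, "Error SS"] <= 1e-20)) {
    abort("singular design: zero error variance for at least one effect.")
  }

  gg <- rep(NA_real_, length(effects))
  mauchly <- rep(NA_real_, length(effects))
  names(gg) <- names(mauchly) <- effects
  fix_names <- function(m) {
    if (!is.null(m) && nrow(m)) rownames(m) <- sub("grp", between, rownames(m))
    m
  }
  pa <- fix_names(s$pval.adjustments)
  sph <- fix_names(s$sphericity.tests)
  for (e in effects[is_within]) {
    gg[e] <- if (!is.null(pa) && e %in% rownames(pa)) pa[e, "GG eps"] else 1
    if (!is.null(sph) && e %in% rownames(sph)) mauchly[e] <- sph[e, "p-value"]
  }

  tab <- tibble(
    effect = effects,
    ss = unname(ut[effects, "Sum Sq"]),
    df_num = unname(ut[effects, "num Df"]),
    ss_error = unname(ut[effects, "Error SS"]),
    df_den = unname(ut[effects, "den Df"]),
    f = unname(ut[effects, "F value"]),
    p = unname(ut[effects, "Pr(>F)"]),
    gg_epsilon = unname(gg),
    mauchly_p = unname(mauchly)
  ) |>
    mutate(
      ms = .data$ss / .data$df_num,
      ms_error = .data$ss_error / .data$df_den,
      df_num_gg = .data$gg_epsilon * .data$df_num,
      df_den_gg = .data$gg_epsilon * .data$df_den,
      p_gg = ifelse(
        is.na(.data$gg_epsilon), NA_real_,
        pf(.data$f, .data$gg_epsilon * .data$df_num, .data$gg_epsilon * .data$df_den,
          lower.tail = FALSE
        )
      ),
      pes = partial_eta_squared(.data$f, .data$df_num, .data$df_den)
    ) |>
    select(
      "effect", "ss", "df_num", "ss_error", "df_den", "ms", "ms_error",
      "f", "p", "gg_epsilon", "df_num_gg", "df_den_gg", "p_gg", "pes", "mauchly_p"
    )

  structure(
    list(
      table = tab,
      dv = dv, within = within, between = between, subject = subject,
      covariate = covariate,
      n_subjects = nrow(wide),
      group_sizes = setNames(grp_sizes$n, as.character(grp_sizes[[between]])),
      n_within_cells = nrow(cell_grid)
    ),
    class = "rivalry_anova"
  )
}

#' @export
print.rivalry_anova <- function(x, ...) {
  cat(sprintf(
    "Mixed factorial ANOVA: %s ~ %s x %s (%d subjects)%s\n",
    x$dv, paste(x$within, collapse = " x "), x$between, x$n_subjects,
    if (!is.null(x$covariate)) sprintf(", covariate %s", x$covariate) else ""
  ))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}

#' Tidy a mixed-ANOVA table
#'
#' @param x A `rivalry_anova` object.
#' @param ... Unused.
#' @return A tibble with one row per effect: sums of squares, degrees of
#'   freedom, F, p, Greenhouse-Geisser epsilon with corrected dfs and p,
#'   partial eta-squared and Mauchly's p.
#' @export
tidy.rivalry_anova <- function(x, ...) x$table

#' @export
glance.rivalry_anova <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_within_cells = x$n_within_cells,
    between = x$between,
    within = paste(x$within, collapse = ":"),
    covariate = x$covariate %||% NA_character_
  )
}

#' Greenhouse-Geisser epsilon
#'
#' Computes the sphericity index epsilon from the covariance of
#' within-subject scores: with `D` the double-centred covariance matrix,
#' `epsilon = tr(D)^2 / ((k - 1) tr(D^2))`, bounded in `[1/(k-1), 1]` and
#' exactly 1 when `k = 2` or the covariance is compound symmetric.
#'
#' @param x Either an n x k matrix of within-cell scores (n >= 2
#'   participants) or a k x k covariance matrix.
#' @param contrasts Optional k x d matrix of orthonormal contrasts defining
#'   the effect subspace; defaults to the full centring space.
#' @return Epsilon (scalar).
#' @export
gg_epsilon <- function(x, contrasts = NULL) {
  x <- as.matrix(x)
  is_cov <- nrow(x) == ncol(x) && isSymmetric(unname(x), tol = 1e-8)
  if (is_cov) {
    S <- x
  } else {
    if (nrow(x) < 2L) abort("need at least 2 participants to estimate the covariance.")
    S <- cov(x)
  }
  k <- ncol(S)
  if (k < 2L) abort("need at least 2 within-subject levels.")
  if (is.null(contrasts)) {
    C <- diag(k) - 1 / k
    d <- k - 1L
    D <- C %*% S %*% C
  } else {
    M <- as.matrix(contrasts)
    d <- ncol(M)
    D <- t(M) %*% S %*% M
  }
  denom <- sum(D * D)
  if (denom < 1e-24) abort("within-cell covariance is degenerate.")
  sum(diag(D))^2 / (d * denom)
}

#' Partial eta-squared from an F statistic
#'
#' `F * df_num / (F * df_num + df_den)`; the identity holds for raw and
#' Greenhouse-Geisser-corrected degrees of freedom alike, because the
#' correction rescales numerator and denominator dfs by the same epsilon.
#'
#' @param f F statistic (>= 0). Vectorised.
#' @param df_num,df_den Numerator and denominator degrees of freedom
#'   (> 0; fractional values allowed).
#' @return Partial eta-squared in `[0, 1]`.
#' @export
#' @examples
#' partial_eta_squared(232, 1.7, 48.2) # 0.89
partial_eta_squared <- function(f, df_num, df_den) {
  if (any(f < 0) || any(df_num <= 0) || any(df_den <= 0)) {
    abort("`f` must be >= 0 and degrees of freedom > 0.")
  }
  f * df_num / (f * df_num + df_den)
}

#' Cohen's d from an independent-samples t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)`, the standardised mean difference implied by
#' a pooled-variance t.
#'
#' @param t The t statistic.
#' @param n1,n2 Group sizes (>= 2).
#' @return Cohen's d.
#' @export
#' @examples
#' cohens_d_from_t(2.55, 17, 14) # 0.92
cohens_d_from_t <- function(t, n1, n2) {
  if (any(n1 < 2) || any(n2 < 2)) abort("group sizes must be >= 2.")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Independent-samples t-test (pooled variance) with Cohen's d
#'
#' Classical two-sided pooled-variance test, `df = n1 + n2 - 2`.
#'
#' @param x,y Numeric samples.
#' @return A one-row tibble: `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
independent_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) abort("both samples need at least 2 values.")
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0 || !is.finite(sp2)) abort("zero pooled variance.")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  tstat <- unname(tt$statistic)
  tibble(
    t = tstat, df = unname(tt$parameter), p = tt$p.value,
    d = cohens_d_from_t(tstat, n1, n2),
    mean_diff = mean(x) - mean(y)
  )
}

#' Paired-samples t-test with Cohen's d
#'
#' Two-sided paired test; `d` is the standardised mean of the paired
#' differences (d_z).
#'
#' @param x,y Paired numeric samples of equal length.
#' @return A one-row tibble: `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("paired samples must have equal length.")
  if (length(x) < 2L) abort("need at least 2 pairs.")
  d <- x - y
  if (sd(d) == 0 || !is.finite(sd(d))) abort("paired differences have zero variance.")
  tt <- stats::t.test(x, y, paired = TRUE)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    d = mean(d) / sd(d), mean_diff = mean(d)
  )
}

#' Mann-Whitney U test (min-U convention)
#'
#' U is computed by rank algebra with ties mid-ranked, and the smaller of
#' the two sample statistics is reported. The p-value is exact (from the
#' null Wilcoxon distribution) when there are no ties and the combined
#' sample size is at most 20, else a tie-corrected normal approximation.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A one-row tibble: `u`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 # counts x > y pairs + ties/2
  u_y <- n1 * n2 - u_x
  u <- min(u_x, u_y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 + n2 <= 20L) {
    p <- min(1, 2 * stats::pwilcox(u, n1, n2))
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    )
    method <- "normal approximation"
  }
  tibble(u = u, p = p, method = method)
}

#' Pairwise within-subject comparisons with familywise correction
#'
#' All level pairs of a within-subject factor are compared with paired
#' t-tests; p-values are Bonferroni-adjusted (`min(1, p * n_comparisons)`)
#' or left raw (least significant difference, LSD).
#'
#' @param data Long-format data frame.
#' @param dv,factor,subject Column names of the dependent value, the
#'   within-subject factor and the participant id.
#' @param method `"bonferroni"` (default) or `"lsd"`.
#' @return A tibble with one row per level pair: `level_1`, `level_2`,
#'   `mean_diff`, `t`, `df`, `p`, `p_adj`, `method`.
#' @export
pairwise_comparisons <- function(data, dv, factor, subject,
                                 method = c("bonferroni", "lsd")) {
  method <- match.arg(method)
  data <- as_tibble(data)
  levs <- unique(as.character(data[[factor]]))
  if (length(levs) < 2L) abort("`factor` needs at least 2 levels.")
  wide <- tidyr::pivot_wider(
    select(data, all_of(c(subject, factor, dv))),
    names_from = all_of(factor), values_from = all_of(dv)
  )
  pairs <- utils::combn(levs, 2L)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(i) {
    a <- pairs[1L, i]
    b <- pairs[2L, i]
    tt <- paired_t(wide[[a]], wide[[b]])
    tibble(level_1 = a, level_2 = b, mean_diff = tt$mean_diff, t = tt$t, df = tt$df, p = tt$p)
  })
  out <- bind_rows(rows)
  out$p_adj <- if (method == "bonferroni") pmin(1, out$p * n_comp) else out$p
  out$method <- method
  out
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A one-row tibble: `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 observations.")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance input.")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}
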