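#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `length(groups) - 1` degrees of freedom. When every pooled observation
#' is identical the statistic is 0 and p = 1 by convention.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(lengths(groups) >= 1))
  pooled <- unlist(groups)
  if (length(pooled) < 3) stop("need at least 3 observations in total")
  if (length(unique(pooled)) == 1) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(pooled,
                            rep(seq_along(groups), lengths(groups)))
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based pairwise z tests after a Kruskal-Wallis screen:
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) /
#'   \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}}
#' with tie correction \eqn{T = \sum(t^3 - t) / (12(N - 1))}. Two-sided
#' normal p-values are reported both raw and Bonferroni-adjusted over the
#' pairs.
#'
#' @param groups List of at least 2 non-empty numeric vectors. For exactly
#'   2 groups the single pair is still reported.
#' @return Data frame with columns `group_i`, `group_j`, `z`, `p`, `p_adj`.
#' @export
dunn_posthoc <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) == 0)) stop("empty group")
  g <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  rk <- rank(unlist(groups))
  idx <- rep(seq_len(g), n)
  rbar <- tapply(rk, idx, mean)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(g, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- (N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j])
    z <- if (se2 > 0) (rbar[i] - rbar[j]) / sqrt(se2) else 0
    c(z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
  })
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(g))
  data.frame(
    group_i = nm[pairs[1, ]], group_j = nm[pairs[2, ]],
    z = res["z", ], p = res["p", ],
    p_adj = pmin(1, res["p", ] * ncol(pairs)),
    stringsAsFactors = FALSE
  )
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks, with the p-value from the
#' t approximation. Zero rank variance in either argument yields `NA`
#' for both outputs.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List with `rho` and `p`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Kruskal-Wallis feature screen with post-hoc and score correlations
#'
#' Runs the Kruskal-Wallis test on every feature column across the class
#' groups and selects features with `p < alpha` (strict). For each selected
#' feature, Dunn's pairwise comparisons and the Spearman correlations of
#' the feature with the CRS-R and GCS scores are also computed.
#'
#' The binary task restricts the table to the UWS and MCS rows first; the
#' multiclass task uses all three groups.
#'
#' @param table A `feature_table` from [extract_features()].
#' @param alpha Selection level (default 0.05).
#' @param task `"multiclass"` (coma / UWS / MCS) or `"binary"`
#'   (UWS vs. MCS).
#' @return An object of class `selection_result`: a list with `stats` (data
#'   frame: feature, H, p, selected, per-pair Dunn p, rho/p vs CRS-R and
#'   GCS), `selected` (character vector of selected feature names), `alpha`,
#'   `task`.
#' @export
select_features <- function(table, alpha = 0.05,
                            task = c("multiclass", "binary")) {
  task <- match.arg(task)
  stopifnot(inherits(table, "feature_table"))
  keep <- if (task == "binary") table$labels %in% c("UWS", "MCS")
          else !is.na(table$labels)
  labels <- table$labels[keep]
  values <- table$values[keep, , drop = FALSE]
  crs_r <- table$crs_r[keep]
  gcs <- table$gcs[keep]
  classes <- intersect(c("coma", "UWS", "MCS"), unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes present")
  if (any(table(factor(labels, classes)) < 2))
    stop("every class needs at least 2 subjects")

  n_feat <- ncol(values)
  H <- p <- rho_crsr <- p_crsr <- rho_gcs <- p_gcs <- rep(NA_real_, n_feat)
  dunn_cols <- NULL
  dunn_p <- NULL
  for (f in seq_len(n_feat)) {
    groups <- split(values[, f], factor(labels, classes))
    kw <- kruskal_wallis(groups)
    H[f] <- kw$H; p[f] <- kw$p
  }
  selected <- p < alpha
  # post-hoc and score correlations only where the screen fired
  if (length(classes) >= 2) {
    pair_n <- choose(length(classes), 2)
    dunn_p <- matrix(NA_real_, n_feat, pair_n)
    for (f in which(selected)) {
      groups <- split(values[, f], factor(labels, classes))
      dn <- dunn_posthoc(groups)
      if (is.null(dunn_cols))
        dunn_cols <- paste0("dunn_p_", dn$group_i, "_", dn$group_j)
      dunn_p[f, ] <- dn$p
      sc <- spearman_corr(values[, f], crs_r)
      rho_crsr[f] <- sc$rho; p_crsr[f] <- sc$p
      sg <- spearman_corr(values[, f], gcs)
      rho_gcs[f] <- sg$rho; p_gcs[f] <- sg$p
    }
    if (is.null(dunn_cols))
      dunn_cols <- paste0("dunn_p_", seq_len(pair_n))
    colnames(dunn_p) <- dunn_cols
  }
  stats_df <- data.frame(
    feature = table$feature_names, H = H, p = p, selected = selected,
    stringsAsFactors = FALSE
  )
  stats_df <- cbind(stats_df, as.data.frame(dunn_p))
  stats_df$rho_crsr <- rho_crsr
  stats_df$p_crsr <- p_crsr
  stats_df$rho_gcs <- rho_gcs
  stats_df$p_gcs <- p_gcs
  structure(
    list(stats = stats_df,
         selected = table$feature_names[selected],
         alpha = alpha, task = task),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis screen (%s, p < %g): %d of %d features selected\n",
    x$task, x$alpha, length(x$selected), nrow(x$stats)))
  invisible(x)
}

#' Restrict a feature table to a set of feature columns
#'
#' @param table A `feature_table`.
#' @param features Character vector of feature names (e.g. the `selected`
#'   element of a `selection_result`).
#' @return The reduced `feature_table`.
#' @export
subset_features <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  idx <- match(features, table$feature_names)
  if (anyNA(idx)) stop("unknown feature names")
  table$values <- table$values[, idx, drop = FALSE]
  table$feature_names <- table$feature_names[idx]
  table
}
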