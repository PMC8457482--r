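# Collinearity screening and exhaustive all-subsets AIC model selection.
# Screening inspects variance inflation factors (VIF > 10 removed) and
# pairwise squared correlations (r^2 > 0.7 drops the lower-priority member
# of the pair). Selection fits every subset of the screened terms, ranks by
# AIC, and applies the parsimony rule: among models within delta-AIC of the
# best, the one with the fewest terms wins.

#' Variance inflation factors
#'
#' \code{VIF_j = 1 / (1 - R2_j)} where \code{R2_j} comes from regressing
#' covariate j on all the others. Computed from the inverse correlation
#' matrix; exactly collinear columns get \code{Inf}.
#'
#' @param x numeric matrix or data.frame of continuous covariates (>= 2
#'   columns).
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 covariates for VIFs")
  cm <- stats::cor(x)
  inv <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(inv)) {
    # singular: per-column fallback via least squares
    out <- vapply(seq_len(ncol(x)), function(j) {
      fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
      r2 <- 1 - sum(fit$residuals^2) /
        sum((x[, j] - mean(x[, j]))^2)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  } else {
    out <- diag(inv)
    out[out < 1] <- 1
    out[out > 1e12] <- Inf
  }
  stats::setNames(out, colnames(x))
}

#' Screen covariates for collinearity
#'
#' Two stages, mirroring common practice: (1) iteratively drop the worst
#' VIF offender until all VIFs are at or below \code{vif_threshold};
#' (2) for every remaining pair whose squared Pearson correlation exceeds
#' \code{r2_threshold} (largest first), drop the lower-priority member.
#' Priority is a user-supplied ordering encoding which covariates are
#' judged more relevant; it must cover every column.
#'
#' @param x matrix/data.frame of continuous covariates.
#' @param vif_threshold VIF removal threshold (default 10).
#' @param r2_threshold squared-correlation threshold (default 0.7).
#' @param priority character vector, most important first.
#' @param use_abs_r if TRUE, threshold |r| instead of r^2.
#' @return a \code{screening_report}: \code{vif} (initial VIFs),
#'   \code{r2_matrix}, \code{removed} (data.frame of removals with reason
#'   and statistic), \code{retained}.
#' @export
screen_covariates <- function(x, vif_threshold = 10, r2_threshold = 0.7,
                              priority = colnames(x), use_abs_r = FALSE) {
  x <- as.matrix(x)
  if (!setequal(priority, colnames(x)))
    stop("priority must cover exactly the covariate columns")
  vif0 <- compute_vif(x)
  r2 <- stats::cor(x)^2
  removed <- data.frame(covariate = character(), reason = character(),
                        statistic = numeric(), stringsAsFactors = FALSE)
  keep <- colnames(x)
  repeat {
    if (length(keep) < 2) break
    v <- compute_vif(x[, keep, drop = FALSE])
    if (max(v) <= vif_threshold) break
    worst <- names(v)[which.max(v)]
    removed <- rbind(removed, data.frame(covariate = worst, reason = "vif",
                                         statistic = max(v)))
    keep <- setdiff(keep, worst)
  }
  repeat {
    if (length(keep) < 2) break
    r <- stats::cor(x[, keep, drop = FALSE])
    stat <- if (use_abs_r) abs(r) else r^2
    thr <- if (use_abs_r) sqrt(r2_threshold) else r2_threshold
    diag(stat) <- 0
    if (max(stat) <= thr) break
    ij <- which(stat == max(stat), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    loser <- pair[which.max(match(pair, priority))]
    removed <- rbind(removed,
                     data.frame(covariate = loser, reason = "correlation",
                                statistic = max(stat)))
    keep <- setdiff(keep, loser)
  }
  structure(list(vif = vif0, r2_matrix = r2, removed = removed,
                 retained = keep,
                 thresholds = c(vif = vif_threshold, r2 = r2_threshold)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> %d retained, %d removed\n",
              length(x$retained), nrow(x$removed)))
  if (nrow(x$removed)) print(x$removed)
  invisible(x)
}

#' Enumerate candidate term-sets
#'
#' All subsets of the supplied terms, including the empty (intercept-only)
#' model: \code{2^n} candidates. Refuses more than 20 terms.
#'
#' @param covariates character vector of term names.
#' @return list of character vectors (first element is the empty set).
#' @export
enumerate_subsets <- function(covariates) {
  n <- length(covariates)
  if (n < 1) stop("need at least one covariate")
  if (n > 20) stop("refusing to enumerate 2^", n, " subsets")
  lapply(seq_len(2^n) - 1L, function(mask) {
    covariates[bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L]
  })
}

# parsimony rule: among rows (sorted by aic, with delta_aic filled) within
# delta_threshold of the best, pick the fewest terms; ties -> lower AIC,
# then lexicographic model string
parsimony_pick <- function(rows, delta_threshold) {
  window <- which(rows$delta_aic <= delta_threshold)
  cand <- rows[window, , drop = FALSE]
  window[order(cand$n_terms, cand$aic, cand$model)[1]]
}

#' Exhaustive AIC ranking and parsimonious selection
#'
#' Fits every candidate term-set with the bootstrap disabled (the AIC needs
#' only the maximized likelihood), ranks by AIC, then selects: among the
#' models within \code{delta_threshold} of the lowest AIC, the one with the
#' fewest terms; ties break to the lower AIC, then to lexicographic term
#' order. The categorical land-cover term enters as a single atomic term
#' (all of its indicator columns in or out together).
#'
#' @param data an \code{rspf_data}.
#' @param subsets list of term-sets (default: all subsets of
#'   \code{data$terms}).
#' @param delta_threshold AIC window for the parsimony rule (default 2.0).
#' @return a \code{model_ranking}: \code{rows} (data.frame with
#'   \code{model}, \code{n_terms}, \code{k}, \code{aic}, \code{delta_aic},
#'   sorted by AIC), \code{selected} (row index), \code{selected_terms},
#'   \code{n_unconverged}.
#' @export
rank_and_select <- function(data, subsets = NULL, delta_threshold = 2.0) {
  if (is.null(subsets)) subsets <- enumerate_subsets(data$terms)
  rows <- vector("list", length(subsets))
  uncon <- 0L
  for (i in seq_along(subsets)) {
    terms <- sort(subsets[[i]])
    d <- design_subset(data, terms)
    fit <- tryCatch(fit_rspf(list(x = d$x, y = d$y,
                                  terms = terms,
                                  reference_class = data$reference_class),
                             B = 0),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { uncon <- uncon + 1L; next }
    rows[[i]] <- data.frame(
      model = if (length(terms)) paste(terms, collapse = " + ") else "(intercept only)",
      n_terms = length(terms), k = fit$k, aic = fit$aic,
      stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows) || !nrow(rows)) stop("no candidate model converged")
  rows <- rows[order(rows$aic, rows$n_terms, rows$model), , drop = FALSE]
  rows$delta_aic <- rows$aic - rows$aic[1]
  rownames(rows) <- NULL
  pick <- parsimony_pick(rows, delta_threshold)
  sel_terms <- if (rows$model[pick] == "(intercept only)") character(0) else
    strsplit(rows$model[pick], " + ", fixed = TRUE)[[1]]
  structure(list(rows = rows, selected = pick,
                 selected_terms = sel_terms,
                 delta_threshold = delta_threshold,
                 n_unconverged = uncon),
            class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, n = 5, ...) {
  cat(sprintf("<model_ranking> %d models; selected #%d (parsimony window %.1f)\n",
              nrow(x$rows), x$selected, x$delta_threshold))
  print(utils::head(x$rows, n))
  cat("selected:", x$rows$model[x$selected], "\n")
  invisible(x)
}
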