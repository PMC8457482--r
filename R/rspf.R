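# Logistic resource selection probability function (RSPF) estimated from a
# use-availability design. The model gives the absolute probability that a
# location with covariates x is used:
#
#   w(x) = exp(b0 + b1 x1 + ... + bn xn) / (1 + exp(b0 + b1 x1 + ... + bn xn))
#
# Estimation maximizes the weighted-distributions use-availability
# log-likelihood
#
#   l(b) = sum_{i in used} [ log w(x_i; b) - log( mean_{j in avail} w(x_j; b) ) ]
#
# in which the availability sample stands in for the landscape-wide
# distribution of covariates. Standard errors come from a nonparametric
# bootstrap that resamples the used and available strata independently
# (unmatched design, m = 0).

#' Logistic selection probability
#'
#' Numerically stable evaluation of \code{w(x) = plogis(b0 + sum(b * x))}.
#'
#' @param beta coefficient vector (intercept first).
#' @param x covariate vector (without the leading 1), or a matrix with one
#'   row per location.
#' @return probabilities in (0, 1).
#' @export
eval_w <- function(beta, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (!all(is.finite(beta)) || !all(is.finite(x)))
    stop("beta and x must be finite")
  if (ncol(x) != length(beta) - 1L)
    stop(sprintf("dimension mismatch: %d covariates vs %d slopes",
                 ncol(x), length(beta) - 1L))
  eta <- drop(beta[1] + x %*% beta[-1])
  stats::plogis(eta)
}

#' Use-availability negative log-likelihood
#'
#' Returns \code{-l(beta)} for the weighted-distributions likelihood (see
#' the package overview): each used point contributes its log selection
#' probability minus the log of the mean selection probability over the
#' availability sample. At \code{beta = 0} every w is 1/2 and the
#' likelihood is exactly 0. The value is invariant to duplicating the
#' availability sample.
#'
#' @param beta coefficient vector (intercept first).
#' @param x_used,x_avail design matrices (columns = covariates, no
#'   intercept column) for the used and available strata.
#' @return a single number, \code{-l(beta)}.
#' @export
neg_log_likelihood <- function(beta, x_used, x_avail) {
  if (!nrow(x_used) || !nrow(x_avail)) stop("both strata must be non-empty")
  eta_u <- drop(beta[1] + x_used %*% beta[-1])
  eta_a <- drop(beta[1] + x_avail %*% beta[-1])
  log_w_u <- stats::plogis(eta_u, log.p = TRUE)
  w_a <- stats::plogis(eta_a)
  -(sum(log_w_u) - nrow(x_used) * log(mean(w_a)))
}

# analytic gradient of the negative log-likelihood
nll_gradient <- function(beta, x_used, x_avail) {
  eta_u <- drop(beta[1] + x_used %*% beta[-1])
  eta_a <- drop(beta[1] + x_avail %*% beta[-1])
  w_u <- stats::plogis(eta_u)
  w_a <- stats::plogis(eta_a)
  xu1 <- cbind(1, x_used)
  xa1 <- cbind(1, x_avail)
  g_used <- colSums(xu1 * (1 - w_u))
  g_avail <- colSums(xa1 * (w_a * (1 - w_a))) / sum(w_a)
  -(g_used - nrow(x_used) * g_avail)
}

#' Build an RSPF design from an extracted point table
#'
#' Splits a labelled, covariate-extracted \code{point_set} into a numeric
#' design: continuous covariates pass through on their (possibly
#' log-transformed) raw scale; the categorical cover term expands into
#' indicator columns for every non-reference class. The reference class is
#' the most frequent class in the availability sample (recorded in the
#' result, since coefficient values depend on it).
#'
#' @param points a \code{point_set} with covariate columns.
#' @param continuous character vector of continuous covariate column names.
#' @param categorical optional name of one categorical column.
#' @return an \code{rspf_data} list: \code{x} (model matrix without
#'   intercept), \code{y} (labels), \code{terms}, \code{reference_class},
#'   \code{term_columns} (term -> column indices).
#' @export
rspf_design <- function(points, continuous,
                        categorical = NULL) {
  df <- as.data.frame(points)
  miss <- setdiff(c(continuous, categorical), names(df))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(df[, c(continuous, categorical)]))
    stop("design contains missing covariate values")
  y <- df$label
  if (!any(y == 1) || !any(y == 0)) stop("both labels must be present")
  x <- as.matrix(df[, continuous, drop = FALSE])
  term_columns <- as.list(stats::setNames(seq_along(continuous), continuous))
  ref <- NULL
  if (!is.null(categorical)) {
    codes <- df[[categorical]]
    avail_tab <- table(codes[y == 0])
    ref <- as.numeric(names(avail_tab)[which.max(avail_tab)])
    classes <- setdiff(sort(unique(codes)), ref)
    if (length(classes)) {
      dummies <- vapply(classes, function(k) as.numeric(codes == k),
                        numeric(length(codes)))
      colnames(dummies) <- paste0(categorical, "_", classes)
      term_columns[[categorical]] <- ncol(x) + seq_along(classes)
      x <- cbind(x, dummies)
    }
  }
  structure(list(x = x, y = y,
                 terms = c(continuous, categorical),
                 continuous = continuous, categorical = categorical,
                 reference_class = ref, term_columns = term_columns),
            class = "rspf_data")
}

# subset an rspf_data to a term set (possibly empty = intercept-only)
design_subset <- function(data, terms) {
  unknown <- setdiff(terms, data$terms)
  if (length(unknown)) stop("unknown term(s): ", paste(unknown, collapse = ", "))
  cols <- unlist(data$term_columns[terms], use.names = FALSE)
  list(x = data$x[, cols, drop = FALSE], y = data$y)
}

#' Parameter count of a candidate RSPF
#'
#' One intercept, one slope per continuous term, and \code{n_cover_classes
#' - 1} indicator slopes if the land-cover term is included. A model with
#' seven continuous covariates plus an eight-class cover layer therefore
#' has 15 estimated parameters; with six continuous covariates, 14.
#'
#' @param terms character vector of term names (may be empty for the
#'   intercept-only model).
#' @param categorical name of the categorical term, or NULL.
#' @param n_cover_classes number of classes of the categorical term.
#' @return integer parameter count.
#' @export
count_df <- function(terms, categorical = "cover", n_cover_classes = 8) {
  if (anyDuplicated(terms)) stop("duplicated term")
  has_cover <- !is.null(categorical) && categorical %in% terms
  n_cont <- length(setdiff(terms, categorical))
  as.integer(1L + n_cont + if (has_cover) n_cover_classes - 1 else 0L)
}

# Core maximizer. The covariates are standardized internally (the optimum
# is reparametrized exactly back to the raw scale) so that quasi-Newton
# steps are well conditioned regardless of covariate units, and the
# likelihood is maximized over a compact parameter box on that scale
# (slopes within +/-15 per covariate SD, intercept within +/-30) — a
# standard regularity condition for use-availability RSPF estimation,
# since the likelihood supremum can otherwise sit at infinity whenever a
# halfspace separates every used point from part of the availability
# sample. A solution on a slope face of the box is exactly that
# quasi-separation and is reported as such; an intercept pinned to its
# face marks the weakly identified exponential-tail ridge and is flagged,
# not fatal.
slope_box <- 15
intercept_box <- 30

fit_core <- function(x, y, start = NULL, max_iter = 500,
                     check_ridge = FALSE) {
  p <- ncol(x) + 1L
  mu <- if (ncol(x)) colMeans(x) else numeric(0)
  sd_ <- if (ncol(x)) apply(x, 2, stats::sd) else numeric(0)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  z <- if (ncol(x)) sweep(sweep(x, 2, mu), 2, sd_, "/") else x
  to_z <- function(b) c(b[1] + sum(b[-1] * mu), b[-1] * sd_)
  from_z <- function(b) c(b[1] - sum(b[-1] * mu / sd_), b[-1] / sd_)
  z_used <- z[y == 1, , drop = FALSE]
  z_avail <- z[y == 0, , drop = FALSE]
  if (is.null(start)) {
    start_z <- tryCatch(
      suppressWarnings(unname(stats::coef(
        stats::glm.fit(cbind(1, z), y, family = stats::binomial())))),
      error = function(e) rep(0, p))
    start_z[!is.finite(start_z)] <- 0
  } else start_z <- to_z(start)
  lower <- c(-intercept_box, rep(-slope_box, p - 1L))
  upper <- -lower
  start_z <- pmin(pmax(start_z, lower + 1e-6), upper - 1e-6)
  run <- function(par) {
    stats::optim(par, fn = neg_log_likelihood, gr = nll_gradient,
                 x_used = z_used, x_avail = z_avail, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = max_iter, factr = 1e5))
  }
  opt <- run(start_z)
  if (opt$convergence != 0) opt <- run(opt$par)   # one restart
  grad <- nll_gradient(opt$par, z_used, z_avail)
  converged <- opt$convergence == 0 || max(abs(grad)) < 1e-6
  at_face <- abs(opt$par) > c(intercept_box, rep(slope_box, p - 1L)) - 1e-3
  separated <- ncol(x) > 0 & at_face[-1]
  ridge <- at_face[1]
  if (converged && check_ridge && !any(at_face)) {
    # near-singular curvature also marks the weakly identified ridge
    h <- tryCatch(stats::optimHess(opt$par, fn = neg_log_likelihood,
                                   gr = nll_gradient,
                                   x_used = z_used, x_avail = z_avail),
                  error = function(e) NULL)
    if (!is.null(h) && all(is.finite(h))) {
      ev <- eigen(h, symmetric = TRUE, only.values = TRUE)$values
      ridge <- min(ev) < 1e-8 * max(abs(ev), 1)
    }
  }
  list(beta = from_z(opt$par), loglik = -opt$value, converged = converged,
       grad_norm = max(abs(grad)), ridge = ridge, separated = separated)
}

#' Fit a logistic RSPF by maximum likelihood
#'
#' Maximizes the use-availability log-likelihood by quasi-Newton iteration
#' from an ordinary logistic-regression warm start. Standard errors are the
#' standard deviations of the coefficient estimates over \code{B}
#' nonparametric bootstrap refits in which the used and available points
#' are resampled with replacement independently, preserving stratum sizes
#' (the unmatched, \code{m = 0}, design). p-values are two-sided Wald tests
#' using the bootstrap standard errors. Set \code{B = 0} to skip the
#' bootstrap (e.g. during model search, where only the AIC is needed).
#'
#' @param data an \code{rspf_data} from \code{\link{rspf_design}}, or a
#'   list with elements \code{x} (covariate matrix) and \code{y} (labels).
#' @param B bootstrap replicates (default 1000).
#' @param m matching parameter; only the unmatched design \code{m = 0} is
#'   supported.
#' @param seed RNG seed for the bootstrap.
#' @param max_drop_frac error if more than this fraction of bootstrap
#'   refits fails to converge (default 0.05).
#' @return an \code{rspf_fit}: \code{beta} (named), \code{se}, \code{p},
#'   \code{loglik}, \code{aic}, \code{k}, \code{n_used}, \code{n_avail},
#'   \code{B}, \code{m}, \code{converged}, \code{seed},
#'   \code{reference_class}, \code{n_boot_dropped}.
#' @export
fit_rspf <- function(data, B = 1000, m = 0, seed = 1,
                     max_drop_frac = 0.05) {
  if (m != 0) stop("only the unmatched design (m = 0) is supported")
  x <- data$x; y <- data$y
  if (!any(y == 1) || !any(y == 0)) stop("both labels must be present")
  if (ncol(x)) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("constant column(s): ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  core <- fit_core(x, y, check_ridge = TRUE)
  if (!core$converged)
    warning("maximum-likelihood fit did not converge (gradient max |g| = ",
            signif(core$grad_norm, 3), ")")
  if (any(core$separated))
    stop("apparent separation on column(s): ",
         paste(colnames(x)[core$separated], collapse = ", "))
  k <- length(core$beta)
  beta <- stats::setNames(core$beta, c("(Intercept)", colnames(x)))
  se <- p <- rep(NA_real_, k)
  n_dropped <- 0L
  if (B > 0) {
    iu <- which(y == 1); ia <- which(y == 0)
    boot <- with_seed(seed, {
      bb <- matrix(NA_real_, B, k)
      for (b in seq_len(B)) {
        su <- sample(iu, length(iu), replace = TRUE)
        sa <- sample(ia, length(ia), replace = TRUE)
        xb <- x[c(su, sa), , drop = FALSE]
        yb <- c(rep(1L, length(su)), rep(0L, length(sa)))
        fb <- tryCatch(fit_core(xb, yb, start = core$beta, max_iter = 200),
                       error = function(e) NULL)
        if (!is.null(fb) && fb$converged && !any(fb$separated))
          bb[b, ] <- fb$beta
      }
      bb
    })
    ok <- stats::complete.cases(boot)
    n_dropped <- sum(!ok)
    if (n_dropped > max_drop_frac * B)
      stop(sprintf("%d of %d bootstrap refits failed to converge",
                   n_dropped, B))
    se <- apply(boot[ok, , drop = FALSE], 2, stats::sd)
    p <- 2 * stats::pnorm(-abs(beta / se))
  }
  structure(list(beta = beta, se = stats::setNames(se, names(beta)),
                 p = stats::setNames(p, names(beta)),
                 loglik = core$loglik, aic = -2 * core$loglik + 2 * k,
                 k = k, n_used = sum(y == 1), n_avail = sum(y == 0),
                 B = B, m = m, converged = core$converged, seed = seed,
                 reference_class = data$reference_class,
                 n_boot_dropped = n_dropped,
                 ridge = core$ridge,
                 terms = data$terms),
            class = "rspf_fit")
}

#' @export
print.rspf_fit <- function(x, ...) {
  cat(sprintf(
    "<rspf_fit> %d parameters, n_used = %d, n_avail = %d, B = %d, m = %d\n",
    x$k, x$n_used, x$n_avail, x$B, x$m))
  cat(sprintf("  loglik = %.3f, AIC = %.3f%s\n", x$loglik, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(Estimate = x$beta, SE = x$se, p = x$p)
  print(signif(tab, 4))
  if (!is.null(x$reference_class))
    cat("  land-cover reference class:", x$reference_class, "\n")
  invisible(x)
}

#' @export
coef.rspf_fit <- function(object, ...) object$beta

#' AIC of a converged RSPF fit
#'
#' \code{-2 loglik + 2 k}, with the use-availability log-likelihood.
#'
#' @param fit an \code{rspf_fit}.
#' @return the AIC value.
#' @export
aic_of <- function(fit) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; AIC is unreliable")
  -2 * fit$loglik + 2 * fit$k
}

#' Read a use-availability covariate table
#'
#' Loads a CSV with a binary \code{Conflict} (or \code{label}) column and
#' covariate columns — the layout of a deposited model-input table with
#' location data withheld — into an \code{rspf_data} ready for fitting.
#'
#' @param path CSV path.
#' @param response name of the binary response column; the first of
#'   \code{Conflict}/\code{label} found is used when NULL.
#' @param categorical optional name of a categorical covariate column.
#' @return an \code{rspf_data}.
#' @export
read_conflict_table <- function(path, response = NULL, categorical = NULL) {
  df <- utils::read.csv(path)
  if (is.null(response))
    response <- intersect(c("Conflict", "conflict", "label"), names(df))[1]
  if (is.na(response) || is.null(response) || !response %in% names(df))
    stop("no binary response column found")
  y <- df[[response]]
  covs <- setdiff(names(df), response)
  pts <- point_set(x = rep(0, nrow(df)), y = rep(0, nrow(df)), label = y)
  pts <- cbind(pts, df[, covs, drop = FALSE])
  class(pts) <- c("point_set", "data.frame")
  rspf_design(pts, continuous = setdiff(covs, categorical),
              categorical = categorical)
}
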