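#' Fit a latent profile model over mixed continuous/binary indicators
#'
#' Finite-mixture model with class-conditional normal densities for
#' continuous indicators (local independence, class-invariant variances)
#' and class-conditional Bernoulli probabilities for binary indicators,
#' estimated by EM. Missing indicator entries contribute through the
#' casewise product over that case's observed entries (full-information),
#' not listwise deletion. The best of `n_starts` random initialisations by
#' log-likelihood is returned, with classes sorted ascending by the mean of
#' the first continuous indicator (a symptom-intensity score by convention)
#' so labels are deterministic.
#'
#' @param indicators data.frame or matrix of indicator columns.
#' @param K number of classes (>= 1).
#' @param binary character vector of binary column names; autodetected as
#'   0/1 columns when `NULL`.
#' @param n_starts random initialisations (default 20).
#' @param max_iter EM iteration cap per start.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param seed RNG seed for the initialisations.
#' @return object of class `lpa_fit`: mixture weights, class means,
#'   shared variances, binary probabilities, posterior matrix,
#'   log-likelihood (and its per-iteration trace), parameter count, AIC,
#'   BIC, relative entropy, and flags for degenerate classes
#'   (`pi_k < 1/n`).
#' @examples
#' x <- data.frame(a = c(rnorm(50, 0), rnorm(50, 4)),
#'                 b = c(rnorm(50, 0), rnorm(50, 4)))
#' fit <- fit_lpa(x, K = 2, seed = 1)
#' fit$weights
#' @export
fit_lpa <- function(indicators, K, binary = NULL, n_starts = 20L,
                    max_iter = 500L, tol = 1e-6, seed = 1L) {
  stopifnot(K >= 1L)
  x <- as.data.frame(indicators)
  if (is.null(binary)) {
    binary <- names(x)[vapply(x, is_binary01, logical(1L))]
  }
  cont <- setdiff(names(x), binary)
  if (length(cont) == 0L && length(binary) == 0L) {
    stop("no indicator columns supplied", call. = FALSE)
  }
  Xc <- as.matrix(x[cont])
  Xb <- as.matrix(x[binary])
  n <- nrow(x)
  if (sum(!duplicated(x)) < K) {
    stop("need at least K distinct indicator rows", call. = FALSE)
  }

  best <- NULL
  with_seed(seed, {
    for (s in seq_len(max(1L, if (K == 1L) 1L else n_starts))) {
      fit <- tryCatch(
        lpa_em(Xc, Xb, K, max_iter = max_iter, tol = tol),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik)) {
        best <- fit
      }
    }
  })
  if (is.null(best)) {
    stop("EM failed to converge in all starts", call. = FALSE)
  }
  if (!best$converged) {
    warning("EM did not reach the tolerance within `max_iter` iterations")
  }

  # label-switching convention: ascending mean of the first continuous indicator
  ord <- if (ncol(Xc) > 0L) order(best$means[, 1L]) else order(best$probs[, 1L])
  best$weights <- best$weights[ord]
  if (ncol(Xc) > 0L) best$means <- best$means[ord, , drop = FALSE]
  if (ncol(Xb) > 0L) best$probs <- best$probs[ord, , drop = FALSE]
  best$posteriors <- best$posteriors[, ord, drop = FALSE]

  n_params <- (K - 1L) + K * ncol(Xc) + ncol(Xc) + K * ncol(Xb)
  entropy <- if (K >= 2L) relative_entropy(best$posteriors) else NA_real_
  out <- list(
    K = K, weights = best$weights, means = best$means,
    variances = best$variances, probs = best$probs,
    posteriors = best$posteriors, loglik = best$loglik,
    loglik_trace = best$trace, n_params = n_params,
    aic = -2 * best$loglik + 2 * n_params,
    bic = -2 * best$loglik + n_params * log(n),
    entropy_rel = entropy, n = n,
    continuous = cont, binary = binary,
    degenerate = best$weights < 1 / n,
    converged = best$converged)
  class(out) <- "lpa_fit"
  out
}

# One EM run from a random start. Shared (class-invariant) variances for the
# continuous block; Bernoulli probabilities bounded away from {0,1} by 1e-4.
lpa_em <- function(Xc, Xb, K, max_iter, tol) {
  n <- nrow(Xc) %||% nrow(Xb)
  if (is.null(n) || n == 0L) n <- max(nrow(Xc), nrow(Xb))
  pc <- ncol(Xc); pb <- ncol(Xb)
  obs_c <- !is.na(Xc); obs_b <- !is.na(Xb)
  Xc0 <- Xc; Xc0[!obs_c] <- 0
  Xb0 <- Xb; Xb0[!obs_b] <- 0

  # initialise at K perturbed random cases
  ctr <- Xc[sample.int(n, K), , drop = FALSE]
  if (pc > 0L) {
    cm <- colMeans(Xc, na.rm = TRUE)
    for (k in seq_len(K)) ctr[k, is.na(ctr[k, ])] <- cm[is.na(ctr[k, ])]
    sds <- apply(Xc, 2L, stats::sd, na.rm = TRUE)
    sds[!is.finite(sds) | sds == 0] <- 1
    mu <- ctr + matrix(stats::rnorm(K * pc, 0, 0.1), K, pc) *
      matrix(sds, K, pc, byrow = TRUE)
    sig2 <- sds^2
  } else {
    mu <- matrix(numeric(0), K, 0L)
    sig2 <- numeric(0)
  }
  pr <- if (pb > 0L) {
    matrix(pmin(pmax(colMeans(Xb, na.rm = TRUE) +
                       stats::runif(K * pb, -0.2, 0.2), 0.05), 0.95),
           K, pb, byrow = FALSE)
  } else matrix(numeric(0), K, 0L)
  w <- rep(1 / K, K)

  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: casewise log-density over observed entries
    lg <- matrix(0, n, K)
    for (k in seq_len(K)) {
      acc <- numeric(n)
      if (pc > 0L) {
        ld <- dnorm(Xc0, matrix(mu[k, ], n, pc, byrow = TRUE),
                    matrix(sqrt(sig2), n, pc, byrow = TRUE), log = TRUE)
        acc <- acc + rowSums(ld * obs_c)
      }
      if (pb > 0L) {
        lp <- matrix(log(pr[k, ]), n, pb, byrow = TRUE)
        lq <- matrix(log1p(-pr[k, ]), n, pb, byrow = TRUE)
        acc <- acc + rowSums((Xb0 * lp + (1 - Xb0) * lq) * obs_b)
      }
      lg[, k] <- log(w[k]) + acc
    }
    lse <- row_logsumexp(lg)
    ll <- sum(lse)
    r <- exp(lg - lse)
    trace <- c(trace, ll)

    if (is.finite(ll_old) && (ll - ll_old) < tol * abs(ll)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll

    # M-step
    w <- colMeans(r)
    if (pc > 0L) {
      for (k in seq_len(K)) {
        wk <- r[, k]
        denom <- colSums(wk * obs_c)
        mu[k, ] <- colSums(wk * Xc0) / pmax(denom, 1e-12)
      }
      ssq <- numeric(pc)
      wobs <- numeric(pc)
      for (k in seq_len(K)) {
        d <- (Xc0 - matrix(mu[k, ], n, pc, byrow = TRUE))^2
        ssq <- ssq + colSums(r[, k] * d * obs_c)
        wobs <- wobs + colSums(r[, k] * obs_c)
      }
      sig2 <- pmax(ssq / pmax(wobs, 1e-12), 1e-8)
    }
    if (pb > 0L) {
      for (k in seq_len(K)) {
        wk <- r[, k]
        pr[k, ] <- colSums(wk * Xb0 * obs_b) / pmax(colSums(wk * obs_b), 1e-12)
      }
      pr <- pmin(pmax(pr, 1e-4), 1 - 1e-4)
    }
  }
  if (pc > 0L) {
    colnames(mu) <- colnames(Xc)
    names(sig2) <- colnames(Xc)
  }
  if (pb > 0L) colnames(pr) <- colnames(Xb)
  list(weights = w, means = mu, variances = sig2, probs = pr,
       posteriors = r, loglik = ll_old, trace = trace, converged = converged)
}

#' @export
print.lpa_fit <- function(x, ...) {
  cat("Latent profile model, K =", x$K, "\n")
  cat("  n =", x$n, " loglik =", format(x$loglik, digits = 8),
      " BIC =", format(x$bic, digits = 8), "\n")
  cat("  weights:", paste(round(x$weights, 3), collapse = ", "), "\n")
  if (!is.na(x$entropy_rel)) {
    cat("  relative entropy:", round(x$entropy_rel, 3), "\n")
  }
  if (any(x$degenerate)) {
    cat("  WARNING: degenerate class (weight < 1/n):",
        which(x$degenerate), "\n")
  }
  invisible(x)
}

#' Profile enumeration and model selection table
#'
#' Fits K = 1..K_max profile models and tabulates log-likelihood, AIC, BIC,
#' relative entropy and the smallest class fraction, flagging the
#' BIC-minimising solution. Failed fits are annotated per row rather than
#' dropped.
#'
#' @inheritParams fit_lpa
#' @param K_max largest class count to consider (>= 2).
#' @param ... passed to [fit_lpa()].
#' @return data.frame with one row per K and attribute `"fits"` holding the
#'   fitted models.
#' @export
select_profiles <- function(indicators, K_max, binary = NULL, seed = 1L, ...) {
  stopifnot(K_max >= 2L)
  rows <- vector("list", K_max)
  fits <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    fit <- tryCatch(fit_lpa(indicators, K, binary = binary, seed = seed, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[K]] <- data.frame(K = K, loglik = NA_real_, n_params = NA_integer_,
                              aic = NA_real_, bic = NA_real_,
                              entropy_rel = NA_real_,
                              min_class_frac = NA_real_,
                              error = conditionMessage(fit))
    } else {
      fits[[K]] <- fit
      rows[[K]] <- data.frame(K = K, loglik = fit$loglik,
                              n_params = fit$n_params, aic = fit$aic,
                              bic = fit$bic, entropy_rel = fit$entropy_rel,
                              min_class_frac = min(fit$weights),
                              error = NA_character_)
    }
  }
  tab <- do.call(rbind, rows)
  tab$best_bic <- !is.na(tab$bic) & tab$bic == min(tab$bic, na.rm = TRUE)
  attr(tab, "fits") <- fits
  tab
}

#' Relative entropy of a posterior classification
#'
#' `1 - sum_i sum_k (-p_ik log p_ik) / (n log K)`: 1 for perfectly separated
#' classes, 0 for uniformly uncertain assignment.
#'
#' @param posteriors n x K matrix with rows summing to 1.
#' @return scalar in [0, 1].
#' @export
relative_entropy <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  K <- ncol(posteriors)
  stopifnot(K >= 2L)
  if (any(abs(rowSums(posteriors) - 1) > 1e-8)) {
    stop("posterior rows must sum to 1", call. = FALSE)
  }
  p <- pmin(pmax(posteriors, 0), 1)
  terms <- ifelse(p > 0, -p * log(p), 0)
  1 - sum(terms) / (nrow(p) * log(K))
}

#' Modal class assignment
#'
#' Row-wise argmax of the posterior matrix; ties break toward the lower
#' class index.
#'
#' @param posteriors n x K posterior matrix.
#' @return integer labels in 1..K.
#' @export
modal_assignment <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  max.col(posteriors, ties.method = "first")
}

#' Standardized (z-score) profile means
#'
#' For each indicator, the class-specific model mean (continuous) or
#' proportion (binary) standardized by the pooled sample mean and SD of
#' that indicator, giving the display scale used for profile plots where
#' continuous and dichotomous items share an axis.
#'
#' @param model an `lpa_fit`.
#' @param indicators the indicator data the model was fitted to.
#' @return long data.frame: `indicator`, `type`, `class`, `class_value`,
#'   `pooled_mean`, `pooled_sd`, `z`.
#' @export
profile_zscores <- function(model, indicators) {
  x <- as.data.frame(indicators)
  rows <- list()
  for (j in seq_along(model$continuous)) {
    nm <- model$continuous[j]
    v <- x[[nm]]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero-variance indicator: ", nm, call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      indicator = nm, type = "continuous", class = seq_len(model$K),
      class_value = model$means[, nm], pooled_mean = m, pooled_sd = s,
      z = (model$means[, nm] - m) / s)
  }
  for (nm in model$binary) {
    v <- x[[nm]]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      stop("zero-variance indicator: ", nm, call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      indicator = nm, type = "binary", class = seq_len(model$K),
      class_value = model$probs[, nm], pooled_mean = m, pooled_sd = s,
      z = (model$probs[, nm] - m) / s)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare classes on distal variables
#'
#' Effect sizes for variables deliberately excluded from the mixture
#' likelihood (e.g. quality of life): pooled-SD standardized mean
#' difference (Cohen's d, class 2 minus class 1) for continuous variables,
#' odds ratio for binary ones, with normal-theory 95% CIs.
#'
#' @param dataset data.frame containing the distal columns.
#' @param labels class labels (two classes) from [modal_assignment()].
#' @param distal_columns character vector of column names.
#' @return data.frame with one row per distal variable.
#' @export
compare_distal <- function(dataset, labels, distal_columns) {
  stopifnot(length(labels) == nrow(dataset))
  cls <- sort(unique(labels))
  if (length(cls) != 2L) stop("exactly two classes required", call. = FALSE)
  rows <- lapply(distal_columns, function(nm) {
    v <- dataset[[nm]]
    if (is.null(v)) stop("unknown distal column: ", nm, call. = FALSE)
    v1 <- v[labels == cls[1L] & !is.na(v)]
    v2 <- v[labels == cls[2L] & !is.na(v)]
    if (length(v1) < 2L || length(v2) < 2L) {
      stop("need >= 2 observed cases per class for ", nm, call. = FALSE)
    }
    n1 <- length(v1); n2 <- length(v2)
    if (is_binary01(v)) {
      tab <- c(sum(v2 == 1), sum(v2 == 0), sum(v1 == 1), sum(v1 == 0)) + 0.5
      or <- (tab[1L] / tab[2L]) / (tab[3L] / tab[4L])
      se <- sqrt(sum(1 / tab))
      data.frame(variable = nm, type = "binary", measure = "odds_ratio",
                 estimate = or,
                 lower = exp(log(or) - 1.96 * se),
                 upper = exp(log(or) + 1.96 * se),
                 n1 = n1, n2 = n2)
    } else {
      sp <- sqrt(((n1 - 1) * stats::var(v1) + (n2 - 1) * stats::var(v2)) /
                   (n1 + n2 - 2))
      d <- (mean(v2) - mean(v1)) / sp
      se <- sqrt(1 / n1 + 1 / n2 + d^2 / (2 * (n1 + n2)))
      data.frame(variable = nm, type = "continuous", measure = "cohens_d",
                 estimate = d, lower = d - 1.96 * se, upper = d + 1.96 * se,
                 n1 = n1, n2 = n2)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot standardized profile means
#'
#' Line plot of per-class z-scores across the indicator battery
#' (requires ggplot2).
#'
#' @param zscores output of [profile_zscores()].
#' @return a ggplot object.
#' @export
plot_profile_zscores <- function(zscores) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  zscores$indicator <- factor(zscores$indicator,
                              levels = unique(zscores$indicator))
  ggplot2::ggplot(zscores,
                  ggplot2::aes(x = .data$indicator, y = .data$z,
                               group = factor(.data$class),
                               colour = factor(.data$class))) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "z-score (pooled standardisation)",
                  colour = "Profile") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
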