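#' Admixture model fitted by EM
#'
#' Maximum likelihood in the standard admixture model: sample `i`'s two
#' alleles at locus `j` are independent draws from `K` ancestral
#' populations with ancestry fractions `q_i` (rows of Q, on the simplex)
#' and population alternate-allele frequencies `f_k` (rows of F). The
#' binomial log-likelihood over non-missing dosages `g`,
#' `sum g log(QF) + (2 - g) log(Q(1-F))`, is maximized by multiplicative EM
#' updates, which increase it monotonically. Several random restarts are
#' run and the best kept.
#'
#' @param gm A [genotype_matrix()].
#' @param K Number of ancestral populations (1 to `n_samples`).
#' @param seed RNG seed for the restarts.
#' @param n_restarts Number of random initializations (default 8).
#' @param max_iter EM iteration cap per restart (default 2000).
#' @param tol Relative log-likelihood change for convergence (default 1e-6).
#' @return An `admixture_fit`: list with `K`, `Q` (n x K, rows sum to 1),
#'   `F` (K x m in (0,1)), `loglik`, `loglik_trace` (best restart),
#'   `restart_logliks`, `n_iter`, `converged`.
#' @export
admixture_em <- function(gm, K, seed = 1L, n_restarts = 8L,
                         max_iter = 2000L, tol = 1e-6) {
  K <- as.integer(K)
  n <- n_samples(gm)
  m <- n_loci(gm)
  if (K < 1L || K > n) abort("K must be between 1 and the number of samples")
  if (m < 1L) abort("admixture needs at least one locus")
  g <- gm$geno
  w <- !is.na(g)
  g0 <- g
  g0[!w] <- 0L
  storage.mode(g0) <- "double"
  w_num <- w
  storage.mode(w_num) <- "double"
  m_i <- rowSums(w_num)
  if (any(m_i == 0)) abort("a sample has no non-missing genotypes")
  p_pool <- colSums(g0) / (2 * pmax(colSums(w_num), 1))

  set.seed(derive_seed(seed, paste0("admixture", K)))
  best <- NULL
  restart_ll <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    fit <- admixture_em_once(g0, w_num, m_i, p_pool, K, max_iter, tol)
    restart_ll[r] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  rownames(best$Q) <- gm$samples
  colnames(best$Q) <- paste0("K", seq_len(K))
  colnames(best$F) <- gm$loci$id
  structure(
    list(
      K = K, Q = best$Q, F = best$F, loglik = best$loglik,
      loglik_trace = best$trace, restart_logliks = restart_ll,
      n_iter = best$n_iter, converged = best$converged
    ),
    class = "admixture_fit"
  )
}

admixture_em_once <- function(g0, w, m_i, p_pool, K, max_iter, tol) {
  n <- nrow(g0)
  m <- ncol(g0)
  eps <- 1e-6
  if (K == 1L) {
    q <- matrix(1, n, 1L)
    f <- matrix(pmin(pmax(p_pool, eps), 1 - eps), 1L, m)
    ll <- admixture_loglik(g0, w, q, f)
    return(list(Q = q, F = f, loglik = ll, trace = ll, n_iter = 0L,
      converged = TRUE))
  }
  q <- matrix(rgamma(n * K, 1), n, K)
  q <- q / rowSums(q)
  f <- matrix(
    pmin(pmax(rep(p_pool, each = K) + runif(K * m, -0.1, 0.1), eps), 1 - eps),
    K, m
  )
  trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    p1 <- q %*% f
    p0 <- q %*% (1 - f)
    a_mat <- w * g0 / p1        # expected alt-allele responsibilities / qf
    b_mat <- w * (2 - g0) / p0
    qt_a <- crossprod(q, a_mat) # K x m
    qt_b <- crossprod(q, b_mat)
    f_new <- f * qt_a / (f * qt_a + (1 - f) * qt_b)
    f_new[!is.finite(f_new)] <- eps
    f_new <- pmin(pmax(f_new, eps), 1 - eps)
    q_new <- q * (a_mat %*% t(f) + b_mat %*% t(1 - f)) / (2 * m_i)
    q_new <- q_new / rowSums(q_new)
    q <- q_new
    f <- f_new
    ll <- admixture_loglik(g0, w, q, f)
    trace <- c(trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }
  list(Q = q, F = f, loglik = trace[length(trace)], trace = trace,
    n_iter = iter, converged = converged)
}

admixture_loglik <- function(g0, w, q, f) {
  p1 <- pmax(q %*% f, 1e-300)
  p0 <- pmax(q %*% (1 - f), 1e-300)
  sum(w * (g0 * log(p1) + (2 - g0) * log(p0)))
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "<admixture_fit> K = %d, log-likelihood = %.2f (%s in %d iterations)\n",
    x$K, x$loglik, if (x$converged) "converged" else "iteration cap",
    x$n_iter
  ))
  invisible(x)
}

#' Long-format ancestry fractions of an admixture fit
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble: `sample`, `component`, `ancestry`.
#' @method tidy admixture_fit
#' @export
tidy.admixture_fit <- function(x, ...) {
  tibble(
    sample = rep(rownames(x$Q), times = x$K),
    component = rep(colnames(x$Q), each = nrow(x$Q)),
    ancestry = as.vector(x$Q)
  )
}

#' One-row summary of an admixture fit
#' @param x An `admixture_fit`.
#' @param ... Unused.
#' @return Tibble with `K`, `loglik`, `n_iter`, `converged`,
#'   `mean_max_ancestry`.
#' @method glance admixture_fit
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(
    K = x$K, loglik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    mean_max_ancestry = mean(apply(x$Q, 1L, max))
  )
}

#' Stacked ancestry bar plot
#' @param object An `admixture_fit`.
#' @param varieties Optional sample-to-cultivar map used to order samples.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot admixture_fit
#' @export
autoplot.admixture_fit <- function(object, varieties = NULL, ...) {
  d <- tidy(object)
  if (!is.null(varieties)) {
    v <- variety_assignment(varieties)
    d$sample <- factor(d$sample, levels = v$sample[order(v$variety)])
  }
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$sample, y = .data$ancestry, fill = .data$component
  )) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "ancestry fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6))
}

#' Choose K by entry-masking cross-validation
#'
#' Non-missing genotype entries are partitioned into `folds` folds; per
#' fold the held-out entries are masked, the admixture model refitted, and
#' the prediction error is the root-mean-square of `g - 2 * (QF)` over the
#' masked entries. The CV error per K is the mean over folds, and the
#' selected `k_best` is the argmin (ties to the smaller K).
#'
#' @param gm A [genotype_matrix()].
#' @param k_range Integer vector of K values (default 1:7).
#' @param folds Number of CV folds (default 5).
#' @param seed RNG seed (fold assignment and restarts).
#' @param n_restarts,max_iter,tol Passed to [admixture_em()].
#' @return A `cv_k`: list with `cv` (tibble `K`, `fold`, `rmse`),
#'   `cv_mean` (tibble `K`, `cv_error`), `k_best`.
#' @export
cv_choose_k <- function(gm, k_range = 1:7, folds = 5L, seed = 1L,
                        n_restarts = 8L, max_iter = 2000L, tol = 1e-6) {
  if (length(k_range) == 0L) abort("k_range must be non-empty")
  folds <- as.integer(folds)
  if (folds < 2L) abort("need at least 2 folds")
  w_idx <- which(!is.na(gm$geno))
  if (length(w_idx) < folds * 10L) abort("too few non-missing entries to fold")
  set.seed(derive_seed(seed, "cvfolds"))
  fold_of <- sample(rep_len(seq_len(folds), length(w_idx)))
  rows <- list()
  for (f_i in seq_len(folds)) {
    masked <- w_idx[fold_of == f_i]
    gm_f <- gm
    gm_f$geno[masked] <- NA_integer_
    for (k in k_range) {
      fit <- admixture_em(
        gm_f, k,
        seed = derive_seed(seed, paste0("cv", f_i, "k", k)),
        n_restarts = n_restarts, max_iter = max_iter, tol = tol
      )
      pred <- 2 * (fit$Q %*% fit$F)
      err <- gm$geno[masked] - pred[masked]
      rows[[length(rows) + 1L]] <- tibble(
        K = k, fold = f_i, rmse = sqrt(mean(err^2))
      )
    }
  }
  cv <- bind_rows(rows)
  cv_mean <- cv |>
    group_by(.data$K) |>
    summarise(cv_error = mean(.data$rmse), .groups = "drop") |>
    arrange(.data$K)
  k_best <- cv_mean$K[which.min(cv_mean$cv_error)]
  structure(
    list(cv = cv, cv_mean = cv_mean, k_best = k_best),
    class = "cv_k"
  )
}

#' @export
print.cv_k <- function(x, ...) {
  cat(sprintf("<cv_k> best K = %d\n", x$k_best))
  print(x$cv_mean)
  invisible(x)
}

#' @method tidy cv_k
#' @export
tidy.cv_k <- function(x, ...) x$cv_mean

#' CV-error curve over K
#' @param object A `cv_k`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_k
#' @export
autoplot.cv_k <- function(object, ...) {
  ggplot2::ggplot(object$cv_mean, ggplot2::aes(x = .data$K, y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_best, linetype = 2) +
    ggplot2::labs(x = "K", y = "CV error (RMSE)") +
    ggplot2::theme_minimal()
}
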