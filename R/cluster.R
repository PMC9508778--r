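# Unsupervised subgroup discovery: variational Bayesian Gaussian mixtures
# over moving windows, with small-cluster reassignment.
#
# The mixture is fit by variational inference with a Dirichlet weight
# prior whose small concentration lets superfluous components empty out,
# so the number of clusters is learned from the data: initialized at
# init_k components, well-separated data ends with only the supported
# components non-empty.

# Variational Bayesian Gaussian mixture (full covariance).
# Conjugate priors: Dirichlet(alpha0) on weights, Gaussian-Wishart on each
# component (beta0 = 1, m0 = data mean, nu0 = d, Wishart scale from the
# data covariance). Returns maximum-responsibility assignments.
vbgmm_once <- function(x, init_k, max_iter = 500, tol = 1e-6,
                       weight_conc = NULL, reg_covar = 1e-6) {
  n <- nrow(x); d <- ncol(x)
  alpha0 <- weight_conc %||% (1 / init_k)
  beta0 <- 1
  m0 <- colMeans(x)
  nu0 <- d
  cov_x <- stats::cov(x)
  if (anyNA(cov_x)) cov_x <- matrix(0, d, d)
  invW0 <- cov_x * nu0 + diag(reg_covar, d)

  # responsibilities from a k-means init (one-hot); collapse when the data
  # have fewer distinct rows than components
  ux <- unique(x)
  if (nrow(ux) <= init_k) {
    cl <- match(data.frame(t(x)), data.frame(t(ux)))
  } else {
    cl <- stats::kmeans(x, centers = init_k, nstart = 5,
                        iter.max = 50)$cluster
  }
  r <- matrix(1e-10, n, init_k)
  r[cbind(seq_len(n), cl)] <- 1
  r <- r / rowSums(r)

  for (iter in seq_len(max_iter)) {
    nk <- colSums(r) + 1e-10
    alpha <- alpha0 + nk
    beta <- beta0 + nk
    nu <- nu0 + nk
    xbar <- crossprod(r, x) / nk
    mk <- (beta0 * matrix(m0, init_k, d, byrow = TRUE) + nk * xbar) / beta
    log_rho <- matrix(0, n, init_k)
    e_log_pi <- digamma(alpha) - digamma(sum(alpha))
    for (k in seq_len(init_k)) {
      xc <- sweep(x, 2, xbar[k, ])
      Sk <- crossprod(xc * r[, k], xc) / nk[k]
      dm <- xbar[k, ] - m0
      invWk <- invW0 + nk[k] * Sk +
        (beta0 * nk[k] / (beta0 + nk[k])) * tcrossprod(dm)
      invWk <- (invWk + t(invWk)) / 2 + diag(reg_covar, d)
      ch <- chol(invWk)
      logdet_W <- -2 * sum(log(diag(ch)))
      e_logdet <- sum(digamma((nu[k] + 1 - seq_len(d)) / 2)) +
        d * log(2) + logdet_W
      xm <- sweep(x, 2, mk[k, ])
      # quadratic form via the Cholesky of invWk: x' W x = ||ch^-T x||^2
      sol <- backsolve(ch, t(xm), transpose = TRUE)
      quad <- nu[k] * colSums(sol^2) + d / beta[k]
      log_rho[, k] <- e_log_pi[k] + 0.5 * e_logdet -
        0.5 * d * log(2 * pi) - 0.5 * quad
    }
    log_rho <- log_rho - apply(log_rho, 1, max)
    r_new <- exp(log_rho)
    r_new <- r_new / rowSums(r_new)
    delta <- mean(abs(r_new - r))
    r <- r_new
    if (delta < tol) {
      attr(r, "converged") <- TRUE
      attr(r, "iterations") <- iter
      break
    }
  }
  assign <- max.col(r, ties.method = "first")
  list(assignment = assign, responsibilities = r,
       means = crossprod(r, x) / (colSums(r) + 1e-10),
       weights = (alpha0 + colSums(r)) / (init_k * alpha0 + n),
       converged = isTRUE(attr(r, "converged")))
}

#' Fit a variational Bayesian Gaussian mixture to one window
#'
#' @param x Participants x features matrix (standardized per window).
#' @param init_k Initial number of components (default 5; superfluous
#'   components empty out under the sparse weight prior).
#' @param seed Optional seed (k-means initialization and retries).
#' @param max_retries Re-initializations allowed on non-convergence.
#' @return A list: `assignment` (1-based component per row), `n_effective`
#'   (components with >= 1 assigned member), `means`, `converged`.
#' @export
fit_mixture_clusters <- function(x, init_k = 5, seed = NULL,
                                 max_retries = 3) {
  x <- as.matrix(x)
  if (nrow(x) < init_k)
    stop_gp("need >= init_k = %d rows (got %d)", init_k, nrow(x))
  with_seed_if(seed, {
    fit <- NULL
    for (try in seq_len(max_retries)) {
      fit <- vbgmm_once(x, init_k)
      if (fit$converged) break
      gp_log("mixture fit did not converge; retry %d", try, level = "WARN")
    }
    if (!fit$converged) stop_gp("mixture fit failed to converge")
    used <- sort(unique(fit$assignment))
    fit$n_effective <- length(used)
    fit
  })
}

#' Reassign members of small clusters to the nearest large cluster
#'
#' Clusters with fewer than `min_size` members are dissolved: each of
#' their members joins the large cluster whose mean feature vector
#' (computed before any reassignment) is nearest in Euclidean distance;
#' exact ties go to the lowest-indexed cluster (logged).
#'
#' @param assignment Integer cluster labels.
#' @param x The feature matrix the clustering was fit on.
#' @param min_size Minimum size of a "large" cluster (default 4).
#' @return The final integer assignment (labels of the large clusters).
#' @export
merge_small_clusters <- function(assignment, x, min_size = 4) {
  x <- as.matrix(x)
  sizes <- table(assignment)
  large <- as.integer(names(sizes)[sizes >= min_size])
  if (!length(large)) stop_gp("no cluster reaches min_size = %d", min_size)
  small <- setdiff(as.integer(names(sizes)), large)
  if (!length(small)) return(assignment)
  means <- t(vapply(large, function(k)
    colMeans(x[assignment == k, , drop = FALSE]), numeric(ncol(x))))
  for (i in which(assignment %in% small)) {
    d2 <- rowSums(sweep(means, 2, x[i, ])^2)
    if (sum(d2 == min(d2)) > 1)
      gp_log("tie reassigning row %d; lowest-index cluster used", i)
    assignment[i] <- large[which.min(d2)]
  }
  assignment
}

# Greedy nearest-mean matching of window clusters onto canonical clusters;
# unmatched window clusters open new canonical entries.
match_clusters <- function(win_means, canon_means) {
  kw <- nrow(win_means); kc <- nrow(canon_means)
  d2 <- outer(rowSums(win_means^2), rowSums(canon_means^2), "+") -
    2 * tcrossprod(win_means, canon_means)
  map <- rep(NA_integer_, kw)
  used_w <- logical(kw); used_c <- logical(kc)
  for (step in seq_len(min(kw, kc))) {
    d2m <- d2
    d2m[used_w, ] <- Inf; d2m[, used_c] <- Inf
    pos <- which(d2m == min(d2m), arr.ind = TRUE)[1, ]
    map[pos[1]] <- pos[2]
    used_w[pos[1]] <- TRUE; used_c[pos[2]] <- TRUE
  }
  map
}

#' Moving-window mixture clustering with assignment frequencies
#'
#' Slides a window of `window_s` seconds with step `step_s` over the
#' combined timeline; in each window, participants' standardized feature
#' vectors are clustered with [fit_mixture_clusters()] and small clusters
#' are dissolved with [merge_small_clusters()]. Cluster identities are
#' matched across windows by nearest cluster means (in raw feature
#' space), and each participant's frequency of assignment to each final
#' cluster across windows is reported. Final clusters are numbered by
#' decreasing size in the first window.
#'
#' @param tl A `cohort_timeline`.
#' @param window_s,step_s Window length and step (seconds).
#' @param features Feature set (default the four headline features).
#' @param init_k,min_size Mixture initialization and small-cluster bound.
#' @param seed Optional seed.
#' @return A list of class `cluster_result`: `frequencies` (participants x
#'   clusters, rows sum to 1 over windows seen), `n_clusters_per_window`,
#'   `cluster_sizes` (mean, sd per cluster across windows), `n_windows`.
#' @export
windowed_cluster_frequencies <- function(tl, window_s = 600, step_s = 60,
                                         features = FOUR_FEATURES,
                                         init_k = 5, min_size = 4,
                                         seed = NULL) {
  total_s <- timeline_duration(tl)
  if (window_s > total_s) stop_gp("window exceeds the timeline")
  starts <- seq(0, total_s - window_s, by = step_s)
  if (length(starts) < 3)
    gp_log("only %d window(s); assignment frequencies will be unstable",
           length(starts), level = "WARN")
  with_seed_if(seed, {
    n <- length(tl$ids)
    canon_means <- NULL
    counts <- NULL      # participants x canonical clusters
    seen <- integer(n)
    k_per_window <- integer(0)
    size_lists <- list()
    for (s0 in starts) {
      m <- epoch_features(tl, s0, window_s)[, features, drop = FALSE]
      ok <- stats::complete.cases(m)
      if (sum(ok) < init_k) next
      xs <- standardize_features(m[ok, , drop = FALSE])
      fit <- fit_mixture_clusters(xs, init_k = init_k)
      assign_f <- merge_small_clusters(fit$assignment, xs,
                                       min_size = min_size)
      labs <- sort(unique(assign_f))
      k_per_window <- c(k_per_window, length(labs))
      win_means <- t(vapply(labs, function(k)
        colMeans(m[ok, , drop = FALSE][assign_f == k, , drop = FALSE]),
        numeric(length(features))))
      if (is.null(canon_means)) {
        ord <- order(-as.numeric(table(assign_f)[as.character(labs)]))
        canon_means <- win_means[ord, , drop = FALSE]
        map <- match(assign_f, labs[ord])
        counts <- matrix(0L, n, nrow(canon_means))
      } else {
        lab_map <- match_clusters(win_means, canon_means)
        for (j in which(is.na(lab_map))) {
          canon_means <- rbind(canon_means, win_means[j, ])
          counts <- cbind(counts, 0L)
          lab_map[j] <- nrow(canon_means)
        }
        map <- lab_map[match(assign_f, labs)]
      }
      rows <- which(ok)
      counts[cbind(rows, map)] <- counts[cbind(rows, map)] + 1L
      seen[rows] <- seen[rows] + 1L
      sz <- tabulate(map, nbins = ncol(counts))
      size_lists <- c(size_lists, list(sz))
    }
    if (is.null(counts)) stop_gp("no window produced a clustering")
    freq <- counts / pmax(seen, 1L)
    rownames(freq) <- tl$ids
    colnames(freq) <- paste0("cluster", seq_len(ncol(freq)))
    sizes <- do.call(rbind, lapply(size_lists, function(s)
      c(s, rep(0L, ncol(counts) - length(s)))))
    structure(list(frequencies = freq, seen = seen,
                   n_clusters_per_window = k_per_window,
                   cluster_sizes = data.frame(
                     cluster = colnames(freq),
                     mean_size = colMeans(sizes),
                     sd_size = apply(sizes, 2, stats::sd)),
                   n_windows = length(k_per_window), groups = tl$groups),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d windows, clusters per window: %s\n",
              x$n_windows, paste(unique(x$n_clusters_per_window),
                                 collapse = "/")))
  for (i in seq_len(nrow(x$cluster_sizes)))
    cat(sprintf("  %s: %.1f +/- %.1f members\n", x$cluster_sizes$cluster[i],
                x$cluster_sizes$mean_size[i], x$cluster_sizes$sd_size[i]))
  invisible(x)
}
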