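# De-novo signature extraction by non-negative matrix factorisation with
# randomisation-based rank selection, cosine matching against reference
# signatures, and per-sample exposure refitting with a minimum-contribution
# threshold.

#' Cosine similarity between two non-negative vectors
#' @param a,b numeric vectors of equal length.
#' @return cosine similarity in [0, 1] for non-negative input; 0 when
#'   either vector is all zero.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# One KL-divergence NMF fit with multiplicative updates. Returns W, H and
# the objective trace (generalized KL divergence, non-increasing).
nmf_kl <- function(V, k, max_iter = 1000, tol = 1e-8) {
  eps <- .Machine$double.eps
  m <- nrow(V); n <- ncol(V)
  W <- matrix(stats::runif(m * k, 0.1, 1), m, k)
  H <- matrix(stats::runif(k * n, 0.1, 1), k, n)
  kl <- function(WH) {
    P <- V > 0
    sum(V[P] * log(V[P] / WH[P])) - sum(V) + sum(WH)
  }
  WH <- W %*% H
  obj <- kl(WH)
  trace <- obj
  for (it in seq_len(max_iter)) {
    H <- H * (t(W) %*% (V / pmax(WH, eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    W <- W * ((V / pmax(WH, eps)) %*% t(H)) / pmax(rep(1, m) %o% rowSums(H), eps)
    WH <- W %*% H
    new_obj <- kl(WH)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) < tol * max(abs(obj), 1)) { obj <- new_obj; break }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

# Consensus-clustering diagnostics over NMF restarts: samples are assigned
# to the signature dominating their exposure; the consensus matrix is the
# co-assignment frequency across restarts.
consensus_diagnostics <- function(memberships, k) {
  n <- length(memberships[[1]])
  consensus <- matrix(0, n, n)
  for (m in memberships) consensus <- consensus + outer(m, m, "==")
  consensus <- consensus / length(memberships)
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  coph <- suppressWarnings(stats::cor(stats::cophenetic(hc), d))
  if (is.na(coph)) coph <- 1  # degenerate: all consensus entries equal
  cl <- stats::cutree(hc, k = min(k, n))
  list(cophenetic = coph,
       silhouette = mean_silhouette(as.matrix(1 - consensus), cl))
}

# Mean silhouette width for a hard clustering on a dissimilarity matrix.
mean_silhouette <- function(D, cl) {
  n <- length(cl)
  if (length(unique(cl)) < 2) return(0)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(D[i, cl == g]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

permute_rows <- function(V) {
  t(apply(V, 1, sample))
}

#' De-novo signature extraction with randomisation-based rank selection
#'
#' For each candidate rank, `n_runs` NMF restarts (generalized
#' Kullback-Leibler objective, multiplicative updates) are fitted; a
#' consensus matrix over restarts yields the cophenetic coefficient and
#' mean silhouette width. The same diagnostics are computed on randomized
#' data, re-permuting each category row across samples for every restart,
#' to give an overfitting baseline. The chosen rank is the largest one
#' whose cophenetic coefficient is at least `coph_min`, mean silhouette at
#' least `sil_min`, and both exceed the randomized baseline at that rank;
#' if no rank qualifies, the rank with maximal cophenetic coefficient is
#' used. Signatures are taken from the restart with the best objective at
#' the chosen rank, columns normalized to sum 1.
#'
#' @param matrix a `FeatureMatrix` (categories x samples) with at least
#'   two non-zero sample columns.
#' @param ranks candidate ranks (default 2:12); ranks not below the number
#'   of samples are skipped with a warning.
#' @param n_runs NMF restarts per rank on the observed data (default 100).
#' @param n_randomized_runs restarts per rank on randomized data
#'   (default 100).
#' @param seed integer seed; the fit is fully deterministic given the seed.
#' @param max_iter,tol multiplicative-update iteration cap and relative
#'   objective-change tolerance per run.
#' @param coph_min,sil_min rank-acceptance thresholds (defaults 0.95, 0.8).
#' @return a `SignatureModel`: list with `scheme`, `W` (categories x K,
#'   columns sum to 1), `H` (exposures of the best run), `chosen_rank`, and
#'   `rank_diagnostics` (per rank: cophenetic, silhouette, and the
#'   randomized baselines).
#' @export
extract_signatures <- function(matrix, ranks = 2:12, n_runs = 100,
                               n_randomized_runs = 100, seed = 1,
                               max_iter = 1000, tol = 1e-8,
                               coph_min = 0.95, sil_min = 0.8) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  V <- matrix$counts
  if (all(V == 0)) stop("all-zero feature matrix")
  n <- ncol(V)
  usable <- ranks[ranks < n]
  if (length(usable) < length(ranks)) {
    warning("skipping rank(s) >= number of samples: ",
            paste(setdiff(ranks, usable), collapse = ", "))
  }
  if (length(usable) == 0) stop("no usable ranks below the sample count")
  diag_rows <- vector("list", length(usable))
  best_fits <- vector("list", length(usable))
  for (ri in seq_along(usable)) {
    k <- usable[ri]
    memberships <- vector("list", n_runs)
    best <- NULL
    for (run in seq_len(n_runs)) {
      set.seed(seed + 7919L * k + run)
      fit <- nmf_kl(V, k, max_iter = max_iter, tol = tol)
      memberships[[run]] <- apply(fit$H, 2, which.max)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    dg <- consensus_diagnostics(memberships, k)
    rnd_memberships <- vector("list", n_randomized_runs)
    for (run in seq_len(n_randomized_runs)) {
      set.seed(seed + 104729L * k + run)
      Vr <- permute_rows(V)
      fit <- nmf_kl(Vr, k, max_iter = max_iter, tol = tol)
      rnd_memberships[[run]] <- apply(fit$H, 2, which.max)
    }
    rdg <- consensus_diagnostics(rnd_memberships, k)
    diag_rows[[ri]] <- data.frame(
      rank = k, cophenetic = dg$cophenetic, silhouette = dg$silhouette,
      rand_cophenetic = rdg$cophenetic, rand_silhouette = rdg$silhouette)
    best_fits[[ri]] <- best
  }
  diagnostics <- do.call(rbind, diag_rows)
  ok <- diagnostics$cophenetic >= coph_min & diagnostics$silhouette >= sil_min &
    diagnostics$cophenetic > diagnostics$rand_cophenetic &
    diagnostics$silhouette > diagnostics$rand_silhouette
  chosen <- if (any(ok)) max(diagnostics$rank[ok]) else
    diagnostics$rank[which.max(diagnostics$cophenetic)]
  fit <- best_fits[[match(chosen, usable)]]
  scale <- colSums(fit$W)
  W <- sweep(fit$W, 2, scale, "/")
  H <- sweep(fit$H, 1, scale, "*")
  colnames(W) <- paste0("S", seq_len(chosen))
  rownames(W) <- rownames(V)
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(V)
  structure(list(scheme = matrix$scheme, W = W, H = H, chosen_rank = chosen,
                 rank_diagnostics = diagnostics,
                 objective_trace = fit$trace),
            class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat("SignatureModel (", x$scheme, "): rank ", x$chosen_rank, "\n", sep = "")
  print(x$rank_diagnostics, row.names = FALSE)
  invisible(x)
}

#' Match extracted signatures to a reference set by cosine similarity
#'
#' @param model a `SignatureModel`, or a categories x K matrix.
#' @param reference categories x R reference matrix with identical row
#'   (category) order; column names are the reference signature ids.
#' @param novel_below matches with best cosine below this value are
#'   labelled `"novel"` (default 0.85).
#' @return data.frame: `signature`, `best_match`, `cosine`.
#' @export
match_to_reference <- function(model, reference, novel_below = 0.85) {
  W <- if (inherits(model, "SignatureModel")) model$W else as.matrix(model)
  reference <- as.matrix(reference)
  if (nrow(W) != nrow(reference)) {
    stop("scheme mismatch: ", nrow(W), " vs ", nrow(reference), " categories")
  }
  if (!is.null(rownames(W)) && !is.null(rownames(reference)) &&
      !identical(rownames(W), rownames(reference))) {
    stop("scheme mismatch: category labels differ or are ordered differently")
  }
  out <- do.call(rbind, lapply(seq_len(ncol(W)), function(j) {
    sims <- apply(reference, 2, cosine_similarity, a = W[, j])
    i <- which.max(sims)
    data.frame(signature = colnames(W)[j] %||% paste0("S", j),
               best_match = if (sims[i] < novel_below) "novel" else
                 colnames(reference)[i] %||% paste0("R", i),
               cosine = unname(sims[i]))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refit per-sample signature exposures
#'
#' The sample catalog is normalized to proportions and fitted on the
#' signature matrix by non-negative least squares. Signatures whose fitted
#' proportion falls below `threshold` are zeroed; if `max_signatures` is
#' finite only the largest `max_signatures` retained proportions are kept.
#' The zeroed weight plus the fit residual is reported as unassigned;
#' retained weights are not re-inflated. Samples with no more than
#' `min_mutations` mutations are entirely unassigned.
#'
#' @param catalog_column named non-negative numeric vector of category
#'   counts for one sample.
#' @param W categories x K signature matrix, columns summing to 1.
#' @param threshold minimum proportion for assignment (default 0.15).
#' @param min_mutations assignment requires strictly more mutations than
#'   this (default 50).
#' @param max_signatures maximum number of signatures assigned per sample
#'   (default unlimited).
#' @return named list with `exposures` (length-K named vector) and
#'   `unassigned`; exposures plus unassigned sum to 1.
#' @export
refit_exposures <- function(catalog_column, W, threshold = 0.15,
                            min_mutations = 50, max_signatures = Inf) {
  W <- as.matrix(W)
  if (ncol(W) == 0 || nrow(W) == 0) stop("empty signature matrix")
  k <- ncol(W)
  sig_names <- colnames(W) %||% paste0("S", seq_len(k))
  zero <- stats::setNames(numeric(k), sig_names)
  total <- sum(catalog_column)
  if (total <= min_mutations) {
    return(list(exposures = zero, unassigned = 1))
  }
  v <- as.numeric(catalog_column) / total
  p <- pracma::lsqnonneg(W, v)$x
  # the fitted mass may exceed 1 slightly when the catalog lies outside the
  # simplex hull of the signatures; deflate so proportions stay in [0, 1]
  if (sum(p) > 1) p <- p / sum(p)
  p[p < threshold] <- 0
  if (is.finite(max_signatures) && sum(p > 0) > max_signatures) {
    keep <- order(p, decreasing = TRUE)[seq_len(max_signatures)]
    p[-keep] <- 0
  }
  exposures <- stats::setNames(p, sig_names)
  list(exposures = exposures, unassigned = 1 - sum(p))
}
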