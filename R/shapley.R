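# Shapley-value attribution: exact enumeration over feature coalitions for
# small p, Monte-Carlo permutation sampling otherwise. The value function
# val(k) is the interventional mean: features in the coalition take the
# explained sample's values, the rest are drawn from a background set, and
# the model output is averaged over the background rows.

coalition_value_fn <- function(model_fn, x, background) {
  x <- as.numeric(x)
  p <- length(x)
  stopifnot(ncol(background) == p, nrow(background) >= 1)
  B <- as.matrix(background)
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(members) {           # members: integer vector of feature indices
    key <- paste0("k", paste(members, collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
    M <- B
    if (length(members)) M[, members] <- matrix(x[members], nrow(B),
                                                length(members), byrow = TRUE)
    v <- mean(model_fn(M))
    cache[[key]] <- v
    v
  }
}

#' Exact Shapley attributions for one sample
#'
#' Enumerates all `2^p` feature coalitions and combines marginal
#' contributions with the Shapley weights `|k|! (p-|k|-1)! / p!`. The
#' attributions satisfy efficiency: they sum, together with the base value
#' (mean model output over the background), to the model output at `x`.
#'
#' @param model_fn function taking a numeric matrix (rows = samples) and
#'   returning one score per row.
#' @param x numeric vector, the sample to explain.
#' @param background numeric matrix of background samples (same columns).
#' @return Numeric attribution vector (named like `x` if it has names), with
#'   attribute `base_value`.
#' @examples
#' f <- function(M) M %*% c(2, -1)
#' bg <- matrix(0, 5, 2)
#' shapley_exact(f, c(1, 3), bg)   # 2*1 and -1*3
#' @export
shapley_exact <- function(model_fn, x, background) {
  p <- length(x)
  if (p > 15)
    stop("exact enumeration is limited to p <= 15 features; ",
         "use shapley_sampled()", call. = FALSE)
  val <- coalition_value_fn(model_fn, x, background)
  phi <- numeric(p)
  wt <- factorial(0:(p - 1)) * factorial(p - 1 - 0:(p - 1)) / factorial(p)
  for (mask in 0:(2^p - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    v <- val(members)
    sz <- length(members)
    for (i in setdiff(seq_len(p), members)) {
      phi[i] <- phi[i] + wt[sz + 1] * (val(sort(c(members, i))) - v)
    }
  }
  names(phi) <- names(x)
  attr(phi, "base_value") <- val(integer(0))
  phi
}

all_permutations <- function(p) {
  if (p == 1) return(list(1L))
  out <- list()
  for (perm in all_permutations(p - 1))
    for (pos in 0:(p - 1))
      out[[length(out) + 1L]] <- append(perm, p, after = pos)
  out
}

#' Monte-Carlo (permutation) Shapley attributions for one sample
#'
#' Averages marginal contributions over feature orderings. When `n_perm` is
#' at least `p!` (and `p <= 8`) the distinct orderings are enumerated and
#' cycled deterministically, so the estimate equals [shapley_exact()];
#' otherwise orderings are sampled from the given seed. Coalition values are
#' full background means, so the only Monte-Carlo error is over orderings.
#'
#' @inheritParams shapley_exact
#' @param n_perm number of orderings.
#' @param seed integer seed.
#' @return Numeric attribution vector with attribute `base_value`.
#' @export
shapley_sampled <- function(model_fn, x, background, n_perm = 200, seed = 1) {
  stopifnot(n_perm >= 1)
  p <- length(x)
  val <- coalition_value_fn(model_fn, x, background)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  if (p <= 8 && n_perm >= factorial(p)) {
    perms <- rep(all_permutations(p), length.out = n_perm)
  } else {
    perms <- lapply(seq_len(n_perm), function(i) sample.int(p))
  }
  phi <- numeric(p)
  for (perm in perms) {
    prev <- integer(0)
    v_prev <- val(prev)
    for (i in perm) {
      cur <- sort(c(prev, i))
      v_cur <- val(cur)
      phi[i] <- phi[i] + (v_cur - v_prev)
      prev <- cur
      v_prev <- v_cur
    }
  }
  phi <- phi / length(perms)
  names(phi) <- names(x)
  attr(phi, "base_value") <- val(integer(0))
  phi
}

#' Shapley attributions for a set of samples
#'
#' @param model_fn score function over a feature matrix.
#' @param X samples to explain (matrix, named columns).
#' @param background background matrix (defaults to `X` itself).
#' @param exact force exact (`TRUE`) or sampled (`FALSE`) mode; default
#'   exact when `p <= 15`.
#' @param n_perm,seed passed to [shapley_sampled()].
#' @return A `shap_result`: `phi` (samples x features), `base_value`,
#'   `feature_names`, `X` (the feature values, kept for dependence exports).
#' @export
shap_values <- function(model_fn, X, background = X,
                        exact = ncol(X) <= 15, n_perm = 200, seed = 1) {
  X <- as.matrix(X)
  one <- function(i) {
    if (exact) shapley_exact(model_fn, X[i, ], background)
    else shapley_sampled(model_fn, X[i, ], background, n_perm = n_perm,
                         seed = seed + i)
  }
  rows <- lapply(seq_len(nrow(X)), one)
  phi <- do.call(rbind, rows)
  rownames(phi) <- rownames(X)
  colnames(phi) <- colnames(X)
  structure(list(phi = phi, base_value = attr(rows[[1]], "base_value"),
                 feature_names = colnames(X), X = X),
            class = "shap_result")
}

#' Rank features by mean absolute Shapley value
#'
#' @param res a [shap_values()] result.
#' @param top_n how many features to report (default 20; truncated to `p`
#'   with a warning if larger).
#' @return List with `ranking` (data frame: feature, mean_abs_shap) and
#'   `dependence` (per-feature data frames of (value, phi) pairs for
#'   dependence plotting).
#' @export
shap_summary <- function(res, top_n = 20) {
  stopifnot(inherits(res, "shap_result"), nrow(res$phi) >= 1)
  p <- ncol(res$phi)
  if (top_n > p) {
    warning("top_n exceeds the number of features; truncated")
    top_n <- p
  }
  mabs <- colMeans(abs(res$phi))
  ord <- order(-mabs, seq_along(mabs))[seq_len(top_n)]
  ranking <- data.frame(feature = colnames(res$phi)[ord],
                        mean_abs_shap = unname(mabs[ord]))
  dependence <- lapply(ord, function(j)
    data.frame(value = res$X[, j], phi = res$phi[, j]))
  names(dependence) <- colnames(res$phi)[ord]
  list(ranking = ranking, dependence = dependence)
}

#' Write a shap_result as TSV plus a JSON summary
#'
#' @param res a [shap_values()] result.
#' @param path TSV path for the per-sample attribution matrix; the top-n
#'   ranking goes to `<path>.json`.
#' @param top_n ranking length for the summary.
#' @return `path`, invisibly.
#' @export
write_shap <- function(res, path, top_n = 20) {
  utils::write.table(data.frame(id = rownames(res$phi), res$phi,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- shap_summary(res, top_n = min(top_n, ncol(res$phi)))
  jsonlite::write_json(list(base_value = res$base_value,
                            top = sm$ranking),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
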