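#' Fit a non-negative matrix factorization topic model
#'
#' Factorizes the TF-IDF matrix `R` (documents x lemmas) as `R ~ W %*% H`
#' with non-negative factors, minimizing the half-squared Frobenius error
#' `0.5 * sum((R - W H)^2)`. `W` is documents x topics, `H` topics x
#' lemmas. The solver is alternating nonnegative least squares in HALS
#' form: each topic's column of `W` (row of `H`) is updated exactly given
#' the others, so the objective never increases across sweeps.
#'
#' Initialization defaults to NNDSVD-ar (non-negative double SVD with
#' seeded random fill of zero entries), which makes fits reproducible for
#' a fixed seed; `init = "random"` draws uniform factors scaled to the
#' data instead.
#'
#' @param R A `term_matrix` from [build_tfidf()], or a plain non-negative
#'   matrix.
#' @param k Number of topics; `2 <= k <= min(n, m)` (k = 1 is allowed for
#'   degenerate rank-1 checks).
#' @param seed Integer seed controlling initialization.
#' @param max_iter Maximum HALS sweeps.
#' @param tol Relative decrease of the objective below which iteration
#'   stops.
#' @param init `"nndsvdar"` (default) or `"random"`.
#' @return An object of class `nmf_model`: list with `W`, `H`, `k`,
#'   `objective`, `objective_trace`, `n_iter`, `converged`, `seed`,
#'   `row_ids`, `lemmas`.
#' @examples
#' R <- outer(c(1, 2, 3), c(2, 1, 0, 1))
#' fit <- fit_nmf(R, k = 1)
#' fit$objective  # ~ 0: exact rank-1 input
#' @export
fit_nmf <- function(R, k, seed = 42L, max_iter = 200L, tol = 1e-6,
                    init = c("nndsvdar", "random")) {
  init <- match.arg(init)
  dense <- as_dense_matrix(R)
  n <- nrow(dense); m <- ncol(dense)
  if (k > min(n, m)) {
    stop("k = ", k, " exceeds min(n, m) = ", min(n, m), call. = FALSE)
  }
  if (k < 1) stop("k must be a positive integer", call. = FALSE)
  if (any(dense < 0)) stop("R must be non-negative", call. = FALSE)

  st <- init_factors(dense, k, seed = seed, method = init)
  res <- cpp_nmf_hals(dense, st$W, st$H, as.integer(max_iter), tol)
  if (!res$converged) {
    warning("NMF did not reach tol within ", max_iter, " iterations",
            call. = FALSE)
  }
  structure(
    list(W = res$W, H = res$H, k = as.integer(k),
         objective = res$objective,
         objective_trace = res$objective_trace,
         n_iter = res$n_iter, converged = res$converged,
         seed = as.integer(seed), init = init,
         row_ids = rownames(dense) %||% sprintf("doc%05d", seq_len(n)),
         lemmas = colnames(dense) %||% sprintf("lemma%05d", seq_len(m))),
    class = "nmf_model"
  )
}

as_dense_matrix <- function(R) {
  if (inherits(R, "term_matrix")) {
    out <- as.matrix(R$values)
  } else if (inherits(R, "Matrix")) {
    out <- as.matrix(R)
  } else {
    out <- as.matrix(R)
  }
  storage.mode(out) <- "double"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NNDSVD(-ar): initialize factors from the leading k singular triplets,
# splitting each into positive and negative parts; "ar" fills structural
# zeros with small seeded uniforms (mean(R)/100) to avoid locked zeros.
init_factors <- function(R, k, seed, method) {
  n <- nrow(R); m <- ncol(R)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))

  if (method == "random") {
    scale <- sqrt(mean(R) / k)
    W <- matrix(stats::runif(n * k), n, k) * scale
    H <- matrix(stats::runif(k * m), k, m) * scale
    return(list(W = W, H = H))
  }

  sv <- svd(R, nu = k, nv = k)
  W <- matrix(0, n, k); H <- matrix(0, k, m)
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      npos <- sqrt(sum(up^2)) * sqrt(sum(vp^2))
      nneg <- sqrt(sum(un^2)) * sqrt(sum(vn^2))
      if (npos >= nneg && npos > 0) {
        scal <- sqrt(sv$d[j] * npos)
        W[, j] <- scal * up / sqrt(sum(up^2))
        H[j, ] <- scal * vp / sqrt(sum(vp^2))
      } else if (nneg > 0) {
        scal <- sqrt(sv$d[j] * nneg)
        W[, j] <- scal * un / sqrt(sum(un^2))
        H[j, ] <- scal * vn / sqrt(sum(vn^2))
      }
    }
  }
  fill <- mean(R) / 100
  zw <- W == 0; zh <- H == 0
  W[zw] <- stats::runif(sum(zw), 0, fill)
  H[zh] <- stats::runif(sum(zh), 0, fill)
  list(W = W, H = H)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @exportS3Method base::print
print.nmf_model <- function(x, ...) {
  cat("<nmf_model> k = ", x$k, ", ", nrow(x$W), " documents x ",
      ncol(x$H), " lemmas\n", sep = "")
  cat("  objective = ", format(x$objective, digits = 6),
      " after ", x$n_iter, " sweeps",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  invisible(x)
}

#' Tidy an NMF model into a long topic-term tibble
#'
#' @param x An `nmf_model`.
#' @param matrix Which factor to tidy: `"H"` (topic-term weights, default)
#'   or `"W"` (document-topic weights).
#' @param ... Unused.
#' @return A tibble in long form: for `"H"`, columns `topic_id`, `lemma`,
#'   `weight`; for `"W"`, columns `doc_id`, `topic_id`, `weight`.
#' @export
tidy.nmf_model <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "H") {
    tibble::tibble(
      topic_id = rep(seq_len(x$k) - 1L, times = ncol(x$H)),
      lemma = rep(x$lemmas, each = x$k),
      weight = as.vector(x$H)
    )
  } else {
    tibble::tibble(
      doc_id = rep(x$row_ids, times = x$k),
      topic_id = rep(seq_len(x$k) - 1L, each = nrow(x$W)),
      weight = as.vector(x$W)
    )
  }
}

#' One-row fit summary of an NMF model
#'
#' @param x An `nmf_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `objective`, `n_iter`, `converged`, `seed`.
#' @export
glance.nmf_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, objective = x$objective, n_iter = x$n_iter,
    converged = x$converged, seed = x$seed
  )
}

#' Export NMF factors as MTX files plus JSON metadata
#'
#' Writes `<stem>-W.mtx`, `<stem>-H.mtx` and `<stem>-meta.json`
#' (`k`, `seed`, `objective`, `n_iter`).
#'
#' @param model An `nmf_model`.
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_nmf_model <- function(model, stem) {
  Matrix::writeMM(Matrix::Matrix(model$W, sparse = TRUE),
                  paste0(stem, "-W.mtx"))
  Matrix::writeMM(Matrix::Matrix(model$H, sparse = TRUE),
                  paste0(stem, "-H.mtx"))
  jsonlite::write_json(
    list(k = model$k, seed = model$seed, objective = model$objective,
         n_iter = model$n_iter),
    paste0(stem, "-meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
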