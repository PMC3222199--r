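#' Nonlinear principal component analysis with optimal scaling
#'
#' Fits a principal component model to mixed nominal/ordinal/numeric data by
#' alternating least squares: category quantifications and per-respondent
#' object scores are updated in turn until a normalized loss converges.
#' Nominal categories are quantified through the centroid principle, ordinal
#' categories through weighted monotone regression (order-preserving), and
#' numeric variables are standardized. On convergence the solution is rotated
#' to its principal axes, so component loadings are the linear correlations
#' between dimensions and optimally scaled variables, and eigenvalues are
#' those of the correlation matrix of the transformed columns. With
#' all-numeric input the fit coincides with classical PCA of the z-scored
#' data.
#'
#' The normalization is variable-principal: each transformed column has zero
#' mean and unit variance, object scores `X` satisfy `colMeans(X) = 0` and
#' `crossprod(X) = N * I`, and `lambda[d] = sum(loadings[, d]^2)`.
#'
#' @param data A data frame; variables may be factors (nominal), ordered
#'   factors (ordinal) or numeric columns. A schema attached by
#'   [as_cohort()] supplies measurement levels where available.
#' @param vars Character vector of columns to analyse; default all columns
#'   except `row_id`.
#' @param ndim Number of dimensions to extract (1 <= `ndim` <= number of
#'   variables).
#' @param levels Optional named character vector overriding measurement
#'   levels (`"nominal"`, `"ordinal"`, `"numeric"`).
#' @param dim_names Optional character vector of length `ndim` naming the
#'   extracted dimensions (e.g. `c("stress", "control")`).
#' @param tol Relative loss-change convergence tolerance (default `1e-6`).
#' @param max_iter Maximum ALS sweeps (default 500).
#' @return An object of class `princals_fit`: a list with elements
#'   `scores` (tibble, one row per respondent), `loadings` (m x ndim matrix),
#'   `quantifications` (tibble: variable, category, frequency,
#'   quantification), `transformed` (tibble of optimally scaled columns),
#'   `eigenvalues`, `vaf_per_dim`, `vaf_total`, `alpha_total`,
#'   `alpha_per_dim`, `loss_trace`, `converged`, `n_iter`, `levels`.
#' @seealso [monotone_regression()], [quantify_nominal()],
#'   [cronbach_alpha()], [classify_loadings()]
#' @export
fit_princals <- function(data, vars = NULL, ndim = 2, levels = NULL,
                         dim_names = NULL, tol = 1e-6, max_iter = 500) {
  schema <- cohort_schema_of(data)
  if (is.null(vars)) vars <- setdiff(names(data), "row_id")
  missing_v <- setdiff(vars, names(data))
  if (length(missing_v) > 0) {
    rlang::abort(paste0("column(s) not found: ", paste(missing_v, collapse = ", ")))
  }
  m <- length(vars)
  if (ndim < 1 || ndim > m) rlang::abort("ndim must be between 1 and the number of variables")
  n <- nrow(data)
  if (is.null(dim_names)) dim_names <- paste0("dim", seq_len(ndim))
  if (length(dim_names) != ndim) rlang::abort("dim_names must have length ndim")

  # resolve measurement level per variable
  var_level <- purrr::map_chr(vars, function(v) {
    if (!is.null(levels) && v %in% names(levels)) return(levels[[v]])
    if (!is.null(schema) && v %in% schema$name) {
      return(schema$level[schema$name == v])
    }
    col <- data[[v]]
    if (is.ordered(col)) "ordinal"
    else if (is.factor(col) || is.character(col)) "nominal"
    else "numeric"
  })
  names(var_level) <- vars

  # per-variable preprocessing: codes, counts, fixed numeric transforms
  g <- vector("list", m); d <- vector("list", m); cat_labels <- vector("list", m)
  qlist <- vector("list", m)
  Tq <- matrix(0, n, m, dimnames = list(NULL, vars))
  for (j in seq_len(m)) {
    col <- data[[vars[j]]]
    if (anyNA(col)) {
      rlang::abort(paste0("variable '", vars[j], "' contains missing values; ",
                          "apply exclusions first"))
    }
    if (var_level[j] == "numeric") {
      x <- as.double(col)
      mu <- mean(x); s <- sqrt(sum((x - mu)^2) / n)
      if (s == 0) rlang::abort(paste0("degenerate variable '", vars[j],
                                      "': zero spread"))
      Tq[, j] <- (x - mu) / s
    } else {
      f <- if (is.factor(col)) droplevels(col) else factor(col)
      if (nlevels(f) < 2) {
        rlang::abort(paste0("degenerate variable '", vars[j],
                            "': fewer than 2 observed categories"))
      }
      g[[j]] <- as.integer(f)
      d[[j]] <- tabulate(g[[j]], nlevels(f))
      cat_labels[[j]] <- levels(f)
      # initial quantification: centered, unit-variance integer coding
      q0 <- seq_len(nlevels(f))
      q0 <- q0 - sum(d[[j]] * q0) / n
      q0 <- q0 * sqrt(n / sum(d[[j]] * q0^2))
      qlist[[j]] <- q0
      Tq[, j] <- q0[g[[j]]]
    }
  }
  is_cat <- !purrr::map_lgl(g, is.null)

  # deterministic initialization: principal scores of the integer-coded data
  X <- ht_orthonormalize(Tq, ndim,
                         error_msg = paste0("cannot support ", ndim, " dimensions"))
  A <- crossprod(Tq, X) / n

  loss_trace <- numeric(0)
  loss_prev <- Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # quantification + loading update, one variable at a time
    for (j in which(is_cat)) {
      a <- A[j, ]
      ssa <- sum(a^2)
      if (ssa < 1e-12) a <- rep(1 / sqrt(ndim), ndim)
      centroids <- rowsum(X, g[[j]]) / d[[j]]
      u <- as.vector(centroids %*% a) / max(sum(a^2), 1e-12)
      q <- if (var_level[j] == "ordinal") monotone_regression(u, d[[j]]) else u
      q <- q - sum(d[[j]] * q) / n
      ss <- sum(d[[j]] * q^2)
      if (ss > 1e-14) {
        q <- q * sqrt(n / ss)
        qlist[[j]] <- q
        Tq[, j] <- q[g[[j]]]
      }
      A[j, ] <- crossprod(Tq[, j], X) / n
    }
    A <- crossprod(Tq, X) / n
    # object score update: orthonormalized least-squares target
    X <- ht_orthonormalize(Tq %*% A, ndim,
                           error_msg = paste0("cannot support ", ndim, " dimensions"))
    cross <- crossprod(Tq, X) / n
    loss <- ndim - (2 / m) * sum(A * cross) + sum(A^2) / m
    loss_trace <- c(loss_trace, loss)
    if (is.finite(loss_prev) &&
        abs(loss_prev - loss) < tol * max(1, abs(loss_prev))) {
      converged <- TRUE
      break
    }
    loss_prev <- loss
  }

  # rotate to principal axes of the transformed columns
  R <- crossprod(Tq) / n
  ee <- eigen(R, symmetric = TRUE)
  lambda <- ee$values[seq_len(ndim)]
  if (any(lambda < 1e-10)) {
    rlang::abort(paste0("cannot support ", ndim, " dimensions: transformed ",
                        "data have rank below ndim"))
  }
  V <- ee$vectors[, seq_len(ndim), drop = FALSE]
  X <- sweep(Tq %*% V, 2, sqrt(lambda), "/")
  A <- sweep(V, 2, sqrt(lambda), "*")
  # sign convention: the largest-|loading| variable loads positively
  for (dd in seq_len(ndim)) {
    jmax <- which.max(abs(A[, dd]))
    if (A[jmax, dd] < 0) {
      A[, dd] <- -A[, dd]
      X[, dd] <- -X[, dd]
    }
  }
  dimnames(A) <- list(vars, dim_names)
  colnames(X) <- dim_names

  quants <- purrr::map_dfr(which(is_cat), function(j) {
    tibble::tibble(variable = vars[j], level = var_level[j],
                   category = cat_labels[[j]], frequency = d[[j]],
                   quantification = qlist[[j]])
  })

  vaf_per_dim <- 100 * lambda / m
  alpha_per_dim <- purrr::map_dbl(lambda, function(l) {
    if (l > 0 && m >= 2) cronbach_alpha(l, m) else NA_real_
  })
  scores <- tibble::as_tibble(X)
  if ("row_id" %in% names(data)) scores <- dplyr::bind_cols(
    tibble::tibble(row_id = data$row_id), scores)

  structure(list(
    scores = scores,
    loadings = A,
    quantifications = quants,
    transformed = tibble::as_tibble(Tq),
    eigenvalues = lambda,
    vaf_per_dim = vaf_per_dim,
    vaf_total = sum(vaf_per_dim),
    alpha_total = if (m >= 2) cronbach_alpha(sum(lambda), m) else NA_real_,
    alpha_per_dim = alpha_per_dim,
    loss_trace = loss_trace,
    converged = converged,
    n_iter = iter,
    levels = var_level,
    ndim = ndim,
    n = n
  ), class = "princals_fit")
}

# symmetric orthonormalization: column-center M, return sqrt(N) * U V' of its
# thin SVD restricted to ndim columns
ht_orthonormalize <- function(M, ndim, error_msg = "rank deficiency") {
  n <- nrow(M)
  M <- sweep(M, 2, colMeans(M))
  sv <- svd(M, nu = ndim, nv = ndim)
  if (length(sv$d) < ndim || sv$d[ndim] < 1e-10 * max(sv$d[1], 1e-300)) {
    rlang::abort(error_msg)
  }
  sqrt(n) * sv$u %*% t(sv$v)
}

#' Centroid quantification of a nominal variable
#'
#' Applies the centroid principle: each category of a nominal variable is
#' quantified, per dimension, by the mean object score of the respondents in
#' that category.
#'
#' @param assignments Factor or character vector, one category per respondent.
#' @param scores Numeric matrix or data frame of object scores (respondents
#'   by dimensions).
#' @return A tibble with `category`, `frequency` and one column per
#'   dimension.
#' @export
quantify_nominal <- function(assignments, scores) {
  f <- if (is.factor(assignments)) assignments else factor(assignments)
  X <- as.matrix(scores)
  if (nrow(X) != length(f)) rlang::abort("assignments and scores differ in length")
  counts <- tabulate(as.integer(f), nlevels(f))
  if (any(counts == 0)) {
    rlang::abort(paste0("empty category: ",
                        paste(levels(f)[counts == 0], collapse = ", ")))
  }
  centroids <- rowsum(X, f) / counts
  if (is.null(colnames(centroids))) {
    colnames(centroids) <- paste0("dim", seq_len(ncol(centroids)))
  }
  out <- tibble::tibble(category = levels(f), frequency = counts)
  dplyr::bind_cols(out, tibble::as_tibble(centroids))
}

#' Recompute object scores from quantified columns
#'
#' One half-step of the alternating least squares cycle: given the optimally
#' scaled data, object scores are recomputed as the (orthonormalized)
#' least-squares update, so that `colMeans(X) = 0` and
#' `crossprod(X) = N * I`. With one dimension and unit loadings, this is the
#' normalized, centered row mean of the quantified columns.
#'
#' @param transformed Numeric matrix or data frame of quantified columns
#'   (respondents by variables).
#' @param loadings Optional m x ndim loading matrix; defaults to all ones.
#' @param ndim Number of dimensions (default 1 when `loadings` is missing).
#' @return An N x ndim matrix of object scores.
#' @export
update_object_scores <- function(transformed, loadings = NULL, ndim = NULL) {
  Tq <- as.matrix(transformed)
  if (is.null(loadings)) {
    if (is.null(ndim)) ndim <- 1
    if (ndim > 1) {
      rlang::abort("supply a loading matrix when requesting more than one dimension")
    }
    loadings <- matrix(1, ncol(Tq), ndim)
  } else {
    loadings <- as.matrix(loadings)
    ndim <- ncol(loadings)
  }
  if (nrow(loadings) != ncol(Tq)) {
    rlang::abort("loadings must have one row per quantified column")
  }
  ht_orthonormalize(Tq %*% loadings / ncol(Tq), ndim,
                    error_msg = paste0("cannot support ", ndim, " dimensions"))
}

#' Cronbach alpha from an eigenvalue sum
#'
#' Internal-consistency coefficient computed from the eigenvalue(s) of the
#' correlation matrix of m (optimally scaled) variables:
#' `alpha = m * (lambda - 1) / ((m - 1) * lambda)`. With `lambda` equal to
#' the sum of the extracted eigenvalues this is the total alpha of a
#' multi-dimensional solution; with a single eigenvalue it is the per-
#' dimension alpha.
#'
#' @param lambda Eigenvalue (or eigenvalue sum), > 0.
#' @param m Number of variables, >= 2.
#' @return The alpha coefficient (unitless; 0 when `lambda = 1`).
#' @examples
#' cronbach_alpha(4 * 0.842, 4)  # 0.937
#' cronbach_alpha(9 * 0.701, 9)  # 0.947
#' @export
cronbach_alpha <- function(lambda, m) {
  if (!is.numeric(lambda) || any(lambda <= 0)) rlang::abort("lambda must be > 0")
  if (m < 2) rlang::abort("m must be at least 2")
  m * (lambda - 1) / ((m - 1) * lambda)
}

#' Classical (covariance-based) Cronbach alpha
#'
#' `alpha = m/(m-1) * (1 - sum of item variances / variance of the item
#' sum)`. Used to report the internal consistency of a subset of transformed
#' items with or without their indicator included as an extra column.
#'
#' @param x Numeric matrix or data frame of items (respondents by items).
#' @return The alpha coefficient.
#' @export
cronbach_alpha_classical <- function(x) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (m < 2) rlang::abort("need at least 2 items")
  item_var <- sum(apply(x, 2, var))
  total_var <- var(rowSums(x))
  if (total_var == 0) rlang::abort("zero variance of the item sum")
  m / (m - 1) * (1 - item_var / total_var)
}

#' Flag essential component loadings
#'
#' Distinguishes essential (|loading| at or above the threshold) from
#' negligible loadings, the rule used to read meaning into extracted
#' dimensions. The conventional threshold is 0.4; a loading exactly at the
#' threshold counts as essential.
#'
#' @param loadings Loading matrix (variables by dimensions) or a
#'   `princals_fit`.
#' @param threshold Absolute cutoff in (0, 1); default 0.4.
#' @return A tibble with `variable`, `dimension`, `loading`, `essential`.
#' @export
classify_loadings <- function(loadings, threshold = 0.4) {
  if (inherits(loadings, "princals_fit")) loadings <- loadings$loadings
  if (threshold <= 0 || threshold >= 1) rlang::abort("threshold must be in (0, 1)")
  A <- as.matrix(loadings)
  if (is.null(rownames(A))) rownames(A) <- paste0("v", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- paste0("dim", seq_len(ncol(A)))
  tibble::tibble(
    variable = rep(rownames(A), times = ncol(A)),
    dimension = rep(colnames(A), each = nrow(A)),
    loading = as.vector(A),
    essential = abs(as.vector(A)) >= threshold
  )
}
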