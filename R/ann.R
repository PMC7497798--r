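# One-hidden-layer feed-forward classifier.
#
#   output = logistic( w2' tanh(W1 x + b1) + b2 )
#
# trained against {0,1} labels by minimizing the regularized objective
#   F = beta * Ed + alpha * Ew,   Ed = 1/2 sum e^2,  Ew = 1/2 sum w^2
# with full-batch Levenberg-Marquardt steps. In Bayesian-regularization
# mode alpha and beta are re-estimated each accepted step by MacKay's
# evidence approximation:
#   gamma = Nw - alpha * tr(H^-1),  H = beta J'J + alpha I
#   alpha = gamma / (2 Ew),         beta = (n - gamma) / (2 Ed)
# where gamma is the effective number of parameters. A fixed-penalty mode
# (constant alpha, beta = 1) is available for reproducibility studies.

MODEL_VERSION <- "1"

#' Initialize a feed-forward network
#'
#' Weights are drawn uniformly in `+- 1/sqrt(n_inputs)` (hidden layer) and
#' `+- 1/sqrt(n_hidden)` (output layer); deterministic under `seed`.
#'
#' @param n_inputs input dimension (7 for FBM features, 256 for DBM).
#' @param n_hidden hidden-layer size.
#' @param seed RNG seed.
#' @return object of class `flim_ann`.
#' @export
init_network <- function(n_inputs, n_hidden = 10, seed = 1L) {
  if (n_inputs < 1 || n_hidden < 1) stop_value("n_inputs and n_hidden must be >= 1")
  withr::with_seed(seed, {
    s1 <- 1 / sqrt(n_inputs)
    s2 <- 1 / sqrt(n_hidden)
    net <- list(
      n_inputs = as.integer(n_inputs), n_hidden = as.integer(n_hidden),
      W1 = matrix(stats::runif(n_hidden * n_inputs, -s1, s1), n_hidden, n_inputs),
      b1 = stats::runif(n_hidden, -s1, s1),
      w2 = stats::runif(n_hidden, -s2, s2),
      b2 = stats::runif(1, -s2, s2),
      stats = NULL, mode = NULL, version = MODEL_VERSION)
  })
  structure(net, class = "flim_ann")
}

#' @export
print.flim_ann <- function(x, ...) {
  cat(sprintf("<flim_ann> %d-%d-1 (tanh / logistic)%s\n",
              x$n_inputs, x$n_hidden,
              if (!is.null(x$mode)) paste0(", mode ", x$mode) else ""))
  invisible(x)
}

n_weights <- function(net) {
  net$n_hidden * net$n_inputs + net$n_hidden + net$n_hidden + 1L
}

weights_to_vec <- function(net) {
  c(as.vector(net$W1), net$b1, net$w2, net$b2)
}

vec_to_weights <- function(net, w) {
  h <- net$n_hidden; d <- net$n_inputs
  net$W1 <- matrix(w[seq_len(h * d)], h, d)
  net$b1 <- w[h * d + seq_len(h)]
  net$w2 <- w[h * d + h + seq_len(h)]
  net$b2 <- w[h * d + 2 * h + 1]
  net
}

forward_pass <- function(net, X) {
  Z <- tanh(X %*% t(net$W1) + matrix(net$b1, nrow(X), net$n_hidden, byrow = TRUE))
  o <- stats::plogis(as.vector(Z %*% net$w2) + net$b2)
  list(Z = Z, o = o)
}

# Jacobian of the output wrt all weights, rows = samples.
# Column order matches weights_to_vec: W1 (column-major), b1, w2, b2.
output_jacobian <- function(net, X, Z, o) {
  n <- nrow(X); h <- net$n_hidden; d <- net$n_inputs
  so <- o * (1 - o)                       # logistic derivative
  dz <- (1 - Z^2) * matrix(net$w2, n, h, byrow = TRUE)  # n x h
  J <- matrix(0, n, h * d + 2 * h + 1)
  for (k in seq_len(d)) {
    J[, (k - 1) * h + seq_len(h)] <- so * dz * X[, k]
  }
  J[, h * d + seq_len(h)] <- so * dz
  J[, h * d + h + seq_len(h)] <- so * Z
  J[, h * d + 2 * h + 1] <- so
  J
}

#' Predict microglia scores
#'
#' Pure forward pass; when the network carries normalization statistics
#' (attached by [train_network()]) they are applied to the raw features
#' first, so prediction uses exactly the training-time scaling.
#'
#' @param object a `flim_ann` or `flim_ann_fit`.
#' @param features numeric matrix (rows = instances) or a
#'   `flim_feature_table`.
#' @param ... unused.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict.flim_ann <- function(object, features, ...) {
  if (inherits(features, "flim_feature_table")) {
    features <- as.matrix(features[feature_names(features)])
  }
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != object$n_inputs) {
    stop_value(sprintf("feature length %d does not match network input size %d",
                       ncol(features), object$n_inputs))
  }
  if (!is.null(object$stats)) {
    features <- sweep(sweep(features, 2, object$stats$mean), 2,
                      object$stats$sd, `/`)
  }
  forward_pass(object, features)$o
}

#' @export
predict.flim_ann_fit <- function(object, features, ...) {
  predict(object$net, features, ...)
}

#' Train the network on a labeled feature table
#'
#' Full-batch Levenberg-Marquardt with Bayesian regularization (the
#' default) or a fixed weight penalty. Tables larger than `max_rows` are
#' subsampled once (seeded) for the LM normal equations; the reported MSEs
#' are always computed on the complete partitions. There is no early
#' stopping in Bayesian-regularization mode; the validation partition is
#' only reported.
#'
#' @param net a `flim_ann` from [init_network()], or `NULL` to initialize
#'   one matching the table (seeded with `seed`).
#' @param table a normalized `flim_feature_table` (see
#'   [normalize_features()]); pass the returned `stats` so they can be
#'   stored with the model.
#' @param split assignment tibble from [split_dataset()].
#' @param stats normalization statistics to embed in the model.
#' @param regularization `"bayes"` or `"fixed"`.
#' @param lambda weight penalty used when `regularization = "fixed"`.
#' @param max_epochs LM iteration cap.
#' @param max_rows subsample cap for the LM equations.
#' @param tol relative objective-change convergence tolerance.
#' @param seed RNG seed (subsampling and, if needed, initialization).
#' @return object of class `flim_ann_fit`: `net` (trained), `report`
#'   (one-row tibble with train/validation/test MSE — the test MSE is the
#'   held-out performance index — plus `alpha`, `beta`, `gamma`, epochs)
#'   and `history` (per-epoch objective trace).
#' @export
train_network <- function(net = NULL, table, split, stats = NULL,
                          regularization = c("bayes", "fixed"),
                          lambda = 1e-4, max_epochs = 100,
                          max_rows = 20000, tol = 1e-9, seed = 1L) {
  regularization <- match.arg(regularization)
  fn <- feature_names(table)
  if (is.null(fn)) stop_value("`table` must be a flim_feature_table")
  if (is.null(net)) {
    net <- init_network(length(fn), seed = seed)
  }
  if (length(fn) != net$n_inputs) {
    stop_value(sprintf("table has %d features but network expects %d",
                       length(fn), net$n_inputs))
  }
  X <- as.matrix(table[fn])
  y <- as.numeric(table$label)
  if (anyNA(y)) stop_value("table has unlabeled rows")
  parts <- split(seq_len(nrow(table)), split$split)
  if (length(parts$train) == 0) stop_value("empty training partition")
  if (length(parts$test) == 0) stop_value("empty test partition")

  tr <- parts$train
  if (length(tr) > max_rows) {
    tr <- withr::with_seed(seed, sample(tr, max_rows))
  }
  Xtr <- X[tr, , drop = FALSE]
  ytr <- y[tr]
  n <- length(ytr)
  Nw <- n_weights(net)

  w <- weights_to_vec(net)
  alpha <- if (regularization == "bayes") 0.01 else lambda
  beta <- 1
  mu <- 5e-3
  gamma <- Nw

  objective <- function(wv) {
    o <- forward_pass(vec_to_weights(net, wv), Xtr)$o
    e <- o - ytr
    list(Ed = 0.5 * sum(e^2), Ew = 0.5 * sum(wv^2), e = e, o = o)
  }

  cur <- objective(w)
  if (!is.finite(cur$Ed)) rlang::abort("non-finite loss at initialization",
                                       class = "flimglia_error_value")
  Fcur <- beta * cur$Ed + alpha * cur$Ew
  history <- numeric(0)
  epoch <- 0

  for (epoch in seq_len(max_epochs)) {
    netc <- vec_to_weights(net, w)
    fp <- forward_pass(netc, Xtr)
    J <- output_jacobian(netc, Xtr, fp$Z, fp$o)
    e <- fp$o - ytr
    A <- beta * crossprod(J)
    g <- beta * as.vector(crossprod(J, e)) + alpha * w
    diag_A <- diag(A) + alpha

    accepted <- FALSE
    for (inner in 1:12) {
      H <- A
      diag(H) <- diag(A) + alpha + mu * pmax(diag_A, 1e-12)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) { mu <- mu * 10; next }
      wn <- w - step
      nxt <- objective(wn)
      if (!is.finite(nxt$Ed)) {
        rlang::abort("training diverged to a non-finite loss",
                     class = "flimglia_error_value")
      }
      Fn <- beta * nxt$Ed + alpha * nxt$Ew
      if (Fn <= Fcur) {
        rel <- (Fcur - Fn) / max(Fcur, 1e-300)
        w <- wn; cur <- nxt
        mu <- max(mu / 3, 1e-12)
        accepted <- TRUE
        if (regularization == "bayes") {
          Hfull <- beta * crossprod(J)   # curvature at the previous point;
          diag(Hfull) <- diag(Hfull) + alpha  # adequate for the evidence update
          trinv <- tryCatch(sum(diag(chol2inv(chol(Hfull)))),
                            error = function(e) NA_real_)
          if (is.finite(trinv)) {
            gamma <- min(max(Nw - alpha * trinv, 1e-3), Nw)
            alpha <- gamma / max(2 * cur$Ew, 1e-12)
            beta <- max(n - gamma, 1e-3) / max(2 * cur$Ed, 1e-12)
          }
        }
        Fcur <- beta * cur$Ed + alpha * cur$Ew
        history <- c(history, Fcur)
        if (rel < tol) attr(history, "converged") <- TRUE
        break
      }
      mu <- mu * 5
      if (mu > 1e12) break
    }
    if (!accepted || isTRUE(attr(history, "converged"))) break
  }

  net <- vec_to_weights(net, w)
  net$stats <- stats
  net$mode <- attr(table, "mode")

  mse_of <- function(rows) {
    if (length(rows) == 0) return(NA_real_)
    o <- forward_pass(net, X[rows, , drop = FALSE])$o
    mean((o - y[rows])^2)
  }
  report <- tibble::tibble(
    mse_train = mse_of(parts$train),
    mse_validation = mse_of(parts$validation),
    mse_test = mse_of(parts$test),
    alpha = alpha, beta = beta, gamma = gamma,
    epochs = epoch, n_train = length(parts$train),
    regularization = regularization, seed = as.integer(seed))

  structure(list(net = net, report = report, history = as.numeric(history)),
            class = "flim_ann_fit")
}

#' @export
print.flim_ann_fit <- function(x, ...) {
  r <- x$report
  cat(sprintf("<flim_ann_fit> %d-%d-1, %s regularization\n",
              x$net$n_inputs, x$net$n_hidden, r$regularization))
  cat(sprintf("  MSE train %.4g / validation %.4g / test %.4g (%d epochs)\n",
              r$mse_train, r$mse_validation, r$mse_test, r$epochs))
  invisible(x)
}

#' Save / load a trained network as JSON
#'
#' Weights and normalization statistics round-trip at full double
#' precision.
#'
#' @param object a `flim_ann` or `flim_ann_fit`.
#' @param path output JSON file.
#' @export
save_model <- function(object, path) {
  net <- if (inherits(object, "flim_ann_fit")) object$net else object
  stopifnot(inherits(net, "flim_ann"))
  payload <- list(
    version = MODEL_VERSION, n_inputs = net$n_inputs, n_hidden = net$n_hidden,
    W1 = as.vector(net$W1), b1 = net$b1, w2 = net$w2, b2 = net$b2,
    mode = net$mode,
    stats = if (!is.null(net$stats)) as.list(net$stats) else NULL)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `flim_ann`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_not_found(sprintf("no such file: %s", path))
  p <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) stop_format(sprintf("cannot parse model file: %s",
                                                        conditionMessage(e))))
  if (is.null(p$version) || !identical(as.character(p$version), MODEL_VERSION)) {
    stop_format(sprintf("model version '%s' does not match supported version '%s'",
                        p$version %||% "?", MODEL_VERSION))
  }
  net <- structure(
    list(n_inputs = as.integer(p$n_inputs), n_hidden = as.integer(p$n_hidden),
         W1 = matrix(p$W1, p$n_hidden, p$n_inputs), b1 = p$b1, w2 = p$w2,
         b2 = p$b2,
         stats = if (!is.null(p$stats)) tibble::as_tibble(p$stats) else NULL,
         mode = p$mode, version = MODEL_VERSION),
    class = "flim_ann")
  net
}
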