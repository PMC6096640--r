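#' Assemble a genomic-prediction training set
#'
#' Holds phenotype records with per-record error-variance weights alongside
#' the matching marker dosages. Weights encode heterogeneous error variance:
#' a record with weight w has residual variance sigma2_e / w, so w acts as a
#' number of effective replicates (trial records from later, better
#' replicated stages get larger weights).
#'
#' @param records Tibble/data frame with columns `id`, `year`, `stage`,
#'   `weight` (> 0) and `phenotype`.
#' @param geno Marker dosage matrix, one row per record.
#' @return A `gp_training` object.
#' @export
training_set <- function(records, geno) {
  records <- as_tibble(records)
  need <- c("id", "year", "stage", "weight", "phenotype")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("training records lack column(s): ",
                                 paste(miss, collapse = ", ")))
  if (!is.matrix(geno) || nrow(geno) != nrow(records)) {
    abort("geno must be a matrix with one row per record")
  }
  if (any(records$weight <= 0)) abort("record weights must be > 0")
  structure(list(records = records, geno = geno), class = "gp_training")
}

#' @export
print.gp_training <- function(x, ...) {
  cat(sprintf("<gp_training> %d records x %d markers, years %s-%s\n",
              nrow(x$records), ncol(x$geno),
              min(x$records$year), max(x$records$year)))
  invisible(x)
}

#' Number of records in a training set
#' @param ts A `gp_training`.
#' @export
n_records <- function(ts) nrow(ts$records)

#' Append new records to a training set
#'
#' Training sets are append-only; the model is retrained from the enlarged
#' set once per simulated year.
#'
#' @param ts A `gp_training`.
#' @param records New records (same columns as [training_set()]); may be
#'   empty.
#' @param geno Matching marker dosages, one row per new record.
#' @return The enlarged `gp_training`.
#' @export
update_training <- function(ts, records, geno) {
  if (is.null(records) || nrow(records) == 0L) return(ts)
  if (ncol(geno) != ncol(ts$geno)) {
    abort("marker dimension of new records does not match the training set")
  }
  add <- training_set(records, geno)
  structure(list(records = dplyr::bind_rows(ts$records, add$records),
                 geno = rbind(ts$geno, add$geno)),
            class = "gp_training")
}

#' Read / write a training set as CSV
#'
#' Layout: columns `id`, `year`, `stage`, `weight`, `phenotype`, followed by
#' one marker-dosage column per marker.
#'
#' @param ts A `gp_training`.
#' @param path File path.
#' @export
write_training_csv <- function(ts, path) {
  df <- data.frame(ts$records, ts$geno, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_training_csv
#' @export
read_training_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- c("id", "year", "stage", "weight", "phenotype")
  geno <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  training_set(df[, meta], geno)
}

#' Fit the ridge-regression genomic prediction model
#'
#' Weighted ridge regression (RR-BLUP) with heterogeneous error variance:
#' marker effects minimise sum_j w_j (y_j - mu - x_j beta)^2 + lambda
#' ||beta||^2 with lambda = sigma2_e / sigma2_beta. Unless `lambda` is
#' supplied, the variance ratio is estimated by REML via an
#' eigendecomposition of the weighted marker crossproduct and a
#' one-dimensional profile-likelihood optimisation. The intercept is the
#' sole fixed effect.
#'
#' @param ts A `gp_training`.
#' @param lambda Optional fixed ridge parameter; `NULL` (default) estimates
#'   it by REML.
#' @param interval Search interval for log(lambda) in the REML step.
#' @return A `gp_model` with fields `intercept`, `effects`,
#'   `variance_components` (marker-effect and residual variances), `lambda`.
#' @export
train_gp <- function(ts, lambda = NULL, interval = c(-15, 25)) {
  y <- ts$records$phenotype
  w <- ts$records$weight
  n <- length(y)
  m <- ncol(ts$geno)
  if (n < 2 || m < 1) {
    abort("training needs >= 2 records and >= 1 marker",
          class = "twopartsim_estimation_failure")
  }
  if (stats::sd(y) < 1e-12) {
    abort("all phenotypes identical: cannot estimate the model",
          class = "twopartsim_estimation_failure")
  }
  sw <- sqrt(w)
  yt <- sw * y
  X <- ts$geno * sw          # row-scaled: sqrt(W) %*% M
  G <- crossprod(X)
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  Zy <- crossprod(X, yt)
  Zx <- crossprod(X, sw)
  py <- crossprod(U, Zy)     # U' X' ytilde
  px <- crossprod(U, Zx)     # U' X' xtilde
  yy <- sum(yt^2)
  xx <- sum(w)
  xy <- sum(w * y)

  # v' H^-1 u with H = XX'/lambda + I, via the eigenpairs of G = X'X
  quad <- function(vu, pv, pu, lam) vu - sum(pv * pu / (d + lam))
  reml_nll <- function(loglam) {
    lam <- exp(loglam)
    yHy <- quad(yy, py, py, lam)
    xHx <- quad(xx, px, px, lam)
    xHy <- quad(xy, px, py, lam)
    rss <- yHy - xHy^2 / xHx
    rss <- max(rss, 1e-300)
    logdetH <- sum(log1p(d / lam))
    (n - 1) * log(rss / (n - 1)) + logdetH + log(xHx)
  }
  if (is.null(lambda)) {
    opt <- optimize(reml_nll, interval = interval, tol = 1e-8)
    lambda <- exp(opt$minimum)
  }
  xHx <- quad(xx, px, px, lambda)
  xHy <- quad(xy, px, py, lambda)
  mu <- xHy / xHx
  yHy <- quad(yy, py, py, lambda)
  sigma2_e <- max(yHy - xHy^2 / xHx, 0) / (n - 1)
  beta <- as.numeric(U %*% ((crossprod(U, Zy - mu * Zx)) / (d + lambda)))
  ids <- colnames(ts$geno) %||% sprintf("M%04d", seq_len(m))
  structure(
    list(intercept = mu,
         effects = setNames(beta, ids),
         variance_components = c(marker = sigma2_e / lambda, residual = sigma2_e),
         lambda = lambda, n_records = n),
    class = "gp_model"
  )
}

#' @export
print.gp_model <- function(x, ...) {
  cat(sprintf("<gp_model> %d markers, lambda = %.4g, sigma2 = (marker %.4g, residual %.4g)\n",
              length(x$effects), x$lambda,
              x$variance_components["marker"], x$variance_components["residual"]))
  invisible(x)
}

#' Genomic estimated breeding values
#'
#' GEBV = intercept + dosage %*% marker effects.
#'
#' @param object A `gp_model`.
#' @param newdata A `haplo_pop` (marker loci are used) or a dosage matrix
#'   whose columns match the model's markers.
#' @param ... Unused.
#' @return A tibble with columns `id` and `gebv`.
#' @export
predict.gp_model <- function(object, newdata, ...) {
  d <- if (inherits(newdata, "haplo_pop")) marker_dosages(newdata) else newdata
  if (ncol(d) != length(object$effects)) {
    abort("marker set of newdata does not match the model")
  }
  if (!is.null(colnames(d)) &&
      !identical(colnames(d), names(object$effects))) {
    abort("marker ids of newdata do not match the model")
  }
  tibble(id = rownames(d) %||% sprintf("ind%04d", seq_len(nrow(d))),
         gebv = as.numeric(object$intercept + d %*% object$effects))
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and true genetic values. With a
#' constant input vector the accuracy is undefined and reported as `NA`
#' rather than 0.
#'
#' @param gebv,true Numeric vectors of equal length (>= 3).
#' @return Correlation in \[-1, 1\], or `NA_real_` when undefined.
#' @export
gp_accuracy <- function(gebv, true) {
  if (length(gebv) != length(true) || length(gebv) < 3) {
    abort("accuracy needs >= 3 matched pairs")
  }
  if (stats::sd(gebv) < 1e-12 || stats::sd(true) < 1e-12) return(NA_real_)
  cor(gebv, true)
}
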