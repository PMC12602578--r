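#' Batch harmonization of radiomic feature tables
#'
#' Scanner/site batch effects — location and scale differences per feature
#' that carry no biology — are removed either by parametric empirical-Bayes
#' ComBat or by a Limma-style linear-model residualization on batch. Both are
#' implemented natively over the `feature_table` container; the fitted
#' per-(batch, feature) adjustments are returned so held-out samples can be
#' transformed without re-estimation ([apply_harmonization()]).
#'
#' @name harmonization
NULL

row_vars <- function(m) {
  n <- ncol(m)
  (rowSums(m^2) - n * rowMeans(m)^2) / (n - 1)
}

check_batches <- function(table) {
  batch <- factor(table$sample_meta$batch)
  counts <- table(batch)
  if (any(counts < 2))
    stop("batch(es) with a single sample: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  batch
}

protect_matrix <- function(table, protect) {
  if (is.null(protect) || !length(protect)) return(NULL)
  miss <- setdiff(protect, names(table$sample_meta))
  if (length(miss))
    stop("protect column(s) absent from sample_meta: ",
         paste(miss, collapse = ", "))
  m <- as.matrix(table$sample_meta[, protect, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Parametric empirical-Bayes (ComBat) harmonization
#'
#' Standard parametric ComBat: each feature is standardized by its grand mean
#' and pooled SD, per-batch location (gamma) and scale (delta) effects are
#' estimated, shrunk toward method-of-moments empirical-Bayes hyperpriors
#' (normal on location, inverse-gamma on scale) by iterated conditional
#' posterior means, and the standardized data are adjusted by the shrunken
#' estimates and back-transformed.
#'
#' @param table a `feature_table` with a `batch` column; at least two batches
#'   of at least two samples each (a single batch returns the input unchanged
#'   with a warning).
#' @param protect optional character vector of `sample_meta` columns whose
#'   (linear) effects are preserved during standardization, e.g. outcome or
#'   clinical covariates.
#' @param conv relative convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return list with `table` (harmonized) and `model` (a
#'   `harmonization_model` usable with [apply_harmonization()]).
#' @export
combat_fit_transform <- function(table, protect = NULL, conv = 1e-4,
                                 max_iter = 100) {
  batch <- factor(table$sample_meta$batch)
  if (nlevels(batch) < 2) {
    warning("single batch: ComBat is an identity transform")
    model <- structure(list(method = "none", batch_levels = levels(batch)),
                       class = "harmonization_model")
    return(list(table = table, model = model))
  }
  batch <- check_batches(table)
  dat <- t(table$values)                      # features x samples
  n_array <- ncol(dat)
  batch_design <- stats::model.matrix(~ -1 + batch)
  n_batches <- colSums(batch_design)
  mod <- protect_matrix(table, protect)
  design <- cbind(batch_design, mod)

  ## standardization
  b_hat <- solve(crossprod(design), t(design) %*% t(dat))
  grand_mean <- drop(crossprod(n_batches / n_array,
                               b_hat[seq_len(nlevels(batch)), , drop = FALSE]))
  fitted_all <- t(design %*% b_hat)
  var_pooled <- rowMeans((dat - fitted_all)^2)

  ## features that cannot be standardized/adjusted pass through unchanged
  within_const <- rep(FALSE, nrow(dat))
  for (b in levels(batch)) {
    sub <- dat[, batch == b, drop = FALSE]
    within_const <- within_const | (row_vars(sub) <
                                      .Machine$double.eps * 100)
  }
  skip <- within_const | var_pooled < .Machine$double.eps * 100
  if (any(skip))
    message(sum(skip), " feature(s) constant within a batch: ",
            "passed through unadjusted")

  stand_mean <- matrix(grand_mean, nrow(dat), n_array)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(nlevels(batch))] <- 0
    stand_mean <- stand_mean + t(tmp %*% b_hat)
  }
  s_data <- (dat - stand_mean) / sqrt(var_pooled)

  nb <- nlevels(batch)
  p <- nrow(dat)
  gamma_hat <- matrix(NA_real_, nb, p)
  delta_hat <- matrix(NA_real_, nb, p)
  for (i in seq_len(nb)) {
    sub <- s_data[, batch == levels(batch)[i], drop = FALSE]
    gamma_hat[i, ] <- rowMeans(sub)
    delta_hat[i, ] <- row_vars(sub)
  }
  adj <- which(!skip)
  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    g_hat <- gamma_hat[i, adj]
    d_hat <- delta_hat[i, adj]
    g_bar <- mean(g_hat)
    t2 <- stats::var(g_hat)
    m <- mean(d_hat)
    s2 <- stats::var(d_hat)
    if (length(adj) < 2 || !is.finite(t2) || t2 <= 0 ||
        !is.finite(s2) || s2 <= 0) {
      # hyperpriors are not estimable: fall back to the unshrunken estimates
      gamma_star[i, adj] <- g_hat
      delta_star[i, adj] <- d_hat
      next
    }
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    sub <- s_data[adj, batch == levels(batch)[i], drop = FALSE]
    n_b <- ncol(sub)
    g_old <- g_hat
    d_old <- d_hat
    for (iter in seq_len(max_iter)) {
      g_new <- (n_b * t2 * g_hat + d_old * g_bar) / (n_b * t2 + d_old)
      sum2 <- rowSums((sub - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior) / (n_b / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / abs(g_old),
                    abs(d_new - d_old) / abs(d_old))
      g_old <- g_new
      d_old <- d_new
      if (change < conv) break
    }
    gamma_star[i, adj] <- g_old
    delta_star[i, adj] <- d_old
  }

  bayes <- s_data
  for (i in seq_len(nb)) {
    sel <- batch == levels(batch)[i]
    bayes[adj, sel] <- (s_data[adj, sel, drop = FALSE] - gamma_star[i, adj]) /
      sqrt(delta_star[i, adj])
  }
  out <- bayes * sqrt(var_pooled) + stand_mean
  out[skip, ] <- dat[skip, ]

  dimnames(gamma_star) <- dimnames(delta_star) <-
    list(levels(batch), rownames(dat))
  model <- structure(
    list(method = "combat", batch_levels = levels(batch),
         feature_ids = rownames(dat), grand_mean = grand_mean,
         var_pooled = var_pooled, gamma_star = gamma_star,
         delta_star = delta_star, skip = skip, protect = protect,
         mod_coef = if (!is.null(mod))
           b_hat[-seq_len(nlevels(batch)), , drop = FALSE]),
    class = "harmonization_model")
  new_table <- table
  new_table$values <- t(out)
  list(table = new_table, model = model)
}

#' Linear-model (Limma-style) batch-effect removal
#'
#' Per feature, ordinary least squares of the value on batch indicators
#' (plus any protected covariates); the batch component, centered over the
#' samples, is subtracted, so batch means are equalized while the overall
#' feature mean is preserved exactly.
#'
#' @inheritParams combat_fit_transform
#' @return list with `table` and `model`, as for [combat_fit_transform()].
#' @export
limma_fit_transform <- function(table, protect = NULL) {
  batch <- factor(table$sample_meta$batch)
  if (nlevels(batch) < 2) {
    warning("single batch: nothing to harmonize")
    model <- structure(list(method = "none", batch_levels = levels(batch)),
                       class = "harmonization_model")
    return(list(table = table, model = model))
  }
  batch <- check_batches(table)
  y <- table$values                          # samples x features
  mod <- protect_matrix(table, protect)
  design <- cbind(stats::model.matrix(~ -1 + batch), mod)
  fit <- stats::lm.fit(design, y)
  coefs <- fit$coefficients
  if (is.null(dim(coefs))) coefs <- matrix(coefs, ncol = 1)
  nb <- nlevels(batch)
  batch_coef <- coefs[seq_len(nb), , drop = FALSE]    # nb x p batch means
  n_b <- as.numeric(table(batch))
  wmean <- drop(crossprod(n_b / sum(n_b), batch_coef)) # weighted batch means
  offsets <- sweep(batch_coef, 2, wmean)               # nb x p, mean-zero
  dimnames(offsets) <- list(levels(batch), colnames(y))
  out <- y - offsets[as.integer(batch), , drop = FALSE]
  model <- structure(
    list(method = "limma", batch_levels = levels(batch),
         feature_ids = colnames(y), offsets = offsets, protect = protect),
    class = "harmonization_model")
  new_table <- table
  new_table$values <- out
  list(table = new_table, model = model)
}

#' Fit a harmonization model by name
#'
#' @param table a `feature_table`.
#' @param method `"none"`, `"combat"` or `"limma"`.
#' @param protect optional protected covariate columns.
#' @return list with `table` and `model`.
#' @export
harmonize <- function(table, method = c("none", "combat", "limma"),
                      protect = NULL) {
  method <- match.arg(method)
  switch(method,
         none = list(table = table,
                     model = structure(list(method = "none",
                                            batch_levels =
                                              unique(table$sample_meta$batch)),
                                       class = "harmonization_model")),
         combat = combat_fit_transform(table, protect = protect),
         limma = limma_fit_transform(table, protect = protect))
}

#' Apply a fitted harmonization model to new samples
#'
#' Uses the stored per-(batch, feature) adjustments without re-estimation —
#' the leakage-safe path for held-out data. Every batch present in `table`
#' must have been seen at fit time.
#'
#' @param model a `harmonization_model`.
#' @param table a `feature_table` on the fitted feature set.
#' @return the harmonized `feature_table`.
#' @export
apply_harmonization <- function(model, table) {
  stopifnot(inherits(model, "harmonization_model"))
  if (model$method == "none") return(table)
  unseen <- setdiff(unique(as.character(table$sample_meta$batch)),
                    model$batch_levels)
  if (length(unseen))
    stop("batch(es) not seen at fit time: ", paste(unseen, collapse = ", "))
  if (!identical(colnames(table$values), model$feature_ids))
    stop("feature set differs from the fitted model")
  bidx <- match(as.character(table$sample_meta$batch), model$batch_levels)
  out <- table
  if (model$method == "limma") {
    out$values <- table$values -
      model$offsets[bidx, , drop = FALSE]
    return(out)
  }
  ## combat
  dat <- t(table$values)
  stand_mean <- matrix(model$grand_mean, nrow(dat), ncol(dat))
  if (!is.null(model$protect)) {
    mod <- protect_matrix(table, model$protect)
    stand_mean <- stand_mean + t(mod %*% model$mod_coef)
  }
  s_data <- (dat - stand_mean) / sqrt(model$var_pooled)
  adj <- which(!model$skip)
  bayes <- s_data
  for (i in seq_along(model$batch_levels)) {
    sel <- bidx == i
    if (!any(sel)) next
    bayes[adj, sel] <- (s_data[adj, sel, drop = FALSE] -
                          model$gamma_star[i, adj]) /
      sqrt(model$delta_star[i, adj])
  }
  res <- bayes * sqrt(model$var_pooled) + stand_mean
  res[model$skip, ] <- dat[model$skip, ]
  out$values <- t(res)
  out
}
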